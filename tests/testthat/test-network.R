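test_that("network edges require strictly super-threshold magnitude", {
  taxa <- paste0("t", 1:5)
  rho <- corr_fixture(taxa, data.frame(
    i = c("t1", "t1", "t2"), j = c("t2", "t3", "t4"),
    rho = c(0.76, 0.75, -0.8)))
  net <- build_network(rho, 0.75)
  g <- net$graph
  expect_setequal(igraph::V(g)$name, c("t1", "t2", "t4"))  # t5 isolate dropped
  el <- igraph::as_edgelist(g)
  expect_equal(nrow(el), 2)                                # 0.75 exactly: no edge
  eid <- igraph::get_edge_ids(g, c("t2", "t4"))
  expect_equal(igraph::E(g)$sign[eid], -1L)
  expect_equal(igraph::E(g)$weight[eid], -0.8)
  expect_error(build_network(rho, 1.2), "threshold")
})

test_that("edge sets nest across thresholds and core is a subset", {
  set.seed(61)
  p <- 10
  m <- matrix(runif(p * p, -1, 1), p)
  rho <- (m + t(m)) / 2; diag(rho) <- 1
  dimnames(rho) <- list(paste0("t", 1:p), paste0("t", 1:p))
  key <- function(net) apply(igraph::as_edgelist(net$graph), 1,
                             function(r) paste(sort(r), collapse = "|"))
  e50 <- key(build_network(rho, 0.50))
  e75 <- key(build_network(rho, 0.75))
  core <- key(core_network(rho))
  expect_true(all(e75 %in% e50))
  expect_true(all(core %in% e75))
})

test_that("topology summary matches hand-computed values", {
  tri <- edge_net(cbind(c("a", "b", "c"), c("b", "c", "a")))
  t1 <- topology_summary(tri)
  expect_equal(t1$n_nodes, 3); expect_equal(t1$n_edges, 3)
  expect_equal(t1$avg_degree, 2)
  expect_equal(t1$clustering_coefficient, 1)
  expect_equal(t1$diameter, 1)
  expect_equal(t1$n_modules, 1)

  pa <- make_fixture_graph("path", 5)
  t2 <- topology_summary(pa)
  expect_equal(t2$diameter, 4)
  expect_equal(t2$clustering_coefficient, 0)

  two_tri <- edge_net(cbind(c("a", "b", "c", "x", "y", "z"),
                            c("b", "c", "a", "y", "z", "x")))
  t3 <- topology_summary(two_tri)
  expect_equal(t3$modularity, 0.5)        # Newman Q for two equal cliques
  expect_equal(t3$n_modules, 2)
  expect_equal(t3$n_edges, t3$n_positive + t3$n_negative)
})

test_that("topology metrics match brute-force oracles on small graphs", {
  graphs <- atlas_connected()
  set.seed(62)
  for (g in sample(graphs, 60)) {
    igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
    net <- as_conetwork(g)
    topo <- topology_summary(net)
    adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) > 0
    n <- nrow(adj)
    # BFS diameter by boolean matrix powers
    dist <- matrix(Inf, n, n); diag(dist) <- 0
    reach <- diag(n) == 1
    step <- 0
    repeat {
      step <- step + 1
      nxt <- (reach %*% adj > 0) | reach
      newly <- nxt & !reach
      if (!any(newly)) break
      dist[newly] <- step
      reach <- nxt
    }
    expect_equal(topo$diameter, max(dist[is.finite(dist)]))
    # local clustering by triple counting
    cl <- vapply(seq_len(n), function(i) {
      nb <- which(adj[i, ])
      k <- length(nb)
      if (k < 2) return(0)
      sum(adj[nb, nb]) / (k * (k - 1))
    }, numeric(1))
    expect_equal(topo$clustering_coefficient, mean(cl), tolerance = 1e-12)
  }
})

test_that("eigenvector centrality matches closed forms and igraph", {
  k4 <- make_fixture_graph("complete", 4)
  expect_equal(unname(eigenvector_centrality(k4)), rep(1, 4))
  st <- make_fixture_graph("star", 5)
  ec <- eigenvector_centrality(st)
  hub <- names(which.max(igraph::degree(st$graph)))
  expect_equal(unname(ec[hub]), 1)
  expect_equal(unname(ec[setdiff(names(ec), hub)]), rep(0.5, 4),
               tolerance = 1e-8)
  p3 <- make_fixture_graph("path", 3)
  ec3 <- sort(eigenvector_centrality(p3))
  expect_equal(unname(ec3), c(1 / sqrt(2), 1 / sqrt(2), 1), tolerance = 1e-8)
  # cross-check a weighted random graph against igraph's implementation
  set.seed(63)
  g <- igraph::sample_gnp(15, 0.3)
  igraph::V(g)$name <- paste0("v", 1:15)
  igraph::E(g)$weight <- runif(igraph::ecount(g), 0.5, 1)
  mine <- eigenvector_centrality(as_conetwork(g))
  ref <- igraph::eigen_centrality(g, weights = abs(igraph::E(g)$weight))$vector
  expect_equal(unname(mine), unname(ref[names(mine)]), tolerance = 1e-6)
})

test_that("ubiquity is presence in every sample of the condition", {
  cts <- rbind(c(1L, 1L, 0L), c(2L, 0L, 0L), c(3L, 5L, 1L), c(1L, 2L, 1L))
  colnames(cts) <- c("a", "b", "c")
  tab <- tiny_table(cts, groups = c("g1", "g1", "g2", "g2"))
  expect_setequal(ubiquity(tab, "g1"), "a")       # b zero in exactly one sample
  expect_setequal(ubiquity(tab, "g2"), c("a", "b", "c"))
  one <- tiny_table(matrix(c(1L, 0L), 1, 2), groups = "solo")
  expect_equal(length(ubiquity(one, "solo")), 1)  # single sample: its presence set
  expect_error(ubiquity(tab, "nope"), "unknown group")
})

test_that("keystone taxa are the triple intersection, cutoffs inclusive", {
  # star network: hub eigenvector 1, leaves 0.5 -> only the hub passes (ii)
  taxa <- c("hub", paste0("leaf", 1:4), "off")
  rho <- corr_fixture(taxa, data.frame(
    i = "hub", j = paste0("leaf", 1:4), rho = 0.9))
  net <- build_network(rho, 0.75)
  # counts: hub ubiquitous & abundant; leaf1 non-ubiquitous; others low clr
  cts <- matrix(20L, 6, 6, dimnames = list(sprintf("s%d", 1:6), taxa))
  cts[, "hub"] <- 400L
  cts[1, "leaf1"] <- 0L
  tab <- tiny_table(cts, groups = "g")
  clr <- clr_transform(tab)
  ks <- keystone_taxa(net, clr, tab, "g")
  expect_true(ks$is_keystone[ks$taxon == "hub"])
  expect_false(any(ks$is_keystone[ks$taxon != "hub"]))
  # independent set construction: triple intersection
  eig <- eigenvector_centrality(net)
  trip <- intersect(intersect(names(eig)[eig >= 0.75], ubiquity(tab, "g")),
                    colnames(clr)[colMeans(clr) >= 0.35])
  expect_setequal(ks$taxon[ks$is_keystone], intersect(trip, ks$taxon))
})

test_that("keystone cutoffs pass at exactly 0.35 and 0.75", {
  net <- edge_net(cbind(c("a", "a"), c("b", "c")))
  ks_fake <- data.frame(taxon = c("a", "b"),
                        mean_clr = c(0.35, 0.349999),
                        eigenvector = c(0.75, 0.75),
                        ubiquitous = TRUE)
  dec <- with(ks_fake, ubiquitous & mean_clr >= 0.35 & eigenvector >= 0.75)
  expect_equal(dec, c(TRUE, FALSE))
})

test_that("network export produces parseable GraphML and GEXF", {
  net <- make_fixture_graph("star", 4)
  gml <- withr::local_tempfile(fileext = ".graphml")
  gexf <- withr::local_tempfile(fileext = ".gexf")
  write_network(net, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), 4)
  expect_equal(igraph::ecount(back), 3)
  write_network(net, gexf, format = "gexf")
  txt <- readLines(gexf)
  expect_true(any(grepl("<gexf", txt)))
  expect_equal(sum(grepl("<edge ", txt)), 3)
  expect_equal(sum(grepl("<node ", txt)), 4)
})
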