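test_that("connectivity loss counts ordered reachable pairs", {
  p3 <- edge_net(cbind(c("A", "B"), c("B", "C")))
  expect_equal(connectivity_loss(p3, character()), 0)
  expect_equal(connectivity_loss(p3, c("A", "B", "C")), 1)
  expect_equal(connectivity_loss(p3, "A"), 2 / 3)   # R0 = 6, survivors B-C: R = 2
  expect_error(connectivity_loss(p3, "Z"), "not in graph")
})

test_that("connectivity loss matches the brute-force oracle on random graphs", {
  set.seed(71)
  for (rep in 1:25) {
    n <- sample(4:9, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.2, 0.7))
    igraph::V(g)$name <- paste0("v", seq_len(n))
    net <- as_conetwork(g)
    adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) > 0
    r0 <- oracle_reachable_pairs(adj)
    if (r0 == 0) next
    removed <- sample(igraph::V(g)$name, sample(0:(n - 1), 1))
    keep <- !(igraph::V(g)$name %in% removed)
    expected <- 1 - oracle_reachable_pairs(adj[keep, keep, drop = FALSE]) / r0
    expect_equal(connectivity_loss(net, removed), expected)
  }
})

test_that("degree attack on a star removes the hub first", {
  st <- make_fixture_graph("star", 5)
  a <- attack(st, "degree")
  hub <- names(which.max(igraph::degree(st$graph)))
  expect_equal(a$removal_order[1], hub)
  expect_equal(a$loss_at_step[1], 1)
  expect_equal(a$fraction_at_target, 0.2)
})

test_that("complete-graph attacks follow the closed form for any strategy", {
  k5 <- make_fixture_graph("complete", 5)
  for (st in c("random", "degree", "betweenness", "cascading")) {
    a <- attack(k5, st, seed = 5)
    expect_equal(a$loss_at_step, 1 - (5 - 1:5) * (4 - 1:5) / 20)
    expect_equal(a$fraction_at_target, 0.6)
  }
})

test_that("loss sequences are non-decreasing for every strategy", {
  set.seed(72)
  for (rep in 1:10) {
    g <- igraph::sample_gnp(sample(6:14, 1), runif(1, 0.2, 0.6))
    if (igraph::ecount(g) == 0) next
    igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
    net <- as_conetwork(g)
    for (st in c("random", "degree", "betweenness", "cascading")) {
      a <- attack(net, st, seed = rep)
      expect_true(all(diff(a$loss_at_step) >= -1e-12))
      expect_equal(a$loss_at_step[length(a$loss_at_step)], 1)
    }
  }
})

test_that("random-attack bootstrap CI behaves on symmetric and star graphs", {
  k5 <- make_fixture_graph("complete", 5)
  ci <- random_attack_ci(k5, n_boot = 20, seed = 1)
  expect_equal(ci$mean, 0.6)
  expect_equal(ci$ci_low, 0.6); expect_equal(ci$ci_high, 0.6)

  st <- make_fixture_graph("star", 5)
  ci2 <- random_attack_ci(st, n_boot = 100, seed = 2)
  expect_gt(ci2$mean, 0.2)     # random rarely hits the hub first
  expect_lte(ci2$ci_low, ci2$mean)
  expect_lte(ci2$mean, ci2$ci_high)
  expect_error(random_attack_ci(st, n_boot = 1), "n_boot")
})

test_that("average path length matches pair enumeration", {
  expect_equal(apl(make_fixture_graph("complete", 6)), 1)
  expect_equal(apl(make_fixture_graph("path", 3)), 4 / 3)
  two_edges <- edge_net(cbind(c("a", "c"), c("b", "d")))
  expect_equal(apl(two_edges), 1)            # only within-edge pairs reachable
  lone <- edge_net(matrix(character(0), 0, 2), nodes = c("a", "b"))
  expect_true(is.nan(apl(lone)))
})

test_that("node addition grows the LCC one node at a time on connected graphs", {
  k4 <- make_fixture_graph("complete", 4)
  res <- add_nodes(k4, 25, seed = 3)
  expect_equal(res$trace$lcc, 4 + 1:25)
  expect_equal(igraph::vcount(res$network$graph), 29)
  expect_true(all(diff(res$trace$lcc) >= 0))
  expect_true(all(res$trace$apl > 0))

  z <- add_nodes(k4, 0, seed = 4)
  expect_equal(nrow(z$trace), 0)
  expect_equal(igraph::vcount(z$network$graph), 4)

  ab <- edge_net(cbind("A", "B"))
  grown <- add_nodes(ab, 1, seed = 5)        # attaches to A or B: path of 3
  expect_equal(grown$trace$apl, 4 / 3)
  expect_error(add_nodes(ab, 1, attach_edges = 3), "attach_edges")
})

test_that("preferential attachment favours high-degree targets", {
  st <- make_fixture_graph("star", 9)
  hub <- names(which.max(igraph::degree(st$graph)))
  hits <- vapply(1:50, function(s) {
    res <- add_nodes(st, 1, rule = "preferential", seed = s)
    igraph::are_adjacent(res$network$graph, "added_0001", hub)
  }, logical(1))
  expect_gt(mean(hits), 0.3)   # uniform would hit the hub ~1/9 of the time
})

test_that("signed-rank p-values match exact enumeration", {
  expect_equal(signed_rank_p(c(1, 2, 3, 4, 5, 6)), 2 / 64, tolerance = 1e-12)
  expect_equal(signed_rank_p(rep(0, 8)), 1)
  # cross-check small random vectors against stats::wilcox.test directly
  set.seed(73)
  for (rep in 1:10) {
    d <- sample(c(-9:-1, 1:9), 7)
    ref <- suppressWarnings(wilcox.test(d, mu = 0, exact = TRUE)$p.value)
    expect_equal(signed_rank_p(d), ref)
  }
})

test_that("addition statistics test final-minus-baseline differences with BH", {
  k4 <- make_fixture_graph("complete", 4)
  traces <- list()
  for (k in c(5, 10))
    traces[[as.character(k)]] <- lapply(1:6, function(r)
      add_nodes(k4, k, seed = 100 * k + r))
  st <- addition_stats(traces, k4)
  expect_equal(nrow(st), 4)               # 2 k-values x 2 metrics
  lcc5 <- st[st$k == 5 & st$metric == "lcc", ]
  expect_equal(lcc5$diff_mean, 5)         # deterministic growth on connected nets
  expect_lt(lcc5$p, 0.05)                 # tied +5 differences: approx p, still small
  expect_true(all(st$q >= st$p))
  expect_equal(st$q, oracle_bh(st$p), tolerance = 1e-12)
  expect_error(addition_stats(list("5" = traces[["5"]][1:3]), k4),
               "at least 5 replicates")
})

test_that("denser networks resist cascading attack at least as long", {
  set.seed(74)
  wins <- 0L
  for (trial in 1:10) {
    g <- igraph::sample_gnp(40, 0.25)
    while (!igraph::is_connected(g)) g <- igraph::sample_gnp(40, 0.25)
    igraph::V(g)$name <- sprintf("v%02d", 1:40)
    keep <- sample(igraph::ecount(g), floor(igraph::ecount(g) * 0.5))
    sparse <- igraph::subgraph_from_edges(g, keep, delete.vertices = FALSE)
    fd <- attack(as_conetwork(g), "cascading")$fraction_at_target
    fs <- attack(as_conetwork(sparse), "cascading")$fraction_at_target
    if (fd >= fs) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("the robustness battery reports four removal rows per network", {
  nets <- list(a = make_fixture_graph("erdos_renyi", 25, 0.25, seed = 8),
               b = make_fixture_graph("barabasi_albert", 25, 2, seed = 9))
  rob <- robustness_battery(nets, n_boot = 10, k_add = c(5, 10), n_reps = 5,
                            seed = 10)
  expect_equal(nrow(rob$removal), 8)
  expect_equal(as.integer(table(rob$removal$network)), c(4L, 4L))
  expect_setequal(unique(rob$removal$strategy),
                  c("cascading", "betweenness", "degree", "random"))
  expect_equal(nrow(rob$addition_stats), 2 * 2 * 2)
  expect_true(all(rob$addition_traces$lcc >= 1))
})
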