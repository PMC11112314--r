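test_that("basis network plants a complete positive module when p_within = 1", {
  gt <- make_basis_network(5, 1, p_within = 1, p_between = 0, neg_frac = 0,
                           corr_strength = 0.6, seed = 1)
  expect_equal(nrow(gt$edges), 10)          # all C(5,2) pairs planted
  expect_true(all(gt$edges$sign == 1))
  expect_equal(unname(gt$module_of), rep(1L, 5))
  off <- gt$basis_corr[upper.tri(gt$basis_corr)]
  expect_true(all(abs(off - 0.6) < 1e-12))  # constant block is already PSD
})

test_that("basis network partitions taxa near-equally and respects module structure", {
  gt <- make_basis_network(30, 3, p_within = 0.4, p_between = 0.01,
                           neg_frac = 0.3, corr_strength = 0.8, seed = 7)
  expect_equal(as.integer(table(gt$module_of)), rep(10L, 3))
  # regenerating under the same seed is byte-identical
  gt2 <- make_basis_network(30, 3, p_within = 0.4, p_between = 0.01,
                            neg_frac = 0.3, corr_strength = 0.8, seed = 7)
  expect_identical(gt, gt2)
  same_mod <- gt$module_of[gt$edges$taxon_i] == gt$module_of[gt$edges$taxon_j]
  n_within <- sum(same_mod)
  # 135 within-module candidate pairs at p = 0.4: binomial 99.99% envelope
  expect_gt(n_within, 30); expect_lt(n_within, 80)
  expect_lt(sum(!same_mod), 10)             # 300 cross pairs at p = 0.01
  ev <- eigen(gt$basis_corr, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  expect_equal(unname(diag(gt$basis_corr)), rep(1, 30))
})

test_that("basis network rejects degenerate inputs", {
  expect_error(make_basis_network(3, 1, 1, 0), "below 4 taxa")
  expect_error(make_basis_network(5, 1, 1.2, 0), "probabilities")
  expect_error(make_basis_network(5, 9, 0.5, 0), "n_modules")
})

test_that("simulated counts reflect the planted correlation structure", {
  # identity basis: every basis log-abundance pair nearly uncorrelated
  gt0 <- make_basis_network(10, 1, p_within = 0, p_between = 0, seed = 1)
  tab0 <- simulate_counts(gt0, 300, depth = 5000, seed = 11)
  bl <- attr(tab0, "basis_log")
  cors <- cor(bl)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.2)

  # one planted pair at +0.9 shows up in the basis logs
  rho <- corr_fixture(sprintf("taxon_%02d", 1:4),
                      data.frame(i = "taxon_01", j = "taxon_02", rho = 0.9))
  gt1 <- list(taxa = rownames(rho), basis_corr = rho,
              module_of = setNames(rep(1L, 4), rownames(rho)),
              edges = data.frame(taxon_i = "taxon_01", taxon_j = "taxon_02",
                                 sign = 1L, target = 0.9))
  class(gt1) <- "ground_truth_network"
  tab1 <- simulate_counts(gt1, 500, depth = 5000, seed = 12)
  bl1 <- attr(tab1, "basis_log")
  expect_gte(cor(bl1[, 1], bl1[, 2]), 0.8)
})

test_that("zero depth dispersion gives exactly constant totals", {
  gt <- make_basis_network(6, 2, 0.5, 0.1, seed = 2)
  tab <- simulate_counts(gt, 10, depth = 1234, depth_dispersion = 0, seed = 3)
  expect_true(all(rowSums(tab$counts) == 1234))
  tab2 <- simulate_counts(gt, 10, depth = 1234, depth_dispersion = 0, seed = 3)
  expect_identical(tab$counts, tab2$counts)
  expect_error(simulate_counts(gt, 1, depth = 100), "n_samples")
})

test_that("non-PSD basis matrices are rejected by the count simulator", {
  bad <- corr_fixture(sprintf("t%d", 1:4),
                      data.frame(i = c("t1", "t1", "t2"), j = c("t2", "t3", "t3"),
                                 rho = c(0.9, 0.9, -0.9)))
  gt <- list(taxa = rownames(bad), basis_corr = bad,
             module_of = setNames(rep(1L, 4), rownames(bad)),
             edges = data.frame())
  class(gt) <- "ground_truth_network"
  expect_error(simulate_counts(gt, 10), "positive semidefinite")
})

test_that("contaminant spiking creates flaggable taxa and honest controls", {
  tab <- random_table(20, 8, lambda = 100, seed = 5)
  # no contaminants: true-sample counts untouched
  same <- spike_contaminants(tab, 0, 2, seed = 6)
  expect_identical(same$counts[1:20, colnames(tab$counts)], tab$counts)
  expect_equal(sum(same$metadata$is_control), 2)

  spiked <- spike_contaminants(tab, 2, 4, prevalence_in_controls = 1.0,
                               prevalence_in_samples = 0.05, seed = 7)
  contam <- attr(spiked, "contaminants")
  expect_length(contam, 2)
  flagged <- flag_contaminants(spiked, 0.1)
  expect_true(all(contam %in% flagged))
  # contaminants stay low-abundance in true samples (reagent carry-over)
  true_rows <- !spiked$metadata$is_control
  expect_true(all(spiked$counts[true_rows, contam] <= 20))

  expect_error(spike_contaminants(tab, 1, 0), "without negative-control")
})

test_that("fixture graphs have their defining shapes", {
  st <- make_fixture_graph("star", 5)
  deg <- sort(igraph::degree(st$graph))
  expect_equal(unname(deg), c(1, 1, 1, 1, 4))
  pa <- make_fixture_graph("path", 3)
  expect_equal(igraph::ecount(pa$graph), 2)
  expect_equal(igraph::diameter(pa$graph), 2)
  ba <- make_fixture_graph("barabasi_albert", 200, param = 2, seed = 3)
  expect_equal(igraph::vcount(ba$graph), 200)
  expect_equal(igraph::ecount(ba$graph), 396)   # m * (n - m)
  bb <- make_fixture_graph("barbell", 11, param = 4)
  expect_equal(igraph::vcount(bb$graph), 11)
  expect_equal(igraph::ecount(bb$graph), 2 * choose(4, 2) + 4)
  expect_error(make_fixture_graph("moebius", 5), "unknown fixture")
})

test_that("ground truth round-trips through JSON", {
  gt <- make_basis_network(8, 2, 0.5, 0.05, 0.2, 0.7, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(gt, path)
  back <- read_ground_truth(path)
  expect_equal(back$taxa, gt$taxa)
  expect_equal(back$basis_corr, gt$basis_corr, tolerance = 1e-12)
  expect_equal(back$module_of, gt$module_of)
  expect_equal(nrow(back$edges), nrow(gt$edges))
})
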