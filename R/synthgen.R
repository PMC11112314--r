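#' Plant a modular basis-correlation network
#'
#' Builds the ground truth that the synthetic count generator and the
#' correlation-recovery tests share: taxa are split into near-equal modules,
#' candidate taxon pairs are planted as edges with probability `p_within`
#' inside a module and `p_between` across modules, each planted edge is
#' assigned target correlation `+corr_strength` or `-corr_strength`
#' (negative with probability `neg_frac`), and the resulting target matrix
#' is projected to the nearest valid correlation matrix by eigenvalue
#' clipping at zero followed by rescaling to unit diagonal.
#'
#' @param n_taxa number of taxa (>= 4; SparCC's basis decomposition is not
#'   identifiable below 4 taxa).
#' @param n_modules number of modules to partition the taxa into.
#' @param p_within,p_between edge probabilities within / between modules.
#' @param neg_frac probability that a planted edge is negative.
#' @param corr_strength target |basis correlation| for planted edges, in (0,1).
#' @param seed integer seed; fully determines the output.
#' @return A `ground_truth_network`: list with `taxa`, `basis_corr` (the
#'   projected positive semidefinite correlation matrix), `module_of`
#'   (integer vector named by taxon), `edges` (data.frame `taxon_i`,
#'   `taxon_j`, `sign`, `target` for the planted pairs).
#' @export
make_basis_network <- function(n_taxa, n_modules, p_within, p_between,
                               neg_frac = 0, corr_strength = 0.8, seed = 1L) {
  if (n_taxa < 4) stop("SparCC unidentifiable below 4 taxa")
  if (n_modules < 1 || n_modules > n_taxa) stop("n_modules must be in [1, n_taxa]")
  for (p in c(p_within, p_between, neg_frac))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (corr_strength <= 0 || corr_strength >= 1)
    stop("corr_strength must lie in (0, 1)")

  taxa <- sprintf("taxon_%02d", seq_len(n_taxa))
  # near-equal module sizes, contiguous blocks: 30 taxa / 3 modules -> 10,10,10
  module_of <- sort(rep_len(seq_len(n_modules), n_taxa))
  names(module_of) <- taxa

  set.seed(seed)
  target <- diag(n_taxa)
  edges <- list()
  for (i in seq_len(n_taxa - 1L)) {
    for (j in (i + 1L):n_taxa) {
      p <- if (module_of[i] == module_of[j]) p_within else p_between
      if (stats::runif(1) < p) {
        sgn <- if (stats::runif(1) < neg_frac) -1 else 1
        target[i, j] <- target[j, i] <- sgn * corr_strength
        edges[[length(edges) + 1L]] <- data.frame(
          taxon_i = taxa[i], taxon_j = taxa[j], sign = sgn,
          target = sgn * corr_strength, stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(taxon_i = character(), taxon_j = character(),
               sign = integer(), target = numeric())

  basis_corr <- psd_project(target)
  dimnames(basis_corr) <- list(taxa, taxa)
  structure(list(taxa = taxa, basis_corr = basis_corr, module_of = module_of,
                 edges = edges),
            class = "ground_truth_network")
}

# Nearest-PSD repair: clip eigenvalues at 0, reconstruct, rescale to unit
# diagonal. Identity-preserving for matrices that are already PSD.
psd_project <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= 0) return(m)
  v <- pmax(e$values, 0)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  (out + t(out)) / 2
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat("ground_truth_network: ", length(x$taxa), " taxa, ",
      max(x$module_of), " module(s), ", nrow(x$edges), " planted edge(s) (",
      sum(x$edges$sign < 0), " negative)\n", sep = "")
  invisible(x)
}

#' Serialize / load a ground-truth network as JSON
#' @param gt a `ground_truth_network`.
#' @param path JSON file path.
#' @return `write_ground_truth` returns `path` invisibly; `read_ground_truth`
#'   the reconstructed object.
#' @export
write_ground_truth <- function(gt, path) {
  obj <- list(taxa = gt$taxa, basis_corr = gt$basis_corr,
              module_of = unname(gt$module_of), edges = gt$edges)
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bc <- as.matrix(obj$basis_corr)
  dimnames(bc) <- list(obj$taxa, obj$taxa)
  mo <- as.integer(obj$module_of)
  names(mo) <- obj$taxa
  structure(list(taxa = obj$taxa, basis_corr = bc, module_of = mo,
                 edges = as.data.frame(obj$edges)),
            class = "ground_truth_network")
}

#' Simulate compositional counts from a basis network
#'
#' Logistic-normal--multinomial generator (the generative model SparCC
#' assumes): per sample, basis log-abundances are drawn from a multivariate
#' normal with correlation `gt$basis_corr` and unit per-taxon variance around
#' per-taxon means; a softmax converts them to fractions; the sequencing
#' depth is drawn per sample (negative binomial around `depth` unless
#' `depth_dispersion = 0`, in which case it is exactly `depth`); counts are
#' a multinomial draw at that depth.
#'
#' @param gt a `ground_truth_network` from [make_basis_network()].
#' @param n_samples number of samples (>= 2).
#' @param depth mean sequencing depth (reads per sample, >= 1).
#' @param depth_dispersion non-negative; 0 gives constant depth, otherwise
#'   the per-sample depth is negative binomial with mean `depth` and
#'   variance `depth * (1 + depth * depth_dispersion)`.
#' @param logmean_range length-2 range from which per-taxon basis log-mean
#'   abundances are drawn uniformly (once, shared by all samples).
#' @param group,timepoint metadata labels attached to every sample.
#' @param sample_prefix prefix for generated sample ids.
#' @param seed integer seed; fully determines the output.
#' @return an [abundance_table()]; the matrix of latent basis log-abundances
#'   is attached as attribute `"basis_log"` for generator diagnostics.
#' @export
simulate_counts <- function(gt, n_samples, depth = 5000, depth_dispersion = 0,
                            logmean_range = c(0, 3), group = "groupA",
                            timepoint = NA_character_, sample_prefix = group,
                            seed = 1L) {
  if (n_samples < 2) stop("need n_samples >= 2")
  if (depth < 1) stop("depth must be >= 1")
  if (depth_dispersion < 0) stop("depth_dispersion must be >= 0")
  ev <- eigen(gt$basis_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("basis_corr is not positive semidefinite")

  p <- length(gt$taxa)
  set.seed(seed)
  mu <- stats::runif(p, logmean_range[1], logmean_range[2])
  # eigendecomposition-based MVN draw; tolerates a singular (PSD) correlation
  e <- eigen(gt$basis_corr, symmetric = TRUE)
  rt <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  z <- matrix(stats::rnorm(n_samples * p), n_samples, p)
  logab <- sweep(z %*% rt, 2L, mu, "+")

  frac <- exp(logab - apply(logab, 1L, max))
  frac <- frac / rowSums(frac)

  depths <- if (depth_dispersion == 0) rep(as.integer(round(depth)), n_samples)
            else pmax(1L, stats::rnbinom(n_samples, mu = depth,
                                         size = 1 / depth_dispersion))
  cts <- t(vapply(seq_len(n_samples),
                  function(i) stats::rmultinom(1L, depths[i], frac[i, ])[, 1L],
                  integer(p)))
  rownames(cts) <- sprintf("%s_s%02d", sample_prefix, seq_len(n_samples))
  colnames(cts) <- gt$taxa
  md <- data.frame(sample_id = rownames(cts), group = group,
                   timepoint = timepoint, is_control = FALSE,
                   stringsAsFactors = FALSE)
  out <- abundance_table(cts, md)
  rownames(logab) <- rownames(cts); colnames(logab) <- gt$taxa
  attr(out, "basis_log") <- logab
  out
}

#' Spike reagent-style contaminants and negative-control samples
#'
#' Emulates reagent carry-over: `n_contaminants` new taxa are appended that
#' dominate `n_controls` new water-control samples (present in a fraction
#' `prevalence_in_controls` of them) while appearing only sporadically and at
#' low abundance (1--20 reads) in a fraction `prevalence_in_samples` of the
#' true samples. The spiked taxon ids are recorded in attribute
#' `"contaminants"` so downstream flagging can be scored against truth.
#'
#' @param table an [abundance_table()] of true samples.
#' @param n_contaminants number of contaminant taxa to add.
#' @param n_controls number of negative-control samples to append.
#' @param prevalence_in_controls,prevalence_in_samples presence fractions in
#'   controls / true samples, each in \[0, 1\].
#' @param control_depth total reads given to each control sample.
#' @param seed integer seed.
#' @return an [abundance_table()] with the controls appended
#'   (`is_control = TRUE`, group `"negative_control"`) and attribute
#'   `"contaminants"` naming the spiked taxa.
#' @export
spike_contaminants <- function(table, n_contaminants, n_controls,
                               prevalence_in_controls = 1.0,
                               prevalence_in_samples = 0.1,
                               control_depth = 500, seed = 1L) {
  for (p in c(prevalence_in_controls, prevalence_in_samples))
    if (p < 0 || p > 1) stop("prevalences must lie in [0, 1]")
  if (nrow(table$counts) == 0) stop("table is empty")
  if (n_controls == 0 && n_contaminants > 0)
    stop("cannot spike contaminants without negative-control samples")

  set.seed(seed)
  cts <- table$counts
  n_true <- nrow(cts)
  contam <- if (n_contaminants > 0)
    sprintf("contam_%02d", seq_len(n_contaminants)) else character()

  # contaminant columns in true samples: low counts (1-20) where present
  add_true <- matrix(0L, n_true, n_contaminants,
                     dimnames = list(rownames(cts), contam))
  for (k in seq_len(n_contaminants)) {
    hit <- stats::runif(n_true) < prevalence_in_samples
    add_true[hit, k] <- sample(1:20, sum(hit), replace = TRUE)
  }
  cts <- cbind(cts, add_true)

  if (n_controls > 0) {
    ctrl_ids <- sprintf("negctrl_%02d", seq_len(n_controls))
    ctrl <- matrix(0L, n_controls, ncol(cts),
                   dimnames = list(ctrl_ids, colnames(cts)))
    # faint carry-over of a few real taxa so controls are not empty
    bg_taxa <- utils::head(order(colSums(table$counts), decreasing = TRUE), 3L)
    for (i in seq_len(n_controls)) {
      ctrl[i, bg_taxa] <- sample(1:5, length(bg_taxa), replace = TRUE)
      for (k in seq_len(n_contaminants)) {
        if (stats::runif(1) < prevalence_in_controls) {
          ctrl[i, contam[k]] <- pmax(1L, stats::rpois(1, control_depth / max(1, n_contaminants)))
        }
      }
    }
    md_ctrl <- data.frame(sample_id = ctrl_ids, group = "negative_control",
                          timepoint = NA_character_, is_control = TRUE,
                          stringsAsFactors = FALSE)
    cts <- rbind(cts, ctrl)
    md <- rbind(table$metadata, md_ctrl)
  } else md <- table$metadata

  out <- abundance_table(cts, md)
  attr(out, "contaminants") <- contam
  out
}

#' Named fixture graphs for robustness testing
#'
#' Deterministic small graphs with unit positive edge weights, wrapped as
#' [conetwork] objects: `star` (one hub), `path`, `complete`, `erdos_renyi`
#' (G(n, p), `param` = p), `barabasi_albert` (preferential attachment
#' starting from `param` isolated seed nodes, each newcomer attaching
#' `param` edges, so the edge count is `param * (n - param)`), and `barbell`
#' (two cliques of size `param` joined by a path through the remaining
#' nodes).
#'
#' @param model one of `"star"`, `"path"`, `"complete"`, `"erdos_renyi"`,
#'   `"barabasi_albert"`, `"barbell"`.
#' @param n number of nodes.
#' @param param model parameter (p for `erdos_renyi`, m for
#'   `barabasi_albert`, clique size for `barbell`; ignored otherwise).
#' @param seed integer seed for the random models.
#' @return a [conetwork].
#' @export
make_fixture_graph <- function(model, n, param = NULL, seed = 1L) {
  if (n < 1) stop("need n >= 1")
  set.seed(seed)
  g <- switch(model,
    star = igraph::make_star(n, mode = "undirected"),
    path = igraph::make_ring(n, circular = FALSE),
    complete = igraph::make_full_graph(n),
    erdos_renyi = igraph::sample_gnp(n, param %||% 0.1),
    barabasi_albert = ba_graph(n, m = param %||% 2L),
    barbell = barbell_graph(n, clique = param %||% max(2L, n %/% 3L)),
    stop("unknown fixture model: ", model)
  )
  igraph::V(g)$name <- sprintf("n%03d", seq_len(igraph::vcount(g)))
  igraph::E(g)$weight <- 1
  igraph::E(g)$sign <- 1L
  as_conetwork(g, threshold = NA_real_)
}

# Preferential attachment with m seed nodes and m distinct targets per
# newcomer (the first newcomer attaches to all m seeds); |E| = m * (n - m).
ba_graph <- function(n, m) {
  if (m < 1 || m >= n) stop("barabasi_albert needs 1 <= m < n")
  edges <- integer(0)
  repeated <- integer(0)           # node multiset, multiplicity = degree
  targets <- seq_len(m)
  for (v in (m + 1L):n) {
    edges <- c(edges, rbind(v, targets))
    repeated <- c(repeated, targets, rep(v, m))
    # sample m distinct targets preferentially by degree
    targets <- integer(0)
    pool <- repeated
    while (length(targets) < m) {
      cand <- pool[sample.int(length(pool), 1L)]
      if (!(cand %in% targets)) targets <- c(targets, cand)
    }
  }
  igraph::make_graph(edges, n = n, directed = FALSE)
}

barbell_graph <- function(n, clique) {
  if (n < 2 * clique) stop("barbell needs n >= 2 * clique size")
  g1 <- igraph::make_full_graph(clique)
  g2 <- igraph::make_full_graph(clique)
  g <- igraph::disjoint_union(g1, g2)
  path_n <- n - 2L * clique
  chain <- c(clique, if (path_n > 0) 2L * clique + seq_len(path_n), clique + 1L)
  if (path_n > 0) g <- igraph::add_vertices(g, path_n)
  for (i in seq_len(length(chain) - 1L))
    g <- igraph::add_edges(g, c(chain[i], chain[i + 1L]))
  g
}
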