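#' Flag likely reagent contaminants by prevalence
#'
#' Prevalence-based contaminant identification against negative controls:
#' for each taxon a 2x2 presence/absence table (control vs true sample by
#' present vs absent) is formed, the chi-squared statistic is computed
#' without continuity correction, and the taxon's score is the upper-tail
#' probability of that statistic when the taxon is MORE prevalent in
#' controls than in true samples (otherwise the score is 1, i.e. never
#' contaminant-like). Taxa scoring below `score_threshold` are flagged; the
#' pipeline removes them before any downstream analysis.
#'
#' @param table an [abundance_table()] containing at least one negative
#'   control (`is_control = TRUE`) and one true sample.
#' @param score_threshold flag taxa with score strictly below this (default
#'   0.1, the conventional prevalence-method default).
#' @return character vector of flagged taxon ids (possibly empty), with the
#'   full per-taxon score vector attached as attribute `"scores"`.
#' @export
flag_contaminants <- function(table, score_threshold = 0.1) {
  ctrl <- table$metadata$is_control
  if (!any(ctrl)) stop("prevalence method requires negative controls")
  if (all(ctrl)) stop("prevalence method requires true samples")
  pres <- table$counts > 0
  n_c <- sum(ctrl); n_t <- sum(!ctrl)
  scores <- vapply(seq_len(ncol(pres)), function(j) {
    a <- sum(pres[ctrl, j])        # present in controls
    c_ <- sum(pres[!ctrl, j])      # present in true samples
    if (a / n_c <= c_ / n_t) return(1)
    m <- matrix(c(a, n_c - a, c_, n_t - c_), 2, byrow = TRUE)
    rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
    if (any(cs == 0)) return(1)    # degenerate margin: no signal
    expd <- outer(rs, cs) / n
    x2 <- sum((m - expd)^2 / expd)
    stats::pchisq(x2, df = 1, lower.tail = FALSE)
  }, numeric(1))
  names(scores) <- taxon_ids(table)
  flagged <- names(scores)[scores < score_threshold]
  attr(flagged, "scores") <- scores
  flagged
}

#' Remove low-abundance taxa
#'
#' Keeps exactly the taxa with total reads at or above `min_total_reads`
#' AND non-zero in at least `min_prevalence` of the samples (strict
#' "less than" removal on both criteria); the sample set is unchanged.
#'
#' @param table an [abundance_table()].
#' @param min_total_reads minimum summed reads across samples (default 10).
#' @param min_prevalence minimum fraction of samples with a non-zero count
#'   (default 0.30).
#' @return the filtered [abundance_table()].
#' @export
filter_low_abundance <- function(table, min_total_reads = 10,
                                 min_prevalence = 0.30) {
  if (min_total_reads < 0 || min_prevalence < 0)
    stop("thresholds must be >= 0")
  if (nrow(table$counts) == 0 || ncol(table$counts) == 0)
    stop("table is empty")
  tot <- colSums(table$counts)
  prev <- colMeans(table$counts > 0)
  keep <- taxon_ids(table)[tot >= min_total_reads & prev >= min_prevalence]
  if (length(keep) == 0) stop("no taxon passes the abundance filter")
  subset_table(table, taxa = keep)
}

#' Centered log-ratio transformation
#'
#' Per sample, `clr(x)_t = log(x_t + pseudocount) - mean_t log(x_t +
#' pseudocount)`; every row of the result sums to zero.
#'
#' @param table an [abundance_table()], or a numeric samples x taxa matrix
#'   of counts or proportions.
#' @param pseudocount positive offset added before taking logs (default 0.5,
#'   the usual convention for count tables).
#' @return a `clr_matrix`: numeric samples x taxa matrix with class
#'   attribute, rows summing to zero.
#' @export
clr_transform <- function(table, pseudocount = 0.5) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  m <- if (inherits(table, "abundance_table")) table$counts else as.matrix(table)
  lg <- log(m + pseudocount)
  out <- lg - rowMeans(lg)
  class(out) <- c("clr_matrix", class(out))
  out
}

# Kruskal-Wallis H and p for every column of `mat` against `groups`,
# vectorized with tie correction; agrees with stats::kruskal.test.
kruskal_vec <- function(mat, groups) {
  groups <- as.factor(groups)
  n <- nrow(mat); k <- nlevels(groups)
  gi <- split(seq_len(n), groups)
  H <- vapply(seq_len(ncol(mat)), function(j) {
    r <- rank(mat[, j])
    s <- sum(vapply(gi, function(idx) sum(r[idx])^2 / length(idx), numeric(1)))
    h <- 12 * s / (n * (n + 1)) - 3 * (n + 1)
    ties <- table(mat[, j])
    corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
    if (corr == 0) 0 else h / corr
  }, numeric(1))
  p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  p[H == 0] <- 1
  list(H = H, p = p)
}

#' Differential abundance by Dirichlet Monte-Carlo Kruskal-Wallis
#'
#' The clr-based two-group test: for each of `n_mc_instances` Monte-Carlo
#' instances, per-sample taxon proportions are drawn from
#' Dirichlet(counts + 0.5), clr-transformed, and a per-taxon Kruskal-Wallis
#' test across the two groups is computed; the reported per-taxon p-value is
#' the expectation over instances, adjusted across taxa by
#' Benjamini-Hochberg. The effect size is the between-group difference of
#' Monte-Carlo mean clr values (`group_b` minus `group_a`).
#'
#' @param table an [abundance_table()].
#' @param group_a,group_b group labels (matched against [group_labels()]
#'   and, failing that, against the raw `group` column); each must have at
#'   least 3 samples.
#' @param n_mc_instances number of Dirichlet Monte-Carlo instances.
#' @param seed integer seed.
#' @return data.frame with one row per taxon: `taxon`, `H` (mean statistic),
#'   `p` (expected p), `q` (BH-adjusted), `clr_effect`.
#' @export
diff_abundance <- function(table, group_a, group_b, n_mc_instances = 128,
                           seed = 1L) {
  labels <- group_labels(table)
  pick <- function(g) {
    idx <- which(labels == g & !table$metadata$is_control)
    if (length(idx) == 0)
      idx <- which(table$metadata$group == g & !table$metadata$is_control)
    idx
  }
  ia <- pick(group_a); ib <- pick(group_b)
  if (length(ia) < 3 || length(ib) < 3)
    stop("both groups need at least 3 samples")
  cts <- table$counts[c(ia, ib), , drop = FALSE]
  grp <- factor(rep(c("a", "b"), c(length(ia), length(ib))))
  n <- nrow(cts); p <- ncol(cts)

  set.seed(seed)
  Hs <- ps <- matrix(0, n_mc_instances, p)
  clr_sum <- matrix(0, n, p)
  alpha <- cts + 0.5
  for (m in seq_len(n_mc_instances)) {
    gam <- matrix(stats::rgamma(n * p, shape = alpha), n, p)
    frac <- gam / rowSums(gam)
    lg <- log(frac)
    clr <- lg - rowMeans(lg)
    clr_sum <- clr_sum + clr
    kw <- kruskal_vec(clr, grp)
    Hs[m, ] <- kw$H; ps[m, ] <- kw$p
  }
  clr_mean <- clr_sum / n_mc_instances
  eff <- colMeans(clr_mean[grp == "b", , drop = FALSE]) -
         colMeans(clr_mean[grp == "a", , drop = FALSE])
  p_exp <- colMeans(ps)
  data.frame(taxon = taxon_ids(table), H = colMeans(Hs), p = p_exp,
             q = stats::p.adjust(p_exp, method = "BH"), clr_effect = eff,
             row.names = NULL, stringsAsFactors = FALSE)
}
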