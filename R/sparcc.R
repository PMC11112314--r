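#' Log-ratio variation matrix
#'
#' `t(i, j)` is the sample variance (n-1 denominator) of
#' `log(x_i / x_j)` across samples — the quantity from which SparCC
#' reconstructs basis variances and correlations. Computed via the identity
#' `var(log x_i - log x_j) = v_i + v_j - 2 * cov_ij` on the log fractions.
#'
#' @param fractions strictly positive samples x taxa matrix of relative
#'   abundances (draw Dirichlet proportions from counts first).
#' @return symmetric non-negative taxa x taxa matrix with zero diagonal.
#' @export
variation_matrix <- function(fractions) {
  fractions <- as.matrix(fractions)
  if (nrow(fractions) < 2) stop("need at least 2 samples")
  if (ncol(fractions) < 4) stop("SparCC unidentifiable below 4 taxa")
  if (any(fractions <= 0))
    stop("fractions must be strictly positive; draw Dirichlet proportions first")
  lg <- log(fractions)
  cv <- stats::cov(lg)
  v <- diag(cv)
  t_ <- outer(v, v, "+") - 2 * cv
  t_[t_ < 0] <- 0                 # numerical guard; true values are >= 0
  diag(t_) <- 0
  dimnames(t_) <- list(colnames(fractions), colnames(fractions))
  t_
}

#' Solve for SparCC basis variances
#'
#' Under the sparsity approximation (most pairs uncorrelated),
#' `t_ij ~ omega_i + omega_j`, so summing row i of the variation matrix
#' gives a linear system `A omega = rowSums(T)` with
#' `A = (D - 2) I + 1 1'`. Pairs listed in `excluded` (strongly correlated
#' pairs found during iteration) are removed from the row sums and the
#' corresponding coefficients of `A` decremented. Negative solutions are
#' clipped to a small positive floor so correlations stay defined.
#'
#' @param t_mat variation matrix from [variation_matrix()].
#' @param excluded two-column integer matrix, one row per excluded
#'   unordered pair (may be empty).
#' @param floor lower bound applied to the solved variances.
#' @return numeric vector of basis variances, one per taxon.
#' @export
basis_variances <- function(t_mat, excluded = NULL, floor = 1e-6) {
  d <- ncol(t_mat)
  if (d < 4) stop("SparCC unidentifiable below 4 taxa")
  A <- matrix(1, d, d) + (d - 2) * diag(d)
  b <- rowSums(t_mat)
  if (!is.null(excluded) && nrow(excluded) > 0) {
    for (r in seq_len(nrow(excluded))) {
      i <- excluded[r, 1]; j <- excluded[r, 2]
      b[i] <- b[i] - t_mat[i, j]
      b[j] <- b[j] - t_mat[i, j]
      A[i, i] <- A[i, i] - 1; A[i, j] <- A[i, j] - 1
      A[j, j] <- A[j, j] - 1; A[j, i] <- A[j, i] - 1
    }
  }
  omega <- tryCatch(solve(A, b),
                    error = function(e) stop("singular SparCC system: ",
                                             conditionMessage(e)))
  omega <- pmax(omega, floor)
  names(omega) <- colnames(t_mat)
  omega
}

#' Correlations from basis variances
#'
#' `rho_ij = (omega_i + omega_j - t_ij) / (2 sqrt(omega_i omega_j))`,
#' clipped to \[-1, 1\], unit diagonal.
#'
#' @param t_mat variation matrix.
#' @param omega positive basis variances from [basis_variances()].
#' @return symmetric correlation matrix.
#' @export
correlations_from_basis <- function(t_mat, omega) {
  if (any(omega <= 0)) stop("basis variances must be positive")
  denom <- 2 * sqrt(outer(omega, omega))
  rho <- (outer(omega, omega, "+") - t_mat) / denom
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  dimnames(rho) <- dimnames(t_mat)
  rho
}

#' Single-draw SparCC estimate with strong-pair exclusion
#'
#' One SparCC pass on a fixed fraction matrix: estimate basis variances and
#' correlations, then iteratively exclude the single strongest off-diagonal
#' pair whose |rho| exceeds `exclusion_threshold` (so the sparsity
#' approximation is not poisoned by strongly correlated pairs), re-solving
#' after each exclusion, for at most `max_exclusion_rounds` rounds. A taxon
#' whose every partner ends up excluded is dropped from the system and
#' reported in attribute `"dropped"` (its correlations are set to 0).
#'
#' @param fractions strictly positive samples x taxa matrix.
#' @param exclusion_threshold |rho| above which the strongest pair is
#'   excluded each round (default 0.8, the original SparCC default).
#' @param max_exclusion_rounds cap on exclusion rounds (default 10).
#' @return list with `rho` (correlation matrix), `omega` (basis variances),
#'   `excluded` (pair matrix); attribute `"dropped"` lists dropped taxa.
#' @export
sparcc_single <- function(fractions, exclusion_threshold = 0.8,
                          max_exclusion_rounds = 10) {
  t_mat <- variation_matrix(fractions)
  d <- ncol(t_mat)
  excluded <- matrix(integer(0), 0, 2)
  excl_count <- integer(d)
  dropped <- integer(0)
  for (round in seq_len(max_exclusion_rounds + 1L)) {
    omega <- basis_variances(t_mat, excluded)
    rho <- correlations_from_basis(t_mat, omega)
    if (round > max_exclusion_rounds) break
    cand <- abs(rho)
    diag(cand) <- 0
    if (nrow(excluded)) {
      cand[excluded] <- 0
      cand[excluded[, 2:1, drop = FALSE]] <- 0
    }
    cand[, dropped] <- 0; cand[dropped, ] <- 0
    top <- which(cand == max(cand), arr.ind = TRUE)[1, , drop = TRUE]
    if (cand[top[1], top[2]] <= exclusion_threshold) break
    pair <- sort(c(top[1], top[2]))
    excluded <- rbind(excluded, pair, deparse.level = 0)
    excl_count[pair] <- excl_count[pair] + 1L
    newly_dropped <- which(excl_count >= d - 1L)
    dropped <- union(dropped, newly_dropped)
  }
  if (length(dropped)) {
    rho[dropped, ] <- 0; rho[, dropped] <- 0
    diag(rho) <- 1
  }
  out <- list(rho = rho, omega = omega, excluded = excluded)
  attr(out, "dropped") <- colnames(t_mat)[dropped]
  out
}

#' SparCC correlation inference from counts
#'
#' The full SparCC procedure: for each of `n_resamples` resamples, draw
#' per-sample taxon fractions from Dirichlet(counts + `prior`), run a
#' single SparCC pass with strong-pair exclusion, and aggregate by taking
#' the elementwise median of the resampled correlation matrices.
#'
#' @param counts an [abundance_table()] or a non-negative integer samples x
#'   taxa matrix with at least 4 taxa.
#' @param n_resamples number of Dirichlet resamples (default 20).
#' @param prior Dirichlet pseudocount added to every cell (default 1).
#' @param exclusion_threshold,max_exclusion_rounds passed to
#'   [sparcc_single()].
#' @param seed integer seed; fully determines the estimate.
#' @return an object of class `sparcc`: list with `rho` (median correlation
#'   matrix, unit diagonal, entries in \[-1, 1\]), `omega` (median basis
#'   variances), `n_resamples`, `taxa`, and the call.
#' @seealso [coef.sparcc()], [build_network()]
#' @export
sparcc <- function(counts, n_resamples = 20, prior = 1,
                   exclusion_threshold = 0.8, max_exclusion_rounds = 10,
                   seed = 1L) {
  m <- if (inherits(counts, "abundance_table")) counts$counts else as.matrix(counts)
  if (ncol(m) < 4) stop("SparCC unidentifiable below 4 taxa")
  if (any(m < 0)) stop("counts must be non-negative")
  n <- nrow(m); p <- ncol(m)
  set.seed(seed)
  alpha <- m + prior
  rhos <- array(NA_real_, c(p, p, n_resamples))
  omegas <- matrix(NA_real_, n_resamples, p)
  for (r in seq_len(n_resamples)) {
    gam <- matrix(stats::rgamma(n * p, shape = alpha), n, p)
    frac <- gam / rowSums(gam)
    colnames(frac) <- colnames(m)
    fit <- sparcc_single(frac, exclusion_threshold, max_exclusion_rounds)
    rhos[, , r] <- fit$rho
    omegas[r, ] <- fit$omega
  }
  rho <- apply(rhos, c(1, 2), stats::median)
  rho <- pmin(pmax((rho + t(rho)) / 2, -1), 1)
  diag(rho) <- 1
  dimnames(rho) <- list(colnames(m), colnames(m))
  omega <- apply(omegas, 2, stats::median)
  names(omega) <- colnames(m)
  structure(list(rho = rho, omega = omega, n_resamples = n_resamples,
                 taxa = colnames(m), n_samples = n, call = match.call()),
            class = "sparcc")
}

#' @export
print.sparcc <- function(x, ...) {
  cat("SparCC fit: ", length(x$taxa), " taxa, ", x$n_samples, " samples, ",
      x$n_resamples, " Dirichlet resample(s)\n", sep = "")
  off <- x$rho[upper.tri(x$rho)]
  cat(sprintf("  median |rho|: %.3f   max |rho|: %.3f   pairs with |rho| > 0.75: %d\n",
              stats::median(abs(off)), max(abs(off)), sum(abs(off) > 0.75)))
  invisible(x)
}

#' @export
summary.sparcc <- function(object, thresholds = c(0.75, 0.95), ...) {
  off <- object$rho[upper.tri(object$rho)]
  out <- list(
    n_taxa = length(object$taxa), n_samples = object$n_samples,
    quartiles = stats::quantile(off, c(0, .25, .5, .75, 1)),
    edges_at = vapply(thresholds, function(th) sum(abs(off) > th), numeric(1)),
    thresholds = thresholds)
  class(out) <- "summary.sparcc"
  out
}

#' @export
print.summary.sparcc <- function(x, ...) {
  cat("SparCC correlations over", x$n_taxa, "taxa (", x$n_samples, "samples )\n")
  print(round(x$quartiles, 3))
  for (i in seq_along(x$thresholds))
    cat(sprintf("  pairs with |rho| > %.2f: %d\n", x$thresholds[i],
                x$edges_at[i]))
  invisible(x)
}

#' Extract the correlation matrix from a SparCC fit
#' @param object a `sparcc` fit.
#' @param ... unused.
#' @return the median correlation matrix.
#' @export
coef.sparcc <- function(object, ...) object$rho

#' Write SparCC correlations as TSV
#'
#' @param fit a `sparcc` fit (or a bare correlation matrix).
#' @param path output path.
#' @param long if `TRUE` write long form (`taxon_i`, `taxon_j`, `rho`, upper
#'   triangle only); otherwise a square matrix TSV.
#' @return `path`, invisibly.
#' @export
write_correlations_tsv <- function(fit, path, long = FALSE) {
  rho <- if (inherits(fit, "sparcc")) fit$rho else as.matrix(fit)
  if (long) {
    idx <- which(upper.tri(rho), arr.ind = TRUE)
    df <- data.frame(taxon_i = rownames(rho)[idx[, 1]],
                     taxon_j = colnames(rho)[idx[, 2]],
                     rho = rho[idx])
  } else {
    df <- data.frame(taxon_id = rownames(rho), rho, check.names = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
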