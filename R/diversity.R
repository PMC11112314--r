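#' Rarefy a count table to even depth
#'
#' Per sample, subsample exactly `depth` reads without replacement
#' (hypergeometric rarefaction). Deterministic given `seed`.
#'
#' @param table an [abundance_table()].
#' @param depth target reads per sample; defaults to the minimum sample
#'   total. Must not exceed any sample's total.
#' @param seed integer seed.
#' @return the rarefied [abundance_table()].
#' @export
rarefy <- function(table, depth = min(rowSums(table$counts)), seed = 1L) {
  tot <- rowSums(table$counts)
  bad <- which(tot < depth)
  if (length(bad))
    stop("rarefaction depth ", depth, " exceeds total reads of sample ",
         sample_ids(table)[bad[1]], " (", tot[bad[1]], ")")
  set.seed(seed)
  # vegan chats about count magnitudes; the depth precondition is ours above
  cts <- suppressWarnings(vegan::rrarefy(table$counts, depth))
  storage.mode(cts) <- "integer"
  abundance_table(cts, table$metadata)
}

#' Observed features (richness) per sample
#'
#' @param table an [abundance_table()].
#' @return named integer vector: number of taxa with a non-zero count in
#'   each sample.
#' @export
observed_features <- function(table) {
  out <- rowSums(table$counts > 0)
  storage.mode(out) <- "integer"
  out
}

#' Jaccard distance matrix on presence/absence
#'
#' `d(i, j) = 1 - |A intersect B| / |A union B|` over the presence sets of
#' samples i and j; a pair of all-zero samples is defined to have distance 0
#' (identical empty sets).
#'
#' @param table an [abundance_table()].
#' @return a symmetric `dist_matrix` (square numeric matrix, zero diagonal,
#'   entries in \[0, 1\]) with sample ids as dimnames.
#' @export
jaccard_matrix <- function(table) {
  if (nrow(table$counts) < 2) stop("need at least 2 samples")
  pres <- table$counts > 0
  nonempty <- rowSums(pres) > 0
  d <- matrix(0, nrow(pres), nrow(pres),
              dimnames = list(sample_ids(table), sample_ids(table)))
  if (any(nonempty)) {
    dv <- suppressWarnings(
      vegan::vegdist(pres[nonempty, , drop = FALSE] * 1, method = "jaccard",
                     binary = TRUE))
    d[nonempty, nonempty] <- as.matrix(dv)
  }
  # empty vs non-empty sample: disjoint-by-convention distance 1
  if (any(!nonempty) && any(nonempty)) {
    d[!nonempty, nonempty] <- 1
    d[nonempty, !nonempty] <- 1
  }
  diag(d) <- 0
  class(d) <- c("dist_matrix", class(d))
  d
}

#' Write a distance matrix as square TSV
#' @param d a `dist_matrix` (square symmetric matrix).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), unclass(d), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational partition of the distance-matrix variance among groups:
#' with total sum of squares `SST = sum d^2 / n` over all pairs and within-
#' group sum `SSW = sum_g (within-group sum d^2) / n_g`, the statistic is
#' `F = ((SST - SSW)/(k - 1)) / (SSW/(n - k))`; the p-value is
#' `(1 + #\{permuted F >= observed F\}) / (1 + n_perm)` over label
#' permutations. Perfectly separated groups (zero within-distance) give an
#' infinite F, which only an exactly group-preserving permutation can tie.
#'
#' @param d a `dist_matrix`, square matrix, or `dist` over samples.
#' @param labels group label per sample (same order as `d`); at least two
#'   groups with two samples each.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list with `pseudo_F`, `p_value`, `n_perm`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1L) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 groups")
  if (any(table(labels) < 2)) stop("every group needs at least 2 samples")
  d2 <- as.matrix(stats::as.dist(d))^2
  n <- nrow(d2)
  k <- nlevels(labels)
  sst <- sum(d2[upper.tri(d2)]) / n
  if (sst == 0)   # all samples identical: nothing to partition
    return(list(pseudo_F = NaN, p_value = 1, n_perm = n_perm))
  fstat <- function(lab) {
    ssw <- 0
    for (lv in levels(lab)) {
      idx <- which(lab == lv)
      ssw <- ssw + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    ((sst - ssw) / (k - 1)) / (ssw / (n - k))
  }
  f_obs <- fstat(labels)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm))
    if (fstat(labels[sample.int(n)]) >= f_obs) hits <- hits + 1L
  list(pseudo_F = f_obs, p_value = (1 + hits) / (1 + n_perm), n_perm = n_perm)
}
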