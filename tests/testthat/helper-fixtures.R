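# Small programmatic fixtures shared across test files.

# counts matrix (samples x taxa) with metadata, two groups by default
tiny_table <- function(counts, groups = NULL, timepoints = NA_character_,
                       is_control = FALSE) {
  n <- nrow(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("s%02d", seq_len(n))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("t%02d", seq_len(ncol(counts)))
  if (is.null(groups)) groups <- rep("g1", n)
  md <- data.frame(sample_id = rownames(counts), group = groups,
                   timepoint = timepoints,
                   is_control = rep_len(is_control, n),
                   stringsAsFactors = FALSE)
  abundance_table(counts, md)
}

# random table from independent Poisson counts
random_table <- function(n_samples, n_taxa, lambda = 50, seed = 1,
                         groups = NULL) {
  set.seed(seed)
  cts <- matrix(rpois(n_samples * n_taxa, lambda), n_samples, n_taxa)
  tiny_table(cts, groups = groups)
}

# conetwork from an explicit edge list (unit positive weights)
edge_net <- function(edges, nodes = NULL) {
  g <- igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
  if (!is.null(nodes)) {
    extra <- setdiff(nodes, igraph::V(g)$name)
    if (length(extra)) g <- igraph::add_vertices(g, length(extra), name = extra)
  }
  igraph::E(g)$weight <- 1
  igraph::E(g)$sign <- 1L
  as_conetwork(g)
}

# correlation matrix with named planted entries, identity elsewhere
corr_fixture <- function(taxa, pairs) {
  p <- length(taxa)
  rho <- diag(p); dimnames(rho) <- list(taxa, taxa)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    rho[i, j] <- rho[j, i] <- pairs$rho[k]
  }
  rho
}

# independent reachable-ordered-pair count via boolean transitive closure
oracle_reachable_pairs <- function(adj) {
  n <- nrow(adj)
  if (n == 0) return(0)
  reach <- adj | diag(n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  sum(reach) - n
}

# brute-force step-up BH oracle
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# connected graphs on <= 7 nodes from the igraph atlas
atlas_connected <- function() {
  Filter(function(g) igraph::vcount(g) > 0 && igraph::is_connected(g),
         lapply(0:1252, igraph::graph_from_atlas))
}
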