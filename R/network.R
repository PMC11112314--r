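#' Signed co-occurrence network
#'
#' A `conetwork` wraps an undirected [igraph][igraph::igraph-package] graph
#' whose vertices are taxa and whose edges carry the SparCC correlation as
#' `weight` and its sign as `sign`, plus the magnitude `threshold` used to
#' build it. Create one with [build_network()], [core_network()] or
#' [make_fixture_graph()].
#'
#' @param graph an undirected igraph object with named vertices and edge
#'   attributes `weight` and `sign`.
#' @param threshold the |rho| cutoff the network was built at (NA for
#'   fixture graphs).
#' @return an object of class `conetwork`.
#' @name conetwork
#' @export
as_conetwork <- function(graph, threshold = NA_real_) {
  stopifnot(igraph::is_igraph(graph), !igraph::is_directed(graph))
  if (is.null(igraph::V(graph)$name))
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  if (is.null(igraph::E(graph)$weight)) igraph::E(graph)$weight <- 1
  if (is.null(igraph::E(graph)$sign))
    igraph::E(graph)$sign <- ifelse(igraph::E(graph)$weight < 0, -1L, 1L)
  structure(list(graph = graph, threshold = threshold), class = "conetwork")
}

#' @export
print.conetwork <- function(x, ...) {
  g <- x$graph
  cat("conetwork: ", igraph::vcount(g), " nodes, ", igraph::ecount(g),
      " edges (", sum(igraph::E(g)$sign > 0), " positive, ",
      sum(igraph::E(g)$sign < 0), " negative)",
      if (!is.na(x$threshold)) paste0(", |rho| > ", x$threshold), "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.conetwork <- function(object, ...) topology_summary(object)

#' @export
plot.conetwork <- function(x, ...) {
  g <- x$graph
  igraph::plot.igraph(
    g, edge.color = ifelse(igraph::E(g)$sign > 0, "darkgreen", "darkred"),
    edge.width = 1 + 2 * abs(igraph::E(g)$weight),
    vertex.size = 6, vertex.label.cex = 0.6, ...)
  invisible(x)
}

nodes_of <- function(net) igraph::V(net$graph)$name

#' Build a thresholded co-occurrence network
#'
#' An edge is drawn for every taxon pair whose correlation magnitude is
#' strictly above `threshold` (default 0.75); the edge keeps the signed
#' correlation as weight. Taxa without any edge are dropped (only nodes
#' with at least one connection are part of the network).
#'
#' @param rho a `sparcc` fit or a symmetric correlation matrix with taxon
#'   dimnames.
#' @param threshold magnitude cutoff in (0, 1).
#' @return a [conetwork].
#' @export
build_network <- function(rho, threshold = 0.75) {
  if (inherits(rho, "sparcc")) rho <- rho$rho
  rho <- as.matrix(rho)
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  if (is.null(rownames(rho)))
    rownames(rho) <- colnames(rho) <- sprintf("taxon_%02d", seq_len(ncol(rho)))
  adj <- rho
  adj[abs(adj) <= threshold] <- 0
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  igraph::E(g)$sign <- ifelse(igraph::E(g)$weight < 0, -1L, 1L)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  as_conetwork(g, threshold = threshold)
}

#' Core co-occurrence network (|rho| > 0.95)
#'
#' @param rho as in [build_network()].
#' @return a [conetwork] built at threshold 0.95.
#' @export
core_network <- function(rho) build_network(rho, threshold = 0.95)

#' Topology summary of a co-occurrence network
#'
#' Node/edge/sign counts, Louvain modularity and module count on the
#' |weight| graph (fixed RNG seed, modules relabelled by decreasing size),
#' diameter as the maximum unweighted eccentricity within the largest
#' connected component, average degree `2E/N`, weighted degree (mean node
#' strength over |weight|), and the mean local clustering coefficient of
#' the unweighted, unsigned graph (degree < 2 nodes contribute 0).
#'
#' @param net a [conetwork].
#' @param louvain_seed RNG seed fixed before community detection.
#' @return list of class `topology_report`.
#' @export
topology_summary <- function(net, louvain_seed = 0L) {
  g <- net$graph
  if (igraph::vcount(g) == 0) stop("empty network")
  w <- abs(igraph::E(g)$weight)
  comm <- local({ set.seed(louvain_seed)
                  igraph::cluster_louvain(g, weights = w) })
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  memb <- relabel[as.character(memb)]
  comps <- igraph::components(g)
  lcc <- igraph::induced_subgraph(
    g, which(comps$membership == which.max(comps$csize)))
  clus <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  out <- list(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    n_positive = sum(igraph::E(g)$sign > 0),
    n_negative = sum(igraph::E(g)$sign < 0),
    modularity = igraph::modularity(g, memb, weights = w),
    n_modules = length(sizes),
    diameter = if (igraph::ecount(g) == 0) 0L else
      igraph::diameter(lcc, weights = NA),
    avg_degree = 2 * igraph::ecount(g) / igraph::vcount(g),
    weighted_degree = mean(igraph::strength(g, weights = w)),
    clustering_coefficient = mean(clus),
    membership = memb)
  class(out) <- "topology_report"
  out
}

#' @export
print.topology_report <- function(x, ...) {
  cat("network topology\n")
  flds <- c(n_nodes = "Nodes", n_edges = "Edges", n_positive = "Positive edges",
            n_negative = "Negative edges", modularity = "Modularity",
            n_modules = "Modules", diameter = "Diameter",
            avg_degree = "Average degree", weighted_degree = "Weighted degree",
            clustering_coefficient = "Clustering coefficient")
  for (f in names(flds)) {
    v <- x[[f]]
    cat(sprintf("  %-22s %s\n", flds[f],
                if (is.numeric(v) && v != round(v)) sprintf("%.3f", v) else v))
  }
  invisible(x)
}

#' Eigenvector centrality, max-normalized
#'
#' Power iteration on the |weight| adjacency matrix of the whole (possibly
#' disconnected) graph, shifted by the identity so bipartite components
#' converge; the result is scaled so the maximum value is 1. Nodes outside
#' the spectrally dominant component come out (numerically) 0.
#'
#' @param net a [conetwork].
#' @param tol sup-norm convergence tolerance.
#' @param max_iter iteration cap; exceeded means an error.
#' @return named numeric vector in \[0, 1\], one value per node.
#' @export
eigenvector_centrality <- function(net, tol = 1e-10, max_iter = 1000L) {
  g <- net$graph
  n <- igraph::vcount(g)
  if (n == 0) stop("empty network")
  A <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE))
  A <- abs(A)
  # Blockwise power iteration: within a connected component the shifted
  # matrix A + I is primitive, so iteration always converges; across
  # components the one with the largest leading eigenvalue dominates and
  # the rest flush to 0 (first component wins exact ties, deterministically).
  comp <- igraph::components(g)$membership
  lead_val <- rep(-Inf, max(comp))
  vecs <- numeric(n)
  for (c_ in seq_len(max(comp))) {
    idx <- which(comp == c_)
    M <- A[idx, idx, drop = FALSE] + diag(length(idx))
    v <- rep(1 / sqrt(length(idx)), length(idx))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      nv <- M %*% v
      lam <- sqrt(sum(nv^2))
      nv <- nv / lam
      if (max(abs(nv - v)) < tol) { v <- nv; converged <- TRUE; break }
      v <- nv
    }
    if (!converged)
      stop("eigenvector centrality did not converge in ", max_iter,
           " iterations")
    lead_val[c_] <- lam - 1          # undo the +I shift
    vecs[idx] <- as.numeric(v)
  }
  dom <- which.max(lead_val)
  out <- numeric(n)
  out[comp == dom] <- vecs[comp == dom] / max(vecs[comp == dom])
  names(out) <- igraph::V(g)$name
  out
}

#' Taxa present in every sample of a condition
#'
#' Ubiquitousness: the taxa with a non-zero count in every sample of the
#' given condition (group x timepoint label, or plain group label).
#'
#' @param table an [abundance_table()].
#' @param group condition label matched against [group_labels()] (falling
#'   back to the raw `group` column).
#' @return character vector of ubiquitous taxon ids.
#' @export
ubiquity <- function(table, group) {
  labels <- group_labels(table)
  idx <- which(labels == group)
  if (length(idx) == 0) idx <- which(table$metadata$group == group)
  if (length(idx) == 0) stop("unknown group: ", group)
  sub <- table$counts[idx, , drop = FALSE]
  taxon_ids(table)[colSums(sub > 0) == length(idx)]
}

#' Keystone taxa of a co-occurrence network
#'
#' A network node is a keystone taxon of a condition when it satisfies all
#' three criteria: (i) eigenvector centrality at or above `eig_cut`
#' (default 0.75); (ii) ubiquitousness — present in every sample of the
#' condition; (iii) mean clr abundance over the condition's samples at or
#' above `abund_cut` (default 0.35). Both cutoffs are inclusive.
#'
#' @param net a [conetwork] whose nodes are taxa of `clr`.
#' @param clr a `clr_matrix` from [clr_transform()].
#' @param table the [abundance_table()] the clr matrix came from.
#' @param group condition label (see [ubiquity()]).
#' @param abund_cut,eig_cut inclusive cutoffs for mean clr and eigenvector
#'   centrality.
#' @return data.frame of class `keystone_report`: one row per network node
#'   with `taxon`, `mean_clr`, `eigenvector`, `ubiquitous`, `is_keystone`.
#' @export
keystone_taxa <- function(net, clr, table, group, abund_cut = 0.35,
                          eig_cut = 0.75) {
  nodes <- nodes_of(net)
  if (!all(nodes %in% colnames(clr)))
    stop("network contains taxa absent from the clr matrix")
  labels <- group_labels(table)
  idx <- which(labels == group)
  if (length(idx) == 0) idx <- which(table$metadata$group == group)
  if (length(idx) == 0) stop("unknown group: ", group)
  csub <- clr[rownames(clr) %in% sample_ids(table)[idx], nodes, drop = FALSE]
  if (nrow(csub) == 0) stop("group ", group, " absent from the clr matrix")
  mean_clr <- colMeans(csub)
  eig <- eigenvector_centrality(net)[nodes]
  ubiq <- nodes %in% ubiquity(table, group)
  out <- data.frame(taxon = nodes, mean_clr = unname(mean_clr),
                    eigenvector = unname(eig), ubiquitous = ubiq,
                    is_keystone = ubiq & mean_clr >= abund_cut & eig >= eig_cut,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("keystone_report", class(out))
  out
}

#' Export a network as GraphML or GEXF
#'
#' Writes the graph with node attributes (whatever is present: `mean_clr`,
#' `eigenvector`, `module`, `ubiquitous`) and edge attributes (`weight`,
#' `sign`). GraphML goes through igraph; GEXF 1.2 is written directly.
#'
#' @param net a [conetwork].
#' @param path output path.
#' @param format `"graphml"` or `"gexf"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "gexf")) {
  format <- match.arg(format)
  g <- net$graph
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    write_gexf(g, path)
  }
  invisible(path)
}

write_gexf <- function(g, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", gsub(">", "&gt;", x)))
  vattrs <- setdiff(igraph::vertex_attr_names(g), "name")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines('<?xml version="1.0" encoding="UTF-8"?>', con)
  writeLines('<gexf xmlns="http://gexf.net/1.2" version="1.2">', con)
  writeLines('  <graph defaultedgetype="undirected">', con)
  if (length(vattrs)) {
    writeLines('    <attributes class="node">', con)
    for (i in seq_along(vattrs)) {
      ty <- if (is.numeric(igraph::vertex_attr(g, vattrs[i]))) "double"
            else if (is.logical(igraph::vertex_attr(g, vattrs[i]))) "boolean"
            else "string"
      writeLines(sprintf('      <attribute id="%d" title="%s" type="%s"/>',
                         i - 1L, esc(vattrs[i]), ty), con)
    }
    writeLines('    </attributes>', con)
  }
  writeLines('    <nodes>', con)
  for (v in seq_len(igraph::vcount(g))) {
    nm <- esc(igraph::V(g)$name[v])
    if (length(vattrs)) {
      writeLines(sprintf('      <node id="%s" label="%s">', nm, nm), con)
      writeLines('        <attvalues>', con)
      for (i in seq_along(vattrs))
        writeLines(sprintf('          <attvalue for="%d" value="%s"/>', i - 1L,
                           esc(as.character(igraph::vertex_attr(g, vattrs[i], v)))),
                   con)
      writeLines('        </attvalues>', con)
      writeLines('      </node>', con)
    } else {
      writeLines(sprintf('      <node id="%s" label="%s"/>', nm, nm), con)
    }
  }
  writeLines('    </nodes>', con)
  writeLines('    <edges>', con)
  el <- igraph::as_edgelist(g)
  for (e in seq_len(nrow(el)))
    writeLines(sprintf('      <edge id="%d" source="%s" target="%s" weight="%s"/>',
                       e - 1L, esc(el[e, 1]), esc(el[e, 2]),
                       format(abs(igraph::E(g)$weight[e]), digits = 10)), con)
  writeLines('    </edges>', con)
  writeLines('  </graph>', con)
  writeLines('</gexf>', con)
}
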