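#' Connectivity loss after node removal
#'
#' `loss = 1 - R/R0`, where `R0` is the number of ordered node pairs that
#' are mutually reachable in the original graph and `R` the number of such
#' pairs among the surviving nodes of the pruned graph; removed nodes count
#' as fully disconnected. This is the connectivity-loss notion used for
#' targeted-attack robustness.
#'
#' @param original a [conetwork].
#' @param removed character vector of node names (subset of the network's
#'   nodes).
#' @return a number in \[0, 1\].
#' @export
connectivity_loss <- function(original, removed = character()) {
  g <- original$graph
  nodes <- igraph::V(g)$name
  if (!all(removed %in% nodes)) stop("removed node not in graph")
  n <- length(nodes)
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- vector("list", n)
  for (r in seq_len(nrow(el))) {
    adj[[el[r, 1]]] <- c(adj[[el[r, 1]]], el[r, 2])
    adj[[el[r, 2]]] <- c(adj[[el[r, 2]]], el[r, 1])
  }
  pairs_alive <- function(alive) {
    seen <- !alive
    total <- 0
    for (s in seq_len(n)) {
      if (seen[s]) next
      stack <- s
      seen[s] <- TRUE
      size <- 0L
      while (length(stack)) {
        v <- stack[length(stack)]
        stack <- stack[-length(stack)]
        size <- size + 1L
        for (u in adj[[v]]) if (!seen[u]) { seen[u] <- TRUE; stack <- c(stack, u) }
      }
      total <- total + size * (size - 1)
    }
    total
  }
  r0 <- pairs_alive(rep(TRUE, n))
  if (r0 == 0) return(0)
  1 - pairs_alive(!(nodes %in% removed)) / r0
}

# 31-bit-safe combination of a root seed with a replicate index
mix_seed <- function(root, i) {
  as.integer((as.numeric(root) %% 2147483647 * 48271 + i * 16807) %% 2147483647)
}

reachable_pairs <- function(g) {
  if (igraph::vcount(g) == 0) return(0)
  cs <- igraph::components(g)$csize
  sum(cs * (cs - 1))
}

#' Simulate a node-removal attack
#'
#' Removes nodes one at a time in a strategy-dependent order, recording the
#' connectivity loss after every removal:
#' \describe{
#'   \item{random}{uniformly random order (seeded).}
#'   \item{degree}{descending degree, computed once on the intact graph.}
#'   \item{betweenness}{descending betweenness, computed once on the intact
#'     graph.}
#'   \item{cascading}{highest betweenness first, recomputed on the
#'     surviving graph before every removal.}
#' }
#' Centrality ties are broken lexicographically by node id, so all directed
#' strategies are deterministic.
#'
#' @param net a [conetwork] with at least 2 nodes.
#' @param strategy one of `"random"`, `"degree"`, `"betweenness"`,
#'   `"cascading"`.
#' @param target connectivity-loss target (default 0.80).
#' @param seed integer seed (random strategy only).
#' @return an `attack_curve`: list with `strategy`, `removal_order`,
#'   `loss_at_step`, `fraction_at_target` (fraction of original nodes
#'   removed when loss first reaches `target`), `target`, `n_original`.
#' @export
attack <- function(net, strategy = c("random", "degree", "betweenness",
                                     "cascading"),
                   target = 0.80, seed = 1L) {
  strategy <- match.arg(strategy)
  g0 <- net$graph
  n <- igraph::vcount(g0)
  if (n < 2) stop("need at least 2 nodes")
  nodes <- igraph::V(g0)$name
  r0 <- reachable_pairs(g0)
  if (r0 == 0) stop("network has no connected pair")

  rank_desc <- function(score, names) names[order(-score, names)]
  order_nodes <- switch(strategy,
    random = { set.seed(seed); sample(nodes) },
    degree = rank_desc(igraph::degree(g0), nodes),
    betweenness = rank_desc(igraph::betweenness(g0, weights = NA), nodes),
    cascading = NULL)

  loss <- numeric(n)
  removal <- character(n)
  g <- g0
  for (k in seq_len(n)) {
    victim <- if (strategy == "cascading") {
      surv <- igraph::V(g)$name
      rank_desc(igraph::betweenness(g, weights = NA), surv)[1]
    } else order_nodes[k]
    removal[k] <- victim
    g <- igraph::delete_vertices(g, victim)
    loss[k] <- 1 - reachable_pairs(g) / r0
  }
  hit <- which(loss >= target)[1]
  structure(list(strategy = strategy, removal_order = removal,
                 loss_at_step = loss,
                 fraction_at_target = if (is.na(hit)) 1 else hit / n,
                 target = target, n_original = n),
            class = "attack_curve")
}

#' @export
print.attack_curve <- function(x, ...) {
  cat("attack_curve [", x$strategy, "]: ", x$n_original, " nodes; loss >= ",
      x$target, " after removing ",
      round(x$fraction_at_target * x$n_original), " nodes (fraction ",
      sprintf("%.3f", x$fraction_at_target), ")\n", sep = "")
  invisible(x)
}

#' Bootstrap CI for the random-attack removal fraction
#'
#' Runs `n_boot` independent seeded random attacks and reports the mean
#' fraction of nodes removed to reach the loss target with percentile
#' 2.5/97.5 bounds.
#'
#' @param net a [conetwork].
#' @param target connectivity-loss target.
#' @param n_boot number of bootstrap attack replicates (>= 2).
#' @param seed integer seed.
#' @return list with `mean`, `ci_low`, `ci_high`, `fractions`.
#' @export
random_attack_ci <- function(net, target = 0.80, n_boot = 100, seed = 1L) {
  if (n_boot < 2) stop("need n_boot >= 2")
  fr <- vapply(seq_len(n_boot), function(b)
    attack(net, "random", target = target,
           seed = mix_seed(seed, b))$fraction_at_target,
    numeric(1))
  ci <- stats::quantile(fr, c(0.025, 0.975), names = FALSE, type = 7)
  list(mean = mean(fr), ci_low = ci[1], ci_high = ci[2], fractions = fr)
}

#' Average path length over connected pairs
#'
#' Mean unweighted shortest-path length over the ordered node pairs that are
#' mutually reachable; `NaN` when no connected pair exists.
#'
#' @param net a [conetwork].
#' @return a single number (or `NaN`).
#' @export
apl <- function(net) {
  g <- net$graph
  if (igraph::vcount(g) == 0) stop("empty network")
  if (igraph::ecount(g) == 0) return(NaN)
  suppressWarnings(igraph::mean_distance(g, weights = NA, unconnected = TRUE))
}

#' Grow a network by random node addition
#'
#' Iteratively adds `k` new nodes; each connects by `attach_edges` edges of
#' unit positive weight to distinct existing nodes (previously added nodes
#' included) chosen uniformly at random or preferentially by degree. The
#' size of the largest connected component and the average path length are
#' recorded after every addition.
#'
#' @param net a non-empty [conetwork].
#' @param k number of nodes to add.
#' @param attach_edges edges per added node (must not exceed the current
#'   node count).
#' @param rule `"uniform"` or `"preferential"`.
#' @param seed integer seed.
#' @param trace_apl if `FALSE`, skip the (costly) APL at intermediate steps
#'   and record it only at the final one.
#' @return list with `network` (the grown [conetwork]) and `trace`
#'   (data.frame `iteration`, `lcc`, `apl`).
#' @export
add_nodes <- function(net, k, attach_edges = 1L, rule = c("uniform",
                                                          "preferential"),
                      seed = 1L, trace_apl = TRUE) {
  rule <- match.arg(rule)
  g <- net$graph
  n0 <- igraph::vcount(g)
  if (n0 == 0) stop("network is empty")
  if (k < 0) stop("k must be >= 0")
  if (attach_edges < 1) stop("attach_edges must be >= 1")
  if (attach_edges > n0) stop("attach_edges exceeds current node count")
  set.seed(seed)
  trace <- data.frame(iteration = integer(0), lcc = integer(0),
                      apl = numeric(0))
  if (k == 0) return(list(network = as_conetwork(g, net$threshold), trace = trace))
  lcc <- integer(k); apls <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    cur_n <- igraph::vcount(g)
    prob <- if (rule == "preferential")
      igraph::degree(g) + 1 else rep(1, cur_n)
    targets <- sample.int(cur_n, attach_edges, prob = prob)
    new_name <- sprintf("added_%04d", i)
    g <- igraph::add_vertices(g, 1, name = new_name)
    eids <- as.vector(rbind(cur_n + 1L, targets))
    g <- igraph::add_edges(g, eids, weight = 1, sign = 1L)
    lcc[i] <- max(igraph::components(g)$csize)
    if (trace_apl || i == k)
      apls[i] <- suppressWarnings(igraph::mean_distance(g, weights = NA,
                                                        unconnected = TRUE))
  }
  list(network = as_conetwork(g, net$threshold),
       trace = data.frame(iteration = seq_len(k), lcc = lcc, apl = apls))
}

#' Wilcoxon signed-rank test of paired differences, zeros dropped
#'
#' Exact two-sided signed-rank p-value for the null of zero median
#' difference (exact enumeration for n <= 25 without ties, normal
#' approximation otherwise); an all-zero difference vector gives p = 1.
#'
#' @param diffs numeric vector of differences.
#' @return two-sided p-value.
#' @export
signed_rank_p <- function(diffs) {
  diffs <- diffs[diffs != 0]
  n <- length(diffs)
  if (n == 0) return(1)
  exact <- n <= 25 && !any(duplicated(abs(diffs)))
  suppressWarnings(
    stats::wilcox.test(diffs, mu = 0, exact = exact, correct = !exact)$p.value)
}

#' Per-k statistics for node-addition traces
#'
#' For every k and metric (final LCC size, final APL), the per-replicate
#' difference from the un-grown baseline network is tested against zero
#' with an exact Wilcoxon signed-rank test; p-values are BH-adjusted across
#' the whole (k, metric) family.
#'
#' @param traces named list: `traces[[as.character(k)]]` is a list of
#'   `add_nodes()` results (>= 5 replicates each).
#' @param baseline the un-grown [conetwork].
#' @return data.frame with `k`, `metric`, `baseline`, `diff_mean`, `p`, `q`.
#' @export
addition_stats <- function(traces, baseline) {
  base_lcc <- max(igraph::components(baseline$graph)$csize)
  base_apl <- apl(baseline)
  rows <- list()
  for (kname in names(traces)) {
    reps <- traces[[kname]]
    if (length(reps) < 5) stop("need at least 5 replicates per k")
    fin <- lapply(reps, function(r) r$trace[nrow(r$trace), ])
    d_lcc <- vapply(fin, function(f) f$lcc, numeric(1)) - base_lcc
    d_apl <- vapply(fin, function(f) f$apl, numeric(1)) - base_apl
    rows[[length(rows) + 1L]] <- data.frame(
      k = as.integer(kname), metric = "lcc", baseline = base_lcc,
      diff_mean = mean(d_lcc), p = signed_rank_p(d_lcc))
    rows[[length(rows) + 1L]] <- data.frame(
      k = as.integer(kname), metric = "apl", baseline = base_apl,
      diff_mean = mean(d_apl), p = signed_rank_p(d_apl))
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Full robustness battery over a set of networks
#'
#' For each network: the removal-fraction-at-target for the cascading,
#' betweenness and degree attacks plus the random-attack bootstrap mean and
#' 95% CI; and node-addition traces for every `k` in `k_add` with `n_reps`
#' replicates, summarized by [addition_stats()].
#'
#' @param nets named list of [conetwork] objects.
#' @param target connectivity-loss target (default 0.80).
#' @param n_boot random-attack bootstrap replicates.
#' @param k_add node-addition sizes (default `c(100, 300, 500, 700, 1000)`).
#' @param n_reps addition replicates per k (>= 5).
#' @param attach_edges,rule passed to [add_nodes()].
#' @param seed integer seed.
#' @param trace_apl record APL at every addition step (`FALSE` keeps only
#'   the final value per replicate, which is all [addition_stats()] needs).
#' @return list with `removal` (data.frame: network, strategy,
#'   fraction_at_target, ci_low, ci_high), `addition_traces` (long
#'   data.frame: network, k, replicate, iteration, lcc, apl) and
#'   `addition_stats` (per network x k x metric).
#' @export
robustness_battery <- function(nets, target = 0.80, n_boot = 100,
                               k_add = c(100, 300, 500, 700, 1000),
                               n_reps = 5, attach_edges = 1L,
                               rule = "uniform", seed = 1L,
                               trace_apl = TRUE) {
  if (length(nets) < 1) stop("need at least one network")
  if (is.null(names(nets))) names(nets) <- paste0("net", seq_along(nets))
  removal <- list(); traces_long <- list(); stats_all <- list()
  for (nm in names(nets)) {
    net <- nets[[nm]]
    for (st in c("cascading", "betweenness", "degree")) {
      a <- attack(net, st, target = target)
      removal[[length(removal) + 1L]] <- data.frame(
        network = nm, strategy = st, fraction_at_target = a$fraction_at_target,
        ci_low = NA_real_, ci_high = NA_real_)
    }
    rc <- random_attack_ci(net, target = target, n_boot = n_boot,
                           seed = mix_seed(seed, match(nm, names(nets))))
    removal[[length(removal) + 1L]] <- data.frame(
      network = nm, strategy = "random", fraction_at_target = rc$mean,
      ci_low = rc$ci_low, ci_high = rc$ci_high)

    traces <- list()
    for (k in k_add) {
      reps <- lapply(seq_len(n_reps), function(r)
        add_nodes(net, k, attach_edges = attach_edges, rule = rule,
                  seed = mix_seed(seed, k * 101L + r), trace_apl = trace_apl))
      traces[[as.character(k)]] <- reps
      for (r in seq_along(reps)) {
        tr <- reps[[r]]$trace
        traces_long[[length(traces_long) + 1L]] <- data.frame(
          network = nm, k = k, replicate = r, iteration = tr$iteration,
          lcc = tr$lcc, apl = tr$apl)
      }
    }
    st <- addition_stats(traces, net)
    st <- cbind(network = nm, st)
    stats_all[[length(stats_all) + 1L]] <- st
  }
  list(removal = do.call(rbind, removal),
       addition_traces = do.call(rbind, traces_long),
       addition_stats = do.call(rbind, stats_all))
}
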