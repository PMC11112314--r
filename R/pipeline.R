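#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()] with the
#' standard defaults: edge threshold 0.75, core threshold 0.95, keystone
#' cutoffs 0.35 (mean clr) and 0.75 (eigenvector centrality), abundance
#' filter 10 reads / 30% prevalence, contaminant score threshold 0.1,
#' connectivity-loss target 0.80, SparCC with 20 Dirichlet resamples, and
#' node addition of 100/300/500/700/1000 nodes with 5 replicates. Either
#' set `input$counts_tsv` + `input$metadata_tsv` or leave `input = NULL` to
#' use the synthetic generator settings in `synthetic`.
#'
#' @param seed root seed; every stage derives its own substream from it.
#' @return a named list (class `miconet_config`).
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    input = NULL,
    synthetic = list(
      n_taxa = 30L, n_modules = 3L, p_within = 0.25, p_between = 0.01,
      neg_frac = 0.3, corr_strength = 0.8,
      groups = c("control", "cancer"), timepoints = c("16dpi", "22dpi"),
      n_samples_per_group = 8L, depth = 5000, depth_dispersion = 0.05,
      logmean_range = c(0, 3),
      n_contaminants = 2L, n_controls = 4L,
      prevalence_in_controls = 1.0, prevalence_in_samples = 0.1),
    thresholds = list(
      edge = 0.75, core = 0.95, keystone_abund = 0.35, keystone_eig = 0.75,
      min_total_reads = 10, min_prevalence = 0.30, loss_target = 0.80,
      contaminant_score = 0.1),
    sparcc = list(n_resamples = 20L, prior = 1, exclusion_threshold = 0.8,
                  max_exclusion_rounds = 10L),
    robustness = list(n_boot = 100L, k_add = c(100L, 300L, 500L, 700L, 1000L),
                      n_reps = 5L, attach_edges = 1L, rule = "uniform",
                      trace_apl = FALSE),
    diversity = list(n_perm = 999L, rarefy_depth = NULL),
    diff_abundance = list(n_mc_instances = 128L)
  ), class = "miconet_config")
}

#' Validate a pipeline configuration
#'
#' Checks every threshold against its documented range and fails before any
#' computation, naming the offending field.
#'
#' @param config a list as produced by [default_config()].
#' @return the config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  th <- config$thresholds
  chk <- function(ok, field, msg)
    if (!isTRUE(ok)) stop("invalid config field `", field, "`: ", msg)
  chk(is.numeric(config$seed), "seed", "must be numeric")
  chk(th$edge > 0 && th$edge < 1, "thresholds$edge", "must lie in (0,1)")
  chk(th$core > 0 && th$core < 1, "thresholds$core", "must lie in (0,1)")
  chk(th$keystone_eig >= 0 && th$keystone_eig <= 1,
      "thresholds$keystone_eig", "must lie in [0,1]")
  chk(th$min_total_reads >= 0, "thresholds$min_total_reads", "must be >= 0")
  chk(th$min_prevalence >= 0 && th$min_prevalence <= 1,
      "thresholds$min_prevalence", "must lie in [0,1]")
  chk(th$loss_target > 0 && th$loss_target <= 1,
      "thresholds$loss_target", "must lie in (0,1]")
  chk(th$contaminant_score > 0 && th$contaminant_score <= 1,
      "thresholds$contaminant_score", "must lie in (0,1]")
  chk(config$sparcc$n_resamples >= 1, "sparcc$n_resamples", "must be >= 1")
  chk(all(config$robustness$k_add >= 0), "robustness$k_add", "must be >= 0")
  chk(config$robustness$n_reps >= 5, "robustness$n_reps", "must be >= 5")
  invisible(config)
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @param config a config list.
#' @return `read_config` returns a validated config; `write_config` the
#'   path, invisibly.
#' @export
read_config <- function(path) {
  cfg <- utils::modifyList(default_config(), yaml::read_yaml(path),
                           keep.null = TRUE)
  class(cfg) <- "miconet_config"
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# deterministic per-stage substreams from one root seed (31-bit safe)
stage_seed <- function(root, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(root) * 7919 + h * 104729) %% 2147483647)
}

#' Generate the bundled synthetic study
#'
#' Builds the four-condition synthetic dataset the pipeline is demonstrated
#' on: one planted basis network shared by all groups plus a second,
#' rewired network for the "cancer" groups (so group networks genuinely
#' differ), logistic-normal--multinomial counts per condition cell, and
#' spiked contaminants with negative controls.
#'
#' @param cfg the `synthetic` sub-list of a [default_config()].
#' @param seed integer seed.
#' @return list with `table` (an [abundance_table()] including controls),
#'   `ground_truth` (named list of `ground_truth_network` per group).
#' @export
simulate_study <- function(cfg, seed = 1L) {
  gts <- list()
  tabs <- list()
  for (gi in seq_along(cfg$groups)) {
    g <- cfg$groups[gi]
    # per-group basis network: different seeds give rewired module edges
    gt <- make_basis_network(cfg$n_taxa, cfg$n_modules, cfg$p_within,
                             cfg$p_between, cfg$neg_frac, cfg$corr_strength,
                             seed = stage_seed(seed, paste0("basis_", g)))
    gts[[g]] <- gt
    for (tp in cfg$timepoints) {
      tab <- simulate_counts(
        gt, cfg$n_samples_per_group, depth = cfg$depth,
        depth_dispersion = cfg$depth_dispersion,
        logmean_range = cfg$logmean_range, group = g, timepoint = tp,
        sample_prefix = paste(g, tp, sep = "_"),
        seed = stage_seed(seed, paste0("counts_", g, "_", tp)))
      tabs[[length(tabs) + 1L]] <- tab
    }
  }
  cts <- do.call(rbind, lapply(tabs, function(t) t$counts))
  md <- do.call(rbind, lapply(tabs, function(t) t$metadata))
  table <- abundance_table(cts, md)
  if (cfg$n_contaminants > 0 || cfg$n_controls > 0)
    table <- spike_contaminants(
      table, cfg$n_contaminants, cfg$n_controls,
      cfg$prevalence_in_controls, cfg$prevalence_in_samples,
      seed = stage_seed(seed, "contaminants"))
  list(table = table, ground_truth = gts)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the whole workflow from a count table (or the synthetic
#' generator) to exported artifacts: contaminant flagging and removal,
#' low-abundance filtering, per-condition clr transformation, alpha and
#' Jaccard beta diversity with PERMANOVA, SparCC correlation inference,
#' 0.75 and core 0.95 networks, topology summaries, keystone taxa,
#' cross-network node comparison, the robustness battery, and pairwise
#' differential abundance between matching conditions. All randomness
#' derives from `config$seed`, so reruns are byte-identical.
#'
#' @param config a validated configuration (see [default_config()]).
#' @param outdir output directory (created if missing).
#' @param quiet suppress stage logging.
#' @return (invisibly) a list with the in-memory results: `table`,
#'   `filtered`, `flagged`, `networks`, `core_networks`, `topology`,
#'   `keystones`, `diversity`, `robustness`, `diff_abundance`,
#'   `comparison`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("miconet_"),
                         quiet = FALSE) {
  validate_config(config)
  say <- function(...) if (!quiet) message("[miconet] ", ...)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  if (is.null(config$input)) {
    say("simulating synthetic study (",
        config$synthetic$n_taxa, " taxa)")
    sim <- simulate_study(config$synthetic, seed = stage_seed(seed, "simulate"))
    table <- sim$table
    write_table_tsv(table, file.path(outdir, "counts_raw.tsv"),
                    file.path(outdir, "metadata.tsv"))
  } else {
    say("reading input tables")
    table <- read_table_tsv(config$input$counts_tsv, config$input$metadata_tsv)
  }
  say("input: ", nrow(table$counts), " samples x ", ncol(table$counts), " taxa")

  # contaminant removal (only when controls are present)
  flagged <- character()
  if (any(table$metadata$is_control)) {
    flagged <- flag_contaminants(table, config$thresholds$contaminant_score)
    say("flagged ", length(flagged), " contaminant taxa: ",
        paste(flagged, collapse = ", "))
    keep_taxa <- setdiff(taxon_ids(table), flagged)
    true_samples <- sample_ids(table)[!table$metadata$is_control]
    table <- subset_table(table, samples = true_samples, taxa = keep_taxa)
  }

  filtered <- filter_low_abundance(table, config$thresholds$min_total_reads,
                                   config$thresholds$min_prevalence)
  say("after abundance filter: ", ncol(filtered$counts), " taxa")
  write_table_tsv(filtered, file.path(outdir, "counts_filtered.tsv"),
                  file.path(outdir, "metadata_filtered.tsv"))
  write_table_biom(filtered, file.path(outdir, "counts_filtered.biom"))

  labels <- group_labels(filtered)
  cells <- sort(unique(labels))

  # diversity on the filtered table
  depth <- config$diversity$rarefy_depth %||% min(rowSums(filtered$counts))
  rare <- rarefy(filtered, depth, seed = stage_seed(seed, "rarefy"))
  alpha <- observed_features(rare)
  utils::write.table(
    data.frame(sample_id = names(alpha), metric = "observed_features",
               value = as.integer(alpha)),
    file.path(outdir, "alpha_diversity.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  dm <- jaccard_matrix(rare)
  write_distance_tsv(dm, file.path(outdir, "jaccard_distance.tsv"))
  perm <- permanova(dm, labels, n_perm = config$diversity$n_perm,
                    seed = stage_seed(seed, "permanova"))
  say(sprintf("PERMANOVA over %d conditions: pseudo-F = %.3f, p = %.4f",
              length(cells), perm$pseudo_F, perm$p_value))

  clr <- clr_transform(filtered)

  networks <- list(); core_networks <- list(); topology <- list()
  keystones <- list(); fits <- list()
  for (cell in cells) {
    sub <- subset_table(filtered, samples = sample_ids(filtered)[labels == cell])
    fit <- sparcc(sub, n_resamples = config$sparcc$n_resamples,
                  prior = config$sparcc$prior,
                  exclusion_threshold = config$sparcc$exclusion_threshold,
                  max_exclusion_rounds = config$sparcc$max_exclusion_rounds,
                  seed = stage_seed(seed, paste0("sparcc_", cell)))
    fits[[cell]] <- fit
    write_correlations_tsv(fit, file.path(outdir, paste0("sparcc_", cell, ".tsv")))
    net <- build_network(fit, config$thresholds$edge)
    core <- tryCatch(core_network(fit), error = function(e) NULL)
    networks[[cell]] <- net
    core_networks[[cell]] <- core
    topo <- topology_summary(net)
    topology[[cell]] <- topo
    ks <- keystone_taxa(net, clr, filtered, cell,
                        abund_cut = config$thresholds$keystone_abund,
                        eig_cut = config$thresholds$keystone_eig)
    keystones[[cell]] <- ks
    say(cell, ": ", topo$n_nodes, " nodes, ", topo$n_edges, " edges, ",
        sum(ks$is_keystone), " keystone taxa")

    # annotate and export
    g <- net$graph
    igraph::V(g)$mean_clr <- ks$mean_clr[match(igraph::V(g)$name, ks$taxon)]
    igraph::V(g)$eigenvector <- ks$eigenvector[match(igraph::V(g)$name, ks$taxon)]
    igraph::V(g)$ubiquitous <- ks$ubiquitous[match(igraph::V(g)$name, ks$taxon)]
    igraph::V(g)$module <- as.integer(topo$membership[igraph::V(g)$name])
    annotated <- as_conetwork(g, net$threshold)
    write_network(annotated, file.path(outdir, paste0("network_", cell, ".graphml")))
    write_network(annotated, file.path(outdir, paste0("network_", cell, ".gexf")),
                  format = "gexf")
    utils::write.table(ks, file.path(outdir, paste0("keystones_", cell, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  topo_df <- do.call(rbind, lapply(cells, function(cell) {
    t <- topology[[cell]]
    data.frame(network = cell, n_nodes = t$n_nodes, n_edges = t$n_edges,
               n_positive = t$n_positive, n_negative = t$n_negative,
               modularity = t$modularity, n_modules = t$n_modules,
               diameter = t$diameter, avg_degree = t$avg_degree,
               weighted_degree = t$weighted_degree,
               clustering_coefficient = t$clustering_coefficient)
  }))
  utils::write.table(topo_df, file.path(outdir, "topology.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  comparison <- compare_networks(networks)
  utils::write.table(comparison$patterns, file.path(outdir, "node_overlap.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("robustness battery over ", length(networks), " networks")
  rob <- robustness_battery(
    networks, target = config$thresholds$loss_target,
    n_boot = config$robustness$n_boot, k_add = config$robustness$k_add,
    n_reps = config$robustness$n_reps,
    attach_edges = config$robustness$attach_edges,
    rule = config$robustness$rule, seed = stage_seed(seed, "robustness"),
    trace_apl = config$robustness$trace_apl)
  utils::write.table(rob$removal, file.path(outdir, "robustness_removal.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rob$addition_traces,
                     file.path(outdir, "robustness_addition_traces.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rob$addition_stats,
                     file.path(outdir, "robustness_addition_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # pairwise differential abundance between groups at matching timepoints
  diffs <- list()
  md <- filtered$metadata
  for (tp in unique(as.character(md$timepoint))) {
    gs <- unique(as.character(md$group[md$timepoint %in% tp]))
    if (length(gs) < 2) next
    prs <- utils::combn(sort(gs), 2)
    for (c_ in seq_len(ncol(prs))) {
      a <- paste(prs[1, c_], tp, sep = "_"); b <- paste(prs[2, c_], tp, sep = "_")
      da <- diff_abundance(filtered, a, b,
                           n_mc_instances = config$diff_abundance$n_mc_instances,
                           seed = stage_seed(seed, paste0("da_", a, "_", b)))
      diffs[[paste(a, "vs", b)]] <- da
      utils::write.table(da,
        file.path(outdir, paste0("diff_abundance_", a, "_vs_", b, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  manifest <- list(
    package = "miconet",
    version = as.character(utils::packageVersion("miconet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = config_hash(config),
    n_samples = nrow(filtered$counts), n_taxa = ncol(filtered$counts),
    conditions = cells, flagged_contaminants = flagged,
    permanova = perm[c("pseudo_F", "p_value")])
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("artifacts written to ", outdir)

  invisible(list(table = table, filtered = filtered, flagged = flagged,
                 sparcc = fits, networks = networks,
                 core_networks = core_networks, topology = topology,
                 keystones = keystones,
                 diversity = list(alpha = alpha, jaccard = dm, permanova = perm,
                                  rarefy_depth = depth),
                 robustness = rob, diff_abundance = diffs,
                 comparison = comparison, manifest = manifest,
                 outdir = outdir))
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # small rolling hash; enough to detect config drift in the manifest
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% .Machine$integer.max)
}

#' Shared and unique nodes across networks
#'
#' Per-taxon membership across a set of networks plus intersection-pattern
#' counts (the tabular equivalent of an UpSet plot).
#'
#' @param nets named list of at least two [conetwork] objects.
#' @return list with `membership` (data.frame, one row per taxon, one
#'   logical column per network) and `patterns` (data.frame `pattern`,
#'   `n_taxa`: counts per distinct presence pattern, `pattern` a
#'   `+`/`-`-string in network order).
#' @export
compare_networks <- function(nets) {
  if (length(nets) < 2) stop("need at least 2 networks")
  if (is.null(names(nets))) names(nets) <- paste0("net", seq_along(nets))
  all_taxa <- sort(unique(unlist(lapply(nets, nodes_of))))
  memb <- vapply(nets, function(n) all_taxa %in% nodes_of(n),
                 logical(length(all_taxa)))
  memb <- matrix(memb, nrow = length(all_taxa),
                 dimnames = list(all_taxa, names(nets)))
  pattern <- apply(memb, 1, function(r) paste(ifelse(r, "+", "-"), collapse = ""))
  pat <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(pat) <- c("pattern", "n_taxa")
  pat <- pat[order(-pat$n_taxa, pat$pattern), , drop = FALSE]
  rownames(pat) <- NULL
  list(membership = data.frame(taxon = all_taxa, memb, row.names = NULL,
                               check.names = FALSE),
       patterns = pat)
}
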