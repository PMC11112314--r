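#' Sample-by-taxon abundance table
#'
#' The pipeline's universal input: a samples x taxa matrix of non-negative
#' integer read counts plus per-sample metadata (group label, timepoint,
#' negative-control flag). Genus-collapsed 16S count tables are the intended
#' use case, but any compositional count table fits.
#'
#' @param counts integer matrix, samples in rows, taxa in columns; must carry
#'   both rownames (sample ids) and colnames (taxon ids).
#' @param metadata data.frame with columns `sample_id`, `group`, `timepoint`,
#'   `is_control`; one row per sample, in any order.
#' @return An object of class `abundance_table`: a list with elements
#'   `counts` (integer matrix) and `metadata` (data.frame aligned to the
#'   matrix rows).
#' @examples
#' cts <- matrix(rpois(12, 20), 3, 4,
#'               dimnames = list(paste0("s", 1:3), paste0("t", 1:4)))
#' md <- data.frame(sample_id = rownames(cts), group = "A",
#'                  timepoint = "d16", is_control = FALSE)
#' abundance_table(cts, md)
#' @export
abundance_table <- function(counts, metadata) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have sample rownames and taxon colnames")
  if (anyDuplicated(colnames(counts))) stop("taxon ids must be unique")
  if (anyDuplicated(rownames(counts))) stop("sample ids must be unique")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  need <- c("sample_id", "group", "timepoint", "is_control")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (!setequal(metadata$sample_id, rownames(counts)))
    stop("metadata sample_id set must match count matrix rownames")
  metadata <- metadata[match(rownames(counts), metadata$sample_id), need, drop = FALSE]
  rownames(metadata) <- NULL
  metadata$is_control <- as.logical(metadata$is_control)
  structure(list(counts = counts, metadata = metadata), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table: ", nrow(x$counts), " samples x ", ncol(x$counts),
      " taxa\n", sep = "")
  ctrl <- sum(x$metadata$is_control)
  grp <- table(group_labels(x)[!x$metadata$is_control])
  cat("  groups: ", paste(names(grp), grp, sep = "=", collapse = ", "),
      if (ctrl) paste0("; ", ctrl, " negative control(s)"), "\n", sep = "")
  cat("  total reads: ", sum(x$counts), "\n", sep = "")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' Sample and taxon identifiers of an abundance table
#' @param table an [abundance_table()].
#' @return character vector of ids, in matrix order.
#' @export
sample_ids <- function(table) rownames(table$counts)

#' @rdname sample_ids
#' @export
taxon_ids <- function(table) colnames(table$counts)

#' Combined group x timepoint label per sample
#'
#' Network construction and keystone analysis operate on one condition cell
#' (group x timepoint) at a time; this helper produces the combined label
#' (`group_timepoint`, or just `group` when the timepoint is missing).
#'
#' @param table an [abundance_table()].
#' @return character vector, one label per sample.
#' @export
group_labels <- function(table) {
  md <- table$metadata
  tp <- as.character(md$timepoint)
  ifelse(is.na(tp) | tp == "", as.character(md$group),
         paste(md$group, tp, sep = "_"))
}

#' Subset an abundance table
#'
#' @param table an [abundance_table()].
#' @param samples,taxa character vectors of ids to keep (default: all).
#' @return an [abundance_table()] restricted to the requested ids, in the
#'   requested order.
#' @export
subset_table <- function(table, samples = sample_ids(table),
                         taxa = taxon_ids(table)) {
  if (!all(samples %in% sample_ids(table))) stop("unknown sample id(s)")
  if (!all(taxa %in% taxon_ids(table))) stop("unknown taxon id(s)")
  if (length(samples) == 0L) stop("cannot subset to zero samples")
  if (length(taxa) == 0L) stop("cannot subset to zero taxa")
  cts <- table$counts[samples, taxa, drop = FALSE]
  md <- table$metadata[match(samples, table$metadata$sample_id), , drop = FALSE]
  abundance_table(cts, md)
}

#' Write / read an abundance table as TSV
#'
#' The count matrix is written taxa-as-rows (first column `taxon_id`, one
#' column per sample) and the metadata as a separate four-column TSV
#' (`sample_id`, `group`, `timepoint`, `is_control`).
#'
#' @param table an [abundance_table()].
#' @param counts_path,metadata_path file paths for the two TSVs.
#' @return `write_table_tsv` returns the paths invisibly; `read_table_tsv`
#'   returns an [abundance_table()].
#' @export
write_table_tsv <- function(table, counts_path, metadata_path) {
  df <- data.frame(taxon_id = taxon_ids(table), t(table$counts),
                   check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_path, metadata_path))
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(counts_path, metadata_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  cts <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(cts) <- df[[1]]
  md <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  abundance_table(cts, md)
}

#' Write / read an abundance table as BIOM-style JSON
#'
#' A minimal dense BIOM (format 1.0, JSON) serialization: taxa as rows and
#' samples as columns, with the sample metadata embedded per column. Readable
#' by BIOM-aware tools and by [read_table_biom()].
#'
#' @param table an [abundance_table()].
#' @param path output `.biom` (JSON) file path.
#' @return `write_table_biom` returns `path` invisibly; `read_table_biom`
#'   returns an [abundance_table()].
#' @export
write_table_biom <- function(table, path) {
  md <- table$metadata
  cols <- lapply(seq_len(nrow(md)), function(i) {
    list(id = md$sample_id[i],
         metadata = list(group = as.character(md$group[i]),
                         timepoint = as.character(md$timepoint[i]),
                         is_control = md$is_control[i]))
  })
  rows <- lapply(taxon_ids(table), function(t) list(id = t, metadata = NULL))
  obj <- list(
    id = NULL, format = "Biological Observation Matrix 1.0.0",
    format_url = "http://biom-format.org",
    type = "OTU table", generated_by = "miconet",
    date = "1970-01-01T00:00:00",
    matrix_type = "dense", matrix_element_type = "int",
    shape = c(ncol(table$counts), nrow(table$counts)),
    rows = rows, columns = cols,
    data = lapply(seq_len(ncol(table$counts)),
                  function(j) unname(table$counts[, j]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_table_biom
#' @export
read_table_biom <- function(path) {
  obj <- jsonlite::read_json(path)
  taxa <- vapply(obj$rows, function(r) r$id, "")
  samples <- vapply(obj$columns, function(c) c$id, "")
  if (!identical(obj$matrix_type, "dense"))
    stop("only dense BIOM matrices are supported")
  cts <- t(vapply(obj$data, function(r) as.numeric(unlist(r)),
                  numeric(length(samples))))
  if (length(taxa) == 1L) cts <- matrix(cts, nrow = 1L)
  dimnames(cts) <- list(taxa, samples)
  md <- do.call(rbind, lapply(obj$columns, function(c) {
    data.frame(sample_id = c$id,
               group = c$metadata$group %||% NA_character_,
               timepoint = c$metadata$timepoint %||% NA_character_,
               is_control = isTRUE(c$metadata$is_control),
               stringsAsFactors = FALSE)
  }))
  abundance_table(t(cts), md)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
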