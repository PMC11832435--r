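#' Read a feature table from TSV
#'
#' Expects a tab-separated file with a header row of feature IDs and the first
#' column holding sample IDs (samples in rows). A transposed file (features in
#' rows) is accepted only when declared with `transposed = TRUE`; orientation
#' is never guessed. Missing cells are errors, not zeros: zero-versus-missing
#' ambiguity corrupts rank-based statistics downstream.
#'
#' @param path file path.
#' @param kind feature kind, see [feature_table()].
#' @param transposed set `TRUE` when the file stores features in rows.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, kind, transposed = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "", comment.char = "")
  if (ncol(raw) < 2) stop("expected at least one feature column in ", path, call. = FALSE)
  ids <- raw[[1]]
  validate_ids(ids, if (transposed) "feature" else "sample")
  validate_ids(colnames(raw)[-1], if (transposed) "sample" else "feature")
  mat <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(raw) - 1,
                dimnames = list(ids, colnames(raw)[-1]))
  for (j in seq_len(ncol(mat))) {
    cell <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) | !nzchar(trimws(cell)))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric or missing cell at row '%s', column '%s': '%s'",
                   ids[bad[1]], colnames(mat)[j], cell[bad[1]]), call. = FALSE)
    }
    neg <- which(num < 0)
    if (length(neg) > 0) {
      stop(sprintf("negative abundance at row '%s', column '%s': %s",
                   ids[neg[1]], colnames(mat)[j], cell[neg[1]]), call. = FALSE)
    }
    mat[, j] <- num
  }
  if (transposed) mat <- t(mat)
  feature_table(mat, kind)
}

#' Write a feature table as TSV
#'
#' Inverse of [read_feature_table()]: samples in rows, header row of feature
#' IDs, first column `sample_id`. Full double precision is retained.
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(sample_id = rownames(table), ft_matrix(table),
                   check.names = FALSE)
  utils::write.table(format_numeric_df(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

format_numeric_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- format(df[[j]], digits = 17, trim = TRUE,
                                               scientific = FALSE)
  }
  df
}

#' Read sample metadata from TSV
#'
#' Columns `sample_id`, `group`, `timepoint`, `generation`, `dyad_id`
#' (tab-separated, header row). Empty `dyad_id` cells become `NA`.
#'
#' @param path file path.
#' @return a [sample_metadata()] tibble.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "", na.strings = c("NA", ""))
  sample_metadata(df)
}

#' Write sample metadata as TSV
#' @param metadata a [sample_metadata()] tibble.
#' @param path output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(as.data.frame(metadata), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a literature gene-gene edge list
#'
#' TSV with columns `gene_a`, `gene_b` and an optional third column carrying a
#' sign or free-text annotation. Self-loops are rejected.
#'
#' @param path file path.
#' @return tibble with columns `gene_a`, `gene_b`, `annotation`.
#' @export
read_gene_edges <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "", comment.char = "")
  if (ncol(df) < 2) stop("gene edge list needs at least two columns", call. = FALSE)
  out <- tibble::tibble(
    gene_a = df[[1]], gene_b = df[[2]],
    annotation = if (ncol(df) >= 3) df[[3]] else NA_character_)
  gene_edge_list(out)
}

#' Validate a gene-gene edge list
#' @param edges data frame with columns `gene_a`, `gene_b` (and optionally
#'   `annotation`).
#' @return validated tibble.
#' @export
gene_edge_list <- function(edges) {
  edges <- tibble::as_tibble(edges)
  if (!all(c("gene_a", "gene_b") %in% names(edges))) {
    stop("edge list must have columns gene_a, gene_b", call. = FALSE)
  }
  if (!("annotation" %in% names(edges))) edges$annotation <- NA_character_
  if (any(!nzchar(edges$gene_a)) || any(!nzchar(edges$gene_b))) {
    stop("edge endpoints must be non-empty strings", call. = FALSE)
  }
  loops <- edges$gene_a == edges$gene_b
  if (any(loops)) {
    stop("self-loop in gene edge list: '", edges$gene_a[which(loops)[1]], "'",
         call. = FALSE)
  }
  edges[c("gene_a", "gene_b", "annotation")]
}

#' Read a gene-to-pathway annotation map
#'
#' TSV with columns `gene`, `pathway`; a gene may appear on several rows, one
#' per pathway label.
#'
#' @param path file path.
#' @return named list mapping gene ID to a character vector of pathway labels.
#' @export
read_pathway_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "", comment.char = "")
  if (!all(c("gene", "pathway") %in% names(df))) {
    stop("pathway map must have columns gene, pathway", call. = FALSE)
  }
  if (any(!nzchar(df$pathway))) stop("pathway labels must be non-empty", call. = FALSE)
  split(df$pathway, df$gene)
}

#' Export a distance matrix as square TSV
#' @param dm a [dist_matrix()].
#' @param path output path.
#' @export
write_distance_matrix <- function(dm, path) {
  m <- as.matrix(dm)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(format_numeric_df(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
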