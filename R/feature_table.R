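#' Feature abundance table
#'
#' The central container of the package: a samples x features matrix of
#' non-negative abundances together with a declared feature kind. Sample IDs
#' are the rownames, feature IDs the colnames; both must be unique and
#' non-empty. The `kind` records what the features are (bacterial taxa, lipid
#' species, genes or small-molecule metabolites) so that downstream stages can
#' refuse a table of the wrong layer.
#'
#' @param mat numeric matrix, samples in rows, features in columns, with
#'   rownames (sample IDs) and colnames (feature IDs).
#' @param kind one of `"taxon"`, `"lipid"`, `"gene"`, `"metabolite"`.
#' @return An object of class `feature_table`: the matrix with attributes
#'   `kind`.
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(paste0("S", 1:3), c("fA", "fB")))
#' ft <- feature_table(m, "taxon")
#' dim(ft)
#' @export
feature_table <- function(mat, kind = c("taxon", "lipid", "gene", "metabolite")) {
  kind <- match.arg(kind)
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("`mat` must be a numeric matrix (samples x features)", call. = FALSE)
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("`mat` must carry sample IDs as rownames and feature IDs as colnames",
         call. = FALSE)
  }
  validate_ids(rownames(mat), "sample")
  validate_ids(colnames(mat), "feature")
  bad <- which(!is.finite(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "negative or non-finite abundance at sample '%s', feature '%s'",
      rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]), call. = FALSE)
  }
  structure(mat, kind = kind, class = c("feature_table", "matrix", "array"))
}

validate_ids <- function(ids, what) {
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop(sprintf("%s IDs must be non-empty strings", what), call. = FALSE)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop(sprintf("duplicated %s ID: '%s'", what, dup[1]), call. = FALSE)
  }
  invisible(ids)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d %s features\n",
              nrow(x), ncol(x), attr(x, "kind")))
  if (nrow(x) > 0 && ncol(x) > 0) {
    print(utils::head(unclass(x)[, seq_len(min(5, ncol(x))), drop = FALSE], 5))
  }
  invisible(x)
}

#' Feature kind of a table
#' @param x a [feature_table()].
#' @return the kind string.
#' @export
table_kind <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  attr(x, "kind")
}

ft_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "kind") <- NULL
  m
}

#' Sample metadata table
#'
#' Validates a per-sample metadata data frame: exposure group (CC = no
#' antibiotic exposure, AC = prenatal only, CA = postnatal only, AA = both),
#' collection timepoint (BF = breastfeeding, CD = chow diet, HFD = high-fat
#' diet), generation (dam or pup), and an optional dyad ID linking a dam to
#' her pup.
#'
#' @param df data frame with columns `sample_id`, `group`, `timepoint`,
#'   `generation`, `dyad_id` (`dyad_id` may be `NA`).
#' @return a validated tibble with class `sample_metadata`.
#' @export
sample_metadata <- function(df) {
  required <- c("sample_id", "group", "timepoint", "generation", "dyad_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::as_tibble(df[required])
  df$sample_id <- as.character(df$sample_id)
  df$dyad_id <- as.character(df$dyad_id)
  df$dyad_id[!is.na(df$dyad_id) & !nzchar(df$dyad_id)] <- NA_character_
  validate_ids(df$sample_id, "sample")
  check_levels(df$group, GROUP_LEVELS, "group")
  check_levels(df$timepoint, TIMEPOINT_LEVELS, "timepoint")
  check_levels(df$generation, GENERATION_LEVELS, "generation")
  class(df) <- c("sample_metadata", class(df))
  df
}

GROUP_LEVELS <- c("CC", "AC", "CA", "AA")
TIMEPOINT_LEVELS <- c("BF", "CD", "HFD")
GENERATION_LEVELS <- c("dam", "pup")

check_levels <- function(x, allowed, what) {
  bad <- setdiff(unique(as.character(x)), allowed)
  if (length(bad) > 0) {
    stop(sprintf("unknown %s label '%s'; allowed values: %s",
                 what, bad[1], paste(allowed, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# Align a metadata table to the samples of a feature table; every table
# sample must have exactly one metadata row.
align_metadata <- function(table, metadata) {
  idx <- match(rownames(table), metadata$sample_id)
  if (anyNA(idx)) {
    stop("sample '", rownames(table)[which(is.na(idx))[1]],
         "' has no metadata row", call. = FALSE)
  }
  metadata[idx, , drop = FALSE]
}
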