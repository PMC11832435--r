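LIPID_CLASSES <- c("LPC", "PC", "LPE", "PE", "LPA", "PA", "LPG", "PG",
                   "LPI", "PI", "LPS", "PS", "MG", "DG", "TG", "FA", "FFA",
                   "CE", "SM", "CER")

#' Bundled common fatty-acid name lookup
#'
#' Trivial-name table (behenic acid, palmitic acid, ...) mapping to sum
#' compositions. Users can extend or replace it by pointing `path` at their
#' own TSV with columns `common_name`, `class`, `carbons`, `double_bonds`.
#'
#' @param path TSV lookup file; defaults to the bundled table.
#' @return tibble lookup.
#' @export
fatty_acid_lookup <- function(path = system.file("extdata",
                                                 "fatty_acid_common_names.tsv",
                                                 package = "pupomics")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = c("character", "character",
                                         "integer", "integer"))
  tibble::as_tibble(df)
}

#' Parse lipid shorthand names
#'
#' Parses names of the form `CLASS(C:D)` — tolerant of spacing variants such
#' as `"LPC (22:0)"` — into class code, total acyl carbons and double bonds
#' (sum composition). Common fatty-acid trivial names (e.g. `"behenic acid"`,
#' optionally followed by their composition) are resolved through the bundled
#' lookup to `FA(C:D)`. The canonical form is `CLASS(C:D)` without spaces.
#'
#' @param names character vector of lipid names.
#' @param lookup common-name lookup tibble, see [fatty_acid_lookup()].
#' @return tibble of class `lipid_species`: columns `name` (input), `class`,
#'   `carbons`, `double_bonds`, `canonical`, `from_common_name`.
#' @examples
#' parse_lipid_name(c("LPC (22:0)", "behenic acid (22:0)"))
#' @export
parse_lipid_name <- function(names, lookup = fatty_acid_lookup()) {
  out <- lapply(names, parse_one_lipid, lookup = lookup)
  res <- tibble::as_tibble(do.call(rbind, lapply(out, as.data.frame)))
  class(res) <- c("lipid_species", class(res))
  res
}

parse_one_lipid <- function(name, lookup) {
  if (is.na(name) || !nzchar(trimws(name))) {
    stop("empty lipid name", call. = FALSE)
  }
  s <- trimws(name)
  # shorthand form CLASS(C:D)
  m <- regmatches(s, regexec("^([A-Za-z]+)\\s*\\(\\s*([0-9]+)\\s*:\\s*([0-9]+)\\s*\\)$", s))[[1]]
  if (length(m) == 4) {
    cls <- toupper(m[2])
    if (cls == "FFA") cls <- "FA"
    if (cls == "CER") cls <- "CER"
    if (!(cls %in% LIPID_CLASSES)) {
      stop("unknown lipid class token '", m[2], "' in '", name,
           "' (position 1)", call. = FALSE)
    }
    carbons <- as.integer(m[3]); db <- as.integer(m[4])
    if (carbons < 1) stop("carbons must be >= 1 in '", name, "'", call. = FALSE)
    return(list(name = name, class = cls, carbons = carbons,
                double_bonds = db,
                canonical = sprintf("%s(%d:%d)", cls, carbons, db),
                from_common_name = FALSE))
  }
  # trivial name, optionally followed by "(C:D)"
  m2 <- regmatches(s, regexec("^([A-Za-z][A-Za-z ]*?)\\s*(\\(\\s*([0-9]+)\\s*:\\s*([0-9]+)\\s*\\))?$", s))[[1]]
  if (length(m2) >= 2 && nzchar(m2[2])) {
    key <- tolower(trimws(m2[2]))
    hit <- which(tolower(lookup$common_name) == key)
    if (length(hit) == 1) {
      carbons <- lookup$carbons[hit]; db <- lookup$double_bonds[hit]
      cls <- toupper(lookup$class[hit])
      if (nzchar(m2[3])) {  # composition stated: must agree with the lookup
        c2 <- as.integer(m2[4]); d2 <- as.integer(m2[5])
        if (c2 != carbons || d2 != db) {
          stop("composition (", c2, ":", d2, ") contradicts lookup for '",
               key, "' (", carbons, ":", db, ")", call. = FALSE)
        }
      }
      return(list(name = name, class = cls, carbons = carbons,
                  double_bonds = db,
                  canonical = sprintf("%s(%d:%d)", cls, carbons, db),
                  from_common_name = TRUE))
    }
  }
  # diagnose the failure position: class token ok but composition malformed?
  m3 <- regmatches(s, regexec("^([A-Za-z]+)", s))[[1]]
  if (length(m3) == 2 && toupper(m3[2]) %in% LIPID_CLASSES) {
    stop("malformed composition in '", name, "' after position ",
         nchar(m3[2]), ": expected '(carbons:double_bonds)'", call. = FALSE)
  }
  stop("unknown lipid class or common name in '", name, "' (position 1)",
       call. = FALSE)
}

#' Match lysophosphatidylcholines to their cognate fatty acids
#'
#' Phospholipase A2 hydrolysis of a glycerophospholipid releases a free fatty
#' acid alongside the lysophospholipid, so an LPC and a fatty acid with the
#' same sum composition (carbons:double bonds) are treated as a cognate pair.
#' Matching is by composition equality; pairs are returned in lexicographic
#' order of (LPC canonical, FA raw name), one pair per distinct raw FA name.
#'
#' @param lpc_list,fa_list `lipid_species` tibbles from [parse_lipid_name()]
#'   (or character vectors, parsed on the fly). `lpc_list` entries must be
#'   class LPC, `fa_list` entries class FA.
#' @return tibble with columns `lpc`, `fa`, `lpc_name`, `fa_name`, `carbons`,
#'   `double_bonds`.
#' @export
match_cognates <- function(lpc_list, fa_list) {
  if (is.character(lpc_list)) lpc_list <- parse_lipid_name(lpc_list)
  if (is.character(fa_list)) fa_list <- parse_lipid_name(fa_list)
  lpc <- lpc_list[lpc_list$class == "LPC", , drop = FALSE]
  fa <- fa_list[fa_list$class == "FA", , drop = FALSE]
  pairs <- list()
  for (i in seq_len(nrow(lpc))) {
    hits <- which(fa$carbons == lpc$carbons[i] &
                  fa$double_bonds == lpc$double_bonds[i])
    hits <- hits[!duplicated(fa$name[hits])]
    for (h in hits) {
      row <- list(lpc = lpc$canonical[i], fa = fa$canonical[h],
                  lpc_name = lpc$name[i], fa_name = fa$name[h],
                  carbons = lpc$carbons[i], double_bonds = lpc$double_bonds[i])
      pairs[[length(pairs) + 1L]] <- tibble::as_tibble(row)
    }
  }
  if (length(pairs) == 0) {
    return(tibble::tibble(lpc = character(0), fa = character(0),
                          lpc_name = character(0), fa_name = character(0),
                          carbons = integer(0), double_bonds = integer(0)))
  }
  out <- do.call(rbind, pairs)
  out <- out[!duplicated(paste(out$lpc_name, out$fa_name)), , drop = FALSE]
  out[order(out$lpc, out$fa_name), , drop = FALSE]
}

#' Keep cognate pairs in which both members are elevated
#'
#' Pinpoints LPC/fatty-acid pairs plausibly produced by sPLA2 action: a pair
#' survives only when both the LPC and its cognate fatty acid are flagged
#' elevated in the same contrast of the DE results.
#'
#' @param pairs tibble from [match_cognates()].
#' @param de_results a DE result table with columns `feature`, `direction`,
#'   `contrast` — typically a row-bound combination of lipid and metabolite
#'   screens, with `feature` holding canonical species names.
#' @return the surviving subset of `pairs`, with a `contrast` column.
#' @export
co_elevation_filter <- function(pairs, de_results) {
  if (nrow(pairs) == 0) return(cbind(pairs, tibble::tibble(contrast = character(0))))
  need <- c("feature", "direction", "contrast")
  if (!all(need %in% names(de_results))) {
    stop("de_results must have columns feature, direction, contrast", call. = FALSE)
  }
  missing <- setdiff(unique(c(pairs$lpc, pairs$fa)), de_results$feature)
  if (length(missing) > 0) {
    stop("species missing from DE results: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  kept <- list()
  for (ct in unique(de_results$contrast)) {
    de <- de_results[de_results$contrast == ct, , drop = FALSE]
    up <- de$feature[de$direction == "elevated"]
    ok <- pairs$lpc %in% up & pairs$fa %in% up
    if (any(ok)) {
      kept[[ct]] <- cbind(pairs[ok, , drop = FALSE],
                          tibble::tibble(contrast = ct))
    }
  }
  if (length(kept) == 0) {
    return(cbind(pairs[0, , drop = FALSE], tibble::tibble(contrast = character(0))))
  }
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  out
}
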