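#' Pair dams with their pups into dyads
#'
#' Builds one dyad per (dam, breastfeeding pup) pair sharing a dyad ID. The
#' dam member is her baseline sample; the pup member is the pup's
#' breastfeeding (BF) sample. Dams without a BF pup are skipped with a
#' warning; a pup whose dyad ID matches no dam, or two dams sharing one dyad
#' ID, are errors.
#'
#' @param metadata a [sample_metadata()] with dyad IDs.
#' @return tibble with columns `dyad_id`, `dam_sample`, `pup_sample`, `group`.
#' @export
pair_dyads <- function(metadata) {
  md <- metadata[!is.na(metadata$dyad_id), , drop = FALSE]
  dams <- md[md$generation == "dam", , drop = FALSE]
  pups <- md[md$generation == "pup" & md$timepoint == "BF", , drop = FALSE]
  dup <- dams$dyad_id[duplicated(dams$dyad_id)]
  if (length(dup) > 0) {
    stop("two dam samples share dyad ID '", dup[1], "'", call. = FALSE)
  }
  orphan <- setdiff(pups$dyad_id, dams$dyad_id)
  if (length(orphan) > 0) {
    stop("pup with dyad ID '", orphan[1], "' has no matching dam", call. = FALSE)
  }
  childless <- setdiff(dams$dyad_id, pups$dyad_id)
  if (length(childless) > 0) {
    warning(length(childless), " dam(s) without a breastfeeding pup skipped: ",
            paste(utils::head(childless, 5), collapse = ", "), call. = FALSE)
  }
  keep <- dams$dyad_id %in% pups$dyad_id
  dams <- dams[keep, , drop = FALSE]
  idx <- match(dams$dyad_id, pups$dyad_id)
  tibble::tibble(dyad_id = dams$dyad_id,
                 dam_sample = dams$sample_id,
                 pup_sample = pups$sample_id[idx],
                 group = dams$group)
}

#' Shared taxa between a dam and her pup
#'
#' A taxon is shared when its relative abundance reaches `presence_threshold`
#' in *both* profiles. The default threshold of 1e-4 keeps "shared" from
#' depending on sequencing-depth noise at trace abundances.
#'
#' @param dam_profile,pup_profile named numeric vectors over the same taxon
#'   list (relative abundances).
#' @param presence_threshold minimum relative abundance to count as present.
#' @return list with `shared` (character vector of taxon IDs) and `count`.
#' @export
shared_taxa <- function(dam_profile, pup_profile, presence_threshold = 1e-4) {
  if (is.null(names(dam_profile)) || is.null(names(pup_profile)) ||
      !identical(names(dam_profile), names(pup_profile))) {
    stop("dam and pup profiles must share one taxon list", call. = FALSE)
  }
  if (presence_threshold < 0) stop("presence_threshold must be >= 0", call. = FALSE)
  shared <- names(dam_profile)[dam_profile >= presence_threshold &
                               pup_profile >= presence_threshold]
  list(shared = shared, count = length(shared))
}

#' Per-taxon intergenerational transfer-event counts
#'
#' For each taxon, counts the dyads in which it is present (relative
#' abundance at or above the threshold) in both the dam and the pup — the
#' quantity displayed as circle sizes in dam-pup transfer heatmaps.
#'
#' @param dyads tibble from [pair_dyads()].
#' @param table taxon [feature_table()] holding dam and pup samples
#'   (normalised to relative abundance internally).
#' @param presence_threshold see [shared_taxa()].
#' @return tibble with columns `taxon`, `n_transfer_events`,
#'   `mean_dam_abundance`, `mean_pup_abundance`.
#' @export
transfer_event_counts <- function(dyads, table, presence_threshold = 1e-4) {
  if (nrow(dyads) == 0) stop("empty dyad list", call. = FALSE)
  rel <- ft_matrix(relative_abundance(table))
  dam <- rel[dyads$dam_sample, , drop = FALSE]
  pup <- rel[dyads$pup_sample, , drop = FALSE]
  present <- (dam >= presence_threshold) & (pup >= presence_threshold)
  tibble::tibble(taxon = colnames(rel),
                 n_transfer_events = colSums(present),
                 mean_dam_abundance = colMeans(dam),
                 mean_pup_abundance = colMeans(pup))
}

#' Matched versus pooled dam-pup Bray-Curtis distances
#'
#' For a given exposure group, computes the matched distances (each dam to
#' her own pup) and the pooled distances (every dam x pup combination in the
#' group), plus a Wilcoxon rank-sum p comparing the group's matched distances
#' against those of a reference group (the unexposed CC arm by default). Low
#' matched distances indicate faithful transfer of the maternal community.
#'
#' @param dyads tibble from [pair_dyads()].
#' @param table taxon [feature_table()] holding dam and pup samples.
#' @param group focal group label.
#' @param reference_group comparison group for the rank-sum test; set `NULL`
#'   to skip the test.
#' @return list with `group`, `matched`, `pooled` (numeric distance vectors)
#'   and `p_vs_reference` (NA when not computed).
#' @export
fidelity_distance_comparison <- function(dyads, table, group,
                                         reference_group = "CC") {
  g_dyads <- dyads[dyads$group == group, , drop = FALSE]
  if (nrow(g_dyads) == 0) stop("group '", group, "' absent from dyads", call. = FALSE)
  bc <- unclass(bray_curtis_matrix(table))
  matched <- mapply(function(d, p) bc[d, p], g_dyads$dam_sample,
                    g_dyads$pup_sample)
  pooled <- as.vector(bc[g_dyads$dam_sample, g_dyads$pup_sample, drop = FALSE])
  p <- NA_real_
  if (!is.null(reference_group) && reference_group != group) {
    r_dyads <- dyads[dyads$group == reference_group, , drop = FALSE]
    if (nrow(r_dyads) == 0) stop("reference group '", reference_group,
                                 "' absent from dyads", call. = FALSE)
    if (nrow(g_dyads) < 2 || nrow(r_dyads) < 2) {
      stop("rank-sum comparison needs >= 2 dyads per group; got ",
           nrow(g_dyads), " in '", group, "' and ", nrow(r_dyads), " in '",
           reference_group, "'", call. = FALSE)
    }
    ref_matched <- mapply(function(d, p) bc[d, p], r_dyads$dam_sample,
                          r_dyads$pup_sample)
    p <- rank_sum_test(matched, ref_matched)$p_value
  }
  list(group = group, matched = unname(matched), pooled = pooled,
       p_vs_reference = p)
}

#' Full transfer-fidelity report
#'
#' Combines per-dyad shared-taxon sets, per-taxon transfer-event counts and
#' per-group matched/pooled distance comparisons into one report object.
#'
#' @param table taxon [feature_table()] with dam and pup samples.
#' @param metadata matching [sample_metadata()].
#' @param presence_threshold see [shared_taxa()].
#' @param reference_group reference arm for distance comparisons.
#' @return list of class `transfer_report` with elements `dyads`,
#'   `shared` (tibble: dyad_id, group, shared_count), `events`
#'   (per-taxon tibble), `distances` (per-group list).
#' @export
transfer_report <- function(table, metadata, presence_threshold = 1e-4,
                            reference_group = "CC") {
  dyads <- pair_dyads(metadata)
  if (nrow(dyads) == 0) stop("no dyads could be formed", call. = FALSE)
  rel <- ft_matrix(relative_abundance(table))
  shared_counts <- vapply(seq_len(nrow(dyads)), function(i) {
    shared_taxa(rel[dyads$dam_sample[i], ], rel[dyads$pup_sample[i], ],
                presence_threshold)$count
  }, numeric(1))
  shared <- tibble::tibble(dyad_id = dyads$dyad_id, group = dyads$group,
                           shared_count = shared_counts)
  events <- transfer_event_counts(dyads, table, presence_threshold)
  dist_groups <- unique(dyads$group)
  distances <- lapply(dist_groups, function(g) {
    ref <- if (g == reference_group || !(reference_group %in% dist_groups)) NULL
           else reference_group
    fidelity_distance_comparison(dyads, table, g, ref)
  })
  names(distances) <- dist_groups
  structure(list(dyads = dyads, shared = shared, events = events,
                 distances = distances,
                 presence_threshold = presence_threshold),
            class = "transfer_report")
}

#' Write a transfer report to disk
#'
#' JSON for the full report plus a per-taxon TSV of transfer-event counts
#' and mean dam/pup abundances.
#'
#' @param report a [transfer_report()].
#' @param json_path,tsv_path output paths.
#' @export
write_transfer_report <- function(report, json_path, tsv_path) {
  out <- list(dyads = report$dyads, shared = report$shared,
              events = report$events,
              distances = report$distances,
              presence_threshold = report$presence_threshold)
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  utils::write.table(as.data.frame(report$events), tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(json_path)
}
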