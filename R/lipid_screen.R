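#' Per-feature abundance ratio between two groups
#'
#' Linear-scale ratio of group means, `r = mean(contrast) / mean(reference)`.
#' When a group mean is exactly zero it is replaced by a pseudocount equal to
#' half the smallest positive value in the table, so the ratio stays finite
#' and documented; nonzero means are never perturbed.
#'
#' @param table a [feature_table()].
#' @param metadata matching [sample_metadata()].
#' @param contrast_group,reference_group group labels.
#' @param timepoint restrict to this timepoint (default `"HFD"`, the stage at
#'   which fold changes against the unexposed arm are computed); `NULL`
#'   disables the filter.
#' @return named numeric vector of ratios, one per feature.
#' @export
abundance_ratio <- function(table, metadata, contrast_group,
                            reference_group = "CC", timepoint = "HFD") {
  md <- align_metadata(table, metadata)
  keep <- if (is.null(timepoint)) rep(TRUE, nrow(md)) else md$timepoint == timepoint
  m <- ft_matrix(table)[keep, , drop = FALSE]
  grp <- md$group[keep]
  for (g in c(contrast_group, reference_group)) {
    if (!any(grp == g)) {
      stop("group '", g, "' has no samples",
           if (!is.null(timepoint)) paste0(" at timepoint ", timepoint), call. = FALSE)
    }
  }
  eps <- pseudocount(m)
  mc <- colMeans(m[grp == contrast_group, , drop = FALSE])
  mr <- colMeans(m[grp == reference_group, , drop = FALSE])
  mc[mc == 0] <- eps
  mr[mr == 0] <- eps
  mc / mr
}

pseudocount <- function(m) {
  pos <- m[m > 0]
  if (length(pos) == 0) return(.Machine$double.eps)
  min(pos) / 2
}

#' Ratio-plus-VIP screen for differentially expressed lipids
#'
#' Implements the lipidomics decision rule: a lipid is differentially
#' expressed between an antibiotic-exposed group and the unexposed reference
#' when its abundance ratio falls outside \[0.66, 1.2\] *and* its VIP from a
#' two-component PLS-DA of the two groups exceeds 1. Direction is
#' `"elevated"` when r > `ratio_high`, `"depleted"` when r < `ratio_low`.
#'
#' @param table lipid [feature_table()].
#' @param metadata matching [sample_metadata()].
#' @param contrast_group exposed group; compared against `reference_group`.
#' @param reference_group reference arm (default CC).
#' @param timepoint default `"HFD"`.
#' @param ratio_low,ratio_high,vip_threshold decision thresholds
#'   (defaults 0.66, 1.2, 1).
#' @param n_components PLS components for the VIP (default 2).
#' @return tibble of class `de_screen`: columns `feature`, `ratio`, `vip`,
#'   `ratio_pass`, `vip_pass`, `flagged`, `direction`
#'   (elevated/depleted/none), `contrast`.
#' @export
screen_de_lipids <- function(table, metadata, contrast_group,
                             reference_group = "CC", timepoint = "HFD",
                             ratio_low = 0.66, ratio_high = 1.2,
                             vip_threshold = 1, n_components = 2) {
  md <- align_metadata(table, metadata)
  keep <- (if (is.null(timepoint)) rep(TRUE, nrow(md)) else md$timepoint == timepoint) &
    md$group %in% c(contrast_group, reference_group)
  m <- ft_matrix(table)[keep, , drop = FALSE]
  grp <- md$group[keep]
  if (length(unique(grp)) != 2) {
    stop("need samples from both '", contrast_group, "' and '",
         reference_group, "'", call. = FALSE)
  }
  model <- fit_plsda(m, grp, n_components = n_components)
  vip <- vip_scores(model)[colnames(m)]
  r <- abundance_ratio(table, metadata, contrast_group, reference_group,
                       timepoint)
  ratio_pass <- r < ratio_low | r > ratio_high
  vip_pass <- vip > vip_threshold
  flagged <- ratio_pass & vip_pass
  direction <- rep("none", length(r))
  direction[flagged & r > ratio_high] <- "elevated"
  direction[flagged & r < ratio_low] <- "depleted"
  out <- tibble::tibble(feature = colnames(m), ratio = unname(r),
                        vip = unname(vip), ratio_pass = unname(ratio_pass),
                        vip_pass = unname(vip_pass), flagged = unname(flagged),
                        direction = direction,
                        contrast = paste0(contrast_group, "_vs_", reference_group))
  class(out) <- c("de_screen", class(out))
  out
}

#' Apply the ratio-plus-VIP rule to precomputed values
#'
#' The bare decision rule, exposed for threshold-grid checks and for reusing
#' ratios/VIPs computed elsewhere.
#'
#' @param ratio,vip numeric vectors of equal length.
#' @param ratio_low,ratio_high,vip_threshold thresholds (defaults 0.66, 1.2, 1).
#' @return tibble with `ratio`, `vip`, `flagged`, `direction`.
#' @export
de_decision_rule <- function(ratio, vip, ratio_low = 0.66, ratio_high = 1.2,
                             vip_threshold = 1) {
  stopifnot(length(ratio) == length(vip))
  ratio_pass <- ratio < ratio_low | ratio > ratio_high
  flagged <- ratio_pass & vip > vip_threshold
  direction <- rep("none", length(ratio))
  direction[flagged & ratio > ratio_high] <- "elevated"
  direction[flagged & ratio < ratio_low] <- "depleted"
  tibble::tibble(ratio = ratio, vip = vip, flagged = flagged,
                 direction = direction)
}

#' Write a DE screen result as TSV
#' @param result tibble from [screen_de_lipids()].
#' @param path output path.
#' @export
write_de_screen <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Metabolite content from a calibration-curve concentration
#'
#' Converts the concentration read off a standard curve to content per gram
#' of sample: `content (umol/g) = C * A / m`, with `C` the concentration
#' (umol/L), `A` the dilution factor and `m` the weighed sample mass (mg).
#'
#' @param C concentration in umol/L.
#' @param A dilution factor.
#' @param m sample mass in mg; must be positive.
#' @return content in umol/g.
#' @examples
#' metabolite_content(10, 2, 25)  # 0.8
#' @export
metabolite_content <- function(C, A, m) {
  if (any(!is.finite(m)) || any(m <= 0)) stop("sample mass m must be > 0",
                                              call. = FALSE)
  C * A / m
}
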