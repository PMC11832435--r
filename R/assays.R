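#' Transepithelial electrical resistance (TEER)
#'
#' `TEER = (R - Rb) * A` in ohm * cm^2, where `R` is the measured resistance
#' of the cell monolayer, `Rb` the blank (no-cell) resistance and `A` the
#' filter area in cm^2 (1.12 cm^2 for a standard 12-mm Transwell insert).
#' A measured resistance below the blank is physically suspect and triggers
#' a warning.
#'
#' @param R measured resistance (ohm).
#' @param Rb blank resistance (ohm).
#' @param A filter area (cm^2); must be positive.
#' @return TEER in ohm * cm^2.
#' @examples
#' teer(1100, 100, 1.12)  # 1120
#' @export
teer <- function(R, Rb, A = 1.12) {
  if (any(!is.finite(A)) || any(A <= 0)) stop("filter area A must be > 0",
                                              call. = FALSE)
  if (any(R < Rb)) warning("measured resistance below blank (R < Rb)",
                           call. = FALSE)
  (R - Rb) * A
}

#' Relative expression by the 2^-ddCt method
#'
#' Fold change of a target gene in a sample relative to a control condition,
#' each normalised to a reference gene:
#' `fold = 2^-((Ct_target_sample - Ct_ref_sample) - (Ct_target_control - Ct_ref_control))`.
#'
#' @param ct_target_sample,ct_ref_sample Ct values in the sample condition.
#' @param ct_target_control,ct_ref_control Ct values in the control condition.
#' @return linear fold change.
#' @examples
#' ddct_fold(20, 18, 22, 18)  # 2^-(2 - 4) = 4
#' @export
ddct_fold <- function(ct_target_sample, ct_ref_sample,
                      ct_target_control, ct_ref_control) {
  vals <- c(ct_target_sample, ct_ref_sample, ct_target_control, ct_ref_control)
  if (any(!is.finite(vals))) stop("Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
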