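# Closed-form laboratory quantification utilities.

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target,treated - Ct_reference,treated) -
#'         (Ct_target,control - Ct_reference,control)`;
#' fold change = `2^-ddCt`. Vectorized.
#'
#' @param ct_target_treated,ct_reference_treated,ct_target_control,ct_reference_control
#'   cycle-threshold values (finite).
#' @return positive fold change(s).
#' @export
ddct_fold_change <- function(ct_target_treated, ct_reference_treated,
                             ct_target_control, ct_reference_control) {
  cts <- c(ct_target_treated, ct_reference_treated,
           ct_target_control, ct_reference_control)
  if (any(!is.finite(cts))) abort("Ct values must be finite")
  ddct <- (ct_target_treated - ct_reference_treated) -
    (ct_target_control - ct_reference_control)
  2^(-ddct)
}

#' Population doubling level
#'
#' `PDL = PDL0 + 3.322 * log10(c_final / c_initial)` — the 3.322 constant is
#' 1 / log10(2), so one doubling of cell number adds (almost exactly) one
#' unit.
#'
#' @param pdl0 starting population doubling level.
#' @param c_initial,c_final positive cell counts at seeding and passage.
#' @return updated PDL. Vectorized.
#' @export
population_doublings <- function(pdl0, c_initial, c_final) {
  if (any(c_initial <= 0) || any(c_final <= 0)) {
    abort("cell counts must be positive")
  }
  pdl0 + 3.322 * log10(c_final / c_initial)
}
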