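#' ChIP-qPCR fold enrichment over input
#'
#' `2^(input Ct - IP Ct)`: equal cycle thresholds give 1, each cycle the IP
#' crosses earlier doubles the enrichment.
#'
#' @param input_ct,ip_ct Finite positive cycle-threshold values
#'   (vectorized).
#' @return Fold enrichment.
#' @examples
#' chip_fold_enrichment(25, 22)  # 8
#' @export
chip_fold_enrichment <- function(input_ct, ip_ct) {
  if (any(!is.finite(input_ct)) || any(!is.finite(ip_ct))) {
    abort("Ct values must be finite")
  }
  if (any(input_ct <= 0) || any(ip_ct <= 0)) {
    abort("Ct values must be positive")
  }
  2^(input_ct - ip_ct)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Fold change of a target transcript in treated versus control samples,
#' each normalized to a reference transcript (e.g. Actb), with
#' amplification efficiency fixed at 2:
#' `2^-((target_t - ref_t) - (target_c - ref_c))`.
#'
#' @param target_ct_treated,ref_ct_treated,target_ct_control,ref_ct_control
#'   Finite Ct values (vectorized).
#' @return Fold change relative to control.
#' @examples
#' relative_expression(24, 20, 25, 20)  # 2
#' @export
relative_expression <- function(target_ct_treated, ref_ct_treated,
                                target_ct_control, ref_ct_control) {
  cts <- list(target_ct_treated, ref_ct_treated, target_ct_control,
              ref_ct_control)
  if (any(!vapply(cts, function(x) all(is.finite(x)), logical(1)))) {
    abort("Ct values must be finite")
  }
  ddct <- (target_ct_treated - ref_ct_treated) -
    (target_ct_control - ref_ct_control)
  2^(-ddct)
}
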