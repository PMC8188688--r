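# Closed-form bench formulas for the phenotype and qPCR companion tables.

#' Relative water loss rate of detached leaves
#'
#' `(FW - CW) / FW`, where FW is the fresh weight at excision and CW the
#' current weight at a later time point. Values above FW (CW > FW) produce
#' negative rates; they are returned unclipped with a warning, since they
#' flag weighing noise that should stay visible. Vectorised.
#'
#' @param FW Fresh weight in grams; must be positive.
#' @param CW Current weight in grams.
#' @return Numeric vector of loss fractions (1 = total loss).
#' @export
water_loss_rate <- function(FW, CW) {
  if (any(FW <= 0)) stop("fresh weight FW must be positive")
  if (any(CW > FW)) {
    warning("current weight exceeds fresh weight for ", sum(CW > FW),
            " measurement(s); negative loss rate returned")
  }
  (FW - CW) / FW
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-((Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control))`: the fold change of a target gene
#' in treated vs control samples, normalised against a reference gene
#' (e.g. actin). Vectorised; swapping the treated and control quartet halves
#' inverts the result.
#'
#' @param ct_target_treated,ct_ref_treated Mean Ct of target and reference
#'   gene in the treated sample.
#' @param ct_target_control,ct_ref_control Mean Ct of target and reference
#'   gene in the control sample.
#' @return Positive numeric fold change.
#' @export
fold_change_ddct <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  ct <- c(ct_target_treated, ct_ref_treated,
          ct_target_control, ct_ref_control)
  if (any(!is.finite(ct))) stop("Ct values must be finite")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
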