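# Deterministic assay arithmetic: AAS dilution back-calculation, root
# mineral content from acid digests, and 2^-ddCt relative expression.

#' Back-calculate the culture-solution concentration from a diluted read
#'
#' Hourly samples are small aliquots brought to a fixed final volume
#' before atomic-absorption measurement; the original solution
#' concentration is the measured one scaled by the dilution factor.
#'
#' @param measured_conc mg/L in the diluted filtrate (>= 0); vectorized.
#' @param aliquot_volume_mL aliquot taken from the pot, mL (> 0);
#'   default 1 mL.
#' @param final_volume_mL volume the aliquot is fixed to, mL (> 0);
#'   default 50 mL.
#' @return Concentration in the original culture solution, mg/L.
#' @examples
#' solution_concentration(0.8) # 1 mL fixed to 50 mL -> 40 mg/L
#' @export
solution_concentration <- function(measured_conc, aliquot_volume_mL = 1,
                                   final_volume_mL = 50) {
  if (any(!is.finite(aliquot_volume_mL)) || any(aliquot_volume_mL <= 0) ||
      any(!is.finite(final_volume_mL)) || any(final_volume_mL <= 0)) {
    mgk_stop("aliquot and final volumes must be positive", "invalid_input")
  }
  if (any(measured_conc < 0)) {
    mgk_stop("measured concentration must be non-negative", "invalid_input")
  }
  measured_conc * final_volume_mL / aliquot_volume_mL
}

#' Root mineral content from an acid digest
#'
#' Dried root samples are digested and brought to a final volume; the
#' content per g dry weight is the digest concentration times the digest
#' volume, scaled from mg to ug. Note the dry-weight basis: fresh root
#' weight (FRW) normalizes uptake rates, dry mass normalizes contents —
#' the two are never interchangeable.
#'
#' @param measured_conc mg/L measured in the digest filtrate (>= 0);
#'   vectorized.
#' @param dry_mass_g digested sample dry mass, g (> 0); default 0.2 g.
#' @param digest_volume_mL final digest volume, mL (> 0); default 50 mL.
#' @return Content in ug per g dry weight.
#' @examples
#' root_mg_content(0.5, dry_mass_g = 0.2) # 125 ug/g
#' @export
root_mg_content <- function(measured_conc, dry_mass_g = 0.2,
                            digest_volume_mL = 50) {
  if (any(!is.finite(dry_mass_g)) || any(dry_mass_g <= 0)) {
    mgk_stop("'dry_mass_g' must be positive", "invalid_input")
  }
  if (any(!is.finite(digest_volume_mL)) || any(digest_volume_mL <= 0)) {
    mgk_stop("'digest_volume_mL' must be positive", "invalid_input")
  }
  if (any(measured_conc < 0)) {
    mgk_stop("measured concentration must be non-negative", "invalid_input")
  }
  measured_conc * (digest_volume_mL / 1000) * 1000 / dry_mass_g
}

#' Treatment-minus-control content differences
#'
#' @param values per-treatment contents (or any per-treatment means).
#' @param treatments treatment labels, same length as `values`; each
#'   label must be unique and the control must be present.
#' @param control_label label of the control treatment; default
#'   `"Mg_control"`.
#' @return List with `deltas` (named vector over the non-control
#'   treatments, treatment minus control) and `range` (`c(min, max)` of
#'   the deltas).
#' @examples
#' content_delta_vs_control(
#'   c(50.65, 48.56, 104.96, 107.75, 102.83, 52.57, 137.34),
#'   c("Mg_control", "Mg_All", "Mg_N", "Mg_P", "Mg_K", "Mg_other", "Mg_Mg")
#' )$range # -2.09 86.69
#' @export
content_delta_vs_control <- function(values, treatments,
                                     control_label = "Mg_control") {
  if (length(values) != length(treatments)) {
    mgk_stop("'values' and 'treatments' must have equal length",
             "invalid_input")
  }
  if (anyDuplicated(treatments)) {
    mgk_stop("treatment labels must be unique (pass treatment means)",
             "invalid_input")
  }
  ctrl <- which(treatments == control_label)
  if (length(ctrl) != 1) {
    mgk_stop(sprintf("control treatment '%s' not found", control_label),
             "invalid_input")
  }
  deltas <- values[-ctrl] - values[ctrl]
  names(deltas) <- treatments[-ctrl]
  list(deltas = deltas, range = delta_range(deltas))
}

#' Relative gene expression by the 2^-ddCt method
#'
#' ddCt = (Ct_target,sample - Ct_reference,sample) -
#' (Ct_target,control - Ct_reference,control); the fold change is
#' 2^-ddCt. A sample identical to the control returns exactly 1 (the
#' control normalization). No PCR-efficiency correction is applied.
#'
#' @param ct_target_sample,ct_reference_sample target- and
#'   reference-gene cycle thresholds in the sample (finite, > 0);
#'   vectorized.
#' @param ct_target_control,ct_reference_control the same pair in the
#'   calibrator (control) sample.
#' @return Fold change (dimensionless).
#' @examples
#' fold_change_ddct(20, 18, 22, 18) # ddCt = -2 -> fold 4
#' @export
fold_change_ddct <- function(ct_target_sample, ct_reference_sample,
                             ct_target_control, ct_reference_control) {
  cts <- cbind(ct_target_sample, ct_reference_sample,
               ct_target_control, ct_reference_control)
  if (any(!is.finite(cts)) || any(cts <= 0)) {
    mgk_stop("all Ct values must be finite and positive", "invalid_input")
  }
  ddct <- (ct_target_sample - ct_reference_sample) -
    (ct_target_control - ct_reference_control)
  2^(-ddct)
}
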