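# MCID stratification from the Forgotten Joint Score change at 3 months.
#
# The minimal clinically important difference (MCID) of the FJS is
# surgery-specific: 17.5 points for total hip arthroplasty, 16.6 for total
# knee arthroplasty, 12.5 for unicondylar knee arthroplasty. No published
# threshold exists for revision or resurfacing procedures, so those
# patients are ineligible for stratified analyses.

MCID_LABELS <- c("MCID_plus", "MCID_minus", "ineligible")

#' MCID threshold for a joint / surgery-type combination
#'
#' @param joint `"hip"` or `"knee"` (vectorized).
#' @param surgery_type `"total"`, `"unicondylar"`, `"revision"` or
#'   `"resurfacing"` (vectorized).
#' @return Numeric vector of FJS-score thresholds; `NA` signals an
#'   ineligible combination (no published threshold).
#' @export
mcid_threshold <- function(joint, surgery_type) {
  n <- max(length(joint), length(surgery_type))
  joint <- rep_len(joint, n); surgery_type <- rep_len(surgery_type, n)
  if (any(!joint %in% VALID_JOINTS)) stop("unknown joint")
  if (any(!surgery_type %in% VALID_SURGERY_TYPES)) stop("unknown surgery_type")
  out <- rep(NA_real_, n)
  out[joint == "hip" & surgery_type == "total"] <- 17.5
  out[joint == "knee" & surgery_type == "total"] <- 16.6
  out[joint == "knee" & surgery_type == "unicondylar"] <- 12.5
  out
}

#' Label patients by MCID recovery status
#'
#' A patient achieves the MCID (`MCID_plus`) when the FJS change from
#' pre-operative to 3 months, `fjs_3m - fjs_pre`, is greater than or equal
#' to the surgery-specific threshold — the MCID is a minimal important
#' difference, so meeting it exactly counts as achieving it. Patients with
#' a missing 3-month score, or a revision/resurfacing procedure, are
#' `ineligible`.
#'
#' @param meta Patient metadata (see [read_metadata_csv()]).
#' @return A `data.table` with `patient_id`, `label` (one of `MCID_plus`,
#'   `MCID_minus`, `ineligible`), `fjs_delta`, `threshold_used`.
#' @export
label_recovery <- function(meta) {
  dt <- data.table::as.data.table(meta)
  out <- dt[, .(patient_id,
                fjs_delta = fjs_3m - fjs_pre,
                threshold_used = mcid_threshold(joint, surgery_type))]
  out[, label := data.table::fifelse(
    is.na(fjs_delta) | is.na(threshold_used), "ineligible",
    data.table::fifelse(fjs_delta >= threshold_used, "MCID_plus", "MCID_minus"))]
  out[label == "ineligible", threshold_used := NA_real_]
  out[, .(patient_id, label, fjs_delta, threshold_used)]
}
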