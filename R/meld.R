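#' Model for End-Stage Liver Disease (MELD) score
#'
#' The original MELD formula:
#' `9.57 * ln(creatinine) + 3.78 * ln(total bilirubin) + 11.2 * ln(INR) +
#' 6.43`, with creatinine and bilirubin in mg/dL. By convention each input
#' is floored at 1.0 before taking logarithms (sub-unity labs would
#' otherwise subtract points); the floor is on by default and switchable.
#' No creatinine cap or dialysis override is applied. Higher scores mean
#' higher short-term mortality risk.
#'
#' @param creatinine serum creatinine, mg/dL.
#' @param bilirubin total serum bilirubin, mg/dL.
#' @param inr international normalized ratio.
#' @param clamp floor all three inputs at `floor` (default `TRUE`).
#' @param floor the clamping floor (default 1.0).
#'
#' @return numeric MELD points (vectorized). With clamping on the score is
#'   always >= 6.43.
#' @examples
#' meldScore(1, 1, 1)                       # 6.43, the additive constant
#' meldScore(exp(1), exp(1), exp(1), clamp = FALSE)  # 30.98
#' @export
meldScore <- function(creatinine, bilirubin, inr, clamp = TRUE, floor = 1.0) {
  vals <- cbind(creatinine = creatinine, bilirubin = bilirubin, inr = inr)
  if (any(!is.finite(vals)))
    stop("MELD inputs must be finite", call. = FALSE)
  if (clamp) {
    vals <- pmax(vals, floor)
  } else if (any(vals <= 0)) {
    stop("MELD inputs must be positive when clamping is disabled",
         call. = FALSE)
  }
  unname(9.57 * log(vals[, "creatinine"]) + 3.78 * log(vals[, "bilirubin"]) +
         11.2 * log(vals[, "inr"]) + 6.43)
}

#' Convert analyte concentrations to mg/dL
#'
#' The MELD coefficients assume mg/dL while clinical chemistry panels in
#' much of the world report umol/L; standard molar-mass factors convert:
#' creatinine umol/L / 88.4, bilirubin umol/L / 17.1. mg/dL passes
#' through unchanged.
#'
#' @param value positive concentration(s).
#' @param analyte `"creatinine"` or `"bilirubin"`.
#' @param unit `"umol_per_L"` or `"mg_per_dL"`.
#'
#' @return concentration in mg/dL.
#' @examples
#' normalizeUnits(88.4, "creatinine", "umol_per_L")  # 1.0
#' normalizeUnits(171, "bilirubin", "umol_per_L")    # 10.0
#' @export
normalizeUnits <- function(value, analyte = c("creatinine", "bilirubin"),
                           unit = c("umol_per_L", "mg_per_dL")) {
  analyte <- match.arg(analyte)
  unit <- match.arg(unit)
  .check_lab(value, "value", analyte)
  if (unit == "mg_per_dL") return(value)
  value / switch(analyte, creatinine = 88.4, bilirubin = 17.1)
}

#' MELD from a cohort panel
#'
#' Pulls creatinine, total bilirubin and INR out of a cohort's indicator
#' panel (rather than carrying duplicate MELD-input columns), converts
#' umol/L concentrations to mg/dL according to the registry's units
#' column, and returns one MELD score per patient. Patients missing any of
#' the three inputs get `NA`.
#'
#' @param x a [QDExperiment-class].
#' @param when `"post"` (default) or `"pre"` measurement.
#' @inheritParams meldScore
#'
#' @return numeric vector of MELD scores, one per patient.
#' @export
meldFromPanel <- function(x, when = c("post", "pre"), clamp = TRUE) {
  stopifnot(is(x, "QDExperiment"))
  when <- match.arg(when)
  need <- c("creatinine", "total_bilirubin", "international_normalized_ratio")
  miss <- setdiff(need, rownames(x))
  if (length(miss))
    stop("panel lacks MELD inputs: ", paste(miss, collapse = ", "))
  v <- SummarizedExperiment::assay(x, when)[need, , drop = FALSE]
  units <- SummarizedExperiment::rowData(x)[need, "units"]
  conv <- function(val, unit, analyte) {
    if (all(is.na(val))) return(val)
    u <- if (grepl("mol", unit)) "umol_per_L" else "mg_per_dL"
    out <- val
    out[!is.na(val)] <- normalizeUnits(val[!is.na(val)], analyte, u)
    out
  }
  cr <- conv(v["creatinine", ], units[1], "creatinine")
  bi <- conv(v["total_bilirubin", ], units[2], "bilirubin")
  inr <- v["international_normalized_ratio", ]
  out <- rep(NA_real_, ncol(x))
  ok <- !is.na(cr) & !is.na(bi) & !is.na(inr)
  if (any(ok)) out[ok] <- meldScore(cr[ok], bi[ok], inr[ok], clamp = clamp)
  unname(out)
}
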