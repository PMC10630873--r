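#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom BiocGenerics cbind
#' @import SummarizedExperiment
NULL

# golden ratio: base of the golden logarithm. ln(phi) == ln(1/tau) for
# tau = (sqrt(5)-1)/2, so the two natural readings of the base coincide.
.phi <- (1 + sqrt(5)) / 2

.builtin_cuts <- list(
  cellular_molecular = c(0.80, 1.22),
  organ_tissue       = c(0.47, 0.80),
  body               = c(0.27, 0.47),
  molecular_beta     = c(0.80, 1.22, 1.69)
)

#' Threshold scheme for magnitude bucketing
#'
#' A `ThresholdScheme` holds the ordered cut points against which a golden
#' logarithm is bucketed into a B value. Built-in schemes carry the
#' published constants for the cellular/molecular level (0.80, 1.22), the
#' organ/tissue level (0.47, 0.80), the whole-body level (0.27, 0.47), and
#' the three-cut molecular scheme used by the default workflow
#' (health 0.80, subhealth 1.22, disease 1.69).
#'
#' @slot level scheme name (one of the built-in level names, or `"custom"`).
#' @slot cuts strictly increasing positive cut points (2 for two-bucket
#'   schemes, 3 for the molecular scheme).
#'
#' @seealso [thresholdScheme()], [magnitudeScore()]
#' @export
setClass("ThresholdScheme",
  representation(level = "character", cuts = "numeric"))

setValidity("ThresholdScheme", function(object) {
  msg <- character()
  if (length(object@level) != 1L)
    msg <- c(msg, "'level' must be a single string")
  if (!length(object@cuts) %in% c(2L, 3L))
    msg <- c(msg, "'cuts' must contain 2 or 3 cut points")
  if (any(!is.finite(object@cuts)) || any(object@cuts <= 0))
    msg <- c(msg, "'cuts' must be finite and positive")
  if (is.unsorted(object@cuts, strictly = TRUE))
    msg <- c(msg, "'cuts' must be strictly increasing")
  if (object@level %in% names(.builtin_cuts) &&
      !isTRUE(all.equal(object@cuts, .builtin_cuts[[object@level]])))
    msg <- c(msg, sprintf("cuts do not match the built-in '%s' scheme",
                          object@level))
  if (length(msg)) msg else TRUE
})

#' Construct a threshold scheme
#'
#' @param level name of a built-in scheme (`"molecular_beta"`,
#'   `"cellular_molecular"`, `"organ_tissue"`, `"body"`) or `"custom"`.
#' @param cuts explicit cut points; required for `"custom"`, ignored (and
#'   checked) for built-in levels.
#'
#' @return a [ThresholdScheme-class] object.
#' @examples
#' thresholdScheme("molecular_beta")
#' thresholdScheme("custom", cuts = c(0.5, 1, 2))
#' @export
thresholdScheme <- function(level = c("molecular_beta", "cellular_molecular",
                                      "organ_tissue", "body", "custom"),
                            cuts = NULL) {
  level <- match.arg(level)
  if (level == "custom") {
    if (is.null(cuts))
      stop("a 'custom' scheme requires explicit 'cuts'")
  } else {
    if (is.null(cuts)) cuts <- .builtin_cuts[[level]]
  }
  new("ThresholdScheme", level = level, cuts = as.numeric(cuts))
}

setMethod("show", "ThresholdScheme", function(object) {
  cat("ThresholdScheme '", object@level, "': cuts ",
      paste(format(object@cuts), collapse = " / "), "\n", sep = "")
})

#' Paired pre/post laboratory cohort container
#'
#' `QDExperiment` extends [SummarizedExperiment::SummarizedExperiment] with
#' two assays, `pre` and `post` (indicators in rows, patients in columns),
#' the indicator registry (units, reference interval, liver-panel flag) as
#' rowData, and patient annotations (treatment arm, outcome, clinical-status
#' flags) as colData. Laboratory values must be positive; `NA` marks a
#' missing measurement, which scoring skips and flags.
#'
#' @seealso [QDExperiment()], [readCohort()], [simulateCohort()],
#'   [scoreCohort()]
#' @export
setClass("QDExperiment", contains = "SummarizedExperiment")

.CLINICAL_FLAGS <- c("fatigue", "abdominal_distension", "anorexia",
                     "jaundice", "lower_limb_oedema")
.FLAG_LEVELS <- c("improved", "deteriorated_or_unchanged", "absent")
.OUTCOMES <- c("recovered", "dropped_out", "died")
.LIVER_PANEL <- c("alanine_aminotransferase", "aspartate_aminotransferase",
                  "total_bilirubin", "conjugated_bilirubin")

setValidity("QDExperiment", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("pre", "post") %in% an))
    return("assays 'pre' and 'post' are required")
  for (a in c("pre", "post")) {
    v <- SummarizedExperiment::assay(object, a)
    if (any(is.nan(v)) || any(v <= 0 | is.infinite(v), na.rm = TRUE))
      msg <- c(msg, sprintf("assay '%s' contains non-positive or non-finite values", a))
  }
  rd <- SummarizedExperiment::rowData(object)
  need <- c("units", "ref_low", "ref_high", "is_liver_panel")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste("rowData lacks:", paste(miss, collapse = ", ")))
  cd <- SummarizedExperiment::colData(object)
  if (!"arm" %in% colnames(cd))
    msg <- c(msg, "colData lacks 'arm'")
  if ("outcome" %in% colnames(cd) &&
      !all(cd$outcome %in% c(.OUTCOMES, NA)))
    msg <- c(msg, "'outcome' must be recovered/dropped_out/died or NA")
  if (length(msg)) msg else TRUE
})

setMethod("show", "QDExperiment", function(object) {
  callNextMethod()
  liv <- sum(SummarizedExperiment::rowData(object)$is_liver_panel)
  cat(sprintf("liver-panel indicators: %d; arms: %s\n", liv,
              paste(unique(SummarizedExperiment::colData(object)$arm),
                    collapse = ", ")))
})

#' Per-cohort QD score tables
#'
#' Result container of [scoreCohort()]: a long per-indicator table of
#' A/B/C components and products, and a per-patient table with the liver
#' gates, liver contribution, non-liver sum, composite QD total, and MELD.
#'
#' @slot perIndicator `DataFrame` with one row per scored
#'   (patient, indicator) pair: `patient_id`, `indicator`, `is_liver_panel`,
#'   `a`, `l_tau`, `b`, `c`, `product`, `skipped`.
#' @slot perPatient `DataFrame` with one row per patient: `patient_id`,
#'   `arm`, `outcome`, `d_gate`, `e_gate`, `liver_contribution`,
#'   `non_liver_sum`, `qd_total`, `meld`, `n_skipped`.
#' @slot scheme the [ThresholdScheme-class] used.
#' @slot liverRule the liver combination rule in effect.
#' @export
setClass("QDScores",
  representation(perIndicator = "DataFrame", perPatient = "DataFrame",
                 scheme = "ThresholdScheme", liverRule = "list"))

setMethod("show", "QDScores", function(object) {
  pp <- object@perPatient
  cat(sprintf("QDScores: %d patients, %d scored indicator pairs (scheme '%s', liver rule '%s')\n",
              nrow(pp), sum(!object@perIndicator$skipped),
              object@scheme@level, object@liverRule$rule))
  cat(sprintf("qd_total: mean %.2f, range [%d, %d]\n",
              mean(pp$qd_total), min(pp$qd_total), max(pp$qd_total)))
})

#' @describeIn QDScores per-indicator component table.
#' @param x a `QDScores` object.
#' @export
perIndicatorScores <- function(x) {
  stopifnot(is(x, "QDScores"))
  x@perIndicator
}

#' @describeIn QDScores per-patient score table.
#' @export
patientScores <- function(x) {
  stopifnot(is(x, "QDScores"))
  x@perPatient
}

#' Treatment-effect profile for cohort simulation
#'
#' An `EffectProfile` states, per indicator, the expected post/pre ratio
#' (multiplier) and the log-scale SD of the patient-level ratio
#' (dispersion), plus the distribution of outcome labels and the
#' probability that a clinical-status flag improves. Built-in profiles are
#' parameterized from the published two-arm pre/post group means (the
#' multipliers are mean ratios, e.g. alanine aminotransferase
#' 50.58/689.29) and the outcome counts of the two arms.
#'
#' @slot name profile name.
#' @slot multipliers named positive numeric, expected post/pre ratio per
#'   indicator.
#' @slot dispersions named positive numeric, log-scale SD of the ratio.
#' @slot outcomeProbs probabilities over recovered/dropped_out/died.
#' @slot flagImproveProb probability a present clinical flag improves.
#' @seealso [effectProfile()], [simulateCohort()]
#' @export
setClass("EffectProfile",
  representation(name = "character", multipliers = "numeric",
                 dispersions = "numeric", outcomeProbs = "numeric",
                 flagImproveProb = "numeric"))

setValidity("EffectProfile", function(object) {
  msg <- character()
  if (any(object@multipliers <= 0) || any(!is.finite(object@multipliers)))
    msg <- c(msg, "multipliers must be positive and finite")
  if (any(object@dispersions < 0) || any(!is.finite(object@dispersions)))
    msg <- c(msg, "dispersions must be non-negative and finite")
  if (!identical(sort(names(object@multipliers)),
                 sort(names(object@dispersions))))
    msg <- c(msg, "multipliers and dispersions must cover the same indicators")
  if (length(object@outcomeProbs) != 3L ||
      abs(sum(object@outcomeProbs) - 1) > 1e-8)
    msg <- c(msg, "outcomeProbs must be 3 probabilities summing to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EffectProfile", function(object) {
  cat(sprintf("EffectProfile '%s': %d indicators, mean multiplier %.3f, dispersion %.2f\n",
              object@name, length(object@multipliers),
              exp(mean(log(object@multipliers))),
              mean(object@dispersions)))
})
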