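.arm_matrix <- function(x, indicator, arm) {
  stopifnot(is(x, "QDExperiment"))
  if (!indicator %in% rownames(x))
    stop("unknown indicator: ", indicator)
  sel <- SummarizedExperiment::colData(x)$arm == arm
  if (!any(sel)) stop("no patients in arm '", arm, "'")
  pre <- SummarizedExperiment::assay(x, "pre")[indicator, sel]
  post <- SummarizedExperiment::assay(x, "post")[indicator, sel]
  ok <- !is.na(pre) & !is.na(post)
  list(pre = pre[ok], post = post[ok])
}

#' Group-level QD value for one indicator
#'
#' The published per-group "QD value" column is ambiguous between two
#' aggregations, so both are provided: `"mean_of_patient_ltau"` averages
#' each patient's golden logarithm, while `"ltau_of_group_means"` takes
#' the golden logarithm of the two group means. The two differ whenever
#' patients are heterogeneous.
#'
#' @param x a [QDExperiment-class].
#' @param indicator indicator name.
#' @param arm treatment arm label.
#' @param aggregation which aggregation, see Details.
#'
#' @return a non-negative scalar.
#' @export
groupQDValue <- function(x, indicator, arm,
                         aggregation = c("mean_of_patient_ltau",
                                         "ltau_of_group_means")) {
  aggregation <- match.arg(aggregation)
  v <- .arm_matrix(x, indicator, arm)
  if (!length(v$pre))
    stop("no complete pairs for '", indicator, "' in arm '", arm, "'")
  switch(aggregation,
    mean_of_patient_ltau = mean(goldenLog(v$pre, v$post)),
    ltau_of_group_means = goldenLog(mean(v$pre), mean(v$post)))
}

#' Paired pre/post change test for one indicator
#'
#' Two-sided paired test on pre- vs post-treatment values within one arm;
#' paired t by default, Wilcoxon signed-rank selectable (the source study
#' reports mean (SD) with P values but never names its tests). When every
#' difference is zero the t statistic is undefined; p = 1 is returned with
#' `degenerate = TRUE`.
#'
#' @inheritParams groupQDValue
#' @param method `"t"` or `"wilcoxon"`.
#'
#' @return list with `statistic`, `p_value`, `n`, `method`, `degenerate`.
#' @export
pairedChangeTest <- function(x, indicator, arm, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  v <- .arm_matrix(x, indicator, arm)
  n <- length(v$pre)
  if (n < 2L) stop("need at least 2 complete pairs")
  if (all(v$pre == v$post))
    return(list(statistic = NA_real_, p_value = 1, n = n,
                method = method, degenerate = TRUE))
  ht <- if (method == "t") {
    stats::t.test(v$pre, v$post, paired = TRUE)
  } else {
    stats::wilcox.test(v$pre, v$post, paired = TRUE, exact = FALSE)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value, n = n,
       method = method, degenerate = FALSE)
}

#' Association between the QD and MELD scores
#'
#' Pearson correlation and ordinary least-squares fit of MELD on the QD
#' total across patients, mirroring the published linear-regression
#' comparison of the two scoring systems.
#'
#' @param scores a [QDScores-class] (or a data.frame with `qd_total` and
#'   `meld` columns).
#'
#' @return list with `r`, `p_value`, `n`, `intercept`, `slope`.
#' @export
qdMeldAssociation <- function(scores) {
  df <- if (is(scores, "QDScores")) as.data.frame(patientScores(scores))
        else as.data.frame(scores)
  ok <- !is.na(df$qd_total) & !is.na(df$meld)
  qd <- df$qd_total[ok]
  meld <- df$meld[ok]
  if (length(qd) < 3L) stop("need at least 3 patients with both scores")
  if (stats::sd(qd) == 0 || stats::sd(meld) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = length(qd),
                intercept = NA_real_, slope = NA_real_,
                degenerate = TRUE))
  ct <- stats::cor.test(qd, meld, method = "pearson")
  fit <- stats::lm(meld ~ qd)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(qd),
       intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]), degenerate = FALSE)
}

.mean_sd_row <- function(label, v) {
  data.frame(group = label, n = length(v), mean = mean(v),
             sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
}

#' Outcome-group and clinical-status contrasts of the QD score
#'
#' Summarizes the per-patient QD total as mean (SD) by outcome group
#' (recovered / dropped out / died) and, for each clinical-status flag
#' (fatigue, abdominal distension, anorexia, jaundice, lower-limb
#' oedema), tests improved vs deteriorated-or-unchanged patients with a
#' two-sample test (Welch t by default). Patients are pooled across arms,
#' matching the published layout whose flag counts exceed either arm.
#' Groups with no patients are omitted with a warning.
#'
#' @param x a [QDExperiment-class] (source of outcome and flag columns).
#' @param scores the matching [QDScores-class].
#' @param method `"t"` (Welch) or `"wilcoxon"` for the flag contrasts.
#'
#' @return list with `byOutcome` (data.frame of group, n, mean, sd) and
#'   `byFlag` (data.frame with both groups' mean (SD) and the p-value per
#'   flag).
#' @export
outcomeContrast <- function(x, scores, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  stopifnot(is(x, "QDExperiment"), is(scores, "QDScores"))
  pp <- as.data.frame(patientScores(scores))
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  pp <- pp[match(rownames(cd), pp$patient_id), ]
  by_outcome <- list()
  for (g in .OUTCOMES) {
    v <- pp$qd_total[!is.na(pp$outcome) & pp$outcome == g]
    if (!length(v)) {
      warning("outcome group '", g, "' has no patients; omitted",
              call. = FALSE)
      next
    }
    by_outcome[[g]] <- .mean_sd_row(g, v)
  }
  by_outcome <- do.call(rbind, by_outcome)
  rownames(by_outcome) <- NULL
  flags_present <- intersect(.CLINICAL_FLAGS, names(cd))
  by_flag <- list()
  for (f in flags_present) {
    imp <- pp$qd_total[cd[[f]] %in% "improved"]
    det <- pp$qd_total[cd[[f]] %in% "deteriorated_or_unchanged"]
    p <- if (length(imp) >= 2L && length(det) >= 2L &&
             (stats::sd(c(imp, det)) > 0)) {
      if (method == "t")
        stats::t.test(imp, det)$p.value
      else
        stats::wilcox.test(imp, det, exact = FALSE)$p.value
    } else NA_real_
    by_flag[[f]] <- data.frame(
      flag = f,
      n_improved = length(imp),
      mean_improved = if (length(imp)) mean(imp) else NA_real_,
      sd_improved = if (length(imp) > 1L) stats::sd(imp) else NA_real_,
      n_other = length(det),
      mean_other = if (length(det)) mean(det) else NA_real_,
      sd_other = if (length(det) > 1L) stats::sd(det) else NA_real_,
      p_value = p)
  }
  by_flag <- do.call(rbind, by_flag)
  if (!is.null(by_flag)) rownames(by_flag) <- NULL
  list(byOutcome = by_outcome, byFlag = by_flag)
}

#' Per-indicator two-arm comparison table
#'
#' One row per indicator and arm with pre/post mean (SD), the paired-test
#' p-value, and both group-level QD aggregations — the shape of the
#' published pre/post comparison table. P-values are unadjusted by
#' default (the source applies no multiple-testing correction across its
#' 21 indicators); `adjust = "BH"` switches on Benjamini–Hochberg within
#' each arm.
#'
#' @param x a [QDExperiment-class].
#' @param arms arms to tabulate (default: all present).
#' @param method paired-test method, see [pairedChangeTest()].
#' @param adjust `"none"` (default) or `"BH"`.
#'
#' @return data.frame with columns `indicator`, `arm`, `n`, `pre_mean`,
#'   `pre_sd`, `post_mean`, `post_sd`, `p_value`,
#'   `qd_mean_patient_ltau`, `qd_ltau_of_means`.
#' @export
comparisonTable <- function(x, arms = NULL, method = c("t", "wilcoxon"),
                            adjust = c("none", "BH")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  if (is.null(arms))
    arms <- unique(SummarizedExperiment::colData(x)$arm)
  rows <- list()
  for (arm in arms) {
    for (indicator in rownames(x)) {
      v <- .arm_matrix(x, indicator, arm)
      n <- length(v$pre)
      if (n == 0L) next
      p <- if (n >= 2L) pairedChangeTest(x, indicator, arm,
                                         method = method)$p_value
           else NA_real_
      rows[[paste(arm, indicator)]] <- data.frame(
        indicator = indicator, arm = arm, n = n,
        pre_mean = mean(v$pre), pre_sd = stats::sd(v$pre),
        post_mean = mean(v$post), post_sd = stats::sd(v$post),
        p_value = p,
        qd_mean_patient_ltau = mean(goldenLog(v$pre, v$post)),
        qd_ltau_of_means = goldenLog(mean(v$pre), mean(v$post)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust == "BH")
    out$p_value <- stats::ave(out$p_value, out$arm,
                              FUN = function(p) stats::p.adjust(p, "BH"))
  out
}
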