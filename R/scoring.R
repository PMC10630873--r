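#' Reference-interval correction (C value)
#'
#' Encodes whether a change moves an indicator toward or away from its
#' reference interval. The relative distance of a value to the interval is
#' 0 inside the interval and, outside it, the absolute distance to the
#' nearer bound divided by that bound (absent bounds act as -Inf/+Inf).
#' C is +1 when the post-treatment distance is smaller (or both values lie
#' in range — "improved or maintained normal"), -1 when it is larger, and
#' 0 when both distances are equal and non-zero.
#'
#' @inheritParams goldenLog
#' @param ref_low,ref_high reference bounds (either may be `NA`, not both).
#'
#' @return integer in \{-1, 0, +1\}.
#' @examples
#' # total bilirubin far above range, falling toward it:
#' normalRangeScore(375.23, 220.75, ref_high = 21)           # +1
#' # hemoglobin below range, falling further:
#' normalRangeScore(112.47, 89.53, ref_low = 130, ref_high = 175)  # -1
#' @export
normalRangeScore <- function(pre, post, ref_low = NA, ref_high = NA,
                             indicator = NULL) {
  .check_lab(pre, "pre", indicator)
  .check_lab(post, "post", indicator)
  if (is.na(ref_low) && is.na(ref_high))
    stop("indicator has no reference bounds", call. = FALSE)
  dpre <- .ref_distance(pre, ref_low, ref_high)
  dpost <- .ref_distance(post, ref_low, ref_high)
  ifelse(dpost < dpre | (dpost == 0 & dpre == 0), 1L,
         ifelse(dpost > dpre, -1L, 0L))
}

#' Score a single paired measurement
#'
#' Computes the per-indicator components: A = [directionScore()],
#' Ltau = [goldenLog()], B = [magnitudeScore()], C = [normalRangeScore()],
#' and the per-indicator product A x B x C. Note the literal product
#' algebra implies a worsening indicator can score positive through a
#' double negative (A = -1 moving away from range gives C = -1); this is
#' kept as stated and is auditable in the returned components.
#'
#' @inheritParams normalRangeScore
#' @inheritParams magnitudeScore
#'
#' @return one-row `data.frame` with columns `indicator`, `a`, `l_tau`,
#'   `b`, `c`, `product`.
#' @examples
#' scoreIndicator(689.29, 50.58, ref_low = 7, ref_high = 40,
#'                indicator = "alanine_aminotransferase")
#' @export
scoreIndicator <- function(pre, post, ref_low = NA, ref_high = NA,
                           indicator = NA_character_,
                           scheme = thresholdScheme("molecular_beta")) {
  a <- directionScore(pre, post, indicator)
  l_tau <- goldenLog(pre, post, indicator)
  b <- magnitudeScore(l_tau, scheme)
  cc <- normalRangeScore(pre, post, ref_low, ref_high, indicator)
  data.frame(indicator = indicator, a = a, l_tau = l_tau, b = b, c = cc,
             product = as.integer(a * b * cc))
}

#' Liver-panel modification gates (D and E values)
#'
#' The four liver-function indicators (alanine aminotransferase, aspartate
#' aminotransferase, total bilirubin, conjugated bilirubin) enter the
#' composite score only through a gated modification: the D gate opens when
#' all four A values are +1 (every indicator decreased), the E gate when
#' the summed B values reach 9 (at least three indicators changed at the
#' top magnitude). Under the default `"gated"` rule the contribution is
#' `D * E * sum(A*B*C)` over the four indicators; alternatives are a flat
#' bonus `D * E * k` (`"flat_bonus"`) and the ungated sum plus the bonus
#' (`"ungated_plus_bonus"`).
#'
#' @param a,b,c integer component vectors of length 4, one per liver
#'   indicator (order irrelevant but aligned across the three).
#' @param rule liver combination rule, see Details.
#' @param k bonus size for the bonus rules (default 12, the maximum
#'   attainable gated contribution).
#'
#' @return list with `d_gate`, `e_gate` (0/1) and `liver_contribution`.
#' @examples
#' liverModification(a = c(1, 1, 1, 1), b = c(3, 3, 3, 0), c = c(1, 1, 1, 1))
#' @export
liverModification <- function(a, b, c,
                              rule = c("gated", "flat_bonus",
                                       "ungated_plus_bonus"),
                              k = 12L) {
  rule <- match.arg(rule)
  if (length(a) != 4L || length(b) != 4L || length(c) != 4L)
    stop("the liver modification requires exactly the four liver-panel indicators",
         call. = FALSE)
  stopifnot(all(a %in% -1:1), all(b %in% 0:3), all(c %in% -1:1))
  d_gate <- as.integer(sum(a) == 4L)
  e_gate <- as.integer(sum(b) >= 9L)
  s <- sum(a * b * c)
  contribution <- switch(rule,
    gated = d_gate * e_gate * s,
    flat_bonus = d_gate * e_gate * k,
    ungated_plus_bonus = s + d_gate * e_gate * k)
  list(d_gate = d_gate, e_gate = e_gate,
       liver_contribution = as.integer(contribution))
}

# score one patient's named pre/post vectors against a registry.
# Returns list(perIndicator = data.frame, summary = one-row data.frame).
.score_panel <- function(pre, post, registry, scheme, rule, k,
                         patient_id = NA_character_, warn = TRUE) {
  ind <- rownames(registry)
  pre <- pre[ind]
  post <- post[ind]
  ok <- !is.na(pre) & !is.na(post)
  if (!any(ok))
    stop(sprintf("patient '%s' has no scoreable indicator", patient_id),
         call. = FALSE)
  rows <- vector("list", length(ind))
  for (i in seq_along(ind)) {
    if (ok[i]) {
      rows[[i]] <- scoreIndicator(pre[i], post[i],
                                  ref_low = registry$ref_low[i],
                                  ref_high = registry$ref_high[i],
                                  indicator = ind[i], scheme = scheme)
    } else {
      rows[[i]] <- data.frame(indicator = ind[i], a = NA_integer_,
                              l_tau = NA_real_, b = NA_integer_,
                              c = NA_integer_, product = NA_integer_)
    }
  }
  tab <- do.call(rbind, rows)
  tab$is_liver_panel <- registry$is_liver_panel
  tab$skipped <- !ok
  liver <- registry$is_liver_panel
  if (all(ok[liver]) && sum(liver) == 4L) {
    lm <- liverModification(tab$a[liver], tab$b[liver], tab$c[liver],
                            rule = rule, k = k)
  } else {
    if (warn)
      warning(sprintf(
        "patient '%s': liver panel incomplete; gates undefined, liver contribution 0",
        patient_id), call. = FALSE)
    lm <- list(d_gate = NA_integer_, e_gate = NA_integer_,
               liver_contribution = 0L)
  }
  non_liver_sum <- sum(tab$product[!liver & ok], na.rm = TRUE)
  summary <- data.frame(patient_id = patient_id,
                        d_gate = lm$d_gate, e_gate = lm$e_gate,
                        liver_contribution = lm$liver_contribution,
                        non_liver_sum = as.integer(non_liver_sum),
                        qd_total = as.integer(non_liver_sum +
                                              lm$liver_contribution),
                        n_skipped = sum(!ok))
  list(perIndicator = tab, summary = summary)
}

#' Composite QD score for one patient
#'
#' Assembles the per-indicator A/B/C products for a single patient and
#' applies the liver-panel modification: the composite total is the sum of
#' the non-liver products plus the gated liver contribution. Indicators
#' missing either value are skipped, contribute 0, and are flagged; if any
#' of the four liver indicators is missing the gates are undefined (`NA`)
#' and the liver contribution is 0, with a warning. A higher score
#' indicates better therapeutic efficacy.
#'
#' @param pre,post named numeric vectors of laboratory values (names are
#'   registry indicator names; `NA` = missing).
#' @param registry an indicator registry, see [indicatorRegistry()].
#' @inheritParams magnitudeScore
#' @param liverRule,k liver combination rule and bonus, see
#'   [liverModification()].
#'
#' @return list with `perIndicator` (component table) and `summary`
#'   (one row: gates, liver contribution, non-liver sum, `qd_total`).
#' @examples
#' reg <- defaultRegistry()
#' pre <- setNames(reg$ref_high * 2, rownames(reg))
#' post <- setNames(reg$ref_high * 1.05, rownames(reg))
#' scorePatient(pre, post, reg)$summary
#' @export
scorePatient <- function(pre, post, registry = defaultRegistry(),
                         scheme = thresholdScheme("molecular_beta"),
                         liverRule = c("gated", "flat_bonus",
                                       "ungated_plus_bonus"),
                         k = 12L) {
  liverRule <- match.arg(liverRule)
  if (is.null(names(pre)) || is.null(names(post)))
    stop("'pre' and 'post' must be named by indicator")
  .score_panel(pre, post, registry, scheme, liverRule, k)
}

#' Score a whole cohort
#'
#' Applies [scorePatient()] to every patient of a [QDExperiment-class] and
#' attaches the MELD comparator score computed from the panel's
#' creatinine, total bilirubin and INR (see [meldFromPanel()]).
#'
#' @param x a [QDExperiment-class].
#' @inheritParams scorePatient
#' @param meldWhen which measurement feeds MELD, `"post"` (default) or
#'   `"pre"`.
#'
#' @return a [QDScores-class] object.
#' @examples
#' coh <- simulateCohort(5, effectProfile("dpmas_responder"), seed = 1)
#' sc <- scoreCohort(coh)
#' patientScores(sc)
#' @export
scoreCohort <- function(x, scheme = thresholdScheme("molecular_beta"),
                        liverRule = c("gated", "flat_bonus",
                                      "ungated_plus_bonus"),
                        k = 12L, meldWhen = c("post", "pre")) {
  stopifnot(is(x, "QDExperiment"))
  liverRule <- match.arg(liverRule)
  meldWhen <- match.arg(meldWhen)
  if (ncol(x) == 0L) stop("empty cohort")
  registry <- S4Vectors::DataFrame(SummarizedExperiment::rowData(x))
  rownames(registry) <- rownames(x)
  pre <- SummarizedExperiment::assay(x, "pre")
  post <- SummarizedExperiment::assay(x, "post")
  cd <- SummarizedExperiment::colData(x)
  per_ind <- vector("list", ncol(x))
  per_pat <- vector("list", ncol(x))
  for (j in seq_len(ncol(x))) {
    res <- .score_panel(pre[, j], post[, j], registry, scheme, liverRule, k,
                        patient_id = colnames(x)[j])
    res$perIndicator$patient_id <- colnames(x)[j]
    per_ind[[j]] <- res$perIndicator
    per_pat[[j]] <- res$summary
  }
  tab <- do.call(rbind, per_ind)
  tab <- tab[, c("patient_id", "indicator", "is_liver_panel", "a", "l_tau",
                 "b", "c", "product", "skipped")]
  pp <- do.call(rbind, per_pat)
  pp$arm <- as.character(cd$arm)
  pp$outcome <- if ("outcome" %in% colnames(cd))
    as.character(cd$outcome) else NA_character_
  pp$meld <- meldFromPanel(x, when = meldWhen)
  pp <- pp[, c("patient_id", "arm", "outcome", "d_gate", "e_gate",
               "liver_contribution", "non_liver_sum", "qd_total", "meld",
               "n_skipped")]
  new("QDScores", perIndicator = S4Vectors::DataFrame(tab),
      perPatient = S4Vectors::DataFrame(pp),
      scheme = scheme, liverRule = list(rule = liverRule, k = k))
}
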