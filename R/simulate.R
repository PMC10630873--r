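#' Baseline laboratory distribution parameters
#'
#' Per-indicator pre-treatment mean/SD and group post/pre mean ratios for
#' the two study arms, shipped as an editable CSV shaped like the
#' published two-arm pre/post table. These parameterize the synthetic
#' generator; they are distribution parameters, not patient data.
#'
#' @param path CSV path; default the shipped table.
#' @return data.frame with one row per indicator.
#' @export
cohortBaselines <- function(path = system.file("extdata",
                                               "cohort_baselines.csv",
                                               package = "qdscore",
                                               mustWork = TRUE)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("indicator", "dpmas_pre_mean", "dpmas_pre_sd",
                  "dpmas_post_mean", "conventional_pre_mean",
                  "conventional_pre_sd", "conventional_post_mean")
                %in% names(df)))
  df
}

#' Built-in treatment-effect profiles
#'
#' * `"dpmas_responder"` — multipliers are the artificial-liver arm's
#'   post/pre group-mean ratios (e.g. alanine aminotransferase
#'   50.58/689.29 = 0.0734); outcome probabilities follow that arm's
#'   counts (10 recovered / 4 dropped out / 1 died of 15).
#' * `"conventional"` — the conventional arm's ratios and counts
#'   (2 / 7 / 3 of 12).
#' * `"non_responder"` — a deteriorating profile: both bilirubins rise
#'   (multiplier 1.30), transaminases fall only modestly (0.60 / 0.80),
#'   all other indicators unchanged (1.0); outcomes 0 / 0.6 / 0.4.
#'
#' Dispersion is the log-scale SD of the patient-level post/pre ratio,
#' 0.30 for every indicator by default.
#'
#' @param name profile name.
#' @param dispersion log-scale SD applied to every indicator.
#' @param baseline baseline table, see [cohortBaselines()].
#'
#' @return an [EffectProfile-class].
#' @examples
#' effectProfile("dpmas_responder")
#' @export
effectProfile <- function(name = c("dpmas_responder", "conventional",
                                   "non_responder"),
                          dispersion = 0.30,
                          baseline = cohortBaselines()) {
  name <- match.arg(name)
  ind <- baseline$indicator
  mult <- switch(name,
    dpmas_responder = baseline$dpmas_post_mean / baseline$dpmas_pre_mean,
    conventional = baseline$conventional_post_mean /
      baseline$conventional_pre_mean,
    non_responder = {
      m <- rep(1, length(ind))
      m[ind == "alanine_aminotransferase"] <- 0.60
      m[ind == "aspartate_aminotransferase"] <- 0.80
      m[ind %in% c("total_bilirubin", "conjugated_bilirubin")] <- 1.30
      m
    })
  probs <- switch(name,
    dpmas_responder = c(recovered = 10, dropped_out = 4, died = 1) / 15,
    conventional = c(recovered = 2, dropped_out = 7, died = 3) / 12,
    non_responder = c(recovered = 0, dropped_out = 0.6, died = 0.4))
  flagp <- switch(name, dpmas_responder = 0.65, conventional = 0.45,
                  non_responder = 0.20)
  new("EffectProfile", name = name,
      multipliers = stats::setNames(mult, ind),
      dispersions = stats::setNames(rep(dispersion, length(ind)), ind),
      outcomeProbs = probs, flagImproveProb = flagp)
}

# deterministic per-patient sub-seed: mixing the cohort seed with the
# patient index keeps existing patients fixed when n grows. Kept < 2^31.
.patient_seed <- function(seed, i) {
  as.integer((as.double(seed %% 99991L) * 20011 + i * 7919 + 1) %% 2147483629)
}

# log-normal parameters moment-matched to a natural-scale mean/sd
.lnorm_params <- function(m, s) {
  s2 <- log(1 + (s / m)^2)
  list(mu = log(m) - s2 / 2, sigma = sqrt(s2))
}

#' Simulate a synthetic patient cohort
#'
#' Draws, per patient, pre-treatment values from per-indicator log-normal
#' distributions moment-matched to the configured natural-scale mean/SD
#' (laboratory values are positive and right-skewed — the transaminase SDs
#' of the source table exceed their means — so Gaussian marginals would
#' produce negatives), then `post = pre * multiplier * exp(eps)` with
#' `eps ~ N(0, dispersion^2)`. Outcome labels and clinical-status flags
#' are drawn from the profile. Indicators are generated independently: the
#' source table carries no covariance information.
#'
#' Each patient consumes an isolated random sub-stream derived from
#' `seed` and the patient index, so enlarging `n` never reshuffles
#' existing patients and the same seed reproduces the cohort byte for
#' byte.
#'
#' @param n number of patients (positive integer).
#' @param profile an [EffectProfile-class].
#' @param seed integer random seed for the cohort.
#' @param baseline baseline table ([cohortBaselines()]); the arm-matching
#'   pre-treatment mean/SD columns are used (`dpmas_*` for the responder
#'   profile, `conventional_*` otherwise).
#' @param registry indicator registry for the container's rowData.
#' @param arm arm label stored in colData (default derived from the
#'   profile name).
#' @param idOffset patient index offset: patient ids and sub-streams start
#'   at `idOffset + 1`, letting two calls share a seed without overlap.
#'
#' @return a [QDExperiment-class] with assays `pre` and `post`.
#' @examples
#' coh <- simulateCohort(15, effectProfile("dpmas_responder"), seed = 7)
#' coh
#' @export
simulateCohort <- function(n, profile, seed,
                           baseline = cohortBaselines(),
                           registry = defaultRegistry(),
                           arm = NULL, idOffset = 0L) {
  stopifnot(is(profile, "EffectProfile"))
  if (length(n) != 1L || n < 1L || n != round(n))
    stop("'n' must be a positive integer")
  ind <- rownames(registry)
  if (!setequal(ind, names(profile@multipliers)))
    stop("profile and registry cover different indicator sets")
  if (!setequal(ind, baseline$indicator))
    stop("baseline and registry cover different indicator sets")
  if (is.null(arm))
    arm <- if (profile@name == "dpmas_responder") "dpmas" else "conventional"
  bcol <- if (profile@name == "dpmas_responder") "dpmas" else "conventional"
  bl <- baseline[match(ind, baseline$indicator), ]
  lp <- .lnorm_params(bl[[paste0(bcol, "_pre_mean")]],
                      bl[[paste0(bcol, "_pre_sd")]])
  mult <- profile@multipliers[ind]
  disp <- profile@dispersions[ind]
  p <- length(ind)
  pre <- post <- matrix(NA_real_, p, n, dimnames = list(ind, NULL))
  outcome <- character(n)
  flags <- matrix(NA_character_, n, length(.CLINICAL_FLAGS),
                  dimnames = list(NULL, .CLINICAL_FLAGS))
  for (j in seq_len(n)) {
    idx <- idOffset + j
    set.seed(.patient_seed(seed, idx))
    pre[, j] <- stats::rlnorm(p, meanlog = lp$mu, sdlog = lp$sigma)
    post[, j] <- pre[, j] * mult * exp(stats::rnorm(p, 0, disp))
    outcome[j] <- sample(.OUTCOMES, 1L, prob = profile@outcomeProbs)
    for (f in seq_along(.CLINICAL_FLAGS)) {
      if (stats::runif(1) < 0.10) {
        flags[j, f] <- "absent"
      } else {
        flags[j, f] <- if (stats::runif(1) < profile@flagImproveProb)
          "improved" else "deteriorated_or_unchanged"
      }
    }
  }
  ids <- sprintf("%s_%03d", arm, idOffset + seq_len(n))
  colnames(pre) <- colnames(post) <- ids
  cd <- S4Vectors::DataFrame(patient_id = ids, arm = arm, outcome = outcome,
                             as.data.frame(flags), row.names = ids)
  QDExperiment(pre = pre, post = post, registry = registry, colData = cd)
}

#' Parameter-recovery check for a simulated cohort
#'
#' Estimates each indicator's treatment multiplier as the geometric mean
#' of per-patient post/pre ratios and compares it with the generating
#' profile on the log scale, using the CLT tolerance
#' `3 * dispersion / sqrt(n)`. At small n the tolerance widens
#' accordingly rather than erroring.
#'
#' @param x a simulated [QDExperiment-class].
#' @param profile the [EffectProfile-class] that generated it.
#'
#' @return data.frame with per-indicator `multiplier`, `estimate`,
#'   `log_error`, `tolerance`, `pass`.
#' @export
effectRecoveryCheck <- function(x, profile) {
  stopifnot(is(x, "QDExperiment"), is(profile, "EffectProfile"))
  if (ncol(x) == 0L) stop("empty cohort")
  ratio <- SummarizedExperiment::assay(x, "post") /
    SummarizedExperiment::assay(x, "pre")
  ind <- rownames(x)
  est <- exp(rowMeans(log(ratio), na.rm = TRUE))
  nn <- rowSums(!is.na(ratio))
  mult <- profile@multipliers[ind]
  disp <- profile@dispersions[ind]
  tol <- 3 * disp / sqrt(nn)
  err <- abs(log(est) - log(mult))
  data.frame(indicator = ind, multiplier = unname(mult),
             estimate = unname(est), n = unname(nn),
             log_error = unname(err), tolerance = unname(tol),
             pass = unname(err <= tol), row.names = NULL)
}
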