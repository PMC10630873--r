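# two-patient cohort with chosen pre/post ratios for one indicator
two_patient_cohort <- function(ratios, indicator = "glucose") {
  pre <- post <- matrix(rep(5, nrow(reg) * length(ratios)), nrow(reg),
                        dimnames = list(rownames(reg),
                                        paste0("p", seq_along(ratios))))
  pre[indicator, ] <- 100 * ratios / ratios   # 100 each
  pre[indicator, ] <- c(100, 400)[seq_along(ratios)]
  post[indicator, ] <- pre[indicator, ] / ratios
  QDExperiment(pre, post, reg,
               colData = S4Vectors::DataFrame(
                 patient_id = colnames(pre),
                 arm = rep("dpmas", length(ratios)),
                 row.names = colnames(pre)))
}

test_that("the two group-QD aggregations agree on homogeneous patients and diverge otherwise", {
  one <- two_patient_cohort(2)[, 1]
  expect_equal(groupQDValue(one, "glucose", "dpmas", "mean_of_patient_ltau"),
               1.4404, tolerance = 1e-3)
  expect_equal(groupQDValue(one, "glucose", "dpmas", "ltau_of_group_means"),
               1.4404, tolerance = 1e-3)
  # patients (100 -> 50) and (400 -> 50): hand oracle (Ltau(2)+Ltau(8))/2
  # vs Ltau of mean ratio 250/50 = 5
  both <- two_patient_cohort(c(2, 8))
  expect_equal(groupQDValue(both, "glucose", "dpmas",
                            "mean_of_patient_ltau"),
               (log(2) + log(8)) / 2 / log(phi), tolerance = 1e-9)
  expect_equal(groupQDValue(both, "glucose", "dpmas",
                            "mean_of_patient_ltau"), 2.8808,
               tolerance = 1e-3)
  expect_equal(groupQDValue(both, "glucose", "dpmas",
                            "ltau_of_group_means"),
               log(5) / log(phi), tolerance = 1e-9)
  expect_error(groupQDValue(both, "glucose", "conventional"), "arm")
  expect_error(groupQDValue(both, "nope", "dpmas"), "indicator")
})

test_that("paired change test is antisymmetric and detects strong effects", {
  prof <- effectProfile("dpmas_responder", dispersion = 0.05)
  prof@multipliers[] <- 0.1
  coh <- simulateCohort(15, prof, seed = 6)
  res <- pairedChangeTest(coh, "glucose", "dpmas")
  expect_lt(res$p_value, 0.01)
  # independent oracle: stats::t.test on the raw vectors
  pre <- SummarizedExperiment::assay(coh, "pre")["glucose", ]
  post <- SummarizedExperiment::assay(coh, "post")["glucose", ]
  expect_equal(res$p_value, t.test(pre, post, paired = TRUE)$p.value,
               tolerance = 1e-12)
  # swapping pre and post negates the statistic
  swapped <- QDExperiment(SummarizedExperiment::assay(coh, "post"),
                          SummarizedExperiment::assay(coh, "pre"), reg,
                          colData = SummarizedExperiment::colData(coh))
  expect_equal(pairedChangeTest(swapped, "glucose", "dpmas")$statistic,
               -res$statistic, tolerance = 1e-12)
  # all-zero differences: degenerate flag, p = 1
  same <- QDExperiment(SummarizedExperiment::assay(coh, "pre"),
                       SummarizedExperiment::assay(coh, "pre"), reg,
                       colData = SummarizedExperiment::colData(coh))
  deg <- pairedChangeTest(same, "glucose", "dpmas")
  expect_true(deg$degenerate)
  expect_identical(deg$p_value, 1)
  expect_lt(pairedChangeTest(coh, "glucose", "dpmas",
                             method = "wilcoxon")$p_value, 0.01)
})

test_that("QD-MELD association handles collinear, anti-collinear and noise cases", {
  df <- data.frame(qd_total = c(1, 2, 3, 4, 5),
                   meld = c(2, 4, 6, 8, 10))
  expect_equal(qdMeldAssociation(df)$r, 1, tolerance = 1e-12)
  df$meld <- -df$qd_total
  expect_equal(qdMeldAssociation(df)$r, -1, tolerance = 1e-12)
  set.seed(33)
  noise <- data.frame(qd_total = rnorm(50), meld = rnorm(50))
  res <- qdMeldAssociation(noise)
  expect_lt(abs(res$r), 0.5)
  # oracle: textbook r -> t transform
  r <- cor(noise$qd_total, noise$meld)
  tstat <- r * sqrt(48) / sqrt(1 - r^2)
  expect_equal(res$p_value, 2 * pt(-abs(tstat), df = 48),
               tolerance = 1e-10)
  flat <- data.frame(qd_total = rep(2, 5), meld = 1:5)
  expect_true(qdMeldAssociation(flat)$degenerate)
  expect_error(qdMeldAssociation(df[1:2, ]), "at least 3")
})

test_that("outcome contrasts summarize groups and flag tests pool across arms", {
  d <- simulateCohort(15, effectProfile("dpmas_responder"), seed = 14)
  c2 <- simulateCohort(12, effectProfile("conventional"), seed = 15)
  coh <- cbind(d, c2)
  sc <- scoreCohort(coh)
  oc <- outcomeContrast(coh, sc)
  expect_true(all(oc$byOutcome$n >= 1))
  expect_identical(sum(oc$byOutcome$n), 27L)
  expect_true(all(c("flag", "p_value") %in% names(oc$byFlag)))
  expect_identical(nrow(oc$byFlag), 5L)
  # single-patient groups report a mean but no SD
  one <- oc$byOutcome[oc$byOutcome$n == 1, ]
  if (nrow(one)) expect_true(all(is.na(one$sd)))
  # a missing outcome group is omitted with a warning
  d_only <- simulateCohort(4, effectProfile("dpmas_responder"), seed = 200)
  SummarizedExperiment::colData(d_only)$outcome <-
    c("recovered", "recovered", "recovered", "died")
  expect_warning(outcomeContrast(d_only, scoreCohort(d_only)), "omitted")
})

test_that("the comparison table mirrors the published per-indicator layout", {
  d <- simulateCohort(15, effectProfile("dpmas_responder"), seed = 16)
  c2 <- simulateCohort(12, effectProfile("conventional"), seed = 17)
  tab <- comparisonTable(cbind(d, c2))
  expect_identical(nrow(tab), 42L)   # 21 indicators x 2 arms
  expect_identical(names(tab),
                   c("indicator", "arm", "n", "pre_mean", "pre_sd",
                     "post_mean", "post_sd", "p_value",
                     "qd_mean_patient_ltau", "qd_ltau_of_means"))
  expect_true(all(tab$qd_mean_patient_ltau >= 0))
  bh <- comparisonTable(cbind(d, c2), adjust = "BH")
  expect_true(all(bh$p_value >= tab$p_value - 1e-12))
})
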