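test_that("normal-range correction compares relative distances to the interval", {
  # total bilirubin: both above range, post strictly closer -> +1
  expect_identical(normalRangeScore(375.23, 220.75, ref_high = 21), 1L)
  # hemoglobin: both below range, post farther below -> -1
  expect_identical(normalRangeScore(112.47, 89.53, ref_low = 130,
                                    ref_high = 175), -1L)
  # both inside the interval: improved-or-maintained-normal branch
  expect_identical(normalRangeScore(150, 160, ref_low = 130,
                                    ref_high = 175), 1L)
  # equal non-zero relative distances on opposite sides -> 0
  expect_identical(normalRangeScore(80, 144, ref_low = 100,
                                    ref_high = 120), 0L)
  # overshoot across the whole interval is handled by the distance rule:
  # relative distance decides, whichever side the value lands on
  expect_identical(normalRangeScore(260, 50, ref_low = 100,
                                    ref_high = 130), 1L)   # 1.0 -> 0.5
  expect_identical(normalRangeScore(140, 50, ref_low = 100,
                                    ref_high = 130), -1L)  # 0.077 -> 0.5
  expect_error(normalRangeScore(1, 2), "reference bounds")
})

test_that("indicator scoring composes A, B, C into the product", {
  s <- scoreIndicator(689.29, 50.58, ref_low = 7, ref_high = 40,
                      indicator = "alanine_aminotransferase")
  expect_identical(s$a, 1L)
  expect_identical(s$b, 3L)
  expect_identical(s$c, 1L)
  expect_identical(s$product, 3L)
  expect_equal(s$l_tau, 5.429, tolerance = 1e-2)

  expect_identical(scoreIndicator(12.3, 12.3, ref_high = 40)$product, 0L)

  # documented double-negative: worsening far out of range scores +3
  w <- scoreIndicator(50, 200, ref_high = 40)
  expect_identical(c(w$a, w$b, w$c, w$product), c(-1L, 3L, -1L, 3L))
})

test_that("liver gates follow the all-decreased and summed-B rules", {
  full <- liverModification(a = rep(1L, 4), b = rep(3L, 4), c = rep(1L, 4))
  expect_identical(full, list(d_gate = 1L, e_gate = 1L,
                              liver_contribution = 12L))
  # only 2 of 4 decreased -> D gate closed
  part <- liverModification(a = c(1L, 1L, -1L, -1L), b = rep(3L, 4),
                            c = rep(1L, 4))
  expect_identical(part$d_gate, 0L)
  expect_identical(part$liver_contribution, 0L)
  # summed-B boundary is inclusive at 9
  edge <- liverModification(a = rep(1L, 4), b = c(3L, 3L, 3L, 0L),
                            c = rep(1L, 4))
  expect_identical(edge$e_gate, 1L)
  expect_identical(edge$liver_contribution, 9L)
  expect_identical(liverModification(rep(1L, 4), c(3L, 3L, 2L, 0L),
                                     rep(1L, 4))$e_gate, 0L)
  expect_error(liverModification(rep(1L, 3), rep(3L, 3), rep(1L, 3)),
               "four")
})

test_that("gate soundness holds over random component draws", {
  set.seed(301)
  n <- 10000L
  A <- matrix(sample(c(-1L, 0L, 1L), 4 * n, TRUE), ncol = 4)
  B <- matrix(sample(0:3, 4 * n, TRUE), ncol = 4)
  C <- matrix(sample(c(-1L, 0L, 1L), 4 * n, TRUE), ncol = 4)
  res <- vapply(seq_len(n), function(i)
    unlist(liverModification(A[i, ], B[i, ], C[i, ])), numeric(3))
  any_increase <- rowSums(A == 1L) < 4L
  expect_true(all(res["d_gate", any_increase] == 0))
  expect_true(all(res["liver_contribution", any_increase] == 0))
  expect_true(all(res["liver_contribution", rowSums(B) < 9L] == 0))
  open <- !any_increase & rowSums(B) >= 9L
  expect_equal(res["liver_contribution", open],
               rowSums((A * B * C)[open, , drop = FALSE]))
})

test_that("alternative liver combination rules are available", {
  a <- rep(1L, 4); b <- rep(3L, 4); cc <- c(1L, 1L, 1L, -1L)
  expect_identical(liverModification(a, b, cc)$liver_contribution, 6L)
  expect_identical(liverModification(a, b, cc,
                                     rule = "flat_bonus")$liver_contribution,
                   12L)
  expect_identical(liverModification(a, b, cc, rule = "flat_bonus",
                                     k = 5L)$liver_contribution, 5L)
  expect_identical(
    liverModification(a, b, cc,
                      rule = "ungated_plus_bonus",
                      k = 5L)$liver_contribution, 11L)
  # closed gates zero the bonus too
  expect_identical(liverModification(c(1L, 1L, 1L, -1L), b, cc,
                                     rule = "flat_bonus")$liver_contribution,
                   0L)
})

test_that("a strong responder panel scores exactly the liver contribution", {
  p <- strong_responder_panel()
  res <- scorePatient(p$pre, p$post, reg)
  expect_identical(res$summary$qd_total, 12L)
  expect_identical(res$summary$non_liver_sum, 0L)
  expect_identical(res$summary$d_gate, 1L)
  expect_identical(res$summary$e_gate, 1L)
})

test_that("an all-tied panel totals zero and two rising liver markers close the gate", {
  p <- strong_responder_panel()
  res <- scorePatient(p$pre, p$pre, reg)
  expect_identical(res$summary$qd_total, 0L)
  expect_identical(res$summary$d_gate, 0L)

  worse <- p$post
  worse[c("total_bilirubin", "conjugated_bilirubin")] <-
    p$pre[c("total_bilirubin", "conjugated_bilirubin")] * 3
  res2 <- scorePatient(p$pre, worse, reg)
  expect_identical(res2$summary$d_gate, 0L)
  expect_identical(res2$summary$liver_contribution, 0L)
  expect_identical(res2$summary$qd_total, res2$summary$non_liver_sum)
})

test_that("missing measurements are skipped, flagged and never change the total", {
  p <- strong_responder_panel()
  pre <- p$pre; post <- p$post
  # give one non-liver indicator a zero product, then blank it
  pre["glucose"] <- 5; post["glucose"] <- 5
  base <- scorePatient(pre, post, reg)
  pre["glucose"] <- NA
  dropped <- scorePatient(pre, post, reg)
  expect_identical(dropped$summary$qd_total, base$summary$qd_total)
  expect_identical(dropped$summary$n_skipped, 1L)
  expect_true(dropped$perIndicator$skipped[
    dropped$perIndicator$indicator == "glucose"])

  # missing liver indicator: gates undefined, contribution 0, warning
  pre2 <- p$pre; pre2["total_bilirubin"] <- NA
  expect_warning(res <- scorePatient(pre2, p$post, reg), "liver panel")
  expect_identical(res$summary$liver_contribution, 0L)
  expect_true(is.na(res$summary$d_gate))

  empty <- stats::setNames(rep(NA_real_, nrow(reg)), rownames(reg))
  expect_error(scorePatient(empty, empty, reg), "no scoreable")
})

test_that("cohort scoring is deterministic and respects the total bound", {
  coh <- simulateCohort(12, effectProfile("conventional"), seed = 5)
  s1 <- scoreCohort(coh)
  s2 <- scoreCohort(coh)
  expect_identical(as.data.frame(patientScores(s1)),
                   as.data.frame(patientScores(s2)))
  expect_identical(as.data.frame(perIndicatorScores(s1)),
                   as.data.frame(perIndicatorScores(s2)))
  pp <- as.data.frame(patientScores(s1))
  n_non_liver <- sum(!reg$is_liver_panel)
  expect_true(all(abs(pp$qd_total) <= 3L * n_non_liver + 12L))
  expect_true(all(pp$qd_total == pp$non_liver_sum + pp$liver_contribution))
})
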