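test_that("sarcopenia classification uses strict sex-specific cutoffs", {
  expect_false(classify_sarcopenia(7.0, "M"))   # boundary: non-sarcopenic
  expect_true(classify_sarcopenia(6.99, "M"))
  expect_false(classify_sarcopenia(5.4, "F"))
  expect_true(classify_sarcopenia(compute_asmi(12.0, 153), "F"))  # 5.126
  expect_false(classify_sarcopenia(compute_asmi(21.3, 168), "M")) # 7.547
  expect_error(classify_sarcopenia(-1, "M"), "positive")
  expect_error(classify_sarcopenia(6, "X"), "sex")
  rule <- awgs_cutoff(male_cutoff = 7.5)
  expect_true(classify_sarcopenia(7.2, "M", rule))
})

test_that("confusion counting matches hand arithmetic and the oracle", {
  # perfect agreement
  perf <- confusion_from_labels(rep(c(TRUE, FALSE), each = 10),
                                rep(c(TRUE, FALSE), each = 10))
  expect_equal(perf$sensitivity, 100)
  expect_equal(perf$specificity, 100)
  expect_equal(perf$agreement, 100)
  expect_equal(perf$kappa, 1)

  # the published-style table: tp 20, fp 2, fn 8, tn 165
  cs <- confusion_summary(20, 2, 8, 165)
  expect_equal(cs$sensitivity, 100 * 20 / 28, tolerance = 1e-10)
  expect_equal(round(cs$sensitivity, 1), 71.4)
  expect_equal(round(cs$specificity, 1), 98.8)
  expect_equal(round(cs$agreement, 1), 94.9)

  # all-negative test with positives present: sens 0, PPV undefined
  allneg <- confusion_from_labels(c(TRUE, TRUE, FALSE), rep(FALSE, 3))
  expect_equal(allneg$sensitivity, 0)
  expect_true(is.na(allneg$ppv))

  # exhaustive single-subject label combinations vs counting oracle
  for (r in c(TRUE, FALSE)) for (t in c(TRUE, FALSE)) {
    got <- confusion_from_labels(r, t)
    want <- confusion_oracle(r, t)
    expect_equal(c(tp = got$tp, fp = got$fp, fn = got$fn, tn = got$tn), want)
  }
  # and on random label vectors
  set.seed(4)
  for (i in 1:10) {
    r <- runif(50) < 0.3; t <- runif(50) < 0.3
    got <- confusion_from_labels(r, t)
    want <- confusion_oracle(r, t)
    expect_equal(c(tp = got$tp, fp = got$fp, fn = got$fn, tn = got$tn), want)
  }
})

test_that("Cohen's kappa matches the marginal formula and label oracle", {
  expect_equal(cohens_kappa(25, 25, 25, 25)$kappa, 0)
  k <- cohens_kappa(20, 2, 8, 165)
  expect_equal(k$kappa, 0.7711, tolerance = 1e-4)
  expect_identical(k$band, "substantial")
  expect_identical(cohens_kappa(1, 0, 0, 1)$band, "almost perfect")
  # band boundaries go to the lower band: this table has kappa exactly 0.6
  boundary <- cohens_kappa(40, 10, 10, 40)
  expect_equal(boundary$kappa, 0.6)
  expect_identical(boundary$band, "moderate")
  # degenerate marginals
  expect_true(is.na(cohens_kappa(5, 0, 0, 0)$kappa))
  # random tables vs the two-rater oracle computed from raw labels
  set.seed(8)
  for (i in 1:10) {
    r <- runif(60) < 0.4; t <- xor(r, runif(60) < 0.2)
    cs <- confusion_from_labels(r, t)
    expect_equal(cs$kappa, kappa_oracle(r, t), tolerance = 1e-12)
  }
})

test_that("agreement is invariant to relabelling; rates swap", {
  set.seed(12)
  r <- runif(80) < 0.3; t <- xor(r, runif(80) < 0.15)
  a <- confusion_from_labels(r, t)
  b <- confusion_from_labels(!r, !t)   # swapped positive class
  expect_equal(a$agreement, b$agreement)
  expect_equal(a$kappa, b$kappa)
  expect_equal(a$sensitivity, b$specificity)
  expect_equal(a$specificity, b$sensitivity)
  expect_equal(a$ppv, b$npv)
  expect_equal(a$npv, b$ppv)
})

test_that("diagnostic_report classifies both methods through ASMI", {
  co <- generate_cohort(cohort_config(n_male = 20, n_female = 20, seed = 31))
  # predicted == measured: use an equation that is exactly the truth, with
  # the residual removed by overwriting the DXA value
  eq <- equation_final()
  co$alm_dxa_kg <- predict_cohort(eq, co)$predicted
  co <- bia_cohort(co, check_spectrum = FALSE)
  out <- diagnostic_report(co, eq)
  expect_equal(out$summary$agreement, 100)
  if (out$summary$tp > 0 && out$summary$tn > 0)
    expect_equal(out$summary$kappa, 1)
  expect_equal(nrow(out$subjects), 40)

  # subjects far from the cutoffs are never misclassified
  far <- co
  far$alm_dxa_kg <- far$alm_dxa_kg + 8    # push everyone well above cutoff
  far <- bia_cohort(far, check_spectrum = FALSE)
  eq_far <- alm_equation("shifted", eq$terms, eq$intercept + 8)
  expect_equal(diagnostic_report(far, eq_far)$summary$agreement, 100)
})

test_that("default synthetic fixture reaches high diagnostic agreement", {
  out <- diagnostic_report(generate_cohort(cohort_config(seed = 19)),
                           equation_final())
  expect_gte(out$summary$agreement, 85)
})
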