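test_that("SEE and TE follow their residual-RMS definitions", {
  m <- c(10, 12, 14, 16); pr <- c(11, 11, 15, 15)
  expect_equal(compute_see(m, m, p = 1), 0)
  expect_equal(compute_see(m, pr, p = 1), sqrt(2), tolerance = 1e-6)
  expect_equal(compute_te(m, m), 0)
  expect_equal(compute_te(m, pr), 1)
  expect_error(compute_see(m, pr[1:3], p = 1), "length")
  expect_error(compute_see(m, pr, p = 3), "n > p")
})

test_that("TE <= SEE on shared residuals, with the exact identity", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:60, 1); p <- sample(1:4, 1)
    m <- rnorm(n, 17, 3); pr <- m + rnorm(n)
    see <- compute_see(m, pr, p); te <- compute_te(m, pr)
    expect_lt(te, see)
    expect_equal(see^2 * (n - p - 1), te^2 * n, tolerance = 1e-9)
  }
})

test_that("SEE of normal residuals concentrates around their SD", {
  # chi distribution of the residual SD: mean ~0.97, SD ~0.05 at df = 191
  set.seed(33)
  sees <- replicate(30, {
    m <- rnorm(195, 17, 3.6)
    compute_see(m, m + rnorm(195, 0, 0.97), p = 3)
  })
  expect_equal(mean(sees), 0.97, tolerance = 0.03)
  expect_true(all(sees > 0.77 & sees < 1.17))   # ~4 sigma per draw
})

test_that("CV reproduces the published 5.6% from both contexts", {
  expect_equal(round(compute_cv(0.97, 17.28), 1), 5.6)
  expect_equal(round(compute_cv(1.00, 17.77), 1), 5.6)
  expect_equal(compute_cv(0, 17), 0)
  expect_error(compute_cv(1, 0), "positive")
})

test_that("PIA counts sex-specific within-threshold errors, boundary in", {
  expect_equal(compute_pia(c(1, 1, 0, 0), rep(10, 4), rep(10, 4)), 100)
  m <- rep(10, 4); pr <- m + c(1.0, 2.0, 1.0, 1.2)
  expect_equal(compute_pia(c("M", "M", "F", "F"), m, pr), 50)
  expect_equal(compute_pia("M", 10, 10 + 1.45), 100)   # boundary within
  expect_equal(compute_pia("F", 10, 10 + 1.161), 0)
  # monotone in both thresholds
  set.seed(2)
  sex <- rep(c(1, 0), 25)
  m <- rnorm(50, 17, 3); pr <- m + rnorm(50, 0, 1.2)
  base <- compute_pia(sex, m, pr)
  expect_gte(compute_pia(sex, m, pr, threshold_m = 2.0), base)
  expect_gte(compute_pia(sex, m, pr, threshold_f = 1.6), base)
})

test_that("subjective rating maps errors to the sex-specific bands", {
  expect_identical(subjective_rating(0.97, "M"), "excellent")
  expect_identical(subjective_rating(0.97, "F"), "very good")
  expect_identical(subjective_rating(0.80, "M"), "ideal")
  expect_identical(subjective_rating(0.50, "M"), "ideal")   # below ideal band
  expect_identical(subjective_rating(1.30, "M"), "good")
  expect_identical(subjective_rating(1.45, "M"), "below-good")
  expect_identical(subjective_rating(0.90, "M"), "excellent")  # half-open
  expect_identical(subjective_rating(1.16, "F"), "below-good")
})

test_that("Bland-Altman bias, LoA and direction flag behave", {
  m <- c(10, 11, 12, 13); pr <- m - c(1, -1, 1, -1)
  ba <- bland_altman(m, pr)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 1.1547, tolerance = 1e-4)
  expect_equal(ba$loa_low, -2.2632, tolerance = 1e-3)
  expect_equal(ba$loa_high, 2.2632, tolerance = 1e-3)
  # direction flip: bias negates, LoA endpoints swap and negate
  flip <- bland_altman(m, pr, "predicted-minus-measured")
  expect_equal(flip$bias, -ba$bias)
  expect_equal(flip$loa_low, -ba$loa_high)
  expect_equal(flip$loa_high, -ba$loa_low)
  expect_equal(flip$loa_high - flip$loa_low, ba$loa_high - ba$loa_low)
  # identical vectors are degenerate, not an error
  same <- bland_altman(m, m)
  expect_true(same$degenerate)
  expect_equal(c(same$bias, same$loa_low, same$loa_high), c(0, 0, 0))
  expect_true(is.na(same$r_diff_mean))
  expect_error(bland_altman(m[1:2], pr[1:2]), "3")
})

test_that("synthetic holdouts show near-zero bias and proportional error", {
  biases <- numeric(6); rdm <- numeric(6); slopes <- numeric(6)
  for (s in 1:6) {
    parts <- generate_split(cohort_config(seed = 400 + s))
    dev <- parts$development; hold <- parts$cross_validation
    fit <- fit_ols(dev$alm_dxa_kg,
                   predictor_matrix(dev, c("ZI@2MHz", "sex", "Xc@5kHz")))
    eq <- alm_equation("refit", fit$terms, fit$intercept)
    pr <- predict_cohort(eq, hold)$predicted
    ba <- bland_altman(hold$alm_dxa_kg, pr)
    biases[s] <- ba$bias; rdm[s] <- ba$r_diff_mean
    slopes[s] <- line_of_best_fit(hold$alm_dxa_kg, pr)$slope
  }
  # mean-zero independent noise: bias ~0; diff-vs-mean correlation small
  # and positive (residual noise enters the mean axis); slope ~1
  expect_true(all(abs(biases) < 0.45))
  expect_lt(mean(abs(biases)), 0.25)
  expect_lt(mean(abs(rdm)), 0.25)
  expect_true(all(abs(rdm) < 0.5))
  expect_equal(mean(slopes), 1, tolerance = 0.03)
  expect_true(all(slopes > 0.88 & slopes < 1.12))
})

test_that("paired t flags degenerate differences and is calibrated under the null", {
  m <- c(10, 11, 12)
  expect_true(paired_t(m, m)$degenerate)
  expect_true(paired_t(m, m - 1)$degenerate)   # constant nonzero diff
  set.seed(55)
  pvals <- replicate(200, {
    m <- rnorm(64, 17, 3)
    paired_t(m, m + rnorm(64))$p
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("line of best fit recovers exact linear maps", {
  m <- c(10, 12, 14, 16, 18)
  lf <- line_of_best_fit(m, m)
  expect_equal(lf$slope, 1)
  expect_equal(lf$intercept, 0)
  # default calibration direction regresses measured on predicted
  lf2 <- line_of_best_fit(m, 2 * m + 3)
  expect_equal(lf2$slope, 0.5)
  expect_equal(lf2$intercept, -1.5)
  # the reverse regression recovers the generating map
  lf3 <- line_of_best_fit(m, 2 * m + 3, response = "predicted")
  expect_equal(lf3$slope, 2)
  expect_equal(lf3$intercept, 3)
  expect_error(line_of_best_fit(m, rep(10, 5)), "zero variance")
})

test_that("validate_equation assembles a coherent report", {
  co <- generate_cohort(cohort_config(seed = 77))
  rep <- validate_equation(co, equation_final())
  expect_s3_class(rep, "validation_report")
  expect_lte(rep$loa_low, rep$bias)
  expect_lte(rep$bias, rep$loa_high)
  expect_gte(rep$pia, 0); expect_lte(rep$pia, 100)
  expect_lt(rep$te, rep$see)
  expect_gt(rep$r2, 0.9)
  expect_identical(rep$direction, "measured-minus-predicted")
  # development context reports CV from SEE instead of TE
  dev_rep <- validate_equation(co, equation_final(), context = "development")
  expect_equal(dev_rep$cv, compute_cv(dev_rep$see, dev_rep$mean_measured))
  expect_equal(rep$cv, compute_cv(rep$te, rep$mean_measured))
})
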