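test_that("fit_ols recovers exact linear relations", {
  fit <- fit_ols(c(10, 12, 14, 16), data.frame(x = 1:4))
  expect_equal(unname(fit$terms), 2)
  expect_equal(fit$intercept, 8)
  expect_equal(fit$r2, 1)
  expect_equal(fit$see, 0, tolerance = 1e-10)
})

test_that("fit_ols matches the normal-equations oracle on random designs", {
  set.seed(101)
  for (i in 1:10) {
    n <- 30; p <- 3
    X <- matrix(rnorm(n * p), n, dimnames = list(NULL, c("a", "b", "c")))
    y <- 1.5 + X %*% c(0.5, -2, 0.3) + rnorm(n)
    fit <- fit_ols(as.numeric(y), X)
    oracle <- ols_oracle(as.numeric(y), X)
    expect_equal(unname(fit$terms), as.numeric(oracle$coef),
                 tolerance = 1e-8)
    expect_equal(fit$intercept, as.numeric(oracle$intercept),
                 tolerance = 1e-8)
    expect_equal(fit$r2, oracle$r2, tolerance = 1e-8)
    expect_equal(fit$adj_r2, oracle$adj_r2, tolerance = 1e-8)
    expect_equal(fit$see, oracle$see, tolerance = 1e-8)
  }
})

test_that("rank-deficient designs error or are flagged, as requested", {
  X <- cbind(a = rnorm(20), b = rnorm(20))
  X <- cbind(X, c = X[, "a"] + X[, "b"])
  y <- rnorm(20)
  expect_error(fit_ols(y, X), "singular")
  flagged <- fit_ols(y, cbind(const = rep(1, 20)), degenerate = "flag")
  expect_true(flagged$degenerate)
  expect_equal(unname(flagged$terms), 0)
  expect_equal(flagged$intercept, mean(y))
  expect_equal(flagged$r2, 0)
})

test_that("VIF equals 1/(1 - R^2_j) with the expected special cases", {
  # orthogonal columns
  x1 <- c(1, 1, -1, -1); x2 <- c(1, -1, 1, -1)
  expect_equal(unname(compute_vif(cbind(a = x1, b = x2))), c(1, 1))
  # exact pairwise correlation 0.9 -> VIF = 1/(1 - 0.81) = 5.263
  set.seed(7)
  z <- scale(rnorm(50))[, 1]
  e <- scale(resid(lm(rnorm(50) ~ z)))[, 1]
  x2 <- 0.9 * z + sqrt(1 - 0.81) * e
  expect_equal(cor(z, x2), 0.9, tolerance = 1e-12)
  expect_equal(unname(compute_vif(cbind(a = z, b = x2))),
               c(5.263, 5.263), tolerance = 1e-3)
  # exact linear dependence -> infinite
  X <- cbind(a = rnorm(15), b = rnorm(15))
  X <- cbind(X, c = 2 * X[, "a"] - X[, "b"])
  expect_true(all(is.infinite(compute_vif(X))))
})

test_that("VIF agrees with the car package on a random design", {
  skip_if_not_installed("car")
  set.seed(11)
  X <- MASS::mvrnorm(60, rep(0, 3),
                     matrix(c(1, .6, .2, .6, 1, .1, .2, .1, 1), 3))
  colnames(X) <- c("a", "b", "c")
  y <- X %*% c(1, 1, 1) + rnorm(60)
  ours <- compute_vif(X)
  theirs <- car::vif(lm(y ~ a + b + c, data = as.data.frame(X)))
  expect_equal(unname(ours), unname(theirs[names(ours)]), tolerance = 1e-10)
})

test_that("frequency scan finds a planted noiseless signal", {
  n <- 30
  set.seed(5)
  co <- data.frame(id = as.character(1:n), sex = rep(c(1, 0), n / 2),
                   age = runif(n, 70, 90), height_cm = runif(n, 150, 180),
                   weight_kg = runif(n, 50, 80),
                   z_50khz = runif(n, 350, 650),
                   z_2mhz = runif(n, 300, 600))
  co$alm_dxa_kg <- 0.3 * co$height_cm^2 / co$z_50khz + 2
  co <- bia_cohort(co)
  scan <- frequency_scan(co, kinds = "ZI",
                         frequencies = c("50kHz", "2MHz"))
  expect_equal(attr(scan, "best_r2")$frequency, "50kHz")
  expect_equal(attr(scan, "best_r2")$value, 1)
  expect_equal(attr(scan, "best_see")$frequency, "50kHz")
  # identical channels give identical fits
  co$z_1khz <- co$z_5khz <- co$z_50khz
  co <- bia_cohort(co)
  twin <- frequency_scan(co, frequencies = c("1kHz", "5kHz"))
  expect_equal(twin$r2[1], twin$r2[2])
  expect_equal(twin$see[1], twin$see[2])
  # absent channels: warn-and-skip by default, error under strict mode
  expect_warning(frequency_scan(co, frequencies = c("50kHz", "3MHz")),
                 "skipping")
  expect_error(frequency_scan(co, frequencies = c("50kHz", "3MHz"),
                              strict = TRUE), "z_3mhz")
})

test_that("stepwise keeps a perfect predictor and can return empty", {
  set.seed(9)
  x <- rnorm(40)
  y <- 3 * x + 1
  fit <- stepwise_select(y, cbind(x = x, junk = rnorm(40)))
  expect_identical(fit$selected, "x")
  noise_only <- stepwise_select(rnorm(40), cbind(pure = rnorm(40)))
  # a single pure-noise candidate enters only ~5% of the time; this seed
  # leaves the model empty and flagged
  expect_true(noise_only$empty_model)
  expect_length(noise_only$selected, 0)
})

test_that("stepwise excludes a pure-noise column at close to the nominal level", {
  rejected <- 0L
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    set.seed(1000 + s)
    n <- 200
    signal <- rnorm(n)
    noise <- rnorm(n)
    y <- 2 * signal + rnorm(n)
    fit <- stepwise_select(y, cbind(signal = signal, noise = noise))
    expect_true("signal" %in% fit$selected)
    if (!"noise" %in% fit$selected) rejected <- rejected + 1L
  }
  expect_gte(rejected, 0.90 * n_seeds)
})

test_that("stepwise reaches a fixpoint on the synthetic default cohort", {
  co <- generate_cohort(cohort_config(seed = 23))
  cands <- c(paste0("ZI@", names(bia_frequencies())),
             "Xc@5kHz", "Xc@50kHz", "sex", "weight")
  X <- predictor_matrix(co, cands)
  fit <- stepwise_select(co$alm_dxa_kg, X)
  expect_setequal(fit$selected, c("ZI@2MHz", "sex", "Xc@5kHz"))
  # fixpoint: every included term significant below alpha_remove ...
  expect_true(all(fit$p_values < 0.10))
  # ... and no excluded candidate would enter at alpha_enter
  for (nm in setdiff(cands, fit$selected)) {
    aug <- fit_ols(co$alm_dxa_kg, X[, c(fit$selected, nm)])
    expect_gte(aug$p_values[[nm]], 0.05)
  }
})

test_that("alpha thresholds are validated", {
  expect_error(stepwise_select(rnorm(10), cbind(x = rnorm(10)),
                               alpha_enter = 0.2, alpha_remove = 0.1),
               "alpha_enter")
})
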