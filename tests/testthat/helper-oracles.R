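## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths.

## closed-form normal-equations OLS: solve(X'X) X'y with explicit inversion
ols_oracle <- function(y, X) {
  D <- cbind(1, as.matrix(X))
  beta <- solve(t(D) %*% D) %*% t(D) %*% y
  res <- y - D %*% beta
  n <- length(y); p <- ncol(D) - 1
  rss <- sum(res^2); tss <- sum((y - mean(y))^2)
  list(intercept = beta[1], coef = beta[-1],
       r2 = 1 - rss / tss,
       adj_r2 = 1 - (rss / (n - p - 1)) / (tss / (n - 1)),
       see = sqrt(rss / (n - p - 1)))
}

## two-rater kappa straight from raw label vectors
kappa_oracle <- function(ref, test) {
  n <- length(ref)
  po <- mean(ref == test)
  pe <- mean(ref) * mean(test) + mean(!ref) * mean(!test)
  (po - pe) / (1 - pe)
}

## exhaustive 2x2 counting from labels
confusion_oracle <- function(ref, test) {
  c(tp = sum(ref & test), fp = sum(!ref & test),
    fn = sum(ref & !test), tn = sum(!ref & !test))
}

## small deterministic cohort built by hand (no generator involved)
toy_cohort <- function() {
  bia_cohort(data.frame(
    id = c("a", "b", "c", "d"),
    sex = c("M", "M", "F", "F"),
    age = c(75, 80, 72, 78),
    height_cm = c(166, 170, 153, 150),
    weight_kg = c(65, 70, 55, 52),
    alm_dxa_kg = c(20.5, 22.1, 14.2, 13.5),
    z_2mhz = c(410, 430, 490, 480),
    xc_5khz = c(13.5, 14.0, 12.4, 12.0)))
}
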