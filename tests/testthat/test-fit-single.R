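test_that("the unpenalized fit recovers known weights and slope", {
  d <- single_signal_dataset(n = 500, cc = 3, beta1 = 1, w = c(0.7, 0.3),
                             sd = 0.5, seed = 31)
  fit <- fit_single_wqs(d, "positive", lambda = 0)
  expect_true(fit$converged)
  expect_equal(fit$beta1, 1, tolerance = 0.12)
  expect_equal(unname(fit$w), c(0.7, 0.3, 0), tolerance = 0.1)
  expect_equal(sum(fit$w), 1, tolerance = 1e-8)
})

test_that("the optimizer matches the simplex grid-search oracle", {
  for (seed in c(101, 102)) {
    d <- single_signal_dataset(n = 100, cc = 3, beta1 = 0.8, w = c(0.6, 0.4),
                               sd = 0.6, seed = seed)
    oracle <- grid_search_oracle(d, resolution = 0.02)
    fit <- fit_single_wqs(d, "positive", lambda = 0)
    expect_true(fit$objective_value <= oracle$obj + 1e-3)
  }
})

test_that("null data pins the constrained slope near zero", {
  set.seed(55)
  for (seed in c(1, 2)) {
    X <- matrix(rnorm(1000 * 3), 1000, 3)
    d <- mixture_data(rnorm(1000), X, q = 4)
    fit <- fit_single_wqs(d, "positive", lambda = 0)
    expect_gte(fit$beta1, 0)
    expect_lt(fit$beta1, 0.1)
  }
})

test_that("growing lambda never spreads the weights", {
  d <- single_signal_dataset(n = 300, cc = 5, beta1 = 1, w = c(0.7, 0.3),
                             sd = 0.5, seed = 77)
  spread <- sapply(c(0, 10, 100, 1000), function(lam) {
    sum(sqrt(fit_single_wqs(d, "positive", lambda = lam)$w))
  })
  expect_true(all(diff(spread) <= 1e-6))
})

test_that("direction bounds hold exactly", {
  d <- small_dataset(n = 200, seed = 8)
  expect_gte(fit_single_wqs(d, "positive", 5)$beta1, 0)
  expect_lte(fit_single_wqs(d, "negative", 5)$beta1, 0)
  expect_error(fit_single_wqs(d, "positive", -2), "nonnegative")
  expect_error(fit_single_wqs(d, "positive", 0, v_init = rep(0, 5)), "v = 0")
})

test_that("validation fit equals the closed-form GLM", {
  d <- small_dataset(n = 300, seed = 12)
  w_bar <- c(0.4, 0.3, 0.2, 0.1, 0)
  val <- validate_single(w_bar, d)
  idx <- drop(d$Q %*% w_bar)
  ols <- lm(d$y ~ idx)
  expect_equal(val$beta1, unname(coef(ols)[2]), tolerance = 1e-10)
  expect_equal(model_aic(val), AIC(ols), tolerance = 1e-8)
  ## one-hot index collapses to a single component
  w1 <- c(0, 1, 0, 0, 0)
  val1 <- validate_single(w1, d)
  g1 <- glm(d$y ~ d$Q[, 2])
  expect_equal(val1$beta1, unname(coef(g1)[2]), tolerance = 1e-10)
  expect_error(validate_single(c(0.9, 0.2, 0, 0, 0), d), "simplex")
})

test_that("logit validation recovers a known log-odds slope", {
  set.seed(91)
  n <- 5000
  X <- matrix(rnorm(n * 4), n, 4)
  Q <- quantize_columns(X, 4)
  w_true <- c(0.5, 0.5, 0, 0)
  eta <- -1 + 0.5 * drop(Q %*% w_true)
  y <- rbinom(n, 1, plogis(eta))
  d <- mixture_data(y, Q, q = 4, link = "logit", already_quantized = TRUE)
  val <- validate_single(w_true, d)
  expect_lt(abs(val$beta1 - 0.5) / val$se["WQS"], 3)
  gl <- glm(y ~ drop(Q %*% w_true), family = binomial())
  expect_equal(val$beta1, unname(coef(gl)[2]), tolerance = 1e-6)
  expect_equal(val$aic, AIC(gl), tolerance = 1e-6)
})

test_that("AIC accounting matches the closed form and penalizes noise terms", {
  set.seed(14)
  n <- 60
  d0 <- small_dataset(n = n, seed = 15)
  w_bar <- rep(0.2, 5)
  val <- validate_single(w_bar, d0)
  idx <- drop(d0$Q %*% w_bar)
  rss <- sum(resid(lm(d0$y ~ idx))^2)
  ## Gaussian closed form with sigma2 = RSS/n and k = 2 coefs + 1 variance
  expect_equal(val$aic, n * (log(2 * pi * rss / n) + 1) + 2 * 3,
               tolerance = 1e-8)
  ## adding a pure-noise covariate changes AIC by 2 - (drop in deviance)
  Z <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "noise"))
  dZ <- mixture_data(d0$y, d0$Q, Z, q = 4, already_quantized = TRUE)
  valZ <- validate_single(w_bar, dZ)
  dev_drop <- n * log(rss / sum(resid(lm(d0$y ~ idx + Z))^2))
  expect_equal(valZ$aic - val$aic, 2 - dev_drop, tolerance = 1e-8)
})

test_that("singular validation designs are rejected naming the columns", {
  d <- small_dataset(n = 100, seed = 16)
  Z <- cbind(dup1 = d$Q[, 1] * 0.5, dup2 = d$Q[, 1])
  dd <- mixture_data(d$y, d$Q, Z, q = 4, already_quantized = TRUE)
  expect_error(validate_single(c(1, 0, 0, 0, 0), dd), "dup")
})
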