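test_that("repeated holdout is deterministic given the master seed", {
  d <- small_dataset(n = 300, seed = 31)
  cfg <- list(estimator = "two_index", lambda = 2, H = 3L, B = 4L, seed = 7)
  r1 <- run_repeated_holdout(d, cfg)
  r2 <- run_repeated_holdout(d, cfg)
  expect_identical(r1$per_split, r2$per_split)
  expect_identical(r1$wp, r2$wp)
  expect_identical(r1$wn, r2$wn)
})

test_that("H = 1 reproduces a single split run and collapses the interval", {
  d <- small_dataset(n = 300, seed = 32)
  cfg <- list(estimator = "single_pos", lambda = 0, H = 1L, B = 4L, seed = 9)
  dist <- run_repeated_holdout(d, cfg)
  expect_equal(nrow(dist$per_split), 1)
  s <- summarize_holdout(dist)
  b <- s$coef[s$coef$term == "beta1p", ]
  expect_equal(b$median, b$lower)
  expect_equal(b$median, b$upper)
  expect_equal(b$median, dist$per_split$beta1p[1])
})

test_that("summaries use median and interpolated percentiles, permutation-invariantly", {
  skeleton <- list(
    per_split = data.frame(beta1p = as.numeric(1:100), beta1n = NA_real_,
                           aic = 0, vif_p = NA, vif_n = NA, k_used = NA,
                           fallback = "none", failed = FALSE),
    wp = matrix(rep(c(0.6, 0.4), each = 100), 100, 2,
                dimnames = list(NULL, c("a", "b"))),
    wn = matrix(NA_real_, 100, 2, dimnames = list(NULL, c("a", "b"))),
    component_names = c("a", "b"),
    config = wqs2i:::default_holdout_config())
  class(skeleton) <- "wqs_holdout"
  s <- summarize_holdout(skeleton)
  b <- s$coef[s$coef$term == "beta1p", ]
  expect_equal(b$median, 50.5)
  expect_equal(b$lower, 3.475)
  expect_equal(b$upper, 97.525)
  expect_true(b$significant)
  ## permuting the splits changes nothing
  perm <- sample(100)
  skeleton2 <- skeleton
  skeleton2$per_split <- skeleton$per_split[perm, ]
  skeleton2$wp <- skeleton$wp[perm, ]
  s2 <- summarize_holdout(skeleton2)
  expect_equal(s2$coef, s$coef)
  expect_equal(s2$weights, s$weights)
  ## weight table: a exceeds 1/2, b does not (strict threshold)
  expect_equal(s$weights$selected[s$weights$direction == "positive"],
               c(TRUE, FALSE))
  expect_equal(s$retained[["negative"]], 0)
})

test_that("logit splits are stratified by outcome", {
  set.seed(34)
  X <- matrix(rnorm(200 * 3), 200, 3)
  y <- rep(c(0, 1), c(160, 40))
  d <- mixture_data(y, X, q = 4, link = "logit")
  set.seed(1)
  idx <- wqs2i:::split_indices(d, 0.6)
  expect_equal(sum(d$y[idx] == 1), 24)
  expect_equal(length(idx), 120)
})

test_that("the spread of holdout estimates shrinks with sample size", {
  truth <- small_truth()
  iqr_for_n <- function(n, seed) {
    d <- simulate_dataset(small_corr(), truth, n, seed = seed)
    cfg <- list(estimator = "single_pos", lambda = 0, H = 10L, B = 5L,
                seed = 100 + seed)
    dist <- run_repeated_holdout(d, cfg)
    IQR(dist$per_split$beta1p, na.rm = TRUE)
  }
  ## median over 3 paired draws to damp Monte-Carlo noise
  small_iqr <- sapply(1:3, function(s) iqr_for_n(300, s))
  big_iqr <- sapply(1:3, function(s) iqr_for_n(2400, s))
  expect_lt(median(big_iqr), median(small_iqr))
})

test_that("method-2 style runs share the single-direction weight estimates", {
  d <- small_dataset(n = 400, seed = 36)
  cfg1 <- list(estimator = "single_pos", lambda = 0, H = 3L, B = 5L, seed = 11)
  cfg2 <- list(estimator = "two_index_seq", lambda = 0, H = 3L, B = 5L, seed = 11)
  r1 <- run_repeated_holdout(d, cfg1)
  r2 <- run_repeated_holdout(d, cfg2)
  expect_equal(r1$wp, r2$wp, tolerance = 1e-12)
  ## but the validation models differ (joint vs single)
  expect_false(isTRUE(all.equal(r1$per_split$beta1p, r2$per_split$beta1p)))
})
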