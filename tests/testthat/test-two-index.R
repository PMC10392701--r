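test_that("starting values come from the directional fits, with 1/c fallback", {
  d <- small_dataset(n = 500, seed = 41)
  init <- initialize_two_index(d)
  expect_true(init$diagnostics$positive$converged)
  expect_true(init$diagnostics$negative$converged)
  ## the starter concentrates positive mass on the true positive support
  wp0 <- weights_from_v(init$vp_init)
  expect_gt(sum(wp0[1:2]), 2 / 5)
  ## a failed starter falls back to the uniform 1/c vector
  local_mocked_bindings(
    fit_single_wqs = function(data, direction, ...) {
      list(converged = FALSE, v = rep(9, ncol(data$Q)), beta1 = 0.3)
    }, .package = "wqs2i")
  expect_warning(init2 <- initialize_two_index(d), "failed to converge")
  expect_equal(init2$vp_init, rep(1 / 5, 5))
  expect_equal(init2$vn_init, rep(1 / 5, 5))
  expect_equal(init2$beta1p_init, 0)
})

test_that("index tolerance matches the auxiliary-regression R^2", {
  set.seed(51)
  n <- 200
  ## orthogonal by construction
  ip <- rep(c(1, -1), n / 2)
  im <- rep(c(1, 1, -1, -1), n / 4)
  tl <- index_tolerance(ip, im)
  expect_equal(tl$tol_p, 1, tolerance = 1e-12)
  expect_equal(tl$vif_n, 1, tolerance = 1e-12)
  ## perfect collinearity
  expect_lt(index_tolerance(ip, 2 * ip)$tol_p, 1e-10)
  ## designed R^2 = 0.75: signal plus orthogonalized noise at a 3:1
  ## variance split
  x <- rnorm(n)
  e <- resid(lm(rnorm(n) ~ x))
  y <- sqrt(0.75) * x / sd(x) + sqrt(0.25) * e / sd(e)
  tl2 <- index_tolerance(y, x)
  r2 <- summary(lm(y ~ x))$r.squared
  expect_equal(tl2$tol_p, 1 - r2, tolerance = 1e-10)
  expect_equal(tl2$tol_p, 0.25, tolerance = 0.02)
  expect_equal(tl2$vif_p, 1 / tl2$tol_p, tolerance = 1e-12)
  ## covariates enter the auxiliary regression
  Z <- matrix(rnorm(n), n, 1)
  r2z <- summary(lm(y ~ x + Z))$r.squared
  expect_equal(index_tolerance(y, x, Z)$tol_p, 1 - r2z, tolerance = 1e-10)
  expect_error(index_tolerance(rep(1, n), x), "degenerate index")
  expect_error(index_tolerance(1:5, 1:4), "equal length")
})

test_that("bootstrap ensembles are reproducible and respect sign bounds", {
  d <- small_dataset(n = 400, seed = 61)
  init <- initialize_two_index(d)
  b1 <- fit_two_index_bootstrap(d, B = 6, lambda = 2, init$vp_init,
                                init$vn_init, seed = 99)
  b2 <- fit_two_index_bootstrap(d, B = 6, lambda = 2, init$vp_init,
                                init$vn_init, seed = 99)
  expect_identical(b1, b2)
  expect_true(all(b1$beta1p >= 0))
  expect_true(all(b1$beta1n <= 0))
  expect_true(all(abs(rowSums(b1$wp) - 1) < 1e-8))
  expect_true(all(abs(rowSums(b1$wn) - 1) < 1e-8))
  expect_true(all(b1$tol_p >= 0 & b1$tol_p <= 1))
})

test_that("positive-only data leaves the negative direction uninformative", {
  truth <- truth_spec(0.8, 0, wp = c(a = 0.6, b = 0.4, c = 0, d = 0, e = 0),
                      wn = c(a = 0, b = 0, c = 0.7, d = 0.3, e = 0))
  d <- simulate_dataset(small_corr(), truth, 500, seed = 71)
  init <- initialize_two_index(d)
  boot <- fit_two_index_bootstrap(d, B = 10, lambda = 5, init$vp_init,
                                  init$vn_init, seed = 72)
  expect_gt(mean(boot$informative_p), 0.8)
  ## negative direction is either dropped or carries a near-zero slope
  ## (small relative to the true positive signal of 0.8)
  expect_true(mean(boot$informative_n) < 0.5 ||
                median(abs(boot$beta1n)) < 0.1)
})

test_that("k escalation sharpens the tolerance averaging deterministically", {
  boot <- list(
    wp = rbind(c(0.9, 0.1, 0), c(0.1, 0.9, 0)),
    wn = rbind(c(0, 0, 1), c(0, 0.5, 0.5)),
    beta1p = c(0.5, 0.4), beta1n = c(-0.3, -0.2),
    tol_p = c(0.8, 0.2), tol_n = c(0.5, 0.5),
    converged = c(TRUE, TRUE),
    informative_p = c(TRUE, TRUE), informative_n = c(TRUE, TRUE))
  w3 <- wqs2i:::average_direction(boot, "positive", k = 3)
  expect_equal(unname(round(w3, 5)), c(0.88769, 0.11231, 0))
  ## equal tolerances: plain mean at any k
  expect_equal(unname(wqs2i:::average_direction(boot, "negative", k = 4)),
               c(0, 0.25, 0.75))
  ## larger k pulls the average toward the high-tolerance bootstrap
  w1 <- wqs2i:::average_direction(boot, "positive", k = 1)
  expect_gt(w3[1], w1[1])
})

test_that("finalize fits the joint bounded GLM with VIF diagnostics", {
  d <- small_dataset(n = 600, seed = 81)
  wp_bar <- c(0.5, 0.5, 0, 0, 0)
  wn_bar <- c(0, 0, 0.6, 0.4, 0)
  res <- finalize_two_index(wp_bar, wn_bar, d, k = 3)
  expect_s3_class(res, "two_index_result")
  expect_gte(res$beta1p, 0)
  expect_lte(res$beta1n, 0)
  expect_equal(res$fallback, "none")
  expect_gte(res$vif_p, 1)
  ip <- drop(d$Q %*% wp_bar); im <- drop(d$Q %*% wn_bar)
  tl <- index_tolerance(ip, im)
  expect_equal(res$vif_p, tl$vif_p, tolerance = 1e-10)
  ## unconstrained-interior solution equals plain glm
  gl <- glm(d$y ~ ip + im)
  if (coef(gl)[2] >= 0 && coef(gl)[3] <= 0) {
    expect_equal(res$beta1p, unname(coef(gl)[2]), tolerance = 1e-8)
    expect_equal(res$final_fit$aic, AIC(gl), tolerance = 1e-8)
  }
  expect_error(finalize_two_index(NULL, NULL, d), "either direction")
})

test_that("a missing direction falls back to the single-index model with a warning", {
  d <- small_dataset(n = 400, seed = 82)
  wp_bar <- c(0.5, 0.5, 0, 0, 0)
  expect_warning(res <- finalize_two_index(wp_bar, NULL, d, k = 3),
                 "one of the two directions")
  expect_equal(res$fallback, "positive_only")
  expect_true(is.na(res$beta1n))
  val <- validate_single(wp_bar, d)
  expect_equal(res$beta1p, val$beta1, tolerance = 1e-12)
  expect_equal(res$final_fit$aic, val$aic, tolerance = 1e-12)
})

test_that("orthogonal index weights give unit VIFs and no escalation", {
  set.seed(83)
  ## exposures built independent, disjoint supports keep indices nearly
  ## orthogonal; VIF close to 1 and below any escalation threshold
  X <- matrix(rnorm(500 * 4), 500, 4)
  d <- mixture_data(rnorm(500), X, q = 4)
  res <- finalize_two_index(c(1, 0, 0, 0), c(0, 0, 1, 0), d, k = 2)
  expect_lt(res$vif_p, 1.2)
  expect_false(res$escalate)
})
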