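test_that("correlation builders produce valid matrices", {
  R1 <- build_correlation(list(type = "exchangeable", rho = 0.4, c = 3))
  expect_equal(R1, matrix(c(1, .4, .4, .4, 1, .4, .4, .4, 1), 3))
  expect_equal(build_correlation(list(type = "exchangeable", rho = 0.4, c = 3),
                                 halve = TRUE),
               build_correlation(list(type = "exchangeable", rho = 0.2, c = 3)))
  expect_equal(build_correlation(diag(4), halve = TRUE), diag(4))
  Rb <- build_correlation(list(type = "block", sizes = c(2, 2),
                               rhos = c(0.8, 0.5), between = 0.1))
  expect_equal(Rb[1, 2], 0.8)
  expect_equal(Rb[3, 4], 0.5)
  expect_equal(Rb[1, 3], 0.1)
  expect_equal(diag(Rb), rep(1, 4))
  bad <- diag(3); bad[1, 2] <- 0.5
  expect_error(build_correlation(bad), "symmetric")
  bad2 <- matrix(0.5, 2, 2)
  expect_error(build_correlation(bad2), "unit diagonal")
  ## a CSV-supplied matrix round-trips
  f <- tempfile(fileext = ".csv")
  write.table(R1, f, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_equal(build_correlation(f), R1, ignore_attr = TRUE)
})

test_that("non-PSD matrices are repaired with a warning", {
  R <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_warning(Rp <- build_correlation(R), "PSD")
  ev <- eigen(Rp, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > -1e-12)
  expect_equal(diag(Rp), rep(1, 3))
  expect_true(isSymmetric(Rp))
})

test_that("the generator is reproducible and follows the generating model", {
  truth <- small_truth()
  corr <- small_corr()
  d1 <- simulate_dataset(corr, truth, 300, seed = 5)
  d2 <- simulate_dataset(corr, truth, 300, seed = 5)
  expect_identical(d1$y, d2$y)
  expect_identical(d1$Q, d2$Q)
  expect_error(simulate_dataset(corr, truth, 30, seed = 1), "10 \\* c")

  ## null truth: pure intercept noise
  null_truth <- truth_spec(0, 0, truth$wp, truth$wn, beta0 = 2,
                           residual_sd = 1)
  dn <- simulate_dataset(corr, null_truth, 4000, seed = 6)
  expect_lt(abs(mean(dn$y) - 2), 3 / sqrt(4000))

  ## one-hot positive weight: outcome co-varies with that score
  hot <- truth_spec(0.5, 0, c(a = 1, b = 0, c = 0, d = 0, e = 0), truth$wn)
  dh <- simulate_dataset(corr, hot, 3000, seed = 7)
  expect_gt(cov(dh$y, dh$Q[, "a"]), 0)
})

test_that("OLS on independent exposures recovers the generating slopes", {
  ## with an identity correlation the per-component regression slopes are
  ## beta1d * w_di; check every slope against its 3-SE band
  truth <- default_truth()
  d <- simulate_dataset(diag(38), truth, 5000, seed = 8)
  fit <- summary(lm(d$y ~ d$Q))
  est <- coef(fit)[-1, ]
  expected <- truth$beta1p * truth$wp + truth$beta1n * truth$wn
  expect_true(all(abs(est[, "Estimate"] - expected) <
                    3 * est[, "Std. Error"] + 1e-8))
})

test_that("selection metrics agree with brute-force set comparison", {
  set.seed(9)
  for (i in 1:20) {
    cc <- sample(4:10, 1)
    w_true <- rep(0, cc)
    w_true[sample(cc, 2)] <- c(0.6, 0.4)
    sel <- sample(cc, sample(0:cc, 1))
    m <- wqs2i:::selection_metrics(sel, w_true)
    truth_set <- which(w_true > 0)
    expect_equal(m[["sensitivity"]],
                 length(intersect(sel, truth_set)) / length(truth_set))
    expect_equal(m[["specificity"]],
                 length(setdiff(which(w_true == 0), sel)) / (cc - 2))
  }
})

test_that("a small benchmark runs all methods with exact psi decomposition", {
  bm <- run_benchmark(small_corr(), small_truth(), n = 350, R = 2,
                      methods = c("m1", "m2", "m3", "m4", "m4_1d"),
                      fit_config = list(H = 2L, B = 3L),
                      lambda_policy = list(type = "fixed", value = 2,
                                           value_1d = 2),
                      seed = 31)
  expect_s3_class(bm, "wqs_benchmark")
  expect_equal(sort(unique(bm$metrics$method)),
               c("m1", "m2", "m3", "m4", "m4_1d"))
  ## m4_1d reports the positive direction only
  expect_equal(sum(bm$metrics$method == "m4_1d"), 1)
  expect_true(all(is.finite(bm$metrics$median_error)))
  ## m3 psi decomposition on every replicate
  for (r in 1:2) {
    d <- simulate_dataset(small_corr(), small_truth(), 350,
                          seed = bm$seeds$data[r])
    qg <- fit_qgcomp(d)
    expect_equal(qg$psi, qg$psi_pos + qg$psi_neg, tolerance = 1e-10)
    expect_equal(bm$replicates[[r]]$m3$beta1p, qg$psi_pos)
  }
  expect_error(run_benchmark(small_corr(), small_truth(), n = 350, R = 1),
               "R must be")
  expect_error(run_benchmark(small_corr(), small_truth(), n = 350, R = 2,
                             methods = "m9"), "unknown method")
})

test_that("the benchmark grid policy picks one shared lambda by mean AIC", {
  bm <- run_benchmark(small_corr(), small_truth(), n = 350, R = 2,
                      methods = "m4",
                      fit_config = list(H = 2L, B = 3L),
                      lambda_policy = list(type = "grid",
                                           candidates = c(0, 5),
                                           selection_H = 2L,
                                           selection_B = 3L),
                      seed = 33)
  expect_true(bm$lambda %in% c(0, 5))
  expect_equal(nrow(bm$lambda_trace), 2)
  expect_true(all(is.finite(bm$lambda_trace$mean_aic)))
  expect_equal(bm$replicates[[1]]$m4$lambda, bm$lambda)
})
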