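## Small simulated fixtures shared across test files. Everything is built
## in code under fixed seeds; nothing is read from disk.

## a compact truth with 5 components: 2 positive, 2 negative, 1 null
small_truth <- function(beta1p = 0.7, beta1n = -0.7) {
  truth_spec(beta1p, beta1n,
             wp = c(a = 0.6, b = 0.4, c = 0, d = 0, e = 0),
             wn = c(a = 0, b = 0, c = 0.7, d = 0.3, e = 0))
}

small_corr <- function(rho = 0.3, c = 5) {
  build_correlation(list(type = "exchangeable", rho = rho, c = c))
}

small_dataset <- function(n = 400, seed = 1, truth = small_truth(),
                          rho = 0.3) {
  simulate_dataset(small_corr(rho, length(truth$wp)), truth, n, seed = seed)
}

## single-signal data for the single-index estimator: y depends on a
## weighted sum of the first two of `cc` quantized exposures
single_signal_dataset <- function(n = 500, cc = 3, beta1 = 1,
                                  w = c(0.7, 0.3), sd = 0.5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * cc), n, cc,
              dimnames = list(NULL, paste0("x", seq_len(cc))))
  Q <- quantize_columns(X, 4)
  wfull <- c(w, rep(0, cc - length(w)))
  y <- beta1 * drop(Q %*% wfull) + rnorm(n, 0, sd)
  mixture_data(y, X, q = 4)
}

## exhaustive search over the weight simplex at a fixed resolution with
## beta0/beta1 profiled out by OLS at each grid point: the independent
## oracle for the lambda = 0 single-index fit (c <= 3)
grid_search_oracle <- function(data, resolution = 0.02,
                               direction = "positive") {
  cc <- ncol(data$Q)
  stopifnot(cc == 3, data$link == "identity")
  steps <- round(1 / resolution)
  best <- list(obj = Inf, w = NULL)
  for (i in 0:steps) {
    for (j in 0:(steps - i)) {
      w <- c(i, j, steps - i - j) / steps
      idx <- drop(data$Q %*% w)
      if (stats::sd(idx) < 1e-12) next
      fit <- stats::lm.fit(cbind(1, idx), data$y)
      b1 <- fit$coefficients[2]
      if (direction == "positive" && b1 < 0) {
        ## profile under the sign constraint: slope pinned at 0
        fit <- stats::lm.fit(cbind(rep(1, length(data$y))), data$y)
      }
      obj <- sum(fit$residuals^2)
      if (obj < best$obj) best <- list(obj = obj, w = w)
    }
  }
  best
}
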