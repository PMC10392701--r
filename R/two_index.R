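## Joint estimation of a positive and a negative WQS index with penalized
## weights, tolerance-weighted ensemble averaging and collinearity control.

#' Penalized two-index WQS objective
#'
#' Joint criterion for the two-index model
#' `g(mu) = beta0 + beta1p * (Q wp) + beta1n * (Q wn) + Z phi` with
#' `beta1p >= 0`, `beta1n <= 0`, both weight vectors parameterized as
#' `w = v^2/sum(v^2)`, and an L1 shrinkage penalty
#' `lambda * (sum(|vp_i|) + sum(|vn_i|))` evaluated on the unit-normalized
#' raw parameters of each index.
#'
#' @param theta List with `beta0`, `beta1p`, `beta1n`, `vp`, `vn`, and
#'   optionally `phi`.
#' @param data A [mixture_data()] object.
#' @param lambda Shrinkage parameter `>= 0`.
#' @return Objective value (scalar).
#' @export
penalized_objective_2i <- function(theta, data, lambda) {
  if (lambda < 0) stop("lambda must be nonnegative")
  if (sum(theta$vp^2) == 0 || sum(theta$vn^2) == 0) {
    stop("weights undefined at v = 0")
  }
  phi <- if (is.null(theta$phi)) rep(0, ncol(data$Z)) else theta$phi
  th <- c(theta$beta0, theta$beta1p, theta$beta1n, theta$vp, theta$vn, phi)
  Qd <- data$Q; storage.mode(Qd) <- "double"
  ## exact penalty (eps = 0): the reported objective is not smoothed
  wqs_objective_cpp(th, data$y, Qd, data$Z, lambda,
                    TRUE, data$link == "logit", 0)
}

#' Starting values for the two-index fit
#'
#' Fits two standard (unpenalized) single-index WQS models on the full
#' sample, one per direction, without splitting or bootstrapping, each with
#' raw weight parameters initialized at 1. The fitted `v` vectors seed the
#' joint two-index optimization. A direction whose starter fit does not
#' converge falls back to the uniform initialization `v = 1/c`.
#'
#' @param data A [mixture_data()] object.
#' @return List with `vp_init`, `vn_init`, `beta1p_init`, `beta1n_init`,
#'   and `diagnostics` (per-direction convergence and coefficients).
#' @export
initialize_two_index <- function(data) {
  cc <- ncol(data$Q)
  fp <- fit_single_wqs(data, "positive", lambda = 0, v_init = "ones")
  fn <- fit_single_wqs(data, "negative", lambda = 0, v_init = "ones")
  vp_init <- if (fp$converged) fp$v else rep(1 / cc, cc)
  vn_init <- if (fn$converged) fn$v else rep(1 / cc, cc)
  if (!fp$converged && !fn$converged) {
    warning("both directional starter fits failed to converge; using uniform starting weights")
  }
  list(vp_init = vp_init, vn_init = vn_init,
       beta1p_init = if (fp$converged) fp$beta1 else 0,
       beta1n_init = if (fn$converged) fn$beta1 else 0,
       diagnostics = list(
         positive = list(converged = fp$converged, beta1 = fp$beta1),
         negative = list(converged = fn$converged, beta1 = fn$beta1)))
}

#' Collinearity tolerance of the two WQS indices
#'
#' Tolerance of each index is `1 - R^2` from the auxiliary linear
#' regression of that index on the other index plus covariates and an
#' intercept; `VIF = 1/tolerance`. Used both as the per-bootstrap signal in
#' the ensemble average and as the final-model collinearity diagnostic.
#'
#' @param index_p,index_n Numeric vectors of the two per-subject index
#'   values.
#' @param Z Covariate matrix (may have zero columns).
#' @return List with `tol_p`, `tol_n`, `vif_p`, `vif_n`.
#' @export
index_tolerance <- function(index_p, index_n, Z = NULL) {
  n <- length(index_p)
  if (length(index_n) != n) stop("index vectors must have equal length")
  if (n < 3) stop("at least 3 observations required")
  if (is.null(Z)) Z <- empty_Z(n)
  if (stats::sd(index_p) < 1e-12 || stats::sd(index_n) < 1e-12) {
    stop("degenerate index: constant over the sample")
  }
  aux_r2 <- function(target, other) {
    X <- cbind(1, other, Z)
    fit <- stats::lm.fit(X, target)
    rss <- sum(fit$residuals^2)
    tss <- sum((target - mean(target))^2)
    max(0, min(1, 1 - rss / tss))
  }
  tol_p <- 1 - aux_r2(index_p, index_n)
  tol_n <- 1 - aux_r2(index_n, index_p)
  list(tol_p = tol_p, tol_n = tol_n, vif_p = 1 / tol_p, vif_n = 1 / tol_n)
}

## joint fit on one sample (internal)
fit_two_index_once <- function(data, lambda, vp_init, vn_init,
                               beta1p_init = 0.1, beta1n_init = -0.1) {
  cc <- ncol(data$Q); p <- ncol(data$Z)
  res <- fit_wqs_optim(data$y, data$Q, data$Z, data$link, lambda,
                       two_index = TRUE,
                       beta_init = c(max(beta1p_init, 0.01),
                                     min(beta1n_init, -0.01)),
                       v_init_p = vp_init, v_init_n = vn_init)
  if (!res$converged) {
    res2 <- fit_wqs_optim(data$y, data$Q, data$Z, data$link, lambda,
                          two_index = TRUE, beta_init = c(0.1, -0.1),
                          v_init_p = rep(1 / cc, cc), v_init_n = rep(1 / cc, cc))
    if (res2$converged || res2$value < res$value) res <- res2
  }
  pars <- unpack_theta(res$theta, cc, p, TRUE)
  wp <- weights_from_v(pars$vp); wn <- weights_from_v(pars$vn)
  list(beta0 = pars$beta0, beta1p = pars$beta1p, beta1n = pars$beta1n,
       phi = pars$phi, wp = wp, wn = wn, vp = pars$vp, vn = pars$vn,
       objective_value = res$value, converged = res$converged)
}

#' Bootstrap ensemble for the two-index model
#'
#' Draws `B` bootstrap resamples of the training sample and jointly fits
#' the penalized two-index model on each, recording the per-bootstrap
#' weight vectors, index coefficients and collinearity tolerances (computed
#' on the bootstrap sample from that bootstrap's fitted indices).
#'
#' @param train_data Training-split [mixture_data()].
#' @param B Number of bootstrap resamples.
#' @param lambda Shrinkage parameter.
#' @param vp_init,vn_init Starting raw weight parameters (from
#'   [initialize_two_index()]).
#' @param seed Integer seed for the resampling.
#' @param beta1p_init,beta1n_init Starting index coefficients.
#' @param warm_start Fit the penalized model once on the full training
#'   sample and start every bootstrap fit from that solution (same local
#'   optimization, far fewer iterations per resample).
#' @return List with matrices `wp`, `wn` (B x c), vectors `beta1p`,
#'   `beta1n`, `tol_p`, `tol_n`, `converged`, and logical vectors
#'   `informative_p`, `informative_n` (converged and `|beta1| > 1e-8`).
#' @export
fit_two_index_bootstrap <- function(train_data, B, lambda, vp_init, vn_init,
                                    seed = NULL,
                                    beta1p_init = 0.1, beta1n_init = -0.1,
                                    warm_start = TRUE) {
  if (B < 1) stop("B must be >= 1")
  n <- length(train_data$y); cc <- ncol(train_data$Q)
  if (warm_start) {
    ## unpenalized joint base fit: a dense solution near the signal, so
    ## every bootstrap starts close without inheriting a sparse support
    ## (a raw weight parameter at 0 cannot re-emerge, gradient is
    ## proportional to v)
    base <- fit_two_index_once(train_data, 0, vp_init, vn_init,
                               beta1p_init, beta1n_init)
    if (base$converged) {
      vp_init <- base$vp; vn_init <- base$vn
      beta1p_init <- base$beta1p; beta1n_init <- base$beta1n
    }
  }
  if (!is.null(seed)) set.seed(seed)
  wp <- matrix(NA_real_, B, cc, dimnames = list(NULL, train_data$component_names))
  wn <- wp
  beta1p <- beta1n <- tol_p <- tol_n <- rep(NA_real_, B)
  converged <- logical(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    bd <- subset_rows(train_data, idx)
    fit <- fit_two_index_once(bd, lambda, vp_init, vn_init,
                              beta1p_init, beta1n_init)
    converged[b] <- fit$converged
    wp[b, ] <- fit$wp; wn[b, ] <- fit$wn
    beta1p[b] <- fit$beta1p; beta1n[b] <- fit$beta1n
    tl <- tryCatch(
      index_tolerance(drop(bd$Q %*% fit$wp), drop(bd$Q %*% fit$wn), bd$Z),
      error = function(e) list(tol_p = 0, tol_n = 0))
    tol_p[b] <- tl$tol_p; tol_n[b] <- tl$tol_n
  }
  informative_p <- converged & abs(beta1p) > 1e-8
  informative_n <- converged & abs(beta1n) > 1e-8
  if (!any(informative_p) && !any(informative_n)) {
    stop("no fit obtained: no informative bootstrap in either direction")
  }
  list(wp = wp, wn = wn, beta1p = beta1p, beta1n = beta1n,
       tol_p = tol_p, tol_n = tol_n, converged = converged,
       informative_p = informative_p, informative_n = informative_n,
       B = B, lambda = lambda)
}

## tolerance-signal average of one direction's bootstrap weights; NULL when
## the direction has no informative bootstrap
average_direction <- function(boot, direction = c("positive", "negative"), k) {
  direction <- match.arg(direction)
  inf <- if (direction == "positive") boot$informative_p else boot$informative_n
  if (!any(inf)) return(NULL)
  W <- if (direction == "positive") boot$wp[inf, , drop = FALSE]
       else boot$wn[inf, , drop = FALSE]
  tols <- if (direction == "positive") boot$tol_p[inf] else boot$tol_n[inf]
  sig <- tryCatch(tolerance_signal(tols, k), error = function(e) NULL)
  if (is.null(sig)) return(NULL)
  ensemble_average_weights(W, sig)$w_bar
}

#' Final validation model for the two-index fit
#'
#' Builds both averaged indices on the validation sample and fits the
#' unpenalized joint GLM with the sign bounds kept active
#' (`beta1p >= 0`, `beta1n <= 0`), computing the VIF of each index. When a
#' direction has no averaged weights the single-index model for the other
#' direction is fitted instead and the result is flagged as a fallback,
#' with a warning that no weight estimates are found in one of the two
#' directions.
#'
#' @param wp_bar,wn_bar Averaged weight vectors (either may be `NULL` when
#'   that direction produced no informative bootstrap).
#' @param validation_data Validation-split [mixture_data()].
#' @param k Tolerance-signal exponent used to produce the averages (stored
#'   in the result).
#' @param vif_threshold Collinearity threshold; when either index VIF
#'   exceeds it the result is flagged `escalate = TRUE` so the caller can
#'   re-average with a larger `k`.
#' @return An object of class `two_index_result`: `beta0`, `beta1p`,
#'   `beta1n`, `phi`, `wp_bar`, `wn_bar`, `vif_p`, `vif_n`, `k`,
#'   `fallback` (`"none"`, `"positive_only"`, `"negative_only"`),
#'   `final_fit` (coefficient table, AIC), `escalate`.
#' @export
finalize_two_index <- function(wp_bar, wn_bar, validation_data, k = 3,
                               vif_threshold = 5) {
  if (is.null(wp_bar) && is.null(wn_bar)) {
    stop("no weight estimates in either direction")
  }
  if (is.null(wp_bar) || is.null(wn_bar)) {
    warning("no weight estimates are found in one of the two directions; fitting the single-index model")
    keep_pos <- !is.null(wp_bar)
    w <- if (keep_pos) wp_bar else wn_bar
    fit <- validate_single(w, validation_data)
    out <- list(
      beta0 = unname(fit$coef["(Intercept)"]),
      beta1p = if (keep_pos) fit$beta1 else NA_real_,
      beta1n = if (keep_pos) NA_real_ else fit$beta1,
      phi = fit$coef[setdiff(names(fit$coef), c("(Intercept)", "WQS"))],
      wp_bar = if (keep_pos) wp_bar else NULL,
      wn_bar = if (keep_pos) NULL else wn_bar,
      vif_p = NA_real_, vif_n = NA_real_, k = k,
      fallback = if (keep_pos) "positive_only" else "negative_only",
      final_fit = fit, escalate = FALSE)
    return(structure(out, class = "two_index_result"))
  }
  index_p <- drop(validation_data$Q %*% wp_bar)
  index_n <- drop(validation_data$Q %*% wn_bar)
  fit <- fit_validation_glm(validation_data$y,
                            cbind(WQSp = index_p, WQSn = index_n),
                            validation_data$Z, validation_data$link,
                            lower = c(0, -Inf), upper = c(Inf, 0))
  tl <- index_tolerance(index_p, index_n, validation_data$Z)
  out <- list(
    beta0 = unname(fit$coef["(Intercept)"]),
    beta1p = unname(fit$coef["WQSp"]),
    beta1n = unname(fit$coef["WQSn"]),
    phi = fit$coef[setdiff(names(fit$coef), c("(Intercept)", "WQSp", "WQSn"))],
    wp_bar = wp_bar, wn_bar = wn_bar,
    vif_p = tl$vif_p, vif_n = tl$vif_n, k = k,
    fallback = "none", final_fit = fit,
    escalate = tl$vif_p > vif_threshold || tl$vif_n > vif_threshold)
  structure(out, class = "two_index_result")
}

#' @export
print.two_index_result <- function(x, ...) {
  cat("two-index WQS validation fit\n")
  cat(sprintf("  beta1p = %s  beta1n = %s  (fallback: %s)\n",
              format(x$beta1p, digits = 4), format(x$beta1n, digits = 4),
              x$fallback))
  if (x$fallback == "none") {
    cat(sprintf("  VIF: positive %.2f, negative %.2f (k = %g)\n",
                x$vif_p, x$vif_n, x$k))
  }
  cat(sprintf("  AIC = %.2f\n", x$final_fit$aic))
  invisible(x)
}
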