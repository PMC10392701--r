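## Validation-split GLMs for the WQS indices, plus AIC bookkeeping.

glm_family <- function(link) {
  if (link == "logit") stats::binomial() else stats::gaussian()
}

## number of mean parameters + 1 residual-variance parameter for identity
aic_k_params <- function(n_coef, link) n_coef + as.integer(link == "identity")

check_full_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design: collinear columns ", paste(bad, collapse = ", "))
  }
}

## Unpenalized GLM of y on index columns + covariates. `lower`/`upper`
## bound the index coefficients only (length = ncol(index_mat)); when the
## unconstrained solution already satisfies the bounds it is returned
## as-is (and equals stats::glm). Otherwise a bound-constrained ML fit is
## used with SEs from the observed information at the solution.
fit_validation_glm <- function(y, index_mat, Z, link,
                               lower = NULL, upper = NULL) {
  index_mat <- as.matrix(index_mat)
  X <- cbind(`(Intercept)` = 1, index_mat, Z)
  check_full_rank(X)
  fam <- glm_family(link)
  fit <- stats::glm.fit(X, y, family = fam)
  coefs <- fit$coefficients
  ki <- seq_len(ncol(index_mat)) + 1L
  ok_bounds <- TRUE
  if (!is.null(lower)) ok_bounds <- all(coefs[ki] >= lower - 1e-12)
  if (ok_bounds && !is.null(upper)) ok_bounds <- all(coefs[ki] <= upper + 1e-12)

  n <- length(y)
  bound_active <- FALSE
  if (ok_bounds) {
    ## dispersion and vcov as in summary.glm
    w <- fit$weights
    XtWX <- crossprod(X * sqrt(w))
    disp <- if (link == "identity") sum(fit$residuals^2 * w) / fit$df.residual else 1
    vc <- solve(XtWX) * disp
    se <- sqrt(diag(vc))
    deviance <- fit$deviance
  } else {
    bound_active <- TRUE
    lo <- rep(-Inf, ncol(X)); up <- rep(Inf, ncol(X))
    if (!is.null(lower)) lo[ki] <- lower
    if (!is.null(upper)) up[ki] <- upper
    negll <- function(b) {
      eta <- drop(X %*% b)
      if (link == "logit") sum(log1p(exp(eta)) - y * eta)
      else 0.5 * sum((y - eta)^2)   # profile-sigma scale handled below
    }
    o <- stats::optim(pmin(pmax(coefs, lo), up), negll, method = "L-BFGS-B",
                      lower = lo, upper = up,
                      control = list(maxit = 500, factr = 1e7))
    coefs <- o$par
    eta <- drop(X %*% coefs)
    if (link == "logit") {
      mu <- stats::plogis(eta)
      deviance <- -2 * sum(y * log(pmax(mu, 1e-12)) +
                             (1 - y) * log(pmax(1 - mu, 1e-12)))
      W <- mu * (1 - mu)
    } else {
      deviance <- sum((y - eta)^2)
      W <- rep(1, n)
    }
    XtWX <- crossprod(X * sqrt(W))
    disp <- if (link == "identity") deviance / (n - ncol(X)) else 1
    vc <- tryCatch(solve(XtWX) * disp, error = function(e) matrix(NA, ncol(X), ncol(X)))
    se <- sqrt(diag(vc))
  }
  k <- aic_k_params(ncol(X), link)
  aic <- if (link == "identity") {
    sigma2 <- deviance / n
    n * (log(2 * pi * sigma2) + 1) + 2 * k
  } else {
    deviance + 2 * k
  }
  zval <- coefs / se
  pval <- 2 * stats::pnorm(-abs(zval))
  coef_table <- data.frame(term = colnames(X), estimate = unname(coefs),
                           se = unname(se), statistic = unname(zval),
                           p_value = unname(pval), row.names = NULL)
  list(coef = coefs, se = se, coef_table = coef_table, aic = aic,
       deviance = deviance, n = n, link = link,
       bound_active = bound_active, index_cols = colnames(index_mat))
}

#' Fit the validation-split model for a single averaged index
#'
#' Builds the scalar index `WQS = Q %*% w_bar` on the validation sample and
#' fits the unpenalized GLM `g(mu) = beta0 + beta1 WQS + Z phi`, the model
#' on which inference for the mixture effect is based.
#'
#' @param w_bar Averaged weight vector on the simplex.
#' @param validation_data A [mixture_data()] object (held out from weight
#'   estimation).
#' @return List with `coef`, `se`, `coef_table` (Wald tests, two-sided),
#'   `aic`, `beta1`, `index` (the per-subject index values).
#' @export
validate_single <- function(w_bar, validation_data) {
  w_bar <- as.numeric(w_bar)
  if (abs(sum(w_bar) - 1) > 1e-6 || any(w_bar < -1e-12)) {
    stop("w_bar must be on the simplex")
  }
  index <- drop(validation_data$Q %*% w_bar)
  fit <- fit_validation_glm(validation_data$y, cbind(WQS = index),
                            validation_data$Z, validation_data$link)
  fit$beta1 <- unname(fit$coef["WQS"])
  fit$index <- index
  fit
}

#' AIC of a validation-split model
#'
#' `AIC = -2 log L + 2 k`, where `k` counts the intercept, index
#' coefficient(s) and covariates, plus one residual-variance parameter for
#' the identity link (so it matches [stats::AIC()] on the corresponding
#' `glm` object).
#'
#' @param final_fit A fit returned by [validate_single()] or the two-index
#'   finalizer.
#' @return AIC (scalar).
#' @export
model_aic <- function(final_fit) {
  if (is.null(final_fit$aic)) stop("not a validation fit")
  final_fit$aic
}
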