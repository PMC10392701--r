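## Internal optimizer core shared by the single- and two-index estimators.
##
## theta layout, single index: (beta0, beta1, v[1..c], phi[1..p])
## theta layout, two index:    (beta0, beta1p, beta1n, vp[1..c], vn[1..c], phi)
## Sign constraints on the index coefficients are enforced as optimizer
## bounds; the simplex constraint on weights is built into w = v^2/sum(v^2).

empty_Z <- function(n) matrix(numeric(0), nrow = n, ncol = 0)

init_beta0 <- function(y, link) {
  if (link == "logit") {
    p <- mean(y); p <- min(max(p, 1e-3), 1 - 1e-3)
    log(p / (1 - p))
  } else mean(y)
}

## projected gradient infinity-norm for box constraints
projected_grad_norm <- function(par, grad, lower, upper, tol = 1e-8) {
  g <- grad
  at_lo <- par <= lower + tol
  at_up <- par >= upper - tol
  g[at_lo] <- pmin(g[at_lo], 0)
  g[at_up] <- pmax(g[at_up], 0)
  max(abs(g))
}

fit_wqs_optim <- function(y, Q, Z, link, lambda, two_index,
                          beta_init, v_init_p, v_init_n = NULL,
                          maxit = getOption("wqs2i.maxit", 400L),
                          factr = getOption("wqs2i.factr", 1e8)) {
  n <- length(y); cc <- ncol(Q); p <- ncol(Z)
  binomial <- link == "logit"
  Qd <- Q; storage.mode(Qd) <- "double"
  n_idx <- if (two_index) 2L else 1L
  theta0 <- c(init_beta0(y, link), beta_init,
              v_init_p, if (two_index) v_init_n, rep(0, p))
  lower <- c(-Inf, 0, if (two_index) -Inf, rep(-Inf, n_idx * cc + p))
  upper <- c(Inf, Inf, if (two_index) 0, rep(Inf, n_idx * cc + p))
  if (!two_index && beta_init < 0) { lower[2] <- -Inf; upper[2] <- 0 }
  theta0 <- pmin(pmax(theta0, lower), upper)

  eps <- getOption("wqs2i.eps", 1e-6)
  f0 <- wqs_objective_cpp(theta0, y, Qd, Z, lambda, two_index, binomial, eps)
  ## optim evaluates fn then gr at the same point: fuse them behind a
  ## one-point cache so each iteration costs a single data pass
  cache_theta <- NULL
  cache_res <- NULL
  fused <- function(th) {
    res <- wqs_objgrad_cpp(th, y, Qd, Z, lambda, two_index, binomial, eps)
    cache_theta <<- th
    cache_res <<- res
    res
  }
  fn <- function(th) {
    if (!is.null(cache_theta) && identical(th, cache_theta)) return(cache_res[1])
    fused(th)[1]
  }
  gr <- function(th) {
    if (!is.null(cache_theta) && identical(th, cache_theta)) return(cache_res[-1])
    fused(th)[-1]
  }
  opt <- try(stats::optim(theta0, fn, gr,
                          method = "L-BFGS-B", lower = lower, upper = upper,
                          control = list(maxit = maxit, factr = factr)),
             silent = TRUE)
  if (inherits(opt, "try-error")) {
    return(list(converged = FALSE, value = f0, theta = theta0,
                message = as.character(opt)))
  }
  g <- wqs_gradient_cpp(opt$par, y, Qd, Z, lambda, two_index, binomial, eps)
  pg <- projected_grad_norm(opt$par, g, lower, upper)
  ## relative projected-gradient check on top of the optimizer's own
  ## function-decrease criterion; flags flat-region/maxit terminations
  converged <- opt$convergence == 0 && pg <= 1e-3 * max(1, abs(opt$value))
  list(converged = converged, value = opt$value, theta = opt$par,
       counts = opt$counts, pg_norm = pg, f0 = f0)
}

unpack_theta <- function(theta, cc, p, two_index) {
  n_idx <- if (two_index) 2L else 1L
  out <- list(beta0 = theta[1], beta1p = theta[2])
  if (two_index) out$beta1n <- theta[3]
  out$vp <- theta[(1 + n_idx + 1):(n_idx + cc + 1)]
  if (two_index) out$vn <- theta[(n_idx + cc + 2):(n_idx + 2 * cc + 1)]
  out$phi <- if (p > 0) theta[(1 + n_idx + n_idx * cc + 1):length(theta)] else numeric(0)
  out
}

#' Penalized single-index WQS objective
#'
#' The estimation criterion for the penalized single-index model: the GLM
#' loss (residual sum of squares for the identity link, deviance for the
#' logit link) of `g(mu) = beta0 + beta1 * sum_i(w_i q_i) + Z phi` with
#' `w = v^2/sum(v^2)`, plus the shrinkage penalty `lambda * sum(|v_i|)`
#' evaluated on the unit-normalized `v` (equivalently
#' `lambda * sum(sqrt(w_i))`), so the objective is invariant to rescaling
#' `v`.
#'
#' @param theta List with elements `beta0`, `beta1`, `v` (length c) and
#'   optionally `phi` (length p).
#' @param data A [mixture_data()] object.
#' @param lambda Shrinkage parameter, `>= 0`.
#' @return Objective value (scalar).
#' @examples
#' d <- mixture_data(c(1, 0), rbind(c(1, 0), c(0, 0)), q = 2,
#'                   already_quantized = TRUE)
#' penalized_objective(list(beta0 = 0, beta1 = 1, v = c(1, 0)), d, lambda = 2)
#' @export
penalized_objective <- function(theta, data, lambda) {
  if (lambda < 0) stop("lambda must be nonnegative")
  if (sum(theta$v^2) == 0) stop("weights undefined at v = 0")
  phi <- if (is.null(theta$phi)) rep(0, ncol(data$Z)) else theta$phi
  th <- c(theta$beta0, theta$beta1, theta$v, phi)
  Qd <- data$Q; storage.mode(Qd) <- "double"
  ## exact penalty (eps = 0): the reported objective is not smoothed
  wqs_objective_cpp(th, data$y, Qd, data$Z, lambda,
                    FALSE, data$link == "logit", 0)
}

#' Fit a penalized single-index WQS model on one sample
#'
#' Minimizes [penalized_objective()] by bound-constrained quasi-Newton
#' optimization (L-BFGS-B with analytic gradients), with the index
#' coefficient constrained to the requested direction. This is the
#' building block used inside bootstrap ensembles; for a full analysis with
#' training/validation splits see [wqs2i()].
#'
#' @param data A [mixture_data()] object.
#' @param direction `"positive"` (`beta1 >= 0`) or `"negative"`
#'   (`beta1 <= 0`).
#' @param lambda Shrinkage parameter `>= 0`.
#' @param v_init Starting raw weight parameters: `"ones"` (all 1, i.e.
#'   uniform weights) or a numeric vector of length c.
#' @param beta_init Optional starting value for `beta1` (default: a small
#'   value of the requested sign).
#' @return An object of class `wqs_fit_single`: list with `beta0`, `beta1`,
#'   `phi`, `v`, `w`, `lambda`, `direction`, `link`, `objective_value`,
#'   `converged`, `n_train`.
#' @export
fit_single_wqs <- function(data, direction = c("positive", "negative"),
                           lambda = 0, v_init = "ones", beta_init = NULL) {
  direction <- match.arg(direction)
  if (lambda < 0) stop("lambda must be nonnegative")
  cc <- ncol(data$Q); p <- ncol(data$Z); n <- length(data$y)
  if (identical(v_init, "ones")) v_init <- rep(1, cc)
  if (sum(v_init^2) == 0) stop("weights undefined at v = 0")
  sgn <- if (direction == "positive") 1 else -1
  if (is.null(beta_init)) beta_init <- sgn * 0.1
  beta_init <- sgn * max(abs(beta_init), 0.01)

  res <- fit_wqs_optim(data$y, data$Q, data$Z, data$link, lambda,
                       two_index = FALSE, beta_init = beta_init,
                       v_init_p = v_init)
  if (!res$converged && !all(v_init == v_init[1])) {
    ## one restart from the uniform initialization
    res2 <- fit_wqs_optim(data$y, data$Q, data$Z, data$link, lambda,
                          two_index = FALSE, beta_init = sgn * 0.1,
                          v_init_p = rep(1 / cc, cc))
    if (res2$converged || res2$value < res$value) res <- res2
  }
  if (abs(res$theta[2]) < 1e-8) {
    ## beta1 pinned at its sign bound leaves the weights without gradient
    ## (a boundary trap): retry once from marginal-correlation-informed
    ## weights and a larger starting slope, keep the better objective
    w0 <- pmax(sgn * suppressWarnings(stats::cor(data$y, data$Q)), 0.02)
    w0[is.na(w0)] <- 0.02
    res3 <- fit_wqs_optim(data$y, data$Q, data$Z, data$link, lambda,
                          two_index = FALSE, beta_init = sgn * 0.5,
                          v_init_p = sqrt(drop(w0) / sum(w0)))
    if (res3$value < res$value) res <- res3
  }
  pars <- unpack_theta(res$theta, cc, p, FALSE)
  w <- weights_from_v(pars$vp)
  names(w) <- data$component_names
  ## degenerate design: the fitted index is constant over the sample
  idx <- drop(data$Q %*% w)
  converged <- res$converged && stats::sd(idx) > 1e-12
  structure(
    list(beta0 = pars$beta0, beta1 = pars$beta1, phi = pars$phi,
         v = pars$vp, w = w, lambda = lambda, direction = direction,
         link = data$link, objective_value = res$value,
         converged = converged, n_train = n),
    class = "wqs_fit_single"
  )
}

#' @export
print.wqs_fit_single <- function(x, ...) {
  cat(sprintf("single-index WQS fit (%s direction, lambda = %g, %s link)\n",
              x$direction, x$lambda, x$link))
  cat(sprintf("  beta1 = %.4f  objective = %.4f  converged = %s\n",
              x$beta1, x$objective_value, x$converged))
  top <- sort(x$w, decreasing = TRUE)
  top <- top[top > 1e-6][seq_len(min(5, sum(x$w > 1e-6)))]
  cat("  leading weights:", paste(sprintf("%s=%.3f", names(top), top),
                                  collapse = ", "), "\n")
  invisible(x)
}
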