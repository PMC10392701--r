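#' Map raw weight parameters to simplex weights
#'
#' The estimators parameterize the mixture weights as `w = v^2 / sum(v^2)`,
#' which enforces `0 <= w_i <= 1` and `sum(w) = 1` without explicit
#' constraints and lets an L1 penalty on `v` act as a sparsity penalty on
#' the weights.
#'
#' @param v Real vector of raw weight parameters (not all zero).
#' @return Weight vector on the simplex.
#' @examples
#' weights_from_v(c(1, -1))   # 0.5 0.5
#' @export
weights_from_v <- function(v) {
  v <- as.numeric(v)
  s <- sum(v^2)
  if (s == 0) stop("weights undefined at v = 0")
  v^2 / s
}

#' Signal values for t-statistic based ensemble averaging
#'
#' Converts per-bootstrap t-statistics of the index coefficient into
#' nonnegative signal values used to weight each bootstrap's estimated
#' weight vector in the ensemble average.
#'
#' @param stat Vector of per-bootstrap t statistics.
#' @param kind `"abst"` (|t|), `"t2"` (t^2, the default used by the
#'   single-index estimator), `"expt"` (e^|t|) or `"one"` (plain mean).
#' @return Nonnegative signal vector, same length as `stat`.
#' @export
signal_value <- function(stat, kind = c("t2", "abst", "expt", "one")) {
  kind <- match.arg(kind)
  stat <- as.numeric(stat)
  if (any(!is.finite(stat))) stop("t statistics must be finite")
  switch(kind,
         abst = abs(stat),
         t2   = stat^2,
         expt = exp(abs(stat)),
         one  = rep(1, length(stat)))
}

#' Tolerance-based signal values
#'
#' For the two-index estimator the ensemble average uses the collinearity
#' tolerance of each bootstrap fit (tolerance = 1/VIF of the index in that
#' bootstrap's joint model): `f_b = (tol_b / sum(tol))^k`. Larger `k`
#' concentrates the average on the bootstraps whose two indices are least
#' collinear.
#'
#' @param tols Per-bootstrap tolerances in `[0, 1]`, not all zero.
#' @param k Positive integer exponent.
#' @return Nonnegative signal vector.
#' @examples
#' tolerance_signal(c(0.8, 0.2), k = 3)  # 0.512 0.008
#' @export
tolerance_signal <- function(tols, k = 3L) {
  tols <- as.numeric(tols)
  if (any(!is.finite(tols)) || any(tols < 0) || any(tols > 1)) {
    stop("tolerances must lie in [0, 1]")
  }
  if (k < 1) stop("k must be a positive integer")
  tot <- sum(tols)
  if (tot == 0) stop("all tolerances are zero")
  (tols / tot)^k
}

#' Signal-weighted average of bootstrap weight vectors
#'
#' @param per_bootstrap_w B x c matrix, one simplex weight vector per row.
#' @param signals Nonnegative signal values, length B, not all zero.
#' @return List with `w_bar` (averaged simplex weights), `signals`
#'   (normalized), and `n_informative` (number of rows with positive
#'   signal).
#' @export
ensemble_average_weights <- function(per_bootstrap_w, signals) {
  W <- as.matrix(per_bootstrap_w)
  signals <- as.numeric(signals)
  if (nrow(W) != length(signals)) stop("one signal per bootstrap row required")
  if (any(signals < 0)) stop("signals must be nonnegative")
  tot <- sum(signals)
  if (tot == 0) stop("no informative bootstrap in this direction")
  f <- signals / tot
  w_bar <- drop(crossprod(W, f))
  names(w_bar) <- colnames(W)
  list(w_bar = w_bar, signals = f, n_informative = sum(signals > 0))
}

#' Components selected by the 1/c weight threshold
#'
#' The conventional rule to call a component part of the mixture effect:
#' its (median) weight strictly exceeds the uninformative value `1/c`.
#'
#' @param w_bar Weight vector on the simplex.
#' @param c Number of mixture components (defaults to `length(w_bar)`).
#' @return Integer indices of selected components.
#' @export
classify_weights <- function(w_bar, c = length(w_bar)) {
  which(as.numeric(w_bar) > 1 / c)
}
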