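## Shrinkage-parameter selection: AIC-magnitude candidate grids and
## AIC-minimizing selection over repeated-holdout runs.

#' Candidate shrinkage values from the AIC magnitude
#'
#' The rule of thumb for the shrinkage parameter: take the order of
#' magnitude `M` of the AIC of the unpenalized fit and try `M/10`, `M`
#' and `10 M`; the refined grid additionally tries the intermediate
#' values `M/2` and `5 M` (e.g. magnitude 1,000 gives
#' 100, 500, 1,000, 5,000, 10,000).
#'
#' @param aic AIC of the unpenalized regression (finite scalar).
#' @param refine Add the intermediate half-decade values.
#' @return Increasing vector of candidate lambda values.
#' @export
lambda_grid_from_aic <- function(aic, refine = FALSE) {
  if (!is.finite(aic)) stop("aic must be finite")
  if (aic == 0) return(c(0, 1, 10))
  M <- 10^round(log10(abs(aic)))
  grid <- c(M / 10, M, M * 10)
  if (refine) grid <- c(grid, M / 2, M * 5)
  sort(grid)
}

#' Select the shrinkage parameter by validation AIC
#'
#' Runs the configured estimator once per candidate lambda (with identical
#' split seeds, so candidates are compared on the same holdout draws) and
#' picks the candidate with the smallest mean validation-model AIC; ties
#' go to the smaller lambda.
#'
#' @param data A [mixture_data()] object.
#' @param candidates Nonnegative candidate lambda values.
#' @param fit_config Config list passed to [run_repeated_holdout()]
#'   (estimator, H, B, seed, ...); `lambda` is overwritten per candidate.
#' @param refine After the grid pass, also evaluate the geometric mean of
#'   the best candidate and its better-scoring neighbor (one rough
#'   bisection step).
#' @return An object of class `lambda_search`: `candidates`, `aics`,
#'   `best_lambda`, `trace` (data frame of every evaluation).
#' @export
select_lambda <- function(data, candidates, fit_config = list(),
                          refine = FALSE) {
  candidates <- sort(unique(as.numeric(candidates)))
  if (!length(candidates)) stop("candidates must be nonempty")
  if (any(candidates < 0)) stop("candidates must be nonnegative")
  fit_config <- fill_config(fit_config)
  eval_one <- function(lam) {
    cfg <- fit_config
    cfg$lambda <- lam
    dist <- tryCatch(run_repeated_holdout(data, cfg), error = function(e) NULL)
    if (is.null(dist)) return(NA_real_)
    ps <- dist$per_split
    mean(ps$aic[!ps$failed], na.rm = TRUE)
  }
  aics <- vapply(candidates, eval_one, numeric(1))
  if (all(is.na(aics))) stop("all candidate lambdas failed to fit")
  trace <- data.frame(lambda = candidates, aic = aics,
                      seed = if (is.null(fit_config$seed)) NA_integer_ else fit_config$seed)
  if (refine && length(candidates) > 1) {
    ok <- which(!is.na(aics))
    best <- ok[which.min(aics[ok])]
    nb <- c(best - 1L, best + 1L)
    nb <- nb[nb >= 1 & nb <= length(candidates)]
    if (length(nb)) {
      nb_best <- nb[which.min(aics[nb])]
      lam_new <- sqrt(max(candidates[best], 1e-12) *
                        max(candidates[nb_best], 1e-12))
      if (!lam_new %in% candidates) {
        aic_new <- eval_one(lam_new)
        trace <- rbind(trace, data.frame(lambda = lam_new, aic = aic_new,
                                         seed = trace$seed[1]))
      }
    }
  }
  trace <- trace[order(trace$lambda), , drop = FALSE]
  ok <- which(!is.na(trace$aic))
  best_lambda <- trace$lambda[ok[which.min(trace$aic[ok])]]
  structure(list(candidates = trace$lambda, aics = trace$aic,
                 best_lambda = best_lambda, trace = trace),
            class = "lambda_search")
}

#' @export
print.lambda_search <- function(x, ...) {
  cat("shrinkage parameter search (validation AIC)\n")
  print(x$trace, digits = 6, row.names = FALSE)
  cat("best lambda:", x$best_lambda, "\n")
  invisible(x)
}
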