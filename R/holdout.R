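## Repeated random holdout: H independent train/validation splits, each
## with its own bootstrap ensemble, summarized by medians and percentile
## intervals.

## t statistic of the index slope in the unpenalized GLM of y on
## (index, Z) — the per-bootstrap statistic for t-based signal functions
index_tstat <- function(y, index, Z, link) {
  fit <- tryCatch(
    fit_validation_glm(y, cbind(WQS = index), Z, link),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  unname(fit$coef["WQS"] / fit$se["WQS"])
}

## bootstrap ensemble for one direction of the standard/penalized
## single-index model
single_ensemble <- function(train_data, B, lambda, direction, signal_kind,
                            seed = NULL, v_init = "ones") {
  n <- length(train_data$y); cc <- ncol(train_data$Q)
  ## warm start: unpenalized fit on the training sample, start bootstraps
  ## there (dense, so the penalty still acts per bootstrap)
  base <- fit_single_wqs(train_data, direction, 0, v_init = v_init)
  beta_init <- NULL
  if (base$converged) { v_init <- base$v; beta_init <- base$beta1 }
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(NA_real_, B, cc, dimnames = list(NULL, train_data$component_names))
  beta1 <- tstat <- rep(NA_real_, B)
  converged <- logical(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    bd <- subset_rows(train_data, idx)
    fit <- fit_single_wqs(bd, direction, lambda, v_init = v_init,
                          beta_init = beta_init)
    converged[b] <- fit$converged
    W[b, ] <- fit$w
    beta1[b] <- fit$beta1
    tstat[b] <- index_tstat(bd$y, drop(bd$Q %*% fit$w), bd$Z, bd$link)
  }
  informative <- converged & abs(beta1) > 1e-8 & is.finite(tstat)
  w_bar <- NULL
  if (any(informative)) {
    sig <- signal_value(tstat[informative], signal_kind)
    if (sum(sig) > 0) {
      w_bar <- ensemble_average_weights(W[informative, , drop = FALSE], sig)$w_bar
    }
  }
  list(w_bar = w_bar, per_bootstrap_w = W, beta1 = beta1, tstat = tstat,
       converged = converged, informative = informative,
       signal_kind = signal_kind, n_informative = sum(informative))
}

default_holdout_config <- function() {
  list(estimator = "two_index", lambda = 0, H = 100L, B = 100L,
       split = 0.6, k = 3L, k_escalate = TRUE, k_cap = 6L,
       vif_threshold = 5, signal = "t2", seed = NULL)
}

fill_config <- function(config) {
  out <- default_holdout_config()
  unknown <- setdiff(names(config), names(out))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  out[names(config)] <- config
  out
}

## train/validation split indices; stratified by outcome for the logit link
split_indices <- function(data, fraction) {
  n <- length(data$y)
  if (data$link == "logit") {
    idx <- unlist(lapply(split(seq_len(n), data$y), function(g) {
      sample(g, max(1L, round(fraction * length(g))))
    }), use.names = FALSE)
    sort(idx)
  } else {
    sort(sample.int(n, max(2L, round(fraction * n))))
  }
}

## run one train/validation split under the configured estimator; `init`
## carries the dataset-level two-index starting values (the starter fits
## use all observations, unsplit and un-bootstrapped)
run_one_split <- function(data, train_idx, config, boot_seed, init = NULL) {
  train <- subset_rows(data, train_idx)
  valid <- subset_rows(data, setdiff(seq_along(data$y), train_idx))
  warnings <- character()
  wcollect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w)); invokeRestart("muffleWarning")
  })
  est <- config$estimator
  rec <- list(beta1p = NA_real_, beta1n = NA_real_, aic = NA_real_,
              vif_p = NA_real_, vif_n = NA_real_, k_used = NA_real_,
              fallback = "none", wp_bar = NULL, wn_bar = NULL,
              beta0 = NA_real_, phi = rep(NA_real_, ncol(data$Z)))
  if (est == "two_index") {
    if (is.null(init)) init <- wcollect(initialize_two_index(data))
    boot <- fit_two_index_bootstrap(train, config$B, config$lambda,
                                    init$vp_init, init$vn_init,
                                    seed = boot_seed,
                                    beta1p_init = init$beta1p_init,
                                    beta1n_init = init$beta1n_init)
    k_cur <- config$k
    repeat {
      wp_bar <- average_direction(boot, "positive", k_cur)
      wn_bar <- average_direction(boot, "negative", k_cur)
      res <- wcollect(finalize_two_index(wp_bar, wn_bar, valid, k_cur,
                                         config$vif_threshold))
      if (!res$escalate || !config$k_escalate || k_cur >= config$k_cap) break
      k_cur <- k_cur + 1L
    }
    if (res$escalate) {
      warnings <- c(warnings, sprintf(
        "index VIF above %g at the k cap (%d); proceeding", config$vif_threshold, k_cur))
    }
    rec[c("beta1p", "beta1n", "vif_p", "vif_n", "fallback")] <-
      res[c("beta1p", "beta1n", "vif_p", "vif_n", "fallback")]
    rec$aic <- res$final_fit$aic
    rec$k_used <- res$k
    rec$wp_bar <- res$wp_bar; rec$wn_bar <- res$wn_bar
    rec$beta0 <- res$beta0; rec$phi <- unname(res$phi)
  } else if (est %in% c("single_pos", "single_neg")) {
    dir <- if (est == "single_pos") "positive" else "negative"
    ens <- single_ensemble(train, config$B, config$lambda, dir,
                           config$signal, seed = boot_seed)
    if (is.null(ens$w_bar)) stop("no informative bootstrap in this direction")
    val <- validate_single(ens$w_bar, valid)
    if (dir == "positive") { rec$beta1p <- val$beta1; rec$wp_bar <- ens$w_bar }
    else { rec$beta1n <- val$beta1; rec$wn_bar <- ens$w_bar }
    rec$aic <- val$aic
    rec$beta0 <- unname(val$coef["(Intercept)"])
    rec$phi <- unname(val$coef[setdiff(names(val$coef), c("(Intercept)", "WQS"))])
  } else if (est == "two_index_seq") {
    ## method-2 style: directions estimated separately (shared with the
    ## single-index ensembles), then one joint validation model
    ens_p <- single_ensemble(train, config$B, config$lambda, "positive",
                             config$signal, seed = boot_seed)
    ens_n <- single_ensemble(train, config$B, config$lambda, "negative",
                             config$signal, seed = boot_seed + 1L)
    res <- wcollect(finalize_two_index(ens_p$w_bar, ens_n$w_bar, valid,
                                       config$k, config$vif_threshold))
    rec[c("beta1p", "beta1n", "vif_p", "vif_n", "fallback")] <-
      res[c("beta1p", "beta1n", "vif_p", "vif_n", "fallback")]
    rec$aic <- res$final_fit$aic
    rec$k_used <- res$k
    rec$wp_bar <- res$wp_bar; rec$wn_bar <- res$wn_bar
    rec$beta0 <- res$beta0; rec$phi <- unname(res$phi)
  } else {
    stop("unknown estimator: ", est)
  }
  rec$warnings <- unique(warnings)
  rec
}

#' Run a repeated-holdout WQS analysis
#'
#' Repeats the full two-step estimation on `H` independent random
#' train/validation splits (60/40 by default, stratified by outcome for
#' the logit link). Each split runs its own bootstrap ensemble on the
#' training part and fits the validation model on the held-out part, so
#' that across repetitions every observation contributes to both weight
#' estimation and inference.
#'
#' @param data A [mixture_data()] object.
#' @param config List of settings; unset fields take defaults:
#'   `estimator` (`"two_index"`, `"single_pos"`, `"single_neg"`,
#'   `"two_index_seq"`), `lambda` (0), `H` (100), `B` (100), `split`
#'   (0.6), `k` (3), `k_escalate` (TRUE), `k_cap` (6), `vif_threshold`
#'   (5), `signal` (`"t2"`, used by the single-index ensembles), `seed`.
#' @return An object of class `wqs_holdout`: `per_split` data frame
#'   (estimates, AIC, VIFs, fallback flag, warnings per split), `wp`,
#'   `wn` (H x c weight matrices, `NA` rows where a direction was
#'   dropped), `seeds`, `config`, `component_names`.
#' @export
run_repeated_holdout <- function(data, config = list()) {
  config <- fill_config(config)
  H <- as.integer(config$H)
  if (H < 1 || config$B < 1) stop("H and B must be >= 1")
  if (!is.null(config$seed)) set.seed(config$seed)
  split_seeds <- sample.int(.Machine$integer.max - 1L, H)
  boot_seeds <- sample.int(.Machine$integer.max - 1L, H)
  cc <- ncol(data$Q)
  wp <- matrix(NA_real_, H, cc, dimnames = list(NULL, data$component_names))
  wn <- wp
  beta0 <- rep(NA_real_, H)
  phi <- matrix(NA_real_, H, ncol(data$Z),
                dimnames = list(NULL, data$covariate_names))
  cols <- c("beta1p", "beta1n", "aic", "vif_p", "vif_n", "k_used")
  per_split <- as.data.frame(matrix(NA_real_, H, length(cols),
                                    dimnames = list(NULL, cols)))
  per_split$fallback <- rep(NA_character_, H)
  per_split$failed <- FALSE
  all_warnings <- vector("list", H)
  init <- if (config$estimator == "two_index") initialize_two_index(data) else NULL
  for (h in seq_len(H)) {
    set.seed(split_seeds[h])
    train_idx <- split_indices(data, config$split)
    rec <- tryCatch(run_one_split(data, train_idx, config, boot_seeds[h],
                                  init = init),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      per_split$failed[h] <- TRUE
      all_warnings[[h]] <- conditionMessage(rec)
      next
    }
    per_split[h, cols] <- unlist(rec[cols])
    per_split$fallback[h] <- rec$fallback
    if (!is.null(rec$wp_bar)) wp[h, ] <- rec$wp_bar
    if (!is.null(rec$wn_bar)) wn[h, ] <- rec$wn_bar
    beta0[h] <- rec$beta0
    if (ncol(phi) && length(rec$phi) == ncol(phi)) phi[h, ] <- rec$phi
    all_warnings[[h]] <- rec$warnings
  }
  if (mean(per_split$failed) > 0.5) {
    stop("more than half of the holdout splits failed")
  }
  structure(
    list(per_split = per_split, wp = wp, wn = wn,
         beta0 = beta0, phi = phi,
         seeds = list(split = split_seeds, bootstrap = boot_seeds),
         config = config, component_names = data$component_names,
         warnings = all_warnings, n = length(data$y), q = data$q),
    class = "wqs_holdout"
  )
}

#' Summarize a repeated-holdout distribution
#'
#' Point estimates are medians across splits; 95% intervals are the 2.5th
#' and 97.5th percentiles (linear interpolation between order statistics).
#' An index is called significant when its percentile interval excludes 0.
#' Per component and direction, the median weight is reported and
#' compared with the `1/c` selection threshold.
#'
#' @param dist A `wqs_holdout` object.
#' @return List with `coef` (data frame: term, median, lower, upper,
#'   n_splits, significant), `weights` (data frame per direction x
#'   component: median weight, selected flag), `retained` (fraction of
#'   splits in which each direction was estimated), `threshold` (1/c).
#' @export
summarize_holdout <- function(dist) {
  ps <- dist$per_split[!dist$per_split$failed, , drop = FALSE]
  if (!nrow(ps)) stop("no successful splits to summarize")
  qs <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(NA_real_, NA_real_, NA_real_, 0))
    c(stats::median(x), stats::quantile(x, c(0.025, 0.975), names = FALSE),
      length(x))
  }
  terms <- c("beta1p", "beta1n", "aic")
  co <- t(vapply(terms, function(tm) qs(ps[[tm]]), numeric(4)))
  coef_df <- data.frame(term = terms, median = co[, 1], lower = co[, 2],
                        upper = co[, 3], n_splits = co[, 4],
                        row.names = NULL)
  coef_df$significant <- !is.na(coef_df$lower) &
    (coef_df$lower > 0 | coef_df$upper < 0)
  coef_df$significant[coef_df$term == "aic"] <- NA
  cc <- length(dist$component_names)
  thr <- 1 / cc
  med_w <- function(W) apply(W, 2, function(x) stats::median(x[!is.na(x)]))
  wdf <- rbind(
    data.frame(direction = "positive", component = dist$component_names,
               median_weight = unname(med_w(dist$wp)), row.names = NULL),
    data.frame(direction = "negative", component = dist$component_names,
               median_weight = unname(med_w(dist$wn)), row.names = NULL))
  wdf$selected <- !is.na(wdf$median_weight) & wdf$median_weight > thr
  retained <- c(positive = mean(!is.na(ps$beta1p)),
                negative = mean(!is.na(ps$beta1n)))
  list(coef = coef_df, weights = wdf, retained = retained, threshold = thr,
       n_splits = nrow(ps), config = dist$config)
}

#' @export
print.wqs_holdout <- function(x, ...) {
  cat(sprintf("repeated-holdout WQS run: estimator = %s, H = %d, B = %d, lambda = %g\n",
              x$config$estimator, nrow(x$per_split), x$config$B, x$config$lambda))
  s <- summarize_holdout(x)
  print(s$coef, digits = 4)
  invisible(x)
}
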