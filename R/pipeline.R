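## Configuration-driven runs: parse a JSON/YAML config, execute a task,
## write JSON/CSV artifacts and a plain-text log. A thin command-line
## wrapper around these functions ships in inst/cli/wqs2i.

#' Read and validate a run configuration
#'
#' @param path JSON (`.json`) or YAML (`.yml`/`.yaml`) configuration file,
#'   or a named list of the same fields. Required: `task` (one of `fit`,
#'   `fit2i`, `select_lambda`, `qgcomp`, `simulate`, `benchmark`); tasks
#'   on real data additionally need `input` (CSV path), `outcome` and
#'   `mixture`. Optional fields with defaults: `covariates` (none),
#'   `q` (4), `link` (`"identity"`), `lambda` (`"aic"`), `H` (100),
#'   `B` (100), `k_policy` (`"escalate"`, starting at 3; give a fixed `k`
#'   instead to disable escalation — setting both is an error),
#'   `signal` (`"t2"` single-index, tolerance for two-index),
#'   `direction` (`"positive"`), `seed` (1), and for the simulation
#'   tasks `corr`, `halve`, `n`, `R`, `methods`.
#' @return A validated config list of class `wqs_run_config` with all
#'   defaults filled.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) {
    path
  } else if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  problems <- character()
  known <- c("task", "input", "outcome", "mixture", "covariates", "q",
             "link", "lambda", "H", "B", "k", "k_policy", "signal",
             "direction", "seed", "split", "corr", "halve", "n", "R",
             "methods", "vif_threshold", "delim")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) problems <- c(problems, paste("unknown keys:", paste(unknown, collapse = ", ")))
  tasks <- c("fit", "fit2i", "select_lambda", "qgcomp", "simulate", "benchmark")
  if (is.null(cfg$task) || !cfg$task %in% tasks) {
    problems <- c(problems, paste("task must be one of:", paste(tasks, collapse = ", ")))
  }
  data_task <- !is.null(cfg$task) && cfg$task %in% c("fit", "fit2i", "select_lambda", "qgcomp")
  if (data_task) {
    for (f in c("input", "outcome", "mixture")) {
      if (is.null(cfg[[f]])) problems <- c(problems, paste("missing required field:", f))
    }
  }
  if (!is.null(cfg[["k"]]) && identical(cfg[["k_policy"]], "escalate")) {
    problems <- c(problems, "contradictory k settings: fixed k and k_policy 'escalate'")
  }
  if (!is.null(cfg$link) && !cfg$link %in% c("identity", "logit")) {
    problems <- c(problems, "link must be 'identity' or 'logit'")
  }
  if (length(problems)) stop("invalid config:\n  - ", paste(problems, collapse = "\n  - "))
  defaults <- list(covariates = character(), q = 4L, link = "identity",
                   lambda = "aic", H = 100L, B = 100L, signal = "t2",
                   direction = "positive", seed = 1L, split = 0.6,
                   halve = FALSE, n = 2000L, R = 20L,
                   methods = c("m1", "m2", "m3", "m4"),
                   vif_threshold = 5, delim = ",")
  filled <- setdiff(names(defaults), names(cfg))
  cfg[filled] <- defaults[filled]
  if (is.null(cfg[["k_policy"]])) {
    cfg$k_policy <- if (is.null(cfg[["k"]])) "escalate" else "fixed"
  }
  if (is.null(cfg[["k"]])) cfg$k <- 3L
  attr(cfg, "defaults_filled") <- filled
  class(cfg) <- "wqs_run_config"
  cfg
}

load_config_data <- function(cfg) {
  read_mixture_csv(cfg$input, cfg$outcome, unlist(cfg$mixture),
                   unlist(cfg$covariates), q = cfg$q, link = cfg$link,
                   delim = cfg$delim)
}

config_corr <- function(cfg) {
  src <- cfg$corr
  if (is.null(src)) src <- list(type = "exchangeable", rho = 0.4, c = 38L)
  if (is.list(src) && !is.null(src$type)) src$c <- as.integer(src$c %||% 38L)
  build_correlation(src, halve = isTRUE(cfg$halve))
}

write_weight_csv <- function(summ, path) {
  utils::write.csv(summ$weights, path, row.names = FALSE)
}

#' Execute a configured run and write its artifacts
#'
#' Runs the task named in the config and writes `summary.json`, weight
#' and metric CSV tables, and `run.log` (seeds, defaults filled,
#' warnings) into `out_dir`.
#'
#' @param config A config list, path, or `wqs_run_config` from
#'   [read_run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the result object of the task.
#' @export
run_wqs_pipeline <- function(config, out_dir = ".") {
  cfg <- if (inherits(config, "wqs_run_config")) config else read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("task: %s", cfg$task),
                 sprintf("seed: %d", cfg$seed),
                 sprintf("defaults filled: %s",
                         paste(attr(cfg, "defaults_filled"), collapse = ", ")))
  result <- switch(
    cfg$task,
    fit = , fit2i = {
      md <- load_config_data(cfg)
      df <- data.frame(y = md$y, md$Z, md$Q, check.names = FALSE)
      form <- if (ncol(md$Z)) stats::reformulate(md$covariate_names, "y") else y ~ 1
      fit <- wqs2i(form, df, mixture = md$component_names, q = cfg$q,
                   link = cfg$link, lambda = cfg$lambda, H = cfg$H,
                   B = cfg$B, k = cfg$k,
                   indices = if (cfg$task == "fit2i") "both" else cfg$direction,
                   split = cfg$split, seed = cfg$seed,
                   k_escalate = cfg$k_policy == "escalate",
                   vif_threshold = cfg$vif_threshold, signal = cfg$signal)
      summ <- fit$summary
      write_weight_csv(summ, file.path(out_dir, "weights.csv"))
      warn <- unique(unlist(fit$holdout$warnings))
      log_lines <- c(log_lines, paste("warning:", warn))
      jsonlite::write_json(
        list(coef = summ$coef, lambda = fit$lambda,
             retained = as.list(summ$retained),
             threshold = summ$threshold, seed = cfg$seed),
        file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
      fit
    },
    select_lambda = {
      md <- load_config_data(cfg)
      est <- if (cfg$direction == "both") "two_index"
             else paste0("single_", substr(cfg$direction, 1, 3))
      cfg1 <- list(estimator = est, H = 1L, B = cfg$B, lambda = 0, seed = cfg$seed)
      aic0 <- run_repeated_holdout(md, cfg1)$per_split$aic[1]
      sel <- select_lambda(md, lambda_grid_from_aic(aic0),
                           list(estimator = est, H = cfg$H, B = cfg$B,
                                seed = cfg$seed))
      utils::write.csv(sel$trace, file.path(out_dir, "lambda_trace.csv"),
                       row.names = FALSE)
      jsonlite::write_json(list(best_lambda = sel$best_lambda, aic_unpenalized = aic0),
                           file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
      sel
    },
    qgcomp = {
      md <- load_config_data(cfg)
      qg <- fit_qgcomp(md)
      utils::write.csv(qg$coef_table, file.path(out_dir, "qgcomp_coefs.csv"),
                       row.names = FALSE)
      jsonlite::write_json(list(psi = qg$psi, psi_pos = qg$psi_pos,
                                psi_neg = qg$psi_neg, aic = qg$aic),
                           file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
      qg
    },
    simulate = {
      corr <- config_corr(cfg)
      md <- simulate_dataset(corr, default_truth(), cfg$n, cfg$q, seed = cfg$seed)
      out_csv <- file.path(out_dir, "simulated.csv")
      utils::write.csv(data.frame(y = md$y, md$Q, check.names = FALSE),
                       out_csv, row.names = FALSE)
      jsonlite::write_json(list(n = cfg$n, c = ncol(md$Q), q = cfg$q,
                                seed = cfg$seed, file = basename(out_csv)),
                           file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
      md
    },
    benchmark = {
      corr <- config_corr(cfg)
      lam_pol <- if (identical(cfg$lambda, "aic")) {
        list(type = "aic", selection_H = 3L, selection_B = 10L)
      } else list(type = "fixed", value = cfg$lambda)
      bm <- run_benchmark(corr, default_truth(), n = cfg$n, R = cfg$R,
                          methods = unlist(cfg$methods),
                          fit_config = list(H = cfg$H, B = cfg$B),
                          lambda_policy = lam_pol, q = cfg$q, seed = cfg$seed)
      utils::write.csv(bm$metrics, file.path(out_dir, "metrics.csv"),
                       row.names = FALSE)
      jsonlite::write_json(bm$metrics, file.path(out_dir, "summary.json"),
                           digits = NA)
      bm
    })
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(result)
}
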