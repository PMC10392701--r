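#' Quantile g-computation comparator
#'
#' Fits the unconstrained GLM of the outcome on all quantized components
#' plus covariates and summarizes the mixture effect as coefficient sums:
#' `psi` (all components), `psi_pos` (positive coefficients only) and
#' `psi_neg` (negative coefficients only). The directional sums are the
#' comparator's analogue of the two WQS index coefficients.
#'
#' @param data A [mixture_data()] object; the design `(1, Q, Z)` must be
#'   full rank.
#' @return An object of class `qgcomp_fit`: `per_component_coefs`, `psi`,
#'   `psi_pos`, `psi_neg`, `phi`, `link`, `coef_table`, `aic`.
#' @export
fit_qgcomp <- function(data) {
  fit <- fit_validation_glm(data$y, data$Q, data$Z, data$link)
  coefs <- fit$coef
  comp <- coefs[data$component_names]
  structure(
    list(per_component_coefs = comp,
         psi = sum(comp),
         psi_pos = sum(pmax(comp, 0)),
         psi_neg = sum(pmin(comp, 0)),
         phi = coefs[setdiff(names(coefs), c("(Intercept)", data$component_names))],
         beta0 = unname(coefs["(Intercept)"]),
         link = data$link, coef_table = fit$coef_table, aic = fit$aic),
    class = "qgcomp_fit"
  )
}

#' @export
print.qgcomp_fit <- function(x, ...) {
  cat(sprintf("quantile g-computation fit (%s link)\n", x$link))
  cat(sprintf("  psi = %.4f (positive %.4f, negative %.4f)\n",
              x$psi, x$psi_pos, x$psi_neg))
  invisible(x)
}

#' @export
coef.qgcomp_fit <- function(object, ...) object$per_component_coefs
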