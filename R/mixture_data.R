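#' Quantile-score exposure columns
#'
#' Replaces each raw exposure with its quantile-group rank, the scale-free
#' scoring used to build weighted quantile sum indices. Scores are 0-based
#' (`0 .. q-1`): a one-unit increase in a score means moving up one quantile
#' group. Boundaries are empirical inverted-CDF quantiles (type 1), with
#' tied values assigned to the lower class.
#'
#' @param X Numeric matrix or data frame of raw exposures (n x c), complete
#'   cases only.
#' @param q Number of quantile groups (default 4, i.e. quartiles).
#' @return Integer matrix of scores in `0 .. q-1` with the same dimnames as
#'   `X`, plus an attribute `"breaks"` (the (q-1) x c matrix of cut points)
#'   so new data can be scored on the training boundaries.
#' @examples
#' quantize_columns(cbind(x = 1:8), q = 4)
#' @export
quantize_columns <- function(X, q = 4L) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("exposure matrix must be numeric")
  q <- as.integer(q)
  if (q < 2L) stop("q must be at least 2")
  if (anyNA(X) || any(!is.finite(X))) stop("complete cases required: exposure matrix contains missing or non-finite values")
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("X", seq_len(ncol(X)))
  probs <- seq_len(q - 1L) / q
  breaks <- matrix(NA_real_, q - 1L, ncol(X), dimnames = list(NULL, cn))
  S <- matrix(0L, nrow(X), ncol(X), dimnames = list(rownames(X), cn))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    if (length(unique(x)) < q) {
      stop(sprintf("cannot form q groups: column '%s' has fewer than %d distinct values", cn[j], q))
    }
    br <- stats::quantile(x, probs, type = 1, names = FALSE)
    sc <- score_with_breaks(x, br)
    if (length(unique(sc)) < q) {
      stop(sprintf("cannot form q groups: column '%s' yields an empty quantile class (heavy ties)", cn[j]))
    }
    breaks[, j] <- br
    S[, j] <- sc
  }
  attr(S, "breaks") <- breaks
  S
}

## ties go to the lower class: score = number of strictly exceeded cut points
score_with_breaks <- function(x, br) {
  as.integer(rowSums(outer(x, br, ">")))
}

#' Construct a mixture analysis data set
#'
#' Bundles the outcome, quantized exposure matrix and covariates used by all
#' estimators in the package. Exposures are quantile-scored on construction
#' unless `already_quantized = TRUE`.
#'
#' @param y Outcome vector: continuous for `link = "identity"`, 0/1 for
#'   `link = "logit"`.
#' @param X Raw exposure matrix/data frame (n x c), or an integer score
#'   matrix when `already_quantized = TRUE`.
#' @param Z Optional covariate matrix/data frame (n x p); must be numeric
#'   (factors should be expanded to indicators by the caller, e.g. via
#'   [stats::model.matrix()]).
#' @param q Number of quantile groups.
#' @param link `"identity"` (continuous outcome) or `"logit"` (binary).
#' @param already_quantized Set `TRUE` when `X` already holds integer scores
#'   in `0 .. q-1`.
#' @return An object of class `mixture_data` with elements `y`, `Q`, `Z`,
#'   `component_names`, `covariate_names`, `q`, `link`, `breaks`.
#' @export
mixture_data <- function(y, X, Z = NULL, q = 4L, link = c("identity", "logit"),
                         already_quantized = FALSE) {
  link <- match.arg(link)
  y <- as.numeric(y)
  q <- as.integer(q)
  if (anyNA(y)) stop("complete cases required: outcome contains missing values")
  if (link == "logit" && !all(y %in% c(0, 1))) {
    stop("link = 'logit' requires a 0/1 outcome")
  }
  breaks <- NULL
  if (already_quantized) {
    Q <- as.matrix(X)
    storage.mode(Q) <- "integer"
    if (anyNA(Q) || any(Q < 0L) || any(Q > q - 1L)) {
      stop("quantized scores must be integers in 0..q-1")
    }
  } else {
    Q <- quantize_columns(X, q)
    breaks <- attr(Q, "breaks")
    attr(Q, "breaks") <- NULL
  }
  if (is.null(colnames(Q))) colnames(Q) <- paste0("X", seq_len(ncol(Q)))
  if (ncol(Q) < 2L) stop("need at least 2 mixture components")
  if (is.null(Z)) {
    Z <- matrix(numeric(0), nrow = length(y), ncol = 0)
  } else {
    Z <- as.matrix(Z)
    if (!is.numeric(Z)) stop("covariates must be numeric")
    if (anyNA(Z)) stop("complete cases required: covariates contain missing values")
    if (is.null(colnames(Z)) && ncol(Z) > 0) colnames(Z) <- paste0("Z", seq_len(ncol(Z)))
  }
  if (length(y) != nrow(Q) || length(y) != nrow(Z)) {
    stop("y, X and Z must have the same number of rows")
  }
  comp <- colnames(Q)
  cov <- colnames(Z)
  if (anyDuplicated(comp)) stop("component names must be unique")
  if (length(intersect(comp, cov))) stop("component and covariate names must be disjoint")
  structure(
    list(y = y, Q = Q, Z = Z, component_names = comp,
         covariate_names = cov, q = q, link = link, breaks = breaks),
    class = "mixture_data"
  )
}

#' @export
print.mixture_data <- function(x, ...) {
  cat(sprintf("mixture_data: n = %d, %d components (q = %d), %d covariates, link = %s\n",
              length(x$y), ncol(x$Q), x$q, ncol(x$Z), x$link))
  invisible(x)
}

#' @export
dim.mixture_data <- function(x) c(length(x$y), ncol(x$Q))

## row subsetting used by splits and bootstraps
subset_rows <- function(data, idx) {
  out <- data
  out$y <- data$y[idx]
  out$Q <- data$Q[idx, , drop = FALSE]
  out$Z <- data$Z[idx, , drop = FALSE]
  out
}

#' Read a mixture data set from CSV
#'
#' @param path CSV file with a header row.
#' @param outcome Name of the outcome column.
#' @param mixture Either a character vector of exposure column names or a
#'   single prefix pattern like `"nutr_*"` (trailing `*` matches any suffix).
#' @param covariates Optional character vector of covariate column names.
#' @param q,link Passed to [mixture_data()].
#' @param delim Field delimiter (default comma).
#' @return A [mixture_data()] object.
#' @export
read_mixture_csv <- function(path, outcome, mixture, covariates = character(),
                             q = 4L, link = c("identity", "logit"), delim = ",") {
  link <- match.arg(link)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (length(mixture) == 1L && grepl("\\*$", mixture)) {
    prefix <- sub("\\*$", "", mixture)
    mixture <- names(df)[startsWith(names(df), prefix)]
    if (!length(mixture)) stop(sprintf("no columns match prefix '%s'", prefix))
  }
  missing_cols <- setdiff(c(outcome, mixture, covariates), names(df))
  if (length(missing_cols)) {
    stop("missing columns in input: ", paste(missing_cols, collapse = ", "))
  }
  Z <- if (length(covariates)) df[covariates] else NULL
  mixture_data(df[[outcome]], df[mixture], Z, q = q, link = link)
}

#' Write the quantized exposure matrix to CSV
#'
#' @param data A [mixture_data()] object.
#' @param path Output file.
#' @export
write_quantized_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data$Q), path, row.names = FALSE)
  invisible(path)
}
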