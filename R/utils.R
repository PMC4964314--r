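#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from integer seeds. Independent named
#' streams (design generation, response noise, subsampling, fold assignment,
#' bootstrap indices) are derived from a master seed with a fixed integer
#' hash so that changing one stream never perturbs another.
#'
#' @param seed Master integer seed.
#' @param key Character stream name, or an integer offset.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (is.character(key)) {
    key <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  }
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  as.integer((((abs(seed) %% m) * 48271) %% m + (key * 69621) %% m) %% m)
}

# Split a data frame into a numeric design matrix and response vector.
# `response` may be absent (design-only data). Predictor columns are all
# numeric columns except the response.
as_design <- function(data, response = "y", require_response = TRUE) {
  stopifnot(is.data.frame(data))
  has_y <- response %in% names(data)
  if (require_response && !has_y) {
    stop("response column '", response, "' not found in `data`", call. = FALSE)
  }
  pred_cols <- setdiff(names(data), response)
  keep <- vapply(data[pred_cols], is.numeric, logical(1))
  pred_cols <- pred_cols[keep]
  if (length(pred_cols) == 0) stop("no numeric predictor columns", call. = FALSE)
  X <- as.matrix(data[pred_cols])
  if (anyNA(X)) stop("missing values in predictors", call. = FALSE)
  y <- if (has_y) {
    yv <- data[[response]]
    if (!is.numeric(yv)) stop("response must be numeric", call. = FALSE)
    if (anyNA(yv)) stop("missing values in response", call. = FALSE)
    as.numeric(yv)
  } else NULL
  list(X = X, y = y, terms = pred_cols)
}

#' Standardize predictor columns
#'
#' Centers each predictor to mean 0 and scales to sample standard deviation 1
#' (denominator `n - 1`). The response column, if present, is left untouched.
#' Standardizing an already standardized table is a numerical no-op.
#'
#' @param data Data frame of predictors (optionally including the response).
#' @param response Name of the response column to exclude (default `"y"`).
#' @return A tibble with standardized predictor columns.
#' @export
standardize_predictors <- function(data, response = "y") {
  d <- as_design(data, response, require_response = FALSE)
  X <- scale(d$X)
  bad <- !is.finite(attr(X, "scaled:scale")) | attr(X, "scaled:scale") < 1e-12
  if (any(bad)) {
    stop("constant predictor column(s): ", paste(d$terms[bad], collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  out[d$terms] <- as.data.frame(X)[d$terms]
  out
}

# Method label used throughout reports: OLS, ridge, enet(alpha), lasso.
method_label <- function(alpha) {
  if (is.null(alpha) || (length(alpha) == 1 && is.na(alpha))) return("OLS")
  stopifnot(alpha >= 0, alpha <= 1)
  if (alpha == 0) "ridge" else if (alpha == 1) "lasso" else sprintf("enet(%g)", alpha)
}

# The six-method family: OLS plus five elastic-net mixing values.
# Represented as a named list of alpha values with NA meaning OLS.
#' Standard six-method family
#'
#' The method family compared throughout: OLS (unpenalized), ridge
#' (`alpha = 0`), elastic net (`alpha` = 0.25, 0.5, 0.75) and lasso
#' (`alpha = 1`). `NA` encodes OLS.
#'
#' @return Named numeric vector of `alpha` values (`NA` = OLS).
#' @export
method_family <- function() {
  alphas <- c(NA, 0, 0.25, 0.5, 0.75, 1)
  setNames(alphas, vapply(alphas, method_label, character(1)))
}

#' Default significance threshold grid
#'
#' Thresholds `1 - alpha*` from 0.50 to 0.95 in steps of 0.05.
#'
#' @return Numeric vector of thresholds.
#' @export
default_thresholds <- function() seq(0.50, 0.95, by = 0.05)
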