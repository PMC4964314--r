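#' Fit ordinary least squares
#'
#' Minimizes the residual sum of squares with an unpenalized intercept. When
#' the design is rank-deficient (possible whenever bootstrap resampling with
#' `n` close to `p` duplicates rows), the minimum-norm least-squares solution
#' is returned, computed via a rank-revealing SVD pseudo-inverse.
#'
#' @param data Data frame containing the predictors and the response.
#' @param response Name of the response column (default `"y"`).
#' @return An object of class `enet_fit` with elements `intercept`,
#'   `coefficients` (named slopes), `zero_pattern` (exact-zero mask),
#'   `alpha` (`NA` for OLS), `lambda`, `method` and `n`.
#' @examples
#' d <- simulate_design(50, 5, seed = 1) |> simulate_response(c(x2 = 1), seed = 1)
#' fit_ols(d)
#' @export
fit_ols <- function(data, response = "y") {
  d <- as_design(data, response)
  if (nrow(d$X) < 2) stop("need at least 2 rows", call. = FALSE)
  slopes <- as.numeric(cpp_ols_minnorm(d$X, d$y))
  new_enet_fit(slopes, d, alpha = NA_real_, lambda = 0)
}

#' Fit a penalized linear model at a fixed penalty
#'
#' Minimizes the scaled elastic-net objective
#' \deqn{\frac{1}{2n}\sum_i (y_i - \beta_0 - x_i'\beta)^2 +
#'   \lambda\left[\tfrac{1-\alpha}{2}\|\beta\|_2^2 + \alpha\|\beta\|_1\right]}
#' by cyclic coordinate descent with warm starts along a decreasing
#' `lambda` path ending at the requested value. `alpha = 0` is ridge,
#' `alpha = 1` the lasso, intermediate values the elastic net; the intercept
#' is never penalized. Coefficients eliminated by soft-thresholding are exact
#' zeros (the sparsity pattern is bitwise, not thresholded). With the raw-RSS
#' objective convention the same solution corresponds to penalty `2n * lambda`.
#'
#' @inheritParams fit_ols
#' @param alpha Elastic-net mixing parameter in `[0, 1]`.
#' @param lambda Penalty weight (`>= 0`). `lambda = 0` reduces to [fit_ols()].
#' @return An `enet_fit` object.
#' @export
fit_penalized <- function(data, response = "y", alpha, lambda) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0, alpha <= 1,
            is.numeric(lambda), length(lambda) == 1, lambda >= 0,
            is.finite(alpha), is.finite(lambda))
  if (lambda == 0) {
    fit <- fit_ols(data, response)
    fit$alpha <- alpha
    fit$method <- method_label(alpha)
    return(fit)
  }
  d <- as_design(data, response)
  if (!all(is.finite(d$X)) || !all(is.finite(d$y))) {
    stop("non-finite values in input", call. = FALSE)
  }
  # warm-started descent from above: a short path ending at the target lambda
  lmax <- lambda_max(d$X, d$y, alpha)
  path <- if (lmax > lambda) {
    unique(c(exp(seq(log(lmax), log(lambda), length.out = 20)), lambda))
  } else lambda
  betas <- cpp_enet_path(d$X, d$y, alpha, path)
  new_enet_fit(betas[, length(path)], d, alpha = alpha, lambda = lambda)
}

# lambda_max such that all slopes are zero for alpha > 0, with the mixing
# parameter floored at 0.001 for path construction so ridge gets a finite path.
lambda_max <- function(X, y, alpha) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  max(abs(crossprod(Xc, yc))) / (nrow(X) * max(alpha, 0.001))
}

#' Build a decreasing regularization path
#'
#' Log-spaced sequence of `n_values` penalty weights from
#' `lambda_max = max_j |x_j'y| / (n * max(alpha, 0.001))` down to
#' `lambda_max * ratio`. At the top of the path any `alpha > 0` fit has every
#' slope exactly zero (intercept-only model); the bottom of the path retains
#' all predictors. The default `ratio` is `1e-4` when `n > p` and `1e-2`
#' otherwise.
#'
#' @inheritParams fit_penalized
#' @param n_values Path length (default 100).
#' @param ratio `lambda_min / lambda_max`; default as described above.
#' @return Numeric vector of strictly decreasing positive penalties.
#' @export
lambda_path <- function(data, response = "y", alpha, n_values = 100,
                        ratio = NULL) {
  d <- as_design(data, response)
  if (var(d$y) < 1e-24) stop("response is constant: lambda_max is 0", call. = FALSE)
  lmax <- lambda_max(d$X, d$y, alpha)
  if (lmax <= 0) stop("all predictors uncorrelated with response", call. = FALSE)
  if (is.null(ratio)) ratio <- if (nrow(d$X) > ncol(d$X)) 1e-4 else 1e-2
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_values))
}

new_enet_fit <- function(slopes, d, alpha, lambda) {
  slopes <- setNames(as.numeric(slopes), d$terms)
  xm <- colMeans(d$X)
  structure(
    list(
      intercept = mean(d$y) - sum(xm * slopes),
      coefficients = slopes,
      zero_pattern = slopes == 0,
      alpha = alpha,
      lambda = lambda,
      method = method_label(alpha),
      n = nrow(d$X)
    ),
    class = "enet_fit"
  )
}

#' @export
print.enet_fit <- function(x, ...) {
  cat(sprintf("<enet_fit> %s, lambda = %.6g, n = %d, nonzero slopes = %d/%d\n",
              x$method, x$lambda, x$n, sum(!x$zero_pattern),
              length(x$coefficients)))
  invisible(x)
}

#' @describeIn fit_ols Tidy the coefficients of a fitted model into a tibble
#'   with columns `term`, `estimate` and `zero` (exact-zero indicator); the
#'   intercept appears as term `"(Intercept)"`.
#' @param x An `enet_fit` object.
#' @param ... Unused.
#' @export
tidy.enet_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients)),
    zero = c(FALSE, unname(x$zero_pattern))
  )
}

#' @describeIn fit_ols One-row model summary.
#' @export
glance.enet_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    alpha = x$alpha,
    lambda = x$lambda,
    n = x$n,
    n_nonzero = sum(!x$zero_pattern)
  )
}

#' Predict from a penalized fit
#'
#' @param object An `enet_fit`.
#' @param newdata Data frame containing the predictor columns.
#' @param ... Unused.
#' @return Numeric vector of fitted values.
#' @export
predict.enet_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata[names(object$coefficients)])
  as.numeric(object$intercept + X %*% object$coefficients)
}

#' Serialize a fit to JSON and back
#'
#' Stores `alpha`, `lambda`, the intercept, named slopes and the exact-zero
#' pattern; the round trip reproduces the fit object.
#'
#' @param fit An `enet_fit`.
#' @param path JSON file path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "enet_fit"))
  jsonlite::write_json(
    list(alpha = fit$alpha, lambda = fit$lambda, intercept = fit$intercept,
         slopes = as.list(fit$coefficients),
         zero_pattern = as.list(fit$zero_pattern), n = fit$n),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  alpha <- if (is.null(raw$alpha)) NA_real_ else raw$alpha
  slopes <- unlist(raw$slopes)
  structure(
    list(intercept = raw$intercept, coefficients = slopes,
         zero_pattern = setNames(unlist(raw$zero_pattern), names(slopes)),
         alpha = alpha, lambda = raw$lambda,
         method = method_label(alpha), n = raw$n),
    class = "enet_fit"
  )
}

# Objective value of a fit on given data (used by tests and certificates).
enet_objective <- function(data, response, intercept, slopes, alpha, lambda) {
  d <- as_design(data, response)
  r <- d$y - intercept - as.numeric(d$X %*% slopes)
  pen <- if (is.na(alpha)) 0 else {
    lambda * ((1 - alpha) / 2 * sum(slopes^2) + alpha * sum(abs(slopes)))
  }
  sum(r^2) / (2 * length(r)) + pen
}
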