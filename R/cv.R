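#' Choose the penalty weight by k-fold cross-validation
#'
#' Partitions the rows into `k` near-equal folds (deterministically from
#' `seed`), fits the regularization path on each training set and scores the
#' held-out fold, and picks the penalty minimizing the cross-validated mean
#' squared error (CV-MSE). Exact ties are broken toward the larger penalty
#' (the sparser model). Training folds are re-standardized internally so no
#' information leaks from held-out rows.
#'
#' @inheritParams fit_penalized
#' @param k Number of folds (`>= 2`, default 5); `k = n` gives leave-one-out.
#' @param seed Integer seed for the fold assignment.
#' @param n_values,ratio Passed to [lambda_path()].
#' @return An object of class `enet_cv`: a list with `path` (tibble of
#'   `lambda`, `cv_mse`, `cv_mse_se`), `chosen_lambda`, `fit` (the full-data
#'   [fit_penalized()] refit at `chosen_lambda`), `alpha`, `k` and `fold_seed`.
#' @examples
#' d <- simulate_design(60, 6, seed = 1) |> simulate_response(c(x2 = 1), seed = 1)
#' cv <- cv_lambda(d, alpha = 1, seed = 3)
#' glance(cv)
#' @export
cv_lambda <- function(data, response = "y", alpha, k = 5, seed = 1,
                      n_values = 100, ratio = NULL) {
  d <- as_design(data, response)
  n <- nrow(d$X)
  stopifnot(k >= 2)
  if (n < 2 * k && k < n) stop("need n >= 2k for ", k, "-fold CV", call. = FALSE)
  if (k > n) stop("more folds than rows", call. = FALSE)
  if (var(d$y) < 1e-24) stop("response is constant", call. = FALSE)

  path <- lambda_path(data, response, alpha, n_values = n_values, ratio = ratio)
  set.seed(substream_seed(seed, "folds"))
  foldid <- sample(rep_len(seq_len(k), n))

  mse <- cpp_cv_mse(d$X, d$y, alpha, path, as.integer(foldid))
  cv_mse <- colMeans(mse)
  cv_se <- apply(mse, 2, sd) / sqrt(k)
  best <- which(cv_mse == min(cv_mse))[1] # path decreasing: first = largest
  chosen <- path[best]

  structure(
    list(
      path = tibble::tibble(lambda = path, cv_mse = cv_mse, cv_mse_se = cv_se),
      chosen_lambda = chosen,
      cv_mse_min = cv_mse[best],
      fit = fit_penalized(data, response, alpha = alpha, lambda = chosen),
      alpha = alpha,
      k = k,
      fold_seed = seed,
      foldid = foldid
    ),
    class = "enet_cv"
  )
}

#' @export
print.enet_cv <- function(x, ...) {
  cat(sprintf(
    "<enet_cv> %s, %d-fold CV over %d lambdas: chosen lambda = %.6g (CV-MSE %.4g)\n",
    method_label(x$alpha), x$k, nrow(x$path), x$chosen_lambda, x$cv_mse_min))
  invisible(x)
}

#' @describeIn cv_lambda CV curve as a tibble (`lambda`, `cv_mse`, `cv_mse_se`).
#' @param x An `enet_cv` object.
#' @param ... Unused.
#' @export
tidy.enet_cv <- function(x, ...) x$path

#' @describeIn cv_lambda One-row summary of the tuning result.
#' @export
glance.enet_cv <- function(x, ...) {
  tibble::tibble(
    method = method_label(x$alpha),
    alpha = x$alpha,
    k = x$k,
    chosen_lambda = x$chosen_lambda,
    cv_mse_min = x$cv_mse_min,
    n_nonzero = sum(!x$fit$zero_pattern)
  )
}

#' @describeIn cv_lambda Plot the CV-MSE curve against `log(lambda)` with
#'   one-standard-error ribbons and the chosen penalty marked.
#' @param object An `enet_cv` object.
#' @export
autoplot.enet_cv <- function(object, ...) {
  ggplot2::ggplot(object$path, ggplot2::aes(log(.data$lambda), .data$cv_mse)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$cv_mse - .data$cv_mse_se,
                   ymax = .data$cv_mse + .data$cv_mse_se),
      fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(object$chosen_lambda),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(log(lambda)), y = "CV-MSE",
                  title = method_label(object$alpha))
}
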