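#' Bootstrap the coefficients of a (penalized) regression
#'
#' Nonparametric bootstrap over subjects: each replicate draws `n` rows with
#' replacement, re-standardizes the resampled predictors, re-tunes the
#' penalty by k-fold cross-validation on the resample (the canonical
#' procedure; `retune_lambda = FALSE` is a labelled fast mode that reuses the
#' full-data penalty), fits at the chosen penalty, and stores the slope
#' estimates in the original column order. No bias-correction refit is
#' applied inside replicates: the bootstrap distribution reflects the
#' penalized estimates themselves, and bias correction is reserved for the
#' final post-selection refit ([bias_corrected_refit()]).
#'
#' A replicate whose resample contains a constant predictor column gets a
#' zero slope for that column and is counted as degenerate; more than 10%
#' degenerate replicates is an error.
#'
#' @inheritParams fit_ols
#' @param alpha Elastic-net mixing parameter in `[0, 1]`, or `NA` for OLS
#'   (no penalty, minimum-norm least squares per replicate).
#' @param B Number of bootstrap replicates (default 5000).
#' @param retune_lambda Re-tune the penalty by CV inside every replicate
#'   (default `TRUE`). `FALSE` reuses the full-data CV-chosen penalty.
#' @param cv_folds Folds for the per-replicate CV (default 5).
#' @param seed Master integer seed; index draws and per-replicate fold
#'   assignments use independent substreams.
#' @param n_values,ratio Regularization path controls, as in [lambda_path()].
#' @param indices Optional n x B integer matrix (or list of B index vectors)
#'   of explicit resample indices, bypassing the RNG. Intended for testing.
#' @return An object of class `be_boot`: list with `estimates` (B x p matrix,
#'   columns named by predictor), `method`, `alpha`, `lambdas` (chosen
#'   penalty per replicate, `NA` for OLS), `B`, `n`, `seed`,
#'   `n_degenerate` and `retune_lambda`.
#' @examples
#' d <- simulate_design(40, 5, seed = 1) |> simulate_response(c(x2 = 1), seed = 1)
#' bb <- bootstrap_fit(d, alpha = 1, B = 25, seed = 2)
#' vip(bb)
#' @export
bootstrap_fit <- function(data, response = "y", alpha = 1, B = 5000,
                          retune_lambda = TRUE, cv_folds = 5, seed = 1,
                          n_values = 100, ratio = NULL, indices = NULL) {
  stopifnot(B >= 1, cv_folds >= 2)
  d <- as_design(data, response)
  n <- nrow(d$X); p <- ncol(d$X)
  is_ols <- is.null(alpha) || is.na(alpha)

  if (is.null(indices)) {
    set.seed(substream_seed(seed, "boot-indices"))
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n, ncol = B)
  } else {
    if (is.list(indices)) indices <- do.call(cbind, indices)
    idx <- matrix(as.integer(indices), nrow = n)
    stopifnot(ncol(idx) == B, all(idx >= 1), all(idx <= n))
  }

  if (is_ols) {
    res <- cpp_boot_ols(d$X, d$y, idx)
    lambdas <- rep(NA_real_, B)
  } else {
    stopifnot(alpha >= 0, alpha <= 1)
    # per-replicate substream for fold assignment: independent, reproducible
    foldid <- matrix(0L, nrow = n, ncol = B)
    for (b in seq_len(B)) {
      set.seed(substream_seed(seed, b))
      foldid[, b] <- sample(rep_len(seq_len(cv_folds), n))
    }
    if (is.null(ratio)) ratio <- if (n > p) 1e-4 else 1e-2
    fixed <- 0
    if (!retune_lambda) {
      fixed <- cv_lambda(data, response, alpha = alpha, k = cv_folds,
                         seed = substream_seed(seed, "full-cv"),
                         n_values = n_values, ratio = ratio)$chosen_lambda
    }
    res <- cpp_boot_enet(d$X, d$y, idx, foldid, alpha, as.integer(n_values),
                         ratio, retune_lambda, fixed)
    lambdas <- as.numeric(res$lambdas)
  }

  n_degen <- sum(res$degenerate)
  if (n_degen > 0.10 * B) {
    stop(n_degen, " of ", B, " bootstrap replicates were degenerate ",
         "(constant column or zero signal)", call. = FALSE)
  }
  if (n_degen > 0) {
    warning(n_degen, " degenerate bootstrap replicate(s); affected slopes set to 0",
            call. = FALSE)
  }

  est <- res$estimates
  colnames(est) <- d$terms
  structure(
    list(
      estimates = est,
      method = method_label(if (is_ols) NA else alpha),
      alpha = if (is_ols) NA_real_ else alpha,
      lambdas = lambdas,
      B = B, n = n, seed = seed,
      retune_lambda = if (is_ols) NA else retune_lambda,
      n_degenerate = n_degen
    ),
    class = "be_boot"
  )
}

#' @export
print.be_boot <- function(x, ...) {
  cat(sprintf("<be_boot> %s: B = %d replicates, %d predictors, n = %d\n",
              x$method, x$B, ncol(x$estimates), x$n))
  invisible(x)
}

#' @describeIn bootstrap_fit Long tibble of bootstrap estimates
#'   (`replicate`, `term`, `estimate`).
#' @param x A `be_boot` object.
#' @param ... Unused.
#' @export
tidy.be_boot <- function(x, ...) {
  tibble::as_tibble(x$estimates) |>
    dplyr::mutate(replicate = dplyr::row_number(), .before = 1) |>
    tidyr::pivot_longer(-"replicate", names_to = "term", values_to = "estimate")
}

#' Write / read a bootstrap distribution as CSV (audit format)
#'
#' B rows by p columns, header = predictor names.
#'
#' @param boot A `be_boot` object.
#' @param path File path.
#' @export
write_bootstrap_csv <- function(boot, path) {
  readr::write_csv(tibble::as_tibble(boot$estimates), path)
  invisible(path)
}

#' @rdname write_bootstrap_csv
#' @export
read_bootstrap_csv <- function(path) {
  as.matrix(readr::read_csv(path, show_col_types = FALSE))
}
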