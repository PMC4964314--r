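#' Simulate a correlated standardized design matrix
#'
#' Generates an `n_subjects` x `n_predictors` table of standardized,
#' positively inter-correlated predictors emulating the statistical structure
#' of ICA-derived network-coherence metrics: all pairwise correlations
#' positive, with the empirical off-diagonal correlation range falling inside
#' `[corr_low - 0.07, corr_high + 0.07]`.
#'
#' The generator uses a one-factor model `x_j = l_j * f + sqrt(1 - l_j^2) * e_j`
#' with loadings `l_j` drawn uniformly on a calibrated interval (starting at
#' `[0.45, 0.9]`). The interval endpoints are nudged for up to `max_attempts`
#' attempts until the empirical correlation range lands in the target window;
#' a single common factor yields the all-positive, wide-range correlation
#' profile typical of within-scan coherence metrics with one calibration knob.
#'
#' @param n_subjects Number of rows (default 122).
#' @param n_predictors Number of predictor columns (default 27).
#' @param corr_low,corr_high Target bounds for the off-diagonal correlation
#'   range (defaults 0.14 and 0.77); require `0 <= corr_low < corr_high < 1`.
#' @param seed Integer seed; the design stream is independent of response and
#'   subsampling streams.
#' @param max_attempts Calibration attempts before failing (default 50).
#' @return A tibble with columns `x1 ... xp`, each mean 0 and sample SD 1.
#' @examples
#' X <- simulate_design(n_subjects = 60, n_predictors = 8, seed = 1)
#' range(cor(X)[lower.tri(cor(X))])
#' @export
simulate_design <- function(n_subjects = 122, n_predictors = 27,
                            corr_low = 0.14, corr_high = 0.77,
                            seed = 1, max_attempts = 50) {
  stopifnot(n_subjects >= 3, n_predictors >= 1,
            corr_low >= 0, corr_low < corr_high, corr_high < 1)
  lo_target <- corr_low - 0.07
  hi_target <- corr_high + 0.07
  interval <- c(0.45, 0.90)

  draw <- function(attempt, interval) {
    set.seed(substream_seed(seed, paste0("design", attempt)))
    loadings <- stats::runif(n_predictors, interval[1], interval[2])
    f <- rnorm(n_subjects)
    E <- matrix(rnorm(n_subjects * n_predictors), n_subjects)
    X <- sweep(E, 2, sqrt(1 - loadings^2), `*`) +
      tcrossprod(f, loadings)
    scale(X)
  }

  for (attempt in seq_len(max_attempts)) {
    X <- draw(attempt, interval)
    if (n_predictors == 1) break # no off-diagonals to calibrate
    r <- cor(X)[lower.tri(diag(n_predictors))]
    ok <- all(r > 0) && min(r) >= lo_target && max(r) <= hi_target
    if (ok) break
    # nudge the loading interval toward the target window
    if (min(r) < lo_target) interval[1] <- min(interval[1] + 0.03, interval[2] - 0.05)
    if (min(r) > corr_low + 0.07) interval[1] <- max(interval[1] - 0.03, 0.05)
    if (max(r) > hi_target) interval[2] <- max(interval[2] - 0.03, interval[1] + 0.05)
    if (max(r) < corr_high - 0.07) interval[2] <- min(interval[2] + 0.03, 0.99)
    if (attempt == max_attempts) {
      stop("could not calibrate the design to the correlation window [",
           lo_target, ", ", hi_target, "] in ", max_attempts, " attempts",
           call. = FALSE)
    }
  }
  colnames(X) <- paste0("x", seq_len(n_predictors))
  tibble::as_tibble(as.data.frame(X))
}

#' Simulate a response from a sparse linear model
#'
#' Adds a response column `y = sum_j beta_j x_j + eps`, `eps ~ N(0, sigma^2)`,
#' to a standardized design. The default active set places coefficients 0.3
#' and -0.4 on predictors 7 and 14, the two-active-predictor regime used in
#' the Monte Carlo study; all other predictors are inactive (coefficient 0).
#'
#' @param design Data frame of standardized predictors (e.g. from
#'   [simulate_design()]).
#' @param coefs Named numeric vector of nonzero true coefficients; names must
#'   be predictor columns of `design`. Default `c(x7 = 0.3, x14 = -0.4)`.
#' @param sigma Error standard deviation (`>= 0`, default 1).
#' @param seed Integer seed for the noise stream.
#' @param response Name of the response column to create (default `"y"`).
#' @return `design` with the response column appended.
#' @examples
#' d <- simulate_design(60, 8, seed = 1) |>
#'   simulate_response(coefs = c(x2 = 0.5), sigma = 0.5, seed = 2)
#' @export
simulate_response <- function(design, coefs = c(x7 = 0.3, x14 = -0.4),
                              sigma = 1, seed = 1, response = "y") {
  stopifnot(is.data.frame(design), sigma >= 0, !is.null(names(coefs)))
  missing_terms <- setdiff(names(coefs), names(design))
  if (length(missing_terms) > 0) {
    stop("active predictor(s) not in design: ",
         paste(missing_terms, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(coefs))) stop("duplicate active predictors", call. = FALSE)
  n <- nrow(design)
  mu <- as.matrix(design[names(coefs)]) %*% coefs
  set.seed(substream_seed(seed, "response"))
  out <- tibble::as_tibble(design)
  out[[response]] <- as.numeric(mu) + rnorm(n, 0, sigma)
  out
}

#' Subsample rows without replacement
#'
#' Draws `n` distinct rows uniformly at random and re-standardizes the
#' predictor columns of the subsample, so downstream fits always see
#' mean-0 / SD-1 predictors. The response column is carried through unchanged.
#'
#' @param data Data frame of predictors, optionally with a response column.
#' @param n Number of rows to keep (`n <= nrow(data)`).
#' @param seed Integer seed for the subsampling stream.
#' @param response Name of the response column (default `"y"`).
#' @return A tibble with `n` rows and re-standardized predictors.
#' @export
subsample_rows <- function(data, n, seed = 1, response = "y") {
  stopifnot(is.data.frame(data))
  if (n > nrow(data)) {
    stop("requested ", n, " rows but only ", nrow(data), " available",
         call. = FALSE)
  }
  set.seed(substream_seed(seed, "subsample"))
  idx <- sample.int(nrow(data), n, replace = FALSE)
  standardize_predictors(data[idx, , drop = FALSE], response = response)
}

#' Write / read a design (with optional response) as CSV
#'
#' Plain comma-separated text with a header row; numeric columns only.
#'
#' @param data Data frame to write.
#' @param path File path.
#' @return `write_design_csv()` returns `path` invisibly; `read_design_csv()`
#'   returns a tibble.
#' @export
write_design_csv <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
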