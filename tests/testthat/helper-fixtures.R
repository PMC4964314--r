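# Shared fixtures and independent oracles for the test suite.

# Small random regression instance with standardized predictors.
make_instance <- function(n, p, seed = 1, sigma = 0.5, beta = NULL) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * p), n, p))
  colnames(X) <- paste0("x", seq_len(p))
  if (is.null(beta)) beta <- rep(0, p)
  y <- as.numeric(X %*% beta + rnorm(n, 0, sigma))
  d <- tibble::as_tibble(as.data.frame(X))
  d$y <- y
  d
}

# Design whose centered columns satisfy X'X / n = I (orthonormal in the
# 1/n inner product), so the lasso solution is elementwise soft-thresholding.
make_orthonormal_instance <- function(n, p, seed = 1, beta = NULL, sigma = 0) {
  set.seed(seed)
  M <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  Q <- qr.Q(qr(M)) * sqrt(n) # columns: mean ~0, x_j'x_j = n
  colnames(Q) <- paste0("x", seq_len(p))
  if (is.null(beta)) beta <- rep(0, p)
  y <- as.numeric(Q %*% beta + rnorm(n, 0, sigma))
  d <- tibble::as_tibble(as.data.frame(Q))
  d$y <- y
  d
}

# Objective the solver minimizes, evaluated directly.
objective_value <- function(data, fit, response = "y") {
  X <- as.matrix(data[names(fit$coefficients)])
  r <- data[[response]] - fit$intercept - as.numeric(X %*% fit$coefficients)
  pen <- if (is.na(fit$alpha)) 0 else {
    fit$lambda * ((1 - fit$alpha) / 2 * sum(fit$coefficients^2) +
                    fit$alpha * sum(abs(fit$coefficients)))
  }
  sum(r^2) / (2 * nrow(data)) + pen
}

# Brute-force type-1 quantile by scanning order statistics against the
# indicator-sum definition: smallest order statistic whose ECDF reaches prob.
scan_quantile <- function(x, prob) {
  xs <- sort(x)
  B <- length(xs)
  for (v in xs) {
    if (sum(x <= v) / B >= prob - 1e-15) return(v)
  }
  xs[B]
}

# Wrap a raw estimates matrix as a bootstrap-distribution object.
fake_boot <- function(estimates, method = "lasso") {
  if (is.null(colnames(estimates))) {
    colnames(estimates) <- paste0("x", seq_len(ncol(estimates)))
  }
  structure(
    list(estimates = estimates, method = method,
         alpha = if (method == "lasso") 1 else NA_real_,
         lambdas = rep(NA_real_, nrow(estimates)),
         B = nrow(estimates), n = NA_integer_, seed = NA_integer_,
         retune_lambda = NA, n_degenerate = 0L),
    class = "be_boot"
  )
}
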