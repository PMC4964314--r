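test_that("OLS recovers exact and generic least-squares solutions", {
  # exact single-predictor line
  x <- scale(rnorm(20))[, 1]
  d <- tibble::tibble(x1 = x, y = 2 * x + 3)
  f <- fit_ols(d)
  expect_equal(unname(f$coefficients["x1"]), 2, tolerance = 1e-10)
  expect_equal(f$intercept, mean(d$y), tolerance = 1e-10)

  # random full-rank instance vs normal equations
  d6 <- make_instance(6, 3, seed = 2)
  f6 <- fit_ols(d6)
  X <- cbind(1, as.matrix(d6[paste0("x", 1:3)]))
  ne <- solve(crossprod(X), crossprod(X, d6$y))
  expect_lt(max(abs(c(f6$intercept, f6$coefficients) - ne)), 1e-8)
})

test_that("rank-deficient OLS returns the minimum-norm solution", {
  d <- make_instance(10, 2, seed = 3, beta = c(1, 0))
  d$x3 <- d$x2 # duplicated column
  f <- fit_ols(d)
  # pseudo-inverse oracle splits the duplicated weight equally
  X <- scale(as.matrix(d[c("x1", "x2", "x3")]), scale = FALSE)
  pinv_beta <- as.numeric(MASS::ginv(X) %*% (d$y - mean(d$y)))
  expect_lt(max(abs(unname(f$coefficients) - pinv_beta)), 1e-8)
  expect_equal(unname(f$coefficients["x2"]), unname(f$coefficients["x3"]),
               tolerance = 1e-8)
})

test_that("zero penalty reduces to OLS for any mixing parameter", {
  d <- make_instance(25, 4, seed = 4, beta = c(1, -1, 0, 0))
  ols <- fit_ols(d)
  for (a in c(0, 0.5, 1)) {
    f <- fit_penalized(d, alpha = a, lambda = 0)
    expect_lt(max(abs(f$coefficients - ols$coefficients)), 1e-6)
  }
})

test_that("ridge matches its closed form", {
  d <- make_instance(8, 4, seed = 5, beta = c(1, 0, 0, 0))
  X <- as.matrix(d[paste0("x", 1:4)])
  yc <- d$y - mean(d$y)
  for (lam in c(0.05, 0.3, 2)) {
    closed <- solve(crossprod(X) / 8 + lam * diag(4), crossprod(X, yc) / 8)
    f <- fit_penalized(d, alpha = 0, lambda = lam)
    expect_lt(max(abs(f$coefficients - closed)), 1e-6)
  }
})

test_that("lasso soft-thresholds exactly in orthonormal designs", {
  d <- make_orthonormal_instance(40, 5, seed = 6, beta = c(1, -0.5, 0.2, 0, 0))
  X <- as.matrix(d[paste0("x", 1:5)])
  b <- as.numeric(crossprod(X, d$y - mean(d$y))) / 40
  for (lam in c(0.1, 0.4, 0.8)) {
    f <- fit_penalized(d, alpha = 1, lambda = lam)
    expected <- sign(b) * pmax(abs(b) - lam, 0)
    expect_lt(max(abs(unname(f$coefficients) - expected)), 1e-7)
    expect_identical(unname(f$zero_pattern), expected == 0)
  }
})

test_that("the top of the path yields the intercept-only model and defaults hold", {
  d <- make_instance(50, 6, seed = 7, beta = c(1, rep(0, 5)))
  path <- lambda_path(d, alpha = 1)
  expect_length(path, 100)
  expect_true(all(diff(path) < 0))
  expect_true(all(path > 0))
  f <- fit_penalized(d, alpha = 1, lambda = path[1])
  expect_true(all(f$coefficients == 0))

  # ridge gets a finite path through the mixing floor
  path0 <- lambda_path(d, alpha = 0)
  expect_true(all(is.finite(path0)))
  expect_equal(path0[1] / lambda_path(d, alpha = 0.001)[1], 1, tolerance = 1e-12)

  dconst <- d
  dconst$y <- 1
  expect_error(lambda_path(dconst, alpha = 1), "constant")
})

test_that("every returned fit satisfies the objective certificate", {
  d <- make_instance(30, 5, seed = 8, beta = c(0.8, -0.6, 0, 0, 0))
  fits <- list(
    fit_ols(d),
    fit_penalized(d, alpha = 0, lambda = 0.2),
    fit_penalized(d, alpha = 0.5, lambda = 0.1),
    fit_penalized(d, alpha = 1, lambda = 0.05)
  )
  for (f in fits) {
    base <- objective_value(d, f)
    for (j in seq_along(f$coefficients)) {
      for (eps in c(-1e-4, 1e-4)) {
        g <- f
        g$coefficients[j] <- g$coefficients[j] + eps
        expect_gt(objective_value(d, g) - base, -1e-9)
      }
    }
  }
})

test_that("sparsity is monotone along the lasso path and ridge norms shrink", {
  for (s in 1:20) {
    d <- make_instance(40, 8, seed = 100 + s, sigma = 1,
                       beta = c(1, -1, 0.5, rep(0, 5)))
    path <- lambda_path(d, alpha = 1, n_values = 30)
    nz <- vapply(path, function(l)
      sum(fit_penalized(d, alpha = 1, lambda = l)$coefficients != 0), numeric(1))
    violations <- sum(diff(nz) < 0) # path is decreasing: nz should increase
    expect_lte(violations, 1)
  }

  d <- make_instance(40, 6, seed = 9, beta = c(1, 1, 0, 0, 0, 0))
  lams <- c(0.01, 0.1, 0.5, 2)
  norms <- vapply(lams, function(l)
    sqrt(sum(fit_penalized(d, alpha = 0, lambda = l)$coefficients^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("solutions are at least as good as glmnet's at matched penalties", {
  skip_if_not_installed("glmnet")
  d <- make_instance(60, 10, seed = 10, beta = c(1, -0.5, rep(0, 8)))
  X <- as.matrix(d[paste0("x", 1:10)])
  for (a in c(0.25, 0.75, 1)) {
    path <- lambda_path(d, alpha = a, n_values = 25)
    g <- glmnet::glmnet(X, d$y, alpha = a, lambda = path,
                        standardize = FALSE, thresh = 1e-14)
    for (i in c(3, 12, 25)) {
      f <- fit_penalized(d, alpha = a, lambda = path[i])
      gf <- f
      gf$coefficients <- setNames(as.numeric(g$beta[, i]), names(f$coefficients))
      gf$intercept <- as.numeric(g$a0[i])
      expect_lte(objective_value(d, f), objective_value(d, gf) + 1e-10)
      expect_lt(max(abs(f$coefficients - gf$coefficients)), 0.05)
    }
  }
})

test_that("R-squared of any predictor subset never exceeds the full OLS fit", {
  d <- make_instance(50, 6, seed = 11, beta = c(1, 0.5, 0, 0, 0, 0))
  r2 <- function(terms) {
    f <- summary(lm(reformulate(terms, "y"), data = d))
    f$r.squared
  }
  full <- r2(paste0("x", 1:6))
  for (sub in list("x1", c("x1", "x2"), c("x3", "x4", "x5"))) {
    expect_lte(r2(sub), full + 1e-12)
  }
})

test_that("fits round trip through JSON", {
  d <- make_instance(30, 3, seed = 13, beta = c(1, 0, 0))
  f <- fit_penalized(d, alpha = 1, lambda = 0.1)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(f, path)
  back <- read_fit_json(path)
  expect_equal(back$coefficients, f$coefficients)
  expect_equal(back$intercept, f$intercept)
  expect_equal(back$lambda, f$lambda)
  expect_equal(unname(back$zero_pattern), unname(f$zero_pattern))

  fo <- fit_ols(d)
  write_fit_json(fo, path)
  expect_true(is.na(read_fit_json(path)$alpha))
})

test_that("tidy and glance expose the fit in broom shape", {
  d <- make_instance(30, 3, seed = 12, beta = c(1, 0, 0))
  f <- fit_penalized(d, alpha = 1, lambda = 0.1)
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "zero"))
  expect_equal(nrow(td), 4)
  expect_equal(td$term[1], "(Intercept)")
  g <- glance(f)
  expect_equal(g$method, "lasso")
  expect_equal(g$n_nonzero, sum(!f$zero_pattern))
  expect_equal(predict(f, d), f$intercept + as.numeric(
    as.matrix(d[paste0("x", 1:3)]) %*% f$coefficients))
})
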