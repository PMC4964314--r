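test_that("an identity resample reproduces the full-data fit", {
  d <- make_instance(30, 4, seed = 1, beta = c(1, -0.5, 0, 0), sigma = 0.3)
  idn <- matrix(1:30, ncol = 1)

  # OLS replicate = full-data OLS on the standardized data
  bo <- bootstrap_fit(d, alpha = NA, B = 1, seed = 2, indices = idn)
  f <- fit_ols(d)
  expect_lt(max(abs(bo$estimates[1, ] - f$coefficients)), 1e-10)

  # fixed-penalty replicate = full-data fit at the same penalty
  bl <- bootstrap_fit(d, alpha = 1, B = 1, seed = 2, retune_lambda = FALSE,
                      indices = idn)
  fl <- fit_penalized(d, alpha = 1, lambda = bl$lambdas[1])
  expect_lt(max(abs(bl$estimates[1, ] - fl$coefficients)), 1e-7)
})

test_that("the bootstrap distribution is bitwise reproducible", {
  d <- make_instance(40, 5, seed = 3, beta = c(1, rep(0, 4)))
  a <- bootstrap_fit(d, alpha = 0.5, B = 30, seed = 11)
  b <- bootstrap_fit(d, alpha = 0.5, B = 30, seed = 11)
  expect_identical(a$estimates, b$estimates)
  expect_identical(a$lambdas, b$lambdas)
  c2 <- bootstrap_fit(d, alpha = 0.5, B = 30, seed = 12)
  expect_false(identical(a$estimates, c2$estimates))
})

test_that("OLS replicates have entirely nonzero estimates", {
  d <- make_instance(60, 5, seed = 4, beta = c(1, -1, 0.5, 0, 0), sigma = 0.5)
  bo <- bootstrap_fit(d, alpha = NA, B = 200, seed = 5)
  expect_true(all(bo$estimates != 0))
  expect_true(all(vip(bo)$vip == 1))
})

test_that("bootstrap means track the full-data fit under strong signal", {
  X <- simulate_design(122, 27, seed = 6)
  d <- simulate_response(X, sigma = 0.2, seed = 6)
  bb <- bootstrap_fit(d, alpha = 1, B = 500, seed = 7)
  full <- cv_lambda(d, alpha = 1, seed = 7)$fit
  expect_lt(abs(mean(bb$estimates[, "x7"]) - full$coefficients["x7"]), 0.1)
})

test_that("column permutation commutes with the bootstrap under an injected index stream", {
  d <- make_instance(30, 5, seed = 8, beta = c(1, -0.5, 0, 0, 0), sigma = 0.3)
  set.seed(1)
  idx <- matrix(sample.int(30, 30 * 20, replace = TRUE), 30, 20)
  perm <- c(4, 2, 5, 1, 3)
  dp <- d[c(paste0("x", perm), "y")]
  names(dp) <- c(paste0("x", 1:5), "y")

  a <- bootstrap_fit(d, alpha = 1, B = 20, seed = 9, indices = idx)
  b <- bootstrap_fit(dp, alpha = 1, B = 20, seed = 9, indices = idx)
  unperm <- b$estimates[, order(perm), drop = FALSE]
  expect_lt(max(abs(a$estimates - unperm)), 1e-8)
})

test_that("lasso replicates never exceed min(n, p) active coefficients", {
  d <- make_instance(20, 27, seed = 10, sigma = 1)
  bb <- bootstrap_fit(d, alpha = 1, B = 40, seed = 13, ratio = 1e-2)
  expect_true(all(rowSums(bb$estimates != 0) <= 20))
})

test_that("degenerate resamples zero the offending column and are capped", {
  # x1 is a near-indicator: resamples omitting row 1 make it constant
  d <- make_instance(20, 3, seed = 14, beta = c(0, 1, 0), sigma = 0.2)
  d$x1 <- c(1, rep(0, 19))
  d <- standardize_predictors(d)
  no_row1 <- matrix(rep(2:20, length.out = 20 * 3), 20, 3)
  with_row1 <- matrix(rep(1:20, 37), 20, 37)
  idx <- cbind(no_row1, with_row1) # 3 of 40 degenerate: below the 10% cap

  expect_warning(
    bb <- bootstrap_fit(d, alpha = 1, B = 40, seed = 15, indices = idx),
    "degenerate")
  expect_true(all(bb$estimates[1:3, "x1"] == 0))
  expect_equal(bb$n_degenerate, 3L)

  idx_bad <- cbind(no_row1, no_row1, no_row1, with_row1[, 1:3]) # 9 of 12
  expect_error(
    suppressWarnings(bootstrap_fit(d, alpha = 1, B = 12, seed = 15,
                                   indices = idx_bad)),
    "degenerate")
})

test_that("tidy and the CSV round trip preserve the distribution", {
  d <- make_instance(25, 3, seed = 16, beta = c(1, 0, 0))
  bb <- bootstrap_fit(d, alpha = 1, B = 10, seed = 17)
  td <- tidy(bb)
  expect_equal(nrow(td), 30)
  expect_named(td, c("replicate", "term", "estimate"))

  path <- withr::local_tempfile(fileext = ".csv")
  write_bootstrap_csv(bb, path)
  back <- read_bootstrap_csv(path)
  expect_equal(unname(back), unname(bb$estimates), tolerance = 1e-12)
  expect_equal(colnames(back), colnames(bb$estimates))
})
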