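test_that("VIP is the exact nonzero proportion", {
  est <- cbind(
    x1 = rep(0, 500),
    x2 = c(rep(1, 250), rep(0, 250)),
    x3 = rnorm(500)
  )
  v <- vip(fake_boot(est))
  expect_equal(v$vip, c(0, 0.5, 1))
  expect_true(all(v$vip >= 0 & v$vip <= 1))
})

test_that("VIP saturates for OLS and is flagged not meaningful", {
  d <- make_instance(50, 4, seed = 1, beta = c(1, 0, 0, 0), sigma = 0.5)
  bo <- bootstrap_fit(d, alpha = NA, B = 100, seed = 2)
  v <- vip(bo)
  expect_true(all(v$vip == 1))
  expect_false(any(v$meaningful))
  for (t in c(0.5, 0.7, 0.95)) {
    expect_setequal(select_vip(bo, t), paste0("x", 1:4))
  }
})

test_that("quantile intervals follow the indicator-sum definition", {
  # hand-evaluated four-point example at the 50% threshold
  est <- cbind(x1 = c(-2, -1, 1, 3))
  q <- quantile_intervals(fake_boot(est), 0.5)
  expect_equal(q$lower, -2)
  expect_equal(q$upper, 1)
  expect_false("x1" %in% select_qnt(q))

  # a constant distribution collapses to a point interval
  qc <- quantile_intervals(fake_boot(cbind(x1 = rep(1.5, 8))), 0.8)
  expect_equal(qc$lower, 1.5)
  expect_equal(qc$upper, 1.5)

  # strictly positive estimates are selected at every threshold
  qp <- fake_boot(cbind(x1 = abs(rnorm(40)) + 0.01))
  for (t in default_thresholds()) {
    expect_equal(select_qnt(qp, t), "x1")
  }
})

test_that("type-1 quantiles agree exactly with the brute-force scan for B <= 50", {
  set.seed(3)
  for (B in c(4, 7, 20, 50)) {
    est <- cbind(x1 = rnorm(B), x2 = sample(c(0, 1, -2), B, replace = TRUE))
    for (t in c(0.5, 0.65, 0.9, 0.95)) {
      q <- quantile_intervals(fake_boot(est), t)
      a <- 1 - t
      for (j in 1:2) {
        expect_identical(q$lower[j], scan_quantile(est[, j], a / 2))
        expect_identical(q$upper[j], scan_quantile(est[, j], 1 - a / 2))
      }
    }
  }
})

test_that("VIP selection uses a strict inequality and QNT a closed interval", {
  est <- cbind(x1 = c(rep(1, 70), rep(0, 30))) # VIP exactly 0.7
  b <- fake_boot(est)
  expect_false("x1" %in% select_vip(b, 0.7)) # boundary: not selected
  expect_true("x1" %in% select_vip(b, 0.69))
  expect_length(select_vip(fake_boot(cbind(x1 = rep(0, 10))), 0.5), 0)

  ints <- tibble::tibble(term = "x1", lower = 0, upper = 0.5, threshold = 0.9)
  expect_length(select_qnt(ints), 0) # zero endpoint contains zero
  ints$lower <- 0.1
  expect_equal(select_qnt(ints), "x1")
})

test_that("the QNT-selected set is a subset of the VIP-selected set everywhere", {
  X <- simulate_design(60, 10, seed = 4)
  d <- simulate_response(X, coefs = c(x3 = 0.5, x8 = -0.5), sigma = 1, seed = 4)
  for (a in c(NA, 0, 0.5, 1)) {
    bb <- bootstrap_fit(d, alpha = a, B = 60, seed = 5)
    grid <- selection_grid(bb)
    wide <- tidyr::pivot_wider(tibble::as_tibble(grid),
                               names_from = "rule", values_from = "selected")
    expect_true(all(!wide$QNT | wide$VIP))
  }
})

test_that("a mostly-zeroed coefficient is selected by neither rule at 50%", {
  set.seed(6)
  vals <- c(abs(rnorm(40)) + 0.1, rep(0, 60)) # nonzero in 40% of replicates
  b <- fake_boot(cbind(x1 = sample(vals)))
  expect_length(select_vip(b, 0.5), 0) # 0.4 < 0.5
  expect_length(select_qnt(b, 0.5), 0) # zero inside the interval
})

test_that("selection is monotone and intervals are nested across thresholds", {
  d <- make_instance(50, 6, seed = 7, beta = c(1, -0.7, 0.3, 0, 0, 0), sigma = 1)
  bb <- bootstrap_fit(d, alpha = 1, B = 80, seed = 8)
  grid <- tibble::as_tibble(selection_grid(bb))
  counts <- dplyr::count(dplyr::filter(grid, selected),
                         rule, threshold)
  for (r in c("VIP", "QNT")) {
    cr <- merge(data.frame(threshold = default_thresholds()),
                counts[counts$rule == r, ], all.x = TRUE)
    cr$n[is.na(cr$n)] <- 0
    expect_true(all(diff(cr$n[order(cr$threshold)]) <= 0))
  }
  q1 <- quantile_intervals(bb, 0.5)
  q2 <- quantile_intervals(bb, 0.9)
  expect_true(all(q2$lower <= q1$lower & q1$upper <= q2$upper))
})

test_that("the bias-corrected refit matches its least-squares oracle", {
  d <- make_instance(50, 5, seed = 9, beta = c(0, 1, 0, -0.5, 0), sigma = 0.5)

  r0 <- bias_corrected_refit(d, selected = character())
  expect_equal(r0$r_squared, 0)
  expect_equal(r0$adj_r_squared, 0)
  expect_equal(r0$error_sd, sd(d$y))

  rall <- bias_corrected_refit(d, selected = paste0("x", 1:5))
  full <- fit_ols(d)
  expect_lt(max(abs(rall$fit$coefficients - full$coefficients)), 1e-10)
  expect_equal(rall$r_squared, summary(lm(y ~ ., data = d))$r.squared,
               tolerance = 1e-10)

  r24 <- bias_corrected_refit(d, selected = c(2, 4))
  X <- cbind(1, as.matrix(d[c("x2", "x4")]))
  ne <- solve(crossprod(X), crossprod(X, d$y))
  expect_lt(max(abs(c(r24$fit$intercept, r24$fit$coefficients) - ne)), 1e-8)
  expect_lte(r24$adj_r_squared, r24$r_squared)
  expect_lte(r24$r_squared, rall$r_squared + 1e-12)
  sm <- summary(lm(y ~ x2 + x4, data = d))
  expect_equal(r24$error_sd, sm$sigma, tolerance = 1e-10)

  expect_error(bias_corrected_refit(d[1:6, ], selected = paste0("x", 1:5)),
               "degrees of freedom")
})

test_that("selection grids and refit tables survive disk round trips", {
  d <- make_instance(40, 4, seed = 10, beta = c(1, 0, 0, 0))
  bb <- bootstrap_fit(d, alpha = 1, B = 30, seed = 11)
  grid <- selection_grid(bb, thresholds = c(0.5, 0.75, 0.95))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_selection_grid_tsv(grid, tsv)
  back <- read_selection_grid_tsv(tsv)
  key <- function(g) dplyr::arrange(tibble::as_tibble(g), rule, threshold, term)
  expect_equal(key(back), key(grid), ignore_attr = TRUE)

  refit <- bias_corrected_refit(d, selected = select_qnt(bb, 0.95))
  csvp <- withr::local_tempfile(fileext = ".csv")
  write_refit_csv(list(lasso = refit), csvp)
  tab <- readr::read_csv(csvp, show_col_types = FALSE)
  expect_equal(nrow(tab), 6) # 4 predictors + R^2 + error SD footer
  expect_equal(tab$predictor[5:6], c("R_squared", "error_sd"))
})

test_that("selection-grid plots build without error", {
  d <- make_instance(30, 3, seed = 12, beta = c(1, 0, 0))
  bb <- bootstrap_fit(d, alpha = 1, B = 20, seed = 13)
  p <- autoplot(selection_grid(bb, thresholds = c(0.5, 0.9)))
  expect_s3_class(p, "ggplot")
})
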