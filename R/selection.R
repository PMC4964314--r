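#' Variable inclusion probabilities
#'
#' For each predictor, the proportion of bootstrap replicates in which its
#' coefficient estimate is nonzero (using the solver's exact-zero pattern,
#' never a magnitude threshold). The VIP is only meaningful for methods that
#' can zero out coefficients (elastic net with `alpha > 0`); for OLS and
#' ridge it is computed but flagged not meaningful, since those methods
#' essentially never produce exact zeros and the VIP saturates at 1.
#'
#' @param boot A `be_boot` object from [bootstrap_fit()].
#' @return A tibble with columns `term`, `vip` (in `[0, 1]`) and `meaningful`.
#' @export
vip <- function(boot) {
  stopifnot(inherits(boot, "be_boot"))
  tibble::tibble(
    term = colnames(boot$estimates),
    vip = unname(colMeans(boot$estimates != 0)),
    meaningful = !(boot$method %in% c("OLS", "ridge"))
  )
}

#' Bootstrap percentile confidence intervals
#'
#' Per-predictor `100 * threshold`% intervals
#' `[Q_{alpha*/2}, Q_{1 - alpha*/2}]` (with `alpha* = 1 - threshold`) of the
#' bootstrap coefficient distribution. Quantiles are type-1 inverse empirical
#' CDF values: the smallest order statistic whose ECDF reaches the target
#' probability, matching the indicator-sum definition
#' `alpha = (1/B) * sum_b 1{estimate_b <= Q_alpha}`. No interpolation is used.
#'
#' @param boot A `be_boot` object.
#' @param threshold Significance threshold `1 - alpha*` in `(0, 1)`.
#' @return A tibble with columns `term`, `lower`, `upper`, `threshold`.
#' @export
quantile_intervals <- function(boot, threshold) {
  stopifnot(inherits(boot, "be_boot"), threshold > 0, threshold < 1,
            nrow(boot$estimates) >= 2)
  a <- 1 - threshold
  q <- apply(boot$estimates, 2, quantile, probs = c(a / 2, 1 - a / 2),
             type = 1, names = FALSE)
  tibble::tibble(
    term = colnames(boot$estimates),
    lower = unname(q[1, ]),
    upper = unname(q[2, ]),
    threshold = threshold
  )
}

#' Select predictors by the VIP rule
#'
#' A predictor is selected at threshold `1 - alpha*` when its VIP strictly
#' exceeds the threshold (`VIP_j > 1 - alpha*`; equality is not selection).
#'
#' @param x A `be_boot` object or a tibble from [vip()].
#' @param threshold Significance threshold in `(0, 1)`.
#' @return Character vector of selected predictor names.
#' @export
select_vip <- function(x, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  v <- if (inherits(x, "be_boot")) vip(x) else x
  v$term[v$vip > threshold]
}

#' Select predictors by the bootstrap quantile (QNT) rule
#'
#' A predictor is selected at threshold `1 - alpha*` when its
#' `100 * (1 - alpha*)`% bootstrap percentile interval does not contain zero.
#' The interval is treated as closed: an endpoint exactly equal to zero
#' counts as containing zero (non-selection).
#'
#' @param x A `be_boot` object or a tibble from [quantile_intervals()].
#' @param threshold Significance threshold in `(0, 1)`; ignored when `x`
#'   already carries intervals.
#' @return Character vector of selected predictor names.
#' @export
select_qnt <- function(x, threshold = NULL) {
  ints <- if (inherits(x, "be_boot")) {
    stopifnot(!is.null(threshold))
    quantile_intervals(x, threshold)
  } else x
  ints$term[ints$lower > 0 | ints$upper < 0]
}

#' Evaluate both selection rules over a threshold grid
#'
#' Applies [select_vip()] and [select_qnt()] at every threshold and returns
#' the full boolean grid (the data behind a selection heat-map). Before
#' returning, the QNT-subset-of-VIP relation is asserted at every threshold:
#' a QNT-selected predictor whose VIP does not exceed the threshold would
#' contradict the ordering theorem relating the two rules, so a violation is
#' reported as an internal error rather than returned.
#'
#' @param boot A `be_boot` object.
#' @param thresholds Increasing vector of thresholds in `(0, 1)`
#'   (default [default_thresholds()]).
#' @return A tibble of class `be_selection_grid` with columns `rule`
#'   (`"VIP"`/`"QNT"`), `threshold`, `term`, `selected`, and attributes
#'   `method` and `vip_meaningful`.
#' @export
selection_grid <- function(boot, thresholds = default_thresholds()) {
  stopifnot(inherits(boot, "be_boot"), all(thresholds > 0 & thresholds < 1),
            !is.unsorted(thresholds, strictly = TRUE))
  terms <- colnames(boot$estimates)
  v <- vip(boot)
  rows <- purrr::map(thresholds, function(t) {
    qnt_sel <- select_qnt(boot, t)
    vip_sel <- select_vip(v, t)
    if (!all(qnt_sel %in% vip_sel)) {
      stop("internal error: QNT-selected set is not a subset of the ",
           "VIP-selected set at threshold ", t, call. = FALSE)
    }
    tibble::tibble(
      rule = rep(c("VIP", "QNT"), each = length(terms)),
      threshold = t,
      term = rep(terms, 2),
      selected = c(terms %in% vip_sel, terms %in% qnt_sel)
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("be_selection_grid", class(out)),
            method = boot$method, vip_meaningful = v$meaningful[1])
}

#' @describeIn selection_grid Heat-map of the selection grid (predictor by
#'   threshold, one panel per rule), mirroring the usual presentation of
#'   bootstrap selection results.
#' @param object A `be_selection_grid`.
#' @param ... Unused.
#' @export
autoplot.be_selection_grid <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$term <- factor(df$term, levels = unique(df$term))
  ggplot2::ggplot(df, ggplot2::aes(.data$term, factor(.data$threshold),
                                   fill = .data$selected)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::facet_wrap(~rule, ncol = 1) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey35", `FALSE` = "grey92")) +
    ggplot2::labs(x = NULL, y = "threshold (1 - alpha*)",
                  title = attr(object, "method"), fill = "selected") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Write / read a selection grid as TSV
#'
#' Rows = predictors, columns = `rule_threshold` pairs, cells 0/1.
#'
#' @param grid A `be_selection_grid`.
#' @param path File path.
#' @export
write_selection_grid_tsv <- function(grid, path) {
  wide <- tibble::as_tibble(grid) |>
    dplyr::mutate(col = sprintf("%s_%.2f", .data$rule, .data$threshold),
                  selected = as.integer(.data$selected)) |>
    dplyr::select("term", "col", "selected") |>
    tidyr::pivot_wider(names_from = "col", values_from = "selected")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname write_selection_grid_tsv
#' @export
read_selection_grid_tsv <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  long <- tidyr::pivot_longer(wide, -"term", names_to = "col",
                              values_to = "selected") |>
    tidyr::separate_wider_delim("col", "_", names = c("rule", "threshold")) |>
    dplyr::mutate(threshold = as.numeric(.data$threshold),
                  selected = .data$selected == 1) |>
    dplyr::select("rule", "threshold", "term", "selected") |>
    dplyr::arrange(.data$threshold, dplyr::desc(.data$rule))
  structure(long, class = c("be_selection_grid", class(long)))
}

#' Bias-corrected post-selection refit
#'
#' Refits an unpenalized OLS model on the selected predictors only, removing
#' the shrinkage bias of the penalized estimates, and reports fit strength.
#' This refit is applied only after selection (final estimates), never
#' inside tuning.
#'
#' @inheritParams fit_ols
#' @param selected Character vector of selected predictor names (possibly
#'   empty, giving the intercept-only model) or integer column indices.
#' @return An object of class `be_refit`: list with `selected`, `fit`
#'   (an `enet_fit` on the subset), `r_squared`, `adj_r_squared`,
#'   `error_sd` (residual SD with denominator `n - |selected| - 1`),
#'   `n` and `terms` (all predictor names, for zero-filled reporting).
#' @export
bias_corrected_refit <- function(data, response = "y", selected = character()) {
  d <- as_design(data, response)
  if (is.numeric(selected)) selected <- d$terms[selected]
  stopifnot(all(selected %in% d$terms))
  selected <- unique(selected)
  n <- length(d$y); k <- length(selected)
  if (k >= n - 1) stop("no residual degrees of freedom: |selected| >= n - 1",
                       call. = FALSE)

  if (k == 0) {
    resid <- d$y - mean(d$y)
    rss <- sum(resid^2); tss <- rss
    fit <- structure(
      list(intercept = mean(d$y), coefficients = setNames(numeric(0), character(0)),
           zero_pattern = logical(0), alpha = NA_real_, lambda = 0,
           method = "OLS", n = n),
      class = "enet_fit")
  } else {
    sub <- data[c(selected, response)]
    fit <- fit_ols(sub, response)
    resid <- d$y - predict(fit, sub)
    rss <- sum(resid^2)
    tss <- sum((d$y - mean(d$y))^2)
  }
  r2 <- 1 - rss / tss
  structure(
    list(
      selected = selected,
      fit = fit,
      r_squared = r2,
      adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - k - 1),
      error_sd = sqrt(rss / (n - k - 1)),
      n = n,
      terms = d$terms
    ),
    class = "be_refit"
  )
}

#' @export
print.be_refit <- function(x, ...) {
  cat(sprintf("<be_refit> %d selected predictor(s): R^2 = %.3f (error SD %.3f)\n",
              length(x$selected), x$r_squared, x$error_sd))
  invisible(x)
}

#' @describeIn bias_corrected_refit All predictors with their bias-corrected
#'   coefficient (0 when unselected).
#' @param x A `be_refit` object.
#' @param ... Unused.
#' @export
tidy.be_refit <- function(x, ...) {
  est <- setNames(rep(0, length(x$terms)), x$terms)
  est[names(x$fit$coefficients)] <- x$fit$coefficients
  tibble::tibble(term = x$terms, estimate = unname(est),
                 selected = x$terms %in% x$selected)
}

#' @describeIn bias_corrected_refit One-row fit summary (R-squared, adjusted
#'   R-squared, residual SD).
#' @export
glance.be_refit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_selected = length(x$selected),
    r_squared = x$r_squared,
    adj_r_squared = x$adj_r_squared,
    error_sd = x$error_sd
  )
}

#' Export coefficient-table CSV for one or more refits
#'
#' One row per predictor with the bias-corrected coefficient per method
#' (0 when unselected), plus footer rows for R-squared and error SD.
#'
#' @param refits Named list of `be_refit` objects (names = method labels).
#' @param path File path.
#' @export
write_refit_csv <- function(refits, path) {
  stopifnot(length(refits) > 0, !is.null(names(refits)))
  cols <- purrr::imap(refits, function(r, nm) {
    td <- tidy(r)
    g <- glance(r)
    c(sprintf("%.6g", td$estimate), sprintf("%.6g", g$r_squared),
      sprintf("%.6g", g$error_sd))
  })
  out <- tibble::tibble(
    predictor = c(refits[[1]]$terms, "R_squared", "error_sd"),
    !!!cols
  )
  readr::write_csv(out, path)
  invisible(path)
}
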