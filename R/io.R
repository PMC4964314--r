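#' Run configuration
#'
#' A plain list describing a complete run: mode (`"generate"`, `"analyze"`
#' or `"simulate"`), input paths, the method family, threshold grid, bootstrap
#' size, CV folds, replication count, seeds and output directory. Configs
#' round-trip losslessly through JSON.
#'
#' @param mode One of `"generate"`, `"analyze"`, `"simulate"`.
#' @param predictors Path to the subjects x predictors CSV (analyze mode).
#' @param criterion Path to the criterion CSV (analyze mode); its first (or
#'   `criterion_column`) column is the response.
#' @param criterion_column Optional criterion column name.
#' @param alphas Named vector of mixing parameters (`NA` = OLS).
#' @param thresholds Threshold grid.
#' @param final_threshold Threshold used for the final bias-corrected refit
#'   (default 0.95).
#' @param B Bootstrap replicates.
#' @param cv_folds CV folds.
#' @param n_replications Monte Carlo replications (simulate mode).
#' @param sample_sizes,sigmas Simulation lattice (simulate mode).
#' @param n_subjects,n_predictors,corr_low,corr_high Generator settings
#'   (generate / simulate modes).
#' @param active Named true coefficients (generate / simulate modes).
#' @param sigma Error SD for generate mode.
#' @param seed Master seed. Required: every stochastic step derives a
#'   substream from it, and the log records enough to replay any step.
#' @param output_dir Output directory.
#' @param desk_scale Desk-scale flag (simulate mode).
#' @return A list of class `be_config`.
#' @export
run_config <- function(mode = c("analyze", "simulate", "generate"),
                       predictors = NULL, criterion = NULL,
                       criterion_column = NULL,
                       alphas = method_family(),
                       thresholds = default_thresholds(),
                       final_threshold = 0.95,
                       B = 5000, cv_folds = 5,
                       n_replications = 50,
                       sample_sizes = c(30, 60, 90, 122),
                       sigmas = c(0.5, 0.7, 1),
                       n_subjects = 122, n_predictors = 27,
                       corr_low = 0.14, corr_high = 0.77,
                       active = c(x7 = 0.3, x14 = -0.4),
                       sigma = 1,
                       seed = NULL, output_dir = ".",
                       desk_scale = TRUE) {
  mode <- match.arg(mode)
  if (mode %in% c("simulate", "generate") && is.null(seed)) {
    stop("a master seed is required in ", mode, " mode", call. = FALSE)
  }
  structure(
    list(mode = mode, predictors = predictors, criterion = criterion,
         criterion_column = criterion_column, alphas = as.list(alphas),
         thresholds = thresholds, final_threshold = final_threshold,
         B = B, cv_folds = cv_folds, n_replications = n_replications,
         sample_sizes = sample_sizes, sigmas = sigmas,
         n_subjects = n_subjects, n_predictors = n_predictors,
         corr_low = corr_low, corr_high = corr_high,
         active = as.list(active), sigma = sigma,
         seed = seed, output_dir = output_dir, desk_scale = desk_scale),
    class = "be_config"
  )
}

#' Write / read a run configuration as JSON
#'
#' @param config A `be_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(run_config, c(list(mode = raw$mode),
                               raw[setdiff(names(raw), "mode")]))
  cfg$alphas <- lapply(raw$alphas, function(a) if (is.null(a)) NA_real_ else a)
  cfg
}

config_alphas <- function(config) {
  a <- vapply(config$alphas, function(x) if (is.null(x)) NA_real_ else as.numeric(x),
              numeric(1))
  if (is.null(names(a)) || any(names(a) == "")) {
    names(a) <- vapply(as.list(a), method_label, character(1))
  }
  a
}

#' Generate a synthetic dataset to disk
#'
#' Writes `design.csv` (standardized correlated predictors plus response)
#' under `config$output_dir`.
#'
#' @param config A `be_config` with `mode = "generate"`.
#' @return Path of the written CSV, invisibly.
#' @export
run_generate <- function(config) {
  stopifnot(inherits(config, "be_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  X <- simulate_design(config$n_subjects, config$n_predictors,
                       config$corr_low, config$corr_high, seed = config$seed)
  dat <- simulate_response(X, coefs = unlist(config$active),
                           sigma = config$sigma, seed = config$seed)
  write_design_csv(dat, file.path(config$output_dir, "design.csv"))
}

#' Analyze a predictor table with the full bootstrap-selection pipeline
#'
#' Reads the predictor and criterion CSVs, standardizes the predictors, runs
#' every configured method through bootstrap resampling, builds VIP/QNT
#' selection grids, and produces bias-corrected refits at the configured
#' final threshold. Writes, under `config$output_dir`: one selection-grid TSV
#' and one bootstrap-distribution CSV per method, a coefficient-table CSV
#' (`coefficients.csv`), and `run_log.json` recording seeds and the CV-MSE
#' per method.
#'
#' @param config A `be_config` with `mode = "analyze"`.
#' @return Invisibly, a named list with the grids, refits and log.
#' @export
run_analyze <- function(config) {
  stopifnot(inherits(config, "be_config"))
  X <- readr::read_csv(config$predictors, show_col_types = FALSE)
  # drop a leading subject-ID column and any non-numeric columns
  if (grepl("^(subject|id)", names(X)[1], ignore.case = TRUE)) X <- X[-1]
  X <- X[vapply(X, is.numeric, logical(1))]
  crit <- readr::read_csv(config$criterion, show_col_types = FALSE)
  ycol <- config$criterion_column %||% names(crit)[1]
  y <- crit[[ycol]]
  if (!is.numeric(y)) stop("criterion column is not numeric", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("missing values in input", call. = FALSE)
  if (nrow(X) != length(y)) stop("predictor and criterion sizes differ", call. = FALSE)
  if (nrow(X) <= ncol(X) + 1) {
    warning("n <= p + 1: OLS has few residual degrees of freedom", call. = FALSE)
  }

  dat <- standardize_predictors(X)
  dat$y <- y
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  alphas <- config_alphas(config)
  seed <- config$seed %||% 1

  results <- purrr::imap(alphas, function(a, lab) {
    mseed <- substream_seed(seed, paste0("analyze-", lab))
    boot <- bootstrap_fit(dat, alpha = a, B = config$B,
                          cv_folds = config$cv_folds, seed = mseed)
    grid <- selection_grid(boot, config$thresholds)
    sel <- select_qnt(boot, config$final_threshold)
    refit <- bias_corrected_refit(dat, selected = sel)
    cv_mse <- if (is.na(a)) NA_real_ else {
      glance(cv_lambda(dat, alpha = a, k = config$cv_folds,
                       seed = substream_seed(mseed, "full-cv")))$cv_mse_min
    }
    slug <- gsub("[^a-z0-9]+", "-", tolower(lab))
    write_selection_grid_tsv(grid, file.path(config$output_dir,
                                             paste0("selection_", slug, ".tsv")))
    write_bootstrap_csv(boot, file.path(config$output_dir,
                                        paste0("bootstrap_", slug, ".csv")))
    list(boot = boot, grid = grid, refit = refit, seed = mseed, cv_mse = cv_mse)
  })

  write_refit_csv(purrr::map(results, "refit"),
                  file.path(config$output_dir, "coefficients.csv"))
  log <- list(
    master_seed = seed,
    final_threshold = config$final_threshold,
    B = config$B,
    cv_folds = config$cv_folds,
    methods = purrr::imap(results, function(r, lab) {
      list(seed = r$seed, cv_mse = r$cv_mse,
           n_selected_qnt = length(r$refit$selected))
    })
  )
  jsonlite::write_json(log, file.path(config$output_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(results = results, log = log))
}

#' Run the Monte Carlo study from a configuration
#'
#' Generates the synthetic population design, executes the simulation
#' lattice, and writes `simulation.csv` (long format) with its JSON manifest.
#'
#' @param config A `be_config` with `mode = "simulate"`.
#' @return Invisibly, the `be_simulation` tibble.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "be_config"))
  if (is.null(config$seed)) stop("a master seed is required", call. = FALSE)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  pop <- simulate_design(config$n_subjects, config$n_predictors,
                         config$corr_low, config$corr_high,
                         seed = substream_seed(config$seed, "population"))
  design <- simulation_design(
    sample_sizes = config$sample_sizes, sigmas = config$sigmas,
    n_replications = config$n_replications, bootstrap_B = config$B,
    alphas = config_alphas(config), thresholds = config$thresholds,
    active = unlist(config$active), cv_folds = config$cv_folds,
    master_seed = config$seed, desk_scale = config$desk_scale
  )
  sim <- run_simulation(pop, design)
  write_simulation_csv(sim, file.path(config$output_dir, "simulation.csv"))
  invisible(sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
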