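# Reproducible end-to-end runs: configuration, model serialization, the
# simulate -> two-split fit -> select -> validate pipeline, and run manifests.

#' Serialize a model to JSON
#' @param model An `sd_model`.
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  obj <- list(n_nodes = model$grid$n, forces = model$forces, D = model$D,
              F0 = model$F0, C = model$C, Fi = model$Fi,
              correct_side = attr(model, "correct_side"))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a model written by [write_model()]
#' @param path Input path.
#' @param grid Optional pre-built grid (must match the stored size).
#' @return An `sd_model`.
#' @export
read_model <- function(path, grid = NULL) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(grid)) grid <- build_grid(obj$n_nodes)
  m <- latent_model(grid, forces = matrix(unlist(obj$forces), grid$n),
                    D = obj$D, F0 = unlist(obj$F0), C = unlist(obj$C),
                    Fi = if (length(obj$C))
                      matrix(unlist(obj$Fi), grid$n) else NULL)
  if (!is.null(obj$correct_side)) attr(m, "correct_side") <- unlist(obj$correct_side)
  m
}

#' Read a pipeline configuration (YAML)
#'
#' Unspecified fields fall back to the standard defaults (learning rate 0.05,
#' 20 batches, 5000 epochs, 30 line searches, JS threshold 0.0015, 75-ms/10-ms
#' PSTH windows, 0.5-s decoder truncation).
#'
#' @param path YAML file; fields mirror [fit_config()] plus `simulate`
#'   (preset, n_trials, dt, t_max), `grid_n`, and `n_boot`.
#' @return Config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(seed = 1L, grid_n = 64L, n_boot = 0L,
                   fit = list(), simulate = list(preset = "single_barrier_easy",
                                                 n_trials = 100L, dt = 5e-4,
                                                 t_max = 10))
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in names(defaults$simulate))
    if (is.null(cfg$simulate[[nm]])) cfg$simulate[[nm]] <- defaults$simulate[[nm]]
  cfg
}

#' Run the full pipeline
#'
#' Simulate (or load) spike data, fit the model independently on the two
#' standard data halves, select by feature consistency, optionally bootstrap,
#' validate (choice prediction and spike-time R^2 on the cross-validation
#' half), and write all reports plus a manifest sufficient to re-run the
#' stage. Deterministic under a fixed seed. If a stage's outputs already
#' exist in `out_dir` and `force` is FALSE, the stage is skipped and its
#' outputs reloaded.
#'
#' @param config Config list (see [read_run_config()]) or path to a YAML file.
#' @param out_dir Output directory (created if missing).
#' @param force Recompute stages whose outputs already exist.
#' @return Invisible list with the data, selection, and validation report.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  timings <- list()
  paths <- list(data = file.path(out_dir, "spikedata.ndjson"),
                truth = file.path(out_dir, "ground_truth.json"),
                model1 = file.path(out_dir, "selected_model_split1.json"),
                model2 = file.path(out_dir, "selected_model_split2.json"),
                selection = file.path(out_dir, "selection_report.json"),
                validation = file.path(out_dir, "validation_report.csv"),
                manifest = file.path(out_dir, "manifest.json"))

  fc <- do.call(fit_config, c(config$fit, list(seed = config$seed)))
  grid <- build_grid(config$grid_n)

  # stage: data
  tic <- Sys.time()
  if (!force && file.exists(paths$data)) {
    data <- read_spikedata(paths$data)
  } else if (!is.null(config$data)) {
    data <- read_spikedata(config$data)
    write_spikedata(data, paths$data)
  } else {
    sim <- config$simulate
    truth <- ground_truth_library(sim$preset, grid = grid)
    data <- simulate_trials(truth, n_trials = sim$n_trials, dt = sim$dt,
                            seed = config$seed, t_max = sim$t_max)
    write_spikedata(data, paths$data)
    write_model(truth, paths$truth)
  }
  missing_conds <- setdiff(seq_len(max(trial_conditions(data))),
                           unique(trial_conditions(data)))
  if (length(missing_conds))
    stop("data has no trials for condition(s): ",
         paste(missing_conds, collapse = ", "), call. = FALSE)
  timings$data <- as.numeric(Sys.time() - tic, units = "secs")

  # stage: fit + select
  tic <- Sys.time()
  if (!force && file.exists(paths$selection)) {
    sel <- list(model1 = read_model(paths$model1, grid),
                model2 = read_model(paths$model2, grid))
    report <- jsonlite::fromJSON(paths$selection)
    sel$M_star <- report$M_star
    outcome <- report$outcome
  } else {
    splits <- two_split_fit(data, fc, grid = grid)
    sel <- select_models(splits$trace1, splits$trace2, fc$js_threshold)
    outcome <- classify_outcome(sel)
    write_model(sel$model1, paths$model1)
    write_model(sel$model2, paths$model2)
    jsonlite::write_json(
      list(M_star = sel$M_star, outcome = outcome,
           consistent = sel$consistent, threshold = sel$threshold,
           djs_curve = sel$djs_curve,
           barriers = vapply(seq_len(sel$model1$n_conditions), function(l)
             count_barriers(sel$model1$forces[, l], sel$model2$forces[, l],
                            grid), integer(1))),
      paths$selection, digits = NA, auto_unbox = TRUE)
  }
  timings$fit_select <- as.numeric(Sys.time() - tic, units = "secs")

  # stage: bootstrap (optional)
  if (config$n_boot > 0 && (force || !file.exists(file.path(out_dir, "bootstrap_bands.json")))) {
    tic <- Sys.time()
    bands <- bootstrap_bands(data, fc, n_boot = config$n_boot, grid = grid)
    jsonlite::write_json(bands[c("phi_sd", "p0_sd", "tuning_sd")],
                         file.path(out_dir, "bootstrap_bands.json"), digits = NA)
    timings$bootstrap <- as.numeric(Sys.time() - tic, units = "secs")
  }

  # stage: validate (cross-split choice prediction + spike-time R^2)
  tic <- Sys.time()
  if (!force && file.exists(paths$validation)) {
    validation <- utils::read.csv(paths$validation)
  } else {
    validation <- validate_selection(sel, data)
    utils::write.csv(validation, paths$validation, row.names = FALSE)
  }
  timings$validate <- as.numeric(Sys.time() - tic, units = "secs")

  manifest <- list(
    package_version = as.character(utils::packageVersion("spikedrift")),
    config = config, seed = config$seed,
    started = format(t_start), timings = timings,
    outputs = lapply(paths[file.exists(unlist(paths))][
      setdiff(names(paths)[file.exists(unlist(paths))], "manifest")],
      function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(list(data = data, selection = sel, outcome = outcome,
                 validation = validation, timings = timings))
}

#' Cross-split validation report
#'
#' Uses the model selected on each half to predict the other half: Viterbi
#' choice prediction (balanced accuracy) and per-neuron spike-time R^2 from
#' the Viterbi-decoded rate.
#'
#' @param sel An `sd_selection` (or list with `model1`, `model2`).
#' @param data The full `sd_spikedata` the two-split fit was run on.
#' @return Data frame with one row per neuron plus a population row carrying
#'   the choice-prediction balanced accuracy.
#' @export
validate_selection <- function(sel, data) {
  conds <- trial_conditions(data)
  pos <- integer(length(conds))
  for (l in unique(conds)) pos[conds == l] <- seq_len(sum(conds == l))
  fold <- ifelse(pos %% 2L == 0L, 1L, 2L)    # trained on fold h -> predict other
  M <- data$n_neurons
  preds <- rep(NA_real_, length(conds))
  rates <- vector("list", length(conds))
  for (k in seq_along(data$trials)) {
    model <- if (fold[k] == 1L) sel$model2 else sel$model1
    tr <- data$trials[[k]]
    path <- tryCatch(viterbi_path(model, tr), error = function(e) NULL)
    if (is.null(path)) next
    preds[k] <- path$boundary
    tt <- seq(tr$t0, tr$tE, length.out = max(16L, ceiling((tr$tE - tr$t0) / 0.005)))
    rates[[k]] <- lapply(seq_len(M), function(i)
      list(time = tt, rate = path_rate(model, path, i, tt)))
  }
  choice <- vapply(data$trials, function(tr)
    if (is.null(tr$choice)) NA_real_ else as.numeric(tr$choice), numeric(1))
  ok <- !is.na(preds) & !is.na(choice)
  bacc <- if (any(ok)) balanced_accuracy(preds[ok], choice[ok]) else NA_real_
  rows <- lapply(seq_len(M), function(i) {
    rr <- lapply(seq_along(rates), function(k)
      if (is.null(rates[[k]])) list(time = c(0, 1), rate = c(0, 0)) else rates[[k]][[i]])
    r2 <- spike_time_r2(data, rr, neuron = i)
    data.frame(unit = i, r2 = r2$r2, balanced_accuracy = NA_real_)
  })
  rbind(do.call(rbind, rows),
        data.frame(unit = NA_integer_, r2 = NA_real_, balanced_accuracy = bacc))
}
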