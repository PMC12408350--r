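#' Trial-structured spike data
#'
#' A set of trials, each a marked point process on [t0, tE]: an ordered
#' sequence of (spike time, neuron index) events between the trial start t0
#' and the trial end tE (the reaction time), with a condition label and an
#' optional choice label. Times are absolute seconds within the analysed
#' window; neuron indices are 1-based and contiguous.
#'
#' @param trials A list; each element is a list with fields `t0`, `tE`,
#'   `times` (sorted spike times, strictly inside (t0, tE)), `ids` (neuron
#'   index per spike), `condition` (integer label), and optionally `choice`
#'   (-1 = left boundary, +1 = right) and `correct` (logical).
#' @param n_neurons Number of neurons M; spike ids must lie in 1..M.
#' @return An object of class `sd_spikedata`.
#' @export
spike_data <- function(trials, n_neurons) {
  n_neurons <- as.integer(n_neurons)
  if (n_neurons < 1L) stop("n_neurons must be >= 1", call. = FALSE)
  trials <- lapply(trials, function(tr) {
    tr$t0 <- as.numeric(tr$t0); tr$tE <- as.numeric(tr$tE)
    tr$times <- as.numeric(tr$times); tr$ids <- as.integer(tr$ids)
    if (is.null(tr$condition)) tr$condition <- 1L
    tr$condition <- as.integer(tr$condition)
    if (!is.finite(tr$t0) || !is.finite(tr$tE) || tr$tE <= tr$t0)
      stop("each trial needs t0 < tE", call. = FALSE)
    if (length(tr$times) != length(tr$ids))
      stop("times and ids must have equal length", call. = FALSE)
    if (length(tr$times) > 0) {
      o <- order(tr$times, tr$ids)   # ties broken by neuron index
      tr$times <- tr$times[o]; tr$ids <- tr$ids[o]
      if (tr$times[1] <= tr$t0 || tr$times[length(tr$times)] >= tr$tE)
        stop("spike times must lie strictly inside (t0, tE)", call. = FALSE)
      if (any(tr$ids < 1L | tr$ids > n_neurons))
        stop("neuron indices out of range", call. = FALSE)
    }
    tr
  })
  structure(list(trials = trials, n_neurons = n_neurons),
            class = "sd_spikedata")
}

is_spikedata <- function(x) inherits(x, "sd_spikedata")

#' @export
print.sd_spikedata <- function(x, ...) {
  ns <- vapply(x$trials, function(tr) length(tr$times), integer(1))
  cond <- vapply(x$trials, function(tr) tr$condition, integer(1))
  cat("Spike data:", length(x$trials), "trials,", x$n_neurons, "neurons,",
      sum(ns), "spikes, conditions:",
      paste(sort(unique(cond)), collapse = " "), "\n")
  invisible(x)
}

#' Condition labels of all trials
#' @param data An `sd_spikedata`.
#' @return Integer vector, one label per trial.
#' @export
trial_conditions <- function(data) {
  vapply(data$trials, function(tr) tr$condition, integer(1))
}

#' Subset trials of a spike dataset
#' @param data An `sd_spikedata`.
#' @param idx Trial indices to keep (may repeat, e.g. bootstrap resampling).
#' @return An `sd_spikedata` with the selected trials.
#' @export
subset_trials <- function(data, idx) {
  spike_data(data$trials[idx], data$n_neurons)
}

#' Write spike data as line-oriented JSON
#'
#' One JSON object per line: a header with `n_neurons` and `time_unit`,
#' followed by one object per trial with fields `t0`, `tE`, `spike_times`,
#' `neuron_ids` (1-based), `condition`, and optionally `choice` and `correct`.
#'
#' @param data An `sd_spikedata`.
#' @param path Output file path.
#' @export
write_spikedata <- function(data, path) {
  if (!is_spikedata(data)) stop("expected sd_spikedata", call. = FALSE)
  header <- jsonlite::toJSON(
    list(n_neurons = data$n_neurons, time_unit = "s"), auto_unbox = TRUE)
  num <- function(x) sprintf("%.17g", x)   # shortest-exact double round trip
  lines <- vapply(data$trials, function(tr) {
    s <- sprintf('{"t0":%s,"tE":%s,"spike_times":[%s],"neuron_ids":[%s],"condition":%d',
                 num(tr$t0), num(tr$tE),
                 paste(num(tr$times), collapse = ","),
                 paste(tr$ids, collapse = ","), tr$condition)
    if (!is.null(tr$choice) && !is.na(tr$choice))
      s <- paste0(s, sprintf(',"choice":%d', as.integer(tr$choice)))
    if (!is.null(tr$correct) && !is.na(tr$correct))
      s <- paste0(s, sprintf(',"correct":%s', if (isTRUE(tr$correct)) "true" else "false"))
    paste0(s, "}")
  }, character(1))
  writeLines(c(as.character(header), lines), path)
  invisible(path)
}

#' Read spike data written by [write_spikedata()]
#' @param path Input file path.
#' @return An `sd_spikedata`.
#' @export
read_spikedata <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty spike-data file", call. = FALSE)
  header <- jsonlite::fromJSON(lines[1])
  trials <- lapply(lines[-1], function(l) {
    obj <- jsonlite::fromJSON(l)
    tr <- list(t0 = obj$t0, tE = obj$tE,
               times = as.numeric(unlist(obj$spike_times)),
               ids = as.integer(unlist(obj$neuron_ids)),
               condition = obj$condition)
    if (!is.null(obj$choice)) tr$choice <- obj$choice
    if (!is.null(obj$correct)) tr$correct <- obj$correct
    tr
  })
  spike_data(trials, header$n_neurons)
}
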