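# Single-trial validation machinery: continuous-state Viterbi decoding of
# the most probable latent path, spike-time R^2 by time rescaling, the
# renewal-based point-process variability estimator, choice prediction with
# balanced accuracy, leave-one-neuron-out rate prediction, the spike-count
# logistic baseline decoder, and unit-selection filters.

restrict_model <- function(model, neurons) {
  model$C <- model$C[neurons]
  model$Fi <- model$Fi[, neurons, drop = FALSE]
  model$n_neurons <- length(neurons)
  model
}

#' Most probable latent path for one trial (Viterbi)
#'
#' Max-sum Viterbi with backtracking over grid-valued latent states at the
#' trial's event times (start, spikes), maximizing the discretized joint
#' log-density of path and data. The inter-event transition kernels are the
#' spike-decay propagators, so the path honours the absence of spikes during
#' intervals, and the terminal factor is the boundary absorption, so the
#' decoded trajectory terminates at -1 or +1 at the trial end. On an exact
#' terminal tie, the boundary on the side of the domain holding the best
#' terminal interior state is chosen.
#'
#' @param model An `sd_model`.
#' @param trial One trial.
#' @param condition Condition index.
#' @param neuron_subset Restrict emissions (and the decay term) to these
#'   neurons, e.g. for leave-one-neuron-out decoding; spikes of other neurons
#'   are dropped from the trial.
#' @return An `sd_path`: `times` (t0, spike times, tE), `states` (decoded x
#'   at event times, with the terminal boundary value at tE), `boundary`
#'   (-1/+1) and the path `logscore`. Dense paths are obtained by linear
#'   interpolation between event-time states ([path_state_at()]).
#' @export
viterbi_path <- function(model, trial, condition = trial$condition,
                         neuron_subset = NULL) {
  times <- trial$times; ids <- trial$ids
  if (!is.null(neuron_subset)) {
    if (!length(neuron_subset)) stop("neuron_subset must be non-empty", call. = FALSE)
    keep <- ids %in% neuron_subset
    times <- times[keep]
    ids <- match(ids[keep], neuron_subset)
    model <- restrict_model(model, neuron_subset)
  }
  gen <- assemble_generator(model, condition, include_decay = TRUE)
  int <- gen$interior
  p0 <- model_p0(model)[int]
  fint <- model_tuning(model)[int, , drop = FALSE]
  res <- fp_viterbi_cpp(gen$V, gen$Vinv, gen$mu, gen$wint,
                        log(pmax(p0, 1e-300)), log(pmax(fint, 1e-300)),
                        gen$aL, gen$aR,
                        diff(c(trial$t0, times, trial$tE)),
                        as.integer(ids - 1L))
  if (!is.finite(res$logscore) || res$logscore < -1e200)
    stop("no admissible latent path for this trial", call. = FALSE)
  xs <- model$grid$nodes[int][res$states + 1L]
  structure(list(times = c(trial$t0, times, trial$tE),
                 states = c(xs, as.numeric(res$boundary)),
                 boundary = as.integer(res$boundary),
                 logscore = res$logscore),
            class = "sd_path")
}

#' Latent state along a decoded path at arbitrary times
#' @param path An `sd_path`.
#' @param t Times (clamped to the trial window).
#' @return Interpolated latent states.
#' @export
path_state_at <- function(path, t) {
  stats::approx(path$times, path$states, xout = pmin(pmax(t, path$times[1]),
                                                     path$times[length(path$times)]),
                ties = "ordered")$y
}

#' Predicted firing rate of one neuron along a decoded path
#' @param model An `sd_model`.
#' @param path An `sd_path`.
#' @param neuron Neuron index.
#' @param t Times at which to evaluate the rate.
#' @return Rates (Hz), the tuning function evaluated along the path.
#' @export
path_rate <- function(model, path, neuron, t) {
  f <- model_tuning(model)[, neuron]
  xs <- path_state_at(path, t)
  stats::approx(model$grid$nodes, f, xout = xs, rule = 2, ties = "ordered")$y
}

cv2 <- function(isi) {
  if (length(isi) < 2) return(NA_real_)
  stats::var(isi) / mean(isi)^2
}

#' Spike-time R^2 by time rescaling
#'
#' Fraction of single-trial spike-time variation explained by a rate
#' prediction. Total variation is the squared coefficient of variation of raw
#' ISIs; residual variation is the CV^2 of ISIs after rescaling spike times
#' into operational time t' = int lambda dt (trapezoidal rule) with the
#' predicted rate, which removes the predicted rate variation and leaves the
#' point-process variability. R^2 = 1 - CV^2_residual / CV^2_total; the
#' constant-rate baseline gives exactly 0. Conditions are analysed
#' separately and averaged.
#'
#' @param data An `sd_spikedata`.
#' @param rates List, one element per trial: list(time, rate) giving the
#'   predicted rate trace of the analysed neuron over [t0, tE].
#' @param neuron Neuron whose spikes are analysed.
#' @param min_spikes Per-condition spike floor; conditions below it are
#'   flagged as unreliable (default 600).
#' @return List with `r2` (average over usable conditions), `per_condition`
#'   data frame (condition, cv2_total, cv2_residual, r2, n_spikes,
#'   n_excluded_trials, enough_spikes).
#' @export
spike_time_r2 <- function(data, rates, neuron = 1L, min_spikes = 600L) {
  conds <- trial_conditions(data)
  res <- lapply(sort(unique(conds)), function(l) {
    raw <- c(); resc <- c(); nsp <- 0L; nexcl <- 0L
    for (k in which(conds == l)) {
      tr <- data$trials[[k]]
      st <- tr$times[tr$ids == neuron]
      nsp <- nsp + length(st)
      if (length(st) < 3) { nexcl <- nexcl + 1L; next }   # < 2 ISIs
      rt <- rates[[k]]
      if (any(!is.finite(rt$rate)) || any(rt$rate < 0))
        stop("predicted rate must be finite and non-negative", call. = FALSE)
      grid_t <- sort(unique(c(rt$time, st)))
      lam <- stats::approx(rt$time, rt$rate, xout = grid_t, rule = 2,
                           ties = "ordered")$y
      Lam <- c(0, cumsum(diff(grid_t) * (lam[-1] + lam[-length(lam)]) / 2))
      tprime <- stats::approx(grid_t, Lam, xout = st, ties = "ordered")$y
      raw <- c(raw, diff(st))
      resc <- c(resc, diff(tprime))
    }
    data.frame(condition = l, cv2_total = cv2(raw), cv2_residual = cv2(resc),
               r2 = 1 - cv2(resc) / cv2(raw), n_spikes = nsp,
               n_excluded_trials = nexcl, enough_spikes = nsp >= min_spikes)
  })
  per <- do.call(rbind, res)
  ok <- is.finite(per$r2)
  list(r2 = if (any(ok)) mean(per$r2[ok]) else NA_real_, per_condition = per)
}

#' Point-process variability phi from spike-count moments
#'
#' For a doubly stochastic renewal process, spike-count mean and variance at
#' two bin sizes T and 2T determine the operational-time ISI variability phi
#' (CV^2 of rescaled ISIs: 1 for Poisson, < 1 for more regular spiking)
#' through the quadratic
#' (phi^2 - 1)/2 - (4 E[N_T] - E[N_2T]) phi + 4 Var(N_T) - Var(N_2T) = 0.
#' Both roots are reported; the admissible root is the one in (0, 2] closest
#' to the plug-in CV^2 of the raw ISIs (for exact Poisson moments the roots
#' are {1, 4 mu - 1} and the admissible root is 1).
#'
#' @param spike_trains List of per-trial spike-time vectors.
#' @param durations Per-trial durations (s); defaults to the last spike time.
#' @param bin_size Bin size T (s).
#' @return List with `phi`, `roots`, `plug_in`, `failed`.
#' @export
estimate_phi <- function(spike_trains, durations = NULL, bin_size = 0.05) {
  counts_at <- function(T) {
    unlist(lapply(seq_along(spike_trains), function(k) {
      st <- spike_trains[[k]]
      dur <- if (is.null(durations)) max(st, 0) else durations[k]
      nb <- floor(dur / T)
      if (nb < 1) return(integer(0))
      tabulate(pmin(floor(st[st < nb * T] / T) + 1L, nb), nbins = nb)
    }))
  }
  nT <- counts_at(bin_size); n2T <- counts_at(2 * bin_size)
  if (length(nT) < 10 || length(n2T) < 5)
    return(list(phi = NA_real_, roots = c(NA_real_, NA_real_),
                plug_in = NA_real_, failed = TRUE))
  isis <- unlist(lapply(spike_trains, function(st) if (length(st) > 2) diff(st) else numeric(0)))
  plug_in <- cv2(isis)
  phi_from_moments(mean(nT), stats::var(nT), mean(n2T), stats::var(n2T), plug_in)
}

#' Solve the phi quadratic from given spike-count moments
#' @param mean_T,var_T,mean_2T,var_2T Spike-count moments at bin sizes T, 2T.
#' @param plug_in Plug-in CV^2 used to pick the admissible root (default 1).
#' @return List with `phi`, `roots`, `plug_in`, `failed`.
#' @export
phi_from_moments <- function(mean_T, var_T, mean_2T, var_2T, plug_in = 1) {
  # phi^2 - 2 (4 E[N_T] - E[N_2T]) phi + (8 Var(N_T) - 2 Var(N_2T) - 1) = 0
  bq <- -2 * (4 * mean_T - mean_2T)
  cq <- 8 * var_T - 2 * var_2T - 1
  disc <- bq^2 - 4 * cq
  if (!is.finite(disc) || disc < 0)
    return(list(phi = NA_real_, roots = c(NA_real_, NA_real_),
                plug_in = plug_in, failed = TRUE))
  roots <- sort((-bq + c(-1, 1) * sqrt(disc)) / 2)
  adm <- roots[roots > 0 & roots <= 2]
  if (!length(adm)) adm <- roots
  if (!is.finite(plug_in)) plug_in <- 1
  phi <- adm[which.min(abs(adm - min(plug_in, 2)))]
  list(phi = phi, roots = roots, plug_in = plug_in, failed = FALSE)
}

#' Predict the behavioural choice of one trial from its decoded path
#'
#' The decoded latent path terminates on a boundary; the choice is the sign
#' of the terminal state x(tE).
#'
#' @param model An `sd_model`.
#' @param trial One trial.
#' @param condition Condition index.
#' @return -1 (left boundary) or +1 (right boundary).
#' @export
predict_choice <- function(model, trial, condition = trial$condition) {
  viterbi_path(model, trial, condition)$boundary
}

#' Balanced accuracy of binary predictions
#'
#' Average of the true-positive and true-negative rates; invariant to class
#' relabelling and robust to class imbalance. With a single observed class
#' only that class's rate is defined and a constant predictor scores 0.5
#' against a two-class truth.
#'
#' @param pred,truth Vectors of class labels (-1/+1 or any two values).
#' @return Scalar in [0, 1].
#' @export
balanced_accuracy <- function(pred, truth) {
  cls <- sort(unique(truth))
  mean(vapply(cls, function(cl)
    mean(pred[truth == cl] == cl), numeric(1)))
}

#' Leave-one-neuron-out rate prediction and likelihood
#'
#' Decodes the latent path from the spikes of all neurons except the held-out
#' one, predicts the held-out neuron's rate through its tuning function at
#' the decoded states, interpolates the rate with a cubic spline to the
#' held-out neuron's spike times, and evaluates the inhomogeneous-Poisson
#' log-likelihood (trapezoidal time integral).
#'
#' @param model An `sd_model` with at least two neurons.
#' @param trial One trial.
#' @param held_out Index of the held-out neuron.
#' @param condition Condition index.
#' @param dt_eval Evaluation grid step for the rate trace (s).
#' @return List with `time`, `rate` (spline-interpolated trace), `loglik`.
#' @export
lono_rate <- function(model, trial, held_out, condition = trial$condition,
                      dt_eval = 0.005) {
  if (model$n_neurons < 2) stop("LONO needs at least 2 neurons", call. = FALSE)
  others <- setdiff(seq_len(model$n_neurons), held_out)
  path <- viterbi_path(model, trial, condition, neuron_subset = others)
  # rate of the held-out neuron at the other neurons' event times
  ev_t <- path$times
  ev_rate <- path_rate(model, path, held_out, ev_t)
  tt <- seq(trial$t0, trial$tE, by = dt_eval)
  if (tt[length(tt)] < trial$tE) tt <- c(tt, trial$tE)
  st <- trial$times[trial$ids == held_out]
  if (length(unique(ev_t)) >= 4) {
    sp <- stats::splinefun(ev_t, ev_rate, method = "natural")
    rate_tt <- pmax(sp(tt), 0)
    rate_st <- pmax(sp(st), 0)
  } else {
    rate_tt <- stats::approx(ev_t, ev_rate, xout = tt, rule = 2, ties = "ordered")$y
    rate_st <- stats::approx(ev_t, ev_rate, xout = st, rule = 2, ties = "ordered")$y
  }
  integral <- sum(diff(tt) * (rate_tt[-1] + rate_tt[-length(rate_tt)]) / 2)
  ll <- if (any(rate_st <= 0)) -Inf else -integral + sum(log(rate_st))
  list(time = tt, rate = rate_tt, loglik = ll)
}

sliding_counts <- function(trial, neuron, width, step, t_len) {
  nb <- floor((t_len - width) / step)
  starts <- (seq_len(nb) - 1L) * step
  st <- trial$times[trial$ids == neuron] - trial$t0
  vapply(starts, function(s) sum(st >= s & st < s + width), numeric(1))
}

#' Spike-count logistic baseline for choice prediction
#'
#' Trains a linear (ridge-regularized logistic) classifier on spike counts in
#' 75-ms windows sliding in 10-ms steps over the first 0.5 s of each trial
#' (42 windows per neuron), z-scored per condition and window, using two
#' cross-validation folds (train on one half, validate on the other, both
#' directions). Conditions lacking at least `min_errors` incorrect choices in
#' either half are excluded.
#'
#' @param data An `sd_spikedata` whose trials carry `choice` and `correct`.
#' @param truncate_at Counting window length (s).
#' @param width,step Sliding-window parameters (s).
#' @param lambda Ridge penalty of the logistic fit.
#' @param min_errors Minimum incorrect choices per condition and half.
#' @return List with `balanced_accuracy`, `n_bins`, `conditions_used`.
#' @export
baseline_decoder <- function(data, truncate_at = 0.5, width = 0.075,
                             step = 0.01, lambda = 0.01, min_errors = 5L) {
  conds <- trial_conditions(data)
  choice <- vapply(data$trials, function(tr)
    if (is.null(tr$choice)) NA_real_ else as.numeric(tr$choice), numeric(1))
  correct <- vapply(data$trials, function(tr)
    if (is.null(tr$correct)) NA else isTRUE(tr$correct), logical(1))
  nb <- floor((truncate_at - width) / step)
  M <- data$n_neurons
  X <- t(vapply(data$trials, function(tr)
    unlist(lapply(seq_len(M), function(i)
      sliding_counts(tr, i, width, step, truncate_at))), numeric(nb * M)))
  pos <- integer(length(conds))
  for (l in unique(conds)) pos[conds == l] <- seq_len(sum(conds == l))
  fold <- ifelse(pos %% 2L == 0L, 1L, 2L)
  used <- c()
  for (l in unique(conds)) {
    ok <- TRUE
    for (h in 1:2) {
      idx <- conds == l & fold == h
      if (sum(!correct[idx], na.rm = TRUE) < min_errors) ok <- FALSE
    }
    if (ok) used <- c(used, l)
  }
  if (!length(used)) return(list(balanced_accuracy = NA_real_, n_bins = nb,
                                 conditions_used = integer(0)))
  keep <- conds %in% used & !is.na(choice)
  preds <- rep(NA_real_, length(conds))
  for (h in 1:2) {
    tr_idx <- which(keep & fold == h)
    va_idx <- which(keep & fold != h)
    Xtr <- X[tr_idx, , drop = FALSE]; Xva <- X[va_idx, , drop = FALSE]
    # z-score per condition per bin with training statistics
    for (l in used) {
      ct <- conds[tr_idx] == l; cv <- conds[va_idx] == l
      mu <- colMeans(Xtr[ct, , drop = FALSE])
      sdv <- apply(Xtr[ct, , drop = FALSE], 2, stats::sd)
      sdv[!is.finite(sdv) | sdv == 0] <- 1
      Xtr[ct, ] <- sweep(sweep(Xtr[ct, , drop = FALSE], 2, mu), 2, sdv, "/")
      Xva[cv, ] <- sweep(sweep(Xva[cv, , drop = FALSE], 2, mu), 2, sdv, "/")
    }
    y <- factor(choice[tr_idx])
    if (nlevels(y) < 2) next
    fitl <- glmnet::glmnet(Xtr, y, family = "binomial", alpha = 0,
                           lambda = lambda, standardize = FALSE)
    pr <- stats::predict(fitl, Xva, type = "class")
    preds[va_idx] <- as.numeric(pr)
  }
  ok <- !is.na(preds)
  list(balanced_accuracy = balanced_accuracy(preds[ok], choice[ok]),
       n_bins = nb, conditions_used = used)
}

roc_auc <- function(x_pos, x_neg) {
  if (!length(x_pos) || !length(x_neg)) return(NA_real_)
  r <- rank(c(x_pos, x_neg))
  (sum(r[seq_along(x_pos)]) - length(x_pos) * (length(x_pos) + 1) / 2) /
    (length(x_pos) * length(x_neg))
}

#' Unit-selection filters
#'
#' A unit passes if (1) its choice-sorted trial-averaged rate (75-ms windows,
#' 10-ms steps) reaches `rate_threshold` Hz for at least one choice side at
#' some time between the window start and the median reaction time, (2) the
#' total number of trials is at least `min_trials`, and (3) the selectivity
#' index (ROC area for discriminating choice from spike counts in the
#' `count_window` after the window start) exceeds `selectivity_threshold`.
#'
#' @param data An `sd_spikedata` whose trials carry `choice`.
#' @param rate_threshold PSTH peak requirement (Hz, default 15).
#' @param min_trials Trial-count requirement (default 560).
#' @param selectivity_threshold ROC threshold (defaults 0.6; 0.55 for
#'   weakly selective datasets).
#' @param count_window Two times (s) bounding the selectivity count window.
#' @return Data frame: unit, pass, and the three criterion values/flags.
#' @export
unit_selection <- function(data, rate_threshold = 15, min_trials = 560L,
                           selectivity_threshold = 0.6,
                           count_window = c(0.2, 0.35)) {
  choice <- vapply(data$trials, function(tr)
    if (is.null(tr$choice)) NA_real_ else as.numeric(tr$choice), numeric(1))
  med_rt <- stats::median(vapply(data$trials, function(tr) tr$tE - tr$t0, numeric(1)))
  n_tr <- length(data$trials)
  out <- lapply(seq_len(data$n_neurons), function(i) {
    peak <- 0
    for (side in c(-1, 1)) {
      idx <- which(choice == side)
      if (!length(idx)) next
      ps <- psth_rate(data, idx, i, t_end = med_rt)
      keep <- ps$time <= med_rt
      if (any(keep)) peak <- max(peak, max(ps$rate[keep]))
    }
    counts <- vapply(data$trials, function(tr)
      sum(tr$times[tr$ids == i] >= tr$t0 + count_window[1] &
            tr$times[tr$ids == i] < tr$t0 + count_window[2]), numeric(1))
    auc <- roc_auc(counts[which(choice == 1)], counts[which(choice == -1)])
    sel <- max(auc, 1 - auc)   # side-symmetric selectivity index
    data.frame(unit = i, peak_rate = peak, n_trials = n_tr, selectivity = sel,
               pass = peak >= rate_threshold && n_tr >= min_trials &&
                 is.finite(sel) && sel > selectivity_threshold)
  })
  do.call(rbind, out)
}
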