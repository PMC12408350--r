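# Trial and dataset likelihoods of the latent Langevin model, the PSTH
# baseline likelihood, and analytic likelihood gradients for all model
# components. Spikes are processed in continuous time, spike by spike; the
# density vector is rescaled per interval so products over hundreds of spikes
# do not underflow.

trial_to_cpp <- function(trial) {
  list(dts = diff(c(trial$t0, trial$times, trial$tE)),
       ids = as.integer(trial$ids - 1L))
}

#' Joint likelihood of one trial's spikes and reaction time
#'
#' Evaluates the chain p0 -> [ISI propagation with spike decay -> emission] ->
#' final propagation -> boundary absorption as grid vector/operator products.
#' `log_full` is the joint log-density of the observed spikes and of the first
#' passage at tE; `log_tE` is the log-density of the first passage alone
#' (propagation without the decay term); `log_normalized` is their difference,
#' the log-density of the spikes given the reaction time, comparable across
#' models with different boundary treatment of the reaction time.
#'
#' @param model An `sd_model`.
#' @param trial One trial (list with `t0`, `tE`, `times`, `ids`).
#' @param condition Condition index.
#' @param gen,gen0 Optional pre-assembled generators (with and without the
#'   decay term) to amortize the eigendecomposition over many trials.
#' @return List with `log_full`, `log_tE`, `log_normalized` (-Inf allowed).
#' @export
trial_loglik <- function(model, trial, condition = trial$condition,
                         gen = NULL, gen0 = NULL) {
  if (length(trial$times) > 0 &&
      (trial$times[1] <= trial$t0 || trial$times[length(trial$times)] >= trial$tE))
    stop("spike outside (t0, tE)", call. = FALSE)
  if (is.null(gen)) gen <- assemble_generator(model, condition, include_decay = TRUE)
  if (is.null(gen0)) gen0 <- assemble_generator(model, condition, include_decay = FALSE)
  int <- gen$interior
  p0 <- model_p0(model)[int]
  fint <- model_tuning(model)[int, , drop = FALSE]
  tc <- trial_to_cpp(trial)
  log_full <- fp_trial_loglik_cpp(gen$V, gen$Vinv, gen$mu, gen$wint, p0, fint,
                                  gen$aL + gen$aR, tc$dts, tc$ids)
  log_tE <- fp_trial_loglik_cpp(gen0$V, gen0$Vinv, gen0$mu, gen0$wint, p0, fint,
                                gen0$aL + gen0$aR, trial$tE - trial$t0, integer(0))
  list(log_full = log_full, log_tE = log_tE,
       log_normalized = log_full - log_tE)
}

#' Dataset log-likelihood
#'
#' Sum of per-trial log values (trials are independent, so the total data
#' likelihood is the product over trials).
#'
#' @param model An `sd_model`.
#' @param data An `sd_spikedata`; trial conditions index into the model.
#' @param which `"full"` for the joint spikes-and-reaction-time density,
#'   `"normalized"` for the spikes-given-reaction-time density, `"tE"` for the
#'   reaction-time marginal alone.
#' @return Scalar log-likelihood.
#' @export
dataset_loglik <- function(model, data, which = c("full", "normalized", "tE")) {
  which <- match.arg(which)
  if (!is_spikedata(data)) stop("expected sd_spikedata", call. = FALSE)
  conds <- trial_conditions(data)
  if (any(conds > model$n_conditions))
    stop("trial condition not present in model", call. = FALSE)
  int <- model$grid$interior
  p0 <- model_p0(model)[int]
  fint <- model_tuning(model)[int, , drop = FALSE]
  total <- 0
  for (l in sort(unique(conds))) {
    idx <- which(conds == l)
    if (which != "tE") {
      gen <- assemble_generator(model, l, TRUE)
      tc <- lapply(data$trials[idx], trial_to_cpp)
      total <- total + sum(fp_batch_loglik_cpp(gen$V, gen$Vinv, gen$mu, gen$wint,
                                               p0, fint, gen$aL + gen$aR, tc))
    }
    if (which != "full") {
      gen0 <- assemble_generator(model, l, FALSE)
      tc0 <- lapply(data$trials[idx], function(tr)
        list(dts = tr$tE - tr$t0, ids = integer(0)))
      v <- sum(fp_batch_loglik_cpp(gen0$V, gen0$Vinv, gen0$mu, gen0$wint,
                                   p0, fint, gen0$aL + gen0$aR, tc0))
      total <- total + if (which == "tE") v else -v
    }
  }
  total
}

#' Inhomogeneous-Poisson log-likelihood of one neuron's spikes under a given
#' rate trace (the PSTH baseline)
#'
#' -int lambda dt + sum_j log lambda(t_j), with the time integral by the
#' trapezoidal rule on the rate-trace grid restricted to [t0, tE]. The rate is
#' linearly interpolated at spike times; outside the trace range the nearest
#' value is used.
#'
#' @param rate_trace List with `time` (trace times, s) and `rate` (Hz).
#' @param trial One trial.
#' @param neuron Neuron index whose spikes are evaluated.
#' @return Scalar log-likelihood (-Inf if a spike falls where the rate is 0).
#' @export
psth_loglik <- function(rate_trace, trial, neuron) {
  tt <- rate_trace$time; rr <- rate_trace$rate
  if (length(tt) < 2) stop("rate trace needs at least two points", call. = FALSE)
  rate_at <- function(t) {
    t <- pmin(pmax(t, tt[1]), tt[length(tt)])
    stats::approx(tt, rr, xout = t, rule = 2)$y
  }
  grid_t <- sort(unique(c(trial$t0, tt[tt > trial$t0 & tt < trial$tE], trial$tE)))
  lam <- rate_at(grid_t)
  integral <- sum(diff(grid_t) * (lam[-1] + lam[-length(lam)]) / 2)
  st <- trial$times[trial$ids == neuron]
  lam_s <- rate_at(st)
  if (any(lam_s <= 0)) return(-Inf)
  -integral + sum(log(lam_s))
}

#' Trial-averaged firing rates in sliding windows (PSTH)
#'
#' Counts spikes in windows of `width` seconds sliding in `step` second
#' increments from the analysed-window start, averaged across the given
#' trials; a trial contributes to a window while the window start precedes its
#' end time.
#'
#' @param data An `sd_spikedata`.
#' @param trial_idx Trials to average over.
#' @param neuron Neuron index.
#' @param width,step Window width and step (defaults 75 ms / 10 ms).
#' @param t_end Latest window start; defaults to the maximum trial end time.
#' @return List with `time` (window centres) and `rate` (Hz).
#' @export
psth_rate <- function(data, trial_idx, neuron, width = 0.075, step = 0.01,
                      t_end = NULL) {
  trials <- data$trials[trial_idx]
  t0 <- min(vapply(trials, function(tr) tr$t0, numeric(1)))
  if (is.null(t_end)) t_end <- max(vapply(trials, function(tr) tr$tE, numeric(1)))
  starts <- seq(t0, max(t0, t_end - width), by = step)
  counts <- numeric(length(starts)); nn <- numeric(length(starts))
  for (tr in trials) {
    st <- tr$times[tr$ids == neuron]
    live <- starts < tr$tE
    nn[live] <- nn[live] + 1
    if (length(st)) {
      for (b in which(live)) {
        counts[b] <- counts[b] + sum(st >= starts[b] & st < starts[b] + width)
      }
    }
  }
  rate <- ifelse(nn > 0, counts / (nn * width), 0)
  list(time = starts + width / 2, rate = rate)
}

#' Analytic gradients of the dataset log-likelihood
#'
#' Returns the variational derivatives of the summed log-likelihood with
#' respect to the per-condition force values and the shared auxiliary
#' functions, and the derivatives with respect to the scalars D and Ci.
#' Shared-component gradients are sums of per-condition contributions. The
#' gradients are exact for the discretized likelihood (they match central
#' finite differences of [dataset_loglik()]).
#'
#' @param model An `sd_model`.
#' @param data An `sd_spikedata`.
#' @param conditions Conditions to include (default: all present in data).
#' @return List with `dF` (matrix, per condition), `dF0`, `dFi` (matrix, per
#'   neuron), `dD`, `dC`, and the summed `loglik`.
#' @export
likelihood_gradients <- function(model, data, conditions = NULL) {
  conds <- trial_conditions(data)
  if (is.null(conditions)) conditions <- sort(unique(conds))
  by_cond <- lapply(conditions, function(l)
    lapply(data$trials[conds == l], trial_to_cpp))
  names(by_cond) <- as.character(conditions)
  gradients_core(model, by_cond)
}

# fast full-likelihood evaluation on precomputed trial lists
loglik_core <- function(model, by_cond) {
  int <- model$grid$interior
  p0 <- model_p0(model)[int]
  fint <- model_tuning(model)[int, , drop = FALSE]
  tot <- 0
  for (lc in names(by_cond)) {
    trials <- by_cond[[lc]]
    if (!length(trials)) next
    gen <- assemble_generator(model, as.integer(lc), TRUE)
    tot <- tot + sum(fp_batch_loglik_cpp(gen$V, gen$Vinv, gen$mu, gen$wint,
                                         p0, fint, gen$aL + gen$aR, trials))
  }
  tot
}

# by_cond: named list (condition -> list of trial_to_cpp() lists)
gradients_core <- function(model, by_cond) {
  g <- model$grid
  int <- g$interior
  n <- g$n; M <- model$n_neurons
  p0_full <- model_p0(model)
  f_full <- model_tuning(model)
  dF <- matrix(0, n, model$n_conditions)
  df_full <- matrix(0, n, M)    # dlogL / d f_i(x) at nodes
  dp0_full <- numeric(n)
  dD <- 0; loglik <- 0; n_trials_ok <- 0
  for (lc in names(by_cond)) {
    l <- as.integer(lc)
    trials <- by_cond[[lc]]
    if (!length(trials)) next
    gen <- assemble_generator(model, l, include_decay = TRUE)
    res <- fp_batch_grad_cpp(gen$V, gen$Vinv, gen$mu, gen$wint,
                             p0_full[int], f_full[int, , drop = FALSE],
                             gen$aL + gen$aR, trials)
    loglik <- loglik + res$loglik
    n_trials_ok <- n_trials_ok + res$n_ok
    G <- res$G
    D1i <- g$D1[int, int]; D2i <- g$D2[int, int]
    dF[int, l] <- dF[int, l] + model$D * colSums(G * D1i)
    ddiag <- diag(G)
    for (i in seq_len(M)) df_full[int, i] <- df_full[int, i] + res$demis[, i] + ddiag
    dp0_full[int] <- dp0_full[int] + res$dp0
    Fint <- model$forces[int, l]
    dD <- dD + sum(G * (D1i %*% diag(Fint) - D2i)) + res$n_ok / model$D
  }
  # chain to auxiliary parametrizations
  w <- g$weights
  # p0(x) = exp(cumint F0) / normalization
  s <- dp0_full * p0_full
  c0 <- sum(s)
  dF0 <- as.numeric(t(g$cumint) %*% s - c0 * (t(g$cumint) %*% (w * p0_full)))
  # f_i(x) = Ci exp(cumint Fi)
  dFi <- matrix(0, n, M); dC <- numeric(M)
  for (i in seq_len(M)) {
    gf <- df_full[, i] * f_full[, i]
    dFi[, i] <- as.numeric(t(g$cumint) %*% gf)
    dC[i] <- if (model$C[i] > 0) sum(gf) / model$C[i] else sum(df_full[, i] * exp(as.numeric(g$cumint %*% model$Fi[, i])))
  }
  list(dF = dF, dF0 = dF0, dFi = dFi, dD = dD, dC = dC,
       loglik = loglik, n_trials = n_trials_ok)
}
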