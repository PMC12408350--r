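# Maximum-likelihood fitting of all model components with a functional
# variant of ADAM: function-valued components (force, initial-density and
# tuning auxiliaries) are scaled by the running average of the squared L2
# norm of their gradient (one scalar per function, not per node), while the
# scalars D and Ci use standard per-parameter ADAM plus periodic bounded
# quasi-Newton line searches. Mini-batches are drawn per condition; in shared
# optimization the batches of all conditions are pooled and visited in random
# order, condition forces are updated only on their own condition's batches,
# and shared components on every batch.

#' Fitting configuration
#'
#' Defaults follow the reference optimization protocol: learning rate 0.05
#' (use 0.01--0.05 for populations), ADAM moments (0.9, 0.99), epsilon 1e-8,
#' 20 mini-batches per condition, 5000 epochs and 30 line searches spaced
#' logarithmically over the epochs (so most land early).
#'
#' @param alpha Learning rate.
#' @param beta1,beta2,epsilon ADAM moment parameters.
#' @param n_batches Mini-batches per condition and epoch.
#' @param n_epochs Optimization epochs.
#' @param n_line_searches Number of scalar line searches on (D, {Ci}).
#' @param seed RNG seed controlling batching (and anything downstream).
#' @param grid_n Grid size used when the caller does not supply a grid.
#' @param js_threshold Jensen--Shannon consistency threshold for selection.
#' @param shared Restrict F0, {Fi} and D to be equal across conditions while
#'   the force may differ (the only supported mode; a non-shared fit is a fit
#'   to a single condition's trials).
#' @param D_init Initial noise magnitude.
#' @param line_search_maxit Quasi-Newton iterations per line search.
#' @param line_search_in_adam If `FALSE`, scalars are updated by line searches
#'   only, not by ADAM in between.
#' @param store_every Keep a model snapshot every this many epochs (the
#'   complexity scalar is recorded for every stored snapshot).
#' @param n_modes Functional gradients are projected onto the leading
#'   Chebyshev modes before each update (default 16): the likelihood has
#'   almost no curvature along node-scale oscillations of the force and
#'   auxiliary functions, so normalized updates would otherwise accumulate
#'   discretization noise there.
#' @return A list of class `sd_fitconfig`.
#' @export
fit_config <- function(alpha = 0.05, beta1 = 0.9, beta2 = 0.99, epsilon = 1e-8,
                       n_batches = 20L, n_epochs = 5000L, n_line_searches = 30L,
                       seed = 1L, grid_n = 256L, js_threshold = 0.0015,
                       shared = TRUE, D_init = 0.1, line_search_maxit = 4L,
                       line_search_in_adam = TRUE, store_every = 1L,
                       n_modes = 16L) {
  structure(list(alpha = alpha, beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 n_batches = as.integer(n_batches), n_epochs = as.integer(n_epochs),
                 n_line_searches = as.integer(n_line_searches),
                 seed = as.integer(seed), grid_n = as.integer(grid_n),
                 js_threshold = js_threshold, shared = isTRUE(shared),
                 D_init = D_init, line_search_maxit = as.integer(line_search_maxit),
                 line_search_in_adam = isTRUE(line_search_in_adam),
                 store_every = as.integer(store_every),
                 n_modes = as.integer(n_modes)),
            class = "sd_fitconfig")
}

adam_init_state <- function(n, n_conditions, n_neurons) {
  fun_state <- function(len) list(m = numeric(len), v = 0, t = 0L)
  sc_state <- function() list(m = 0, v = 0, t = 0L)
  list(F = lapply(seq_len(n_conditions), function(l) fun_state(n)),
       F0 = fun_state(n),
       Fi = lapply(seq_len(n_neurons), function(i) fun_state(n)),
       D = sc_state(),
       C = lapply(seq_len(n_neurons), function(i) sc_state()))
}

adam_fun_update <- function(st, g, cfg) {
  st$t <- st$t + 1L
  st$m <- cfg$beta1 * st$m + (1 - cfg$beta1) * g
  st$v <- cfg$beta2 * st$v + (1 - cfg$beta2) * sum(g^2)
  mhat <- st$m / (1 - cfg$beta1^st$t)
  vhat <- st$v / (1 - cfg$beta2^st$t)
  list(state = st, delta = -cfg$alpha * mhat / (sqrt(vhat) + cfg$epsilon))
}

adam_sc_update <- function(st, g, cfg) {
  st$t <- st$t + 1L
  st$m <- cfg$beta1 * st$m + (1 - cfg$beta1) * g
  st$v <- cfg$beta2 * st$v + (1 - cfg$beta2) * g^2
  mhat <- st$m / (1 - cfg$beta1^st$t)
  vhat <- st$v / (1 - cfg$beta2^st$t)
  list(state = st, delta = -cfg$alpha * mhat / (sqrt(vhat) + cfg$epsilon))
}

#' One functional ADAM step
#'
#' Applies a descent step on the negative log-likelihood. Function-valued
#' components receive a single scalar scale each (running average of the
#' squared L2 gradient norm); scalars D and Ci use standard ADAM and are
#' rectified to be non-negative after the update.
#'
#' @param state Moment accumulators from [adam_init_state] (or a previous step).
#' @param grads Gradient bundle from [likelihood_gradients()] (gradients of
#'   the log-likelihood; the step ascends it).
#' @param model Current `sd_model` (the raw D may be 0 after rectification;
#'   evaluation floors it).
#' @param config An `sd_fitconfig`.
#' @param conditions Conditions whose force receives an update (a mini-batch
#'   updates only its own condition's force).
#' @param update_scalars Whether D and Ci are updated on this step.
#' @return List with updated `state` and `model`.
#' @export
adam_functional_step <- function(state, grads, model, config,
                                 conditions = seq_len(model$n_conditions),
                                 update_scalars = TRUE) {
  for (l in conditions) {
    up <- adam_fun_update(state$F[[l]], -grads$dF[, l], config)
    state$F[[l]] <- up$state
    model$forces[, l] <- model$forces[, l] + up$delta
  }
  up <- adam_fun_update(state$F0, -grads$dF0, config)
  state$F0 <- up$state
  model$F0 <- model$F0 + up$delta
  for (i in seq_len(model$n_neurons)) {
    up <- adam_fun_update(state$Fi[[i]], -grads$dFi[, i], config)
    state$Fi[[i]] <- up$state
    model$Fi[, i] <- model$Fi[, i] + up$delta
  }
  if (update_scalars) {
    up <- adam_sc_update(state$D, -grads$dD, config)
    state$D <- up$state
    model$D <- max(model$D + up$delta, 0)
    for (i in seq_len(model$n_neurons)) {
      up <- adam_sc_update(state$C[[i]], -grads$dC[i], config)
      state$C[[i]] <- up$state
      model$C[i] <- max(model$C[i] + up$delta, 0)
    }
  }
  list(state = state, model = model)
}

# Evaluation copy of the model: the optimizer may drive D (or Ci) to the
# rectification boundary; the likelihood floors D so the generator stays
# well-posed while the raw optimizer value is retained.
eval_model <- function(model, D_floor = 1e-8) {
  model$D <- max(model$D, D_floor)
  model
}

# Fraction of choice-labelled trials whose absorption mass under the model
# sits on the chosen boundary. Used to fix the reflection gauge of a fit.
orientation_score <- function(model, data) {
  conds <- trial_conditions(data)
  choice <- vapply(data$trials, function(tr)
    if (is.null(tr$choice) || is.na(tr$choice)) NA_real_ else as.numeric(tr$choice),
    numeric(1))
  int <- model$grid$interior
  p0 <- model_p0(model)[int]
  fint <- model_tuning(model)[int, , drop = FALSE]
  num <- 0; den <- 0
  for (l in sort(unique(conds))) {
    gen <- assemble_generator(model, l, TRUE)
    for (k in which(conds == l & !is.na(choice))) {
      tc <- trial_to_cpp(data$trials[[k]])
      ab <- fp_trial_absorb_cpp(gen$V, gen$Vinv, gen$mu, gen$wint, p0, fint,
                                gen$aL, gen$aR, tc$dts, tc$ids)
      if (any(is.na(ab)) || sum(ab) <= 0) next
      num <- num + (if (choice[k] > 0) ab[2] else ab[1]) / sum(ab)
      den <- den + 1
    }
  }
  if (den == 0) NA_real_ else num / den
}

line_search_schedule <- function(n_epochs, n_line_searches) {
  if (n_line_searches <= 0L) return(integer(0))
  unique(pmax(1L, as.integer(round(exp(seq(log(1), log(n_epochs),
                                           length.out = n_line_searches))))))
}

scalar_line_search <- function(model, by_cond, config) {
  M <- model$n_neurons
  pack <- function(m) c(m$D, m$C)
  unpack <- function(th, m) { m$D <- th[1]; m$C <- th[-1]; m }
  fn <- function(th) {
    v <- -loglik_core(eval_model(unpack(th, model)), by_cond)
    if (!is.finite(v)) 1e12 else v
  }
  res <- tryCatch(
    stats::optim(pack(model), fn, method = "L-BFGS-B",
                 lower = c(1e-6, rep(0, M)),
                 control = list(maxit = config$line_search_maxit)),
    error = function(e) NULL)
  if (is.null(res) || !all(is.finite(res$par)) || res$value >= 1e12) return(model)
  unpack(res$par, model)
}

#' Fit the latent model to spike data
#'
#' Mini-batched functional ADAM over all model components, recording a trace
#' of model snapshots and their feature complexity for the feature-consistency
#' model selection. The RNG is fully determined by `config$seed`.
#'
#' @param data An `sd_spikedata` with at least one trial in every condition.
#' @param config An `sd_fitconfig`.
#' @param grid Optional `sd_grid`; defaults to `build_grid(config$grid_n)`.
#' @param init Optional initial `sd_model`; defaults to zero force, uniform
#'   initial density, constant tuning at each neuron's empirical mean rate,
#'   and `D = config$D_init`.
#' @return An `sd_fittrace`: stored `models`, their `epochs`, per-epoch
#'   `complexity` (per condition) and training log-likelihood.
#' @export
fit <- function(data, config = fit_config(), grid = NULL, init = NULL) {
  if (!is_spikedata(data)) stop("expected sd_spikedata", call. = FALSE)
  conds <- trial_conditions(data)
  L <- max(conds)
  if (!setequal(unique(conds), seq_len(L)))
    stop("every condition 1..L must have at least one trial", call. = FALSE)
  if (is.null(grid)) grid <- build_grid(config$grid_n)
  M <- data$n_neurons
  if (is.null(init)) {
    dur <- vapply(data$trials, function(tr) tr$tE - tr$t0, numeric(1))
    cnt <- vapply(seq_len(M), function(i)
      sum(vapply(data$trials, function(tr) sum(tr$ids == i), numeric(1))), numeric(1))
    init <- latent_model(grid, forces = matrix(0, grid$n, L),
                         D = config$D_init, F0 = numeric(grid$n),
                         C = pmax(cnt / sum(dur), 1e-3),
                         Fi = matrix(0, grid$n, M))
  }
  model <- init
  state <- adam_init_state(grid$n, L, M)
  ls_epochs <- line_search_schedule(config$n_epochs, config$n_line_searches)
  cond_idx <- lapply(seq_len(L), function(l) which(conds == l))
  trials_cpp <- lapply(data$trials, trial_to_cpp)
  P <- lowpass_projector(grid, config$n_modes)
  by_cond_all <- lapply(seq_len(L), function(l) trials_cpp[cond_idx[[l]]])
  names(by_cond_all) <- as.character(seq_len(L))

  set.seed(config$seed)
  epochs_stored <- integer(0)
  models <- list()
  complexity <- matrix(NA_real_, config$n_epochs, L)
  train_ll <- rep(NA_real_, config$n_epochs)

  for (ep in seq_len(config$n_epochs)) {
    batches <- list()
    for (l in seq_len(L)) {
      idx <- cond_idx[[l]]
      nb <- min(config$n_batches, length(idx))
      assign_b <- sample(rep(seq_len(nb), length.out = length(idx)))
      for (b in seq_len(nb)) batches[[length(batches) + 1L]] <-
          list(cond = l, idx = idx[assign_b == b])
    }
    batches <- batches[sample(length(batches))]
    ll_epoch <- 0
    for (bt in batches) {
      by_cond <- stats::setNames(list(trials_cpp[bt$idx]), as.character(bt$cond))
      gr <- gradients_core(eval_model(model), by_cond)
      gr$dF <- P %*% gr$dF
      gr$dF0 <- as.numeric(P %*% gr$dF0)
      if (ncol(gr$dFi)) gr$dFi <- P %*% gr$dFi
      if (!is.finite(gr$loglik))
        stop("optimization diverged: non-finite mini-batch log-likelihood at epoch ",
             ep, call. = FALSE)
      ll_epoch <- ll_epoch + gr$loglik
      st <- adam_functional_step(state, gr, model, config, conditions = bt$cond,
                                 update_scalars = config$line_search_in_adam ||
                                   !length(ls_epochs))
      state <- st$state; model <- st$model
    }
    if (ep %in% ls_epochs)
      model <- scalar_line_search(eval_model(model), by_cond_all, config)
    train_ll[ep] <- ll_epoch
    for (l in seq_len(L))
      complexity[ep, l] <- feature_complexity(eval_model(model), l)
    if (ep %% config$store_every == 0L || ep == config$n_epochs) {
      epochs_stored <- c(epochs_stored, ep)
      models[[length(models) + 1L]] <- eval_model(model)
    }
  }
  # Fix the reflection gauge: the likelihood cannot distinguish a model from
  # its mirror image, so orient the fit by the choice labels (right boundary
  # = right choice). Feature complexity is reflection-invariant.
  or <- orientation_score(eval_model(model), data)
  mirrored <- FALSE
  if (is.finite(or) && or < 0.5) {
    models <- lapply(models, mirror_model)
    mirrored <- TRUE
  }
  structure(list(models = models, epochs = epochs_stored,
                 complexity = complexity, train_loglik = train_ll,
                 config = config, n_conditions = L, mirrored = mirrored),
            class = "sd_fittrace")
}

#' @export
print.sd_fittrace <- function(x, ...) {
  cat("Fit trace:", length(x$models), "stored snapshots over",
      nrow(x$complexity), "epochs,", x$n_conditions, "condition(s)\n")
  invisible(x)
}

#' Independent fits on the two standard data halves
#'
#' Splits trials deterministically by their ordinal position within each
#' condition (even positions to the first half, odd to the second), then runs
#' two independent fits with seeds derived from `config$seed`.
#'
#' @param data An `sd_spikedata`.
#' @param config An `sd_fitconfig`.
#' @param grid Optional `sd_grid` shared by both fits.
#' @return List with `trace1`, `trace2`, and the two index vectors
#'   `split1`, `split2`.
#' @export
two_split_fit <- function(data, config = fit_config(), grid = NULL) {
  conds <- trial_conditions(data)
  pos <- integer(length(conds))
  for (l in unique(conds)) pos[conds == l] <- seq_len(sum(conds == l))
  split1 <- which(pos %% 2L == 0L)
  split2 <- which(pos %% 2L == 1L)
  if (!length(split1) || !length(split2))
    stop("need at least 2 trials per condition to split", call. = FALSE)
  cfg1 <- config; cfg1$seed <- (config$seed + 1000003L) %% .Machine$integer.max
  cfg2 <- config; cfg2$seed <- (config$seed + 2000003L) %% .Machine$integer.max
  list(trace1 = fit(subset_trials(data, split1), cfg1, grid = grid),
       trace2 = fit(subset_trials(data, split2), cfg2, grid = grid),
       split1 = split1, split2 = split2)
}
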