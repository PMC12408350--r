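# Feature-consistency model selection: feature complexity as negative
# trajectory entropy relative to free diffusion, Jensen-Shannon consistency
# of the time-dependent latent densities between models fitted on disjoint
# data halves, threshold-based selection, bootstrap uncertainty bands, and
# classification of fit outcomes.

interior_drift_op <- function(model, condition) {
  g <- model$grid; int <- g$interior
  F <- model$forces[, condition]
  H <- model$D * (g$D1 %*% diag(F)) - model$D * g$D2
  H[int, int]
}

#' Feature complexity of one condition's dynamics
#'
#' The negative trajectory entropy of the model relative to a reference free
#' diffusion (constant potential, uniform initial density, same D):
#' M = KL(p0 || uniform) + (D/4) * int_0^inf dt int dx F(x)^2 p(x, t),
#' where p(x, t) is the latent density under the drift--diffusion dynamics
#' with absorbing boundaries. The time integral is evaluated in closed form
#' as int_0^inf exp(-H t) p0 dt = H^{-1} p0 (all eigenvalues of the absorbing
#' generator have positive real part, so the integral converges whenever
#' trajectories are eventually absorbed). The reference model has complexity
#' exactly zero; complexity grows with potential structure.
#'
#' @param model An `sd_model`.
#' @param condition Condition index.
#' @return Non-negative scalar complexity (nats).
#' @export
feature_complexity <- function(model, condition = 1L) {
  g <- model$grid
  p0 <- model_p0(model)
  kl <- sum(g$weights * p0 * log(pmax(p0, 1e-300) / 0.5))
  F <- model$forces[, condition]
  if (all(F == 0)) return(kl)
  int <- g$interior
  y <- tryCatch(solve(interior_drift_op(model, condition), p0[int]),
                error = function(e) NULL)
  if (is.null(y)) {
    warning("time integral of the trajectory entropy did not converge; ",
            "returning the KL term only as a lower bound")
    return(kl)
  }
  kl + (model$D / 4) * sum(g$weights[int] * F[int]^2 * pmax(y, 0))
}

# Latent density p(x, t) of the drift-diffusion dynamics (no spike decay)
# on a common time grid, plus the survival curve. Used by the JS consistency
# metric.
latent_density_movie <- function(model, condition, times) {
  g <- model$grid; int <- g$interior
  H <- interior_drift_op(model, condition)
  ed <- eigen(H)
  Vinv <- solve(ed$vectors)
  p0 <- model_p0(model)[int]
  coef <- Vinv %*% p0
  out <- matrix(0, length(int), length(times))
  for (k in seq_along(times)) {
    out[, k] <- pmax(Re(ed$vectors %*% (exp(-ed$values * times[k]) * coef)), 0)
  }
  out
}

survival_horizon <- function(model, condition, level = 1e-3, t_cap = 64) {
  g <- model$grid; int <- g$interior
  H <- interior_drift_op(model, condition)
  ed <- eigen(H)
  Vinv <- solve(ed$vectors)
  coef <- Vinv %*% model_p0(model)[int]
  w <- g$weights[int]
  t <- 0.25
  while (t < t_cap) {
    s <- sum(w * pmax(Re(ed$vectors %*% (exp(-ed$values * t) * coef)), 0))
    if (!is.finite(s) || s < level) return(t)
    t <- t * 2
  }
  t_cap
}

#' Jensen--Shannon divergence between two models' latent dynamics
#'
#' Compares the time-dependent latent densities p(x, t) of two models (drift,
#' diffusion and initial density; spike decay excluded) for one condition.
#' The default `"occupancy"` method compares the expected occupancy measures
#' int_0^inf p(x, t) dt (computed in closed form as H^{-1} p0 and normalized
#' to densities over x): the occupancy integrates the whole time course of
#' the first-passage dynamics, changes smoothly along the optimization path,
#' and its divergence between data-split fits grows with feature complexity
#' as spurious features appear. The `"joint"` method normalizes the
#' sub-probability density over (x, t) on a common time window and takes the
#' JS divergence of the two joint densities. Both are symmetric and bounded
#' by ln 2.
#'
#' @param modelA,modelB Two `sd_model`s on a common grid.
#' @param condition Condition index.
#' @param method `"occupancy"` (default) or `"joint"`.
#' @param n_time Number of time-quadrature points (joint method).
#' @return Scalar divergence in [0, ln 2].
#' @export
js_divergence <- function(modelA, modelB, condition = 1L,
                          method = c("occupancy", "joint"), n_time = 120L) {
  method <- match.arg(method)
  if (!identical(dim(modelA$grid$D1), dim(modelB$grid$D1)) ||
      max(abs(modelA$grid$nodes - modelB$grid$nodes)) > 1e-12)
    stop("models must share a common grid", call. = FALSE)
  if (method == "occupancy") {
    g <- modelA$grid
    int <- g$interior; w <- g$weights[int]
    occ <- function(m) {
      y <- tryCatch(solve(interior_drift_op(m, condition), model_p0(m)[int]),
                    error = function(e) rep(NaN, length(int)))
      y <- pmax(y, 0)
      z <- sum(w * y)
      if (!is.finite(z) || z <= 0) return(rep(NaN, length(int)))
      y / z
    }
    A <- occ(modelA); B <- occ(modelB)
    if (any(!is.finite(A)) || any(!is.finite(B))) return(NaN)
    mid <- (A + B) / 2
    kl <- function(P) sum(w * P * log(ifelse(P > 0, P / pmax(mid, 1e-300), 1)))
    return(max(0, 0.5 * kl(A) + 0.5 * kl(B)))
  }
  horizon <- max(survival_horizon(modelA, condition),
                 survival_horizon(modelB, condition))
  times <- seq(0, horizon, length.out = n_time)
  wt <- rep(times[2] - times[1], n_time); wt[c(1, n_time)] <- wt[1] / 2
  wx <- modelA$grid$weights[modelA$grid$interior]
  W <- outer(wx, wt)
  A <- latent_density_movie(modelA, condition, times)
  B <- latent_density_movie(modelB, condition, times)
  za <- sum(W * A); zb <- sum(W * B)
  if (za <= 0 || zb <= 0) return(NaN)
  A <- A / za; B <- B / zb
  mid <- (A + B) / 2
  kl_term <- function(P) {
    x <- W * P * log(ifelse(P > 0, P / pmax(mid, 1e-300), 1))
    sum(x[is.finite(x)])
  }
  max(0, 0.5 * kl_term(A) + 0.5 * kl_term(B))
}

trace_complexity_mean <- function(trace) {
  rowMeans(trace$complexity)[trace$epochs]
}

#' Select the model by feature consistency across data splits
#'
#' Pairs snapshots of matched feature complexity across the two traces
#' (nearest-complexity pairing), evaluates the JS divergence of each pair
#' (averaged over conditions) in order of increasing complexity, and selects
#' the last consistent pair before the divergence first exceeds the
#' threshold: the maximum complexity for which the two halves still agree.
#' (True features are learned first and replicate across halves; once
#' overfitting sets in the divergence rises, and beyond that point model
#' pairs are spurious even where their divergence happens to dip again, so
#' the scan stops at the first crossing.) If even the lowest-complexity pair
#' is inconsistent, it is returned with a warning and the result is flagged.
#'
#' @param traceA,traceB `sd_fittrace` objects from the two data halves.
#' @param threshold JS consistency threshold (default 0.0015).
#' @param method Divergence method, see [js_divergence()].
#' @param patience Number of consecutive above-threshold pairs that ends the
#'   scan (guards against isolated noise spikes in the divergence curve).
#' @param n_time Time-quadrature points for the JS evaluation (joint method).
#' @return An `sd_selection`: the selected model pair, the selected
#'   complexity `M_star`, and the evaluated (complexity, divergence) curve.
#' @export
select_models <- function(traceA, traceB, threshold = 0.0015,
                          method = c("occupancy", "joint"), patience = 3L,
                          n_time = 120L) {
  method <- match.arg(method)
  cA <- trace_complexity_mean(traceA)
  cB <- trace_complexity_mean(traceB)
  L <- traceA$n_conditions
  ord <- order(cA, decreasing = FALSE)
  djs_curve <- data.frame(complexity = numeric(0), djs = numeric(0),
                          ia = integer(0), ib = integer(0))
  found <- NULL
  n_above <- 0L
  for (ia in ord) {
    ib <- which.min(abs(cB - cA[ia]))
    pairc <- (cA[ia] + cB[ib]) / 2
    d <- mean(vapply(seq_len(L), function(l)
      js_divergence(traceA$models[[ia]], traceB$models[[ib]], l, method, n_time),
      numeric(1)))
    djs_curve <- rbind(djs_curve,
                       data.frame(complexity = pairc, djs = d, ia = ia, ib = ib))
    if (is.finite(d) && d <= threshold) {
      found <- c(ia, ib)
      n_above <- 0L
    } else {
      n_above <- n_above + 1L
      if (n_above >= patience) break
    }
  }
  consistent <- !is.null(found)
  if (!consistent) {
    warning("no model pair satisfies the consistency threshold; ",
            "returning the lowest-complexity pair")
    ia <- which.min(cA); ib <- which.min(abs(cB - cA[ia]))
    found <- c(ia, ib)
  }
  ia <- found[1]; ib <- found[2]
  structure(list(model1 = traceA$models[[ia]], model2 = traceB$models[[ib]],
                 epoch1 = traceA$epochs[ia], epoch2 = traceB$epochs[ib],
                 M_star = (cA[ia] + cB[ib]) / 2,
                 djs_curve = djs_curve[order(djs_curve$complexity), ],
                 threshold = threshold, consistent = consistent),
            class = "sd_selection")
}

#' @export
print.sd_selection <- function(x, ...) {
  cat("Model selection: M* =", signif(x$M_star, 4),
      if (x$consistent) "(consistent)" else "(NO consistent pair)",
      "at threshold", x$threshold, "\n")
  invisible(x)
}

potential_slope <- function(model, condition) {
  g <- model$grid
  phi <- model_potential(model, condition)
  x <- g$nodes; w <- g$weights
  xb <- sum(w * x) / 2; pb <- sum(w * phi) / 2
  sum(w * (x - xb) * (phi - pb)) / sum(w * (x - xb)^2)
}

#' Classify the outcome of a fitted-and-selected model
#'
#' Heuristics for the three failure modes seen in practice: `overfit` when
#' the tuning reaches unphysiological rates together with pathological noise
#' magnitude or potential depth; `underfit_no_signal` when the potential's
#' linear slope tilts toward the same boundary in every condition (no
#' decision signal); `underfit_split_disagreement` when the two data halves
#' tilt toward opposite boundaries in at least one condition; otherwise
#' `good`.
#'
#' @param selection An `sd_selection`.
#' @param max_rate Overfitting flag on the tuning maximum (Hz).
#' @param D_pathological,depth_pathological Pathological noise magnitude and
#'   potential depth (typical healthy fits have D about 0.2--0.6 and depth
#'   about 2).
#' @return One of `"good"`, `"overfit"`, `"underfit_no_signal"`,
#'   `"underfit_split_disagreement"`.
#' @export
classify_outcome <- function(selection, max_rate = 200, D_pathological = 3,
                             depth_pathological = 20) {
  m1 <- selection$model1; m2 <- selection$model2
  L <- m1$n_conditions
  depth <- max(vapply(seq_len(L), function(l)
    diff(range(model_potential(m1, l))), numeric(1)))
  peak <- max(c(model_tuning(m1), 0))
  if (peak > max_rate && (m1$D >= D_pathological || depth >= depth_pathological))
    return("overfit")
  s1 <- vapply(seq_len(L), function(l) potential_slope(m1, l), numeric(1))
  s2 <- vapply(seq_len(L), function(l) potential_slope(m2, l), numeric(1))
  tilt1 <- -sign(s1); tilt2 <- -sign(s2)   # +1: tilts toward the right boundary
  if (all(tilt1 == tilt1[1]) && all(tilt2 == tilt1[1])) return("underfit_no_signal")
  if (any(tilt1 * tilt2 < 0)) return("underfit_split_disagreement")
  "good"
}

#' Bootstrap uncertainty bands for the selected model
#'
#' Trials are first split into two fixed non-overlapping halves; each
#' bootstrap sample resamples trials with replacement within each half (per
#' condition), refits both halves and reruns model selection. Bands are the
#' pointwise standard deviation of the potential, initial density and tuning
#' functions across the 2 x n_boot selected models.
#'
#' @param data An `sd_spikedata`.
#' @param config An `sd_fitconfig`.
#' @param n_boot Number of bootstrap samples (default 10; 0 returns empty
#'   bands without fitting).
#' @param grid Optional shared `sd_grid`.
#' @return List with `phi_sd` (nodes x conditions), `p0_sd`, `tuning_sd`
#'   (nodes x neurons), and the selected `models`.
#' @export
bootstrap_bands <- function(data, config = fit_config(), n_boot = 10L, grid = NULL) {
  if (n_boot <= 0L) return(list(phi_sd = NULL, p0_sd = NULL, tuning_sd = NULL,
                                models = list()))
  conds <- trial_conditions(data)
  set.seed(config$seed + 777L)
  half <- integer(length(conds))
  for (l in unique(conds)) {
    idx <- which(conds == l)
    half[idx] <- sample(rep(1:2, length.out = length(idx)))
  }
  models <- list()
  for (b in seq_len(n_boot)) {
    set.seed(config$seed + 1000L * b)
    take <- function(h) {
      unlist(lapply(unique(conds), function(l) {
        idx <- which(conds == l & half == h)
        sample(idx, length(idx), replace = TRUE)
      }))
    }
    cfg <- config; cfg$seed <- config$seed + 13L * b
    tr1 <- fit(subset_trials(data, take(1)), cfg, grid = grid)
    cfg$seed <- cfg$seed + 1L
    tr2 <- fit(subset_trials(data, take(2)), cfg, grid = grid)
    sel <- suppressWarnings(select_models(tr1, tr2, config$js_threshold))
    models <- c(models, list(sel$model1, sel$model2))
  }
  n <- models[[1]]$grid$n
  L <- models[[1]]$n_conditions
  M <- models[[1]]$n_neurons
  sd_over <- function(get) {
    arr <- vapply(models, get, numeric(n))
    apply(arr, 1, stats::sd)
  }
  phi_sd <- vapply(seq_len(L), function(l)
    sd_over(function(m) model_potential(m, l)), numeric(n))
  tuning_sd <- if (M > 0) vapply(seq_len(M), function(i)
    sd_over(function(m) model_tuning(m)[, i]), numeric(n)) else NULL
  list(phi_sd = phi_sd, p0_sd = sd_over(model_p0), tuning_sd = tuning_sd,
       models = models)
}
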