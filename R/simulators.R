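# Synthetic-data generators: the latent model's own Langevin-Poisson
# generative process with first-passage trial termination, a library of
# ground-truth models for recovery experiments, the two-pool mean-field
# attractor network with Poisson spike emission and rate-threshold reaction
# times, and the rank-two distributed recurrent network.

#' Simulate trials from a latent model
#'
#' Euler--Maruyama integration of dx = D F(x) dt + sqrt(2 D) dW from
#' x0 ~ p0; a trial ends when x first reaches -1 or +1 (the reaction time,
#' located by a linear bridge across the crossing step). Spikes are emitted
#' by per-step thinning against each neuron's tuning function. Trials that
#' have not been absorbed by `t_max` are flagged and excluded by default.
#'
#' @param model An `sd_model`.
#' @param n_trials Trials per condition (scalar or one value per condition).
#' @param dt Integration step (s); keep well below domain^2/D for stability.
#' @param seed RNG seed.
#' @param t_max Duration cap (s).
#' @param conditions Conditions to simulate (default all).
#' @param keep_truncated Keep capped trials (they carry `truncated = TRUE`).
#' @param track_f2 Record per-trial path integrals of F(x)^2 dt (used by the
#'   trajectory-entropy consistency checks); returned as attribute `f2int`.
#' @return An `sd_spikedata`. Trials carry `choice` (the absorbing boundary,
#'   -1 or +1) and, when the model has a `correct_side` attribute, `correct`.
#'   Attributes: `rts`, `n_truncated`, optionally `f2int`.
#' @export
simulate_trials <- function(model, n_trials, dt = 5e-4, seed = 1L, t_max = 10,
                            conditions = seq_len(model$n_conditions),
                            keep_truncated = FALSE, track_f2 = FALSE) {
  if (!is_model(model)) stop("expected sd_model", call. = FALSE)
  if (dt > 1e-3 * 4 / model$D)
    stop("dt too large for stable integration at this D", call. = FALSE)
  g <- model$grid
  set.seed(seed)
  p0 <- model_p0(model)
  cdf <- as.numeric(g$cumint %*% p0)
  cdf <- cdf / cdf[g$n]
  tuning <- model_tuning(model)
  correct_side <- attr(model, "correct_side")
  if (length(n_trials) == 1L) n_trials <- rep(n_trials, length(conditions))
  trials <- list(); rts <- numeric(0); f2 <- numeric(0); n_trunc <- 0L
  for (ci in seq_along(conditions)) {
    l <- conditions[ci]
    u <- stats::runif(n_trials[ci])
    x0 <- stats::approx(cdf, g$nodes, xout = u, rule = 2, ties = "ordered")$y
    sims <- sim_langevin_cpp(g$nodes, model$forces[, l], tuning, model$D,
                             x0, dt, t_max, track_f2)
    for (s in sims) {
      if (s$truncated) {
        n_trunc <- n_trunc + 1L
        if (!keep_truncated) next
      }
      tr <- list(t0 = 0, tE = s$tE, times = as.numeric(s$times),
                 ids = as.integer(s$ids), condition = l,
                 choice = if (s$boundary != 0) s$boundary else NA_integer_)
      if (!is.null(correct_side) && s$boundary != 0)
        tr$correct <- (s$boundary == correct_side[l])
      trials[[length(trials) + 1L]] <- tr
      rts <- c(rts, s$tE)
      if (track_f2) f2 <- c(f2, s$f2int)
    }
  }
  out <- spike_data(trials, model$n_neurons)
  attr(out, "rts") <- rts
  attr(out, "n_truncated") <- n_trunc
  if (track_f2) attr(out, "f2int") <- f2
  out
}

#' Ground-truth model library
#'
#' Deterministic fixture models for recovery experiments. All have four
#' conditions laid out as (left easy, right easy, left hard, right hard).
#' The single-barrier models use an inverted-parabola potential (linear
#' force) whose maximum is displaced away from the correct boundary, so each
#' trial is a noisy escape from near the barrier top; the displacement is
#' larger for easy conditions. The initial density is a narrow Gaussian at
#' the domain centre; two neurons carry sigmoid tuning of opposite
#' preference (about 5--45 Hz).
#'
#' `single_barrier_easy` has a higher barrier and steeper slope than
#' `single_barrier_hard`; `ramping_linear` has pure constant forces (no
#' barrier); `flat` is free diffusion with uniform initial density and two
#' constant-tuning neurons.
#'
#' @param name One of `"single_barrier_easy"`, `"single_barrier_hard"`,
#'   `"ramping_linear"`, `"flat"`.
#' @param grid An `sd_grid` (default 128 nodes).
#' @return An `sd_model` with attribute `correct_side` (+1/-1 per condition).
#' @export
ground_truth_library <- function(name = c("single_barrier_easy",
                                          "single_barrier_hard",
                                          "ramping_linear", "flat"),
                                 grid = build_grid(128L)) {
  name <- match.arg(name)
  x <- grid$nodes; n <- grid$n
  sides <- c(-1, 1, -1, 1)               # correct boundary per condition
  sigm <- function(s) 5 + 40 / (1 + exp(-4 * s))
  tuning_from_rate <- function(f) {
    Fi <- as.numeric(grid$D1 %*% log(f))
    list(C = f[1], Fi = Fi)
  }
  make <- function(forces, D, narrow_p0 = TRUE, const_tuning = FALSE) {
    F0 <- if (narrow_p0) -x / 0.14^2 else rep(0, n)
    if (const_tuning) {
      C <- c(20, 20); Fi <- matrix(0, n, 2)
    } else {
      t1 <- tuning_from_rate(sigm(x)); t2 <- tuning_from_rate(sigm(-x))
      C <- c(t1$C, t2$C); Fi <- cbind(t1$Fi, t2$Fi)
    }
    m <- latent_model(grid, forces, D, F0 = F0, C = C, Fi = Fi)
    attr(m, "correct_side") <- sides
    m
  }
  # Inverted-parabola potential: linear force k (x - top) with the barrier
  # top displaced opposite to the correct boundary; displacement delta sets
  # difficulty, slope k sets urgency. Easy variant: steeper slope and higher
  # barrier (relative to the start) than hard.
  barrier_forces <- function(k, deltas) {
    sapply(seq_len(4), function(l) k * (x + sides[l] * deltas[l]))
  }
  ramp_forces <- function(slopes) {
    sapply(seq_len(4), function(l) rep(sides[l] * slopes[l], n))
  }
  switch(name,
    single_barrier_easy = make(barrier_forces(7, c(0.3, 0.3, 0.15, 0.15)), D = 0.4),
    single_barrier_hard = make(barrier_forces(5, c(0.2, 0.2, 0.1, 0.1)), D = 0.4),
    ramping_linear = make(ramp_forces(c(2.5, 2.5, 1.4, 1.4)), D = 0.4),
    flat = make(ramp_forces(c(0, 0, 0, 0)), D = 0.4,
                narrow_p0 = FALSE, const_tuning = TRUE))
}

#' Parameters of the two-pool mean-field attractor model
#'
#' Reduction of a winner-take-all spiking network to two NMDA gating
#' variables s1, s2 with
#' ds_i/dt = -s_i/tau_s + (1 - s_i) gamma f(I_i),
#' r = f(I) = (aI - b) / (1 - exp(-d (aI - b))),
#' I_i = J11 s_i + J12 s_j + I_stim,i + I_bg,
#' I_stim,{1,2} = I_stim_coef (1 +/- c).
#'
#' @param coherence Stimulus coherence c in [-1, 1] (positive favours pool 1).
#' @return Named list of parameters.
#' @export
meanfield_params <- function(coherence = 0) {
  if (abs(coherence) > 1) stop("|coherence| must be <= 1", call. = FALSE)
  list(gamma = 0.641, tau_s = 0.1, a = 270, b = 108, d = 0.154,
       J11 = 0.2609, J12 = -0.0497, I_bg = 0.3260, I_stim_coef = 0.0208,
       coherence = coherence)
}

#' Mean-field transfer function
#' @param I Synaptic current (nA).
#' @param p Parameter list from [meanfield_params()].
#' @return Firing rate (Hz); the removable singularity at aI = b evaluates
#'   to 1/d.
#' @export
meanfield_rate <- function(I, p = meanfield_params()) {
  z <- p$a * I - p$b
  out <- ifelse(abs(z * p$d) < 1e-8, 1 / p$d + z / 2, z / (1 - exp(-p$d * z)))
  as.numeric(out)
}

meanfield_flow <- function(s, p) {
  I1 <- p$J11 * s[1] + p$J12 * s[2] + p$I_stim_coef * (1 + p$coherence) + p$I_bg
  I2 <- p$J11 * s[2] + p$J12 * s[1] + p$I_stim_coef * (1 - p$coherence) + p$I_bg
  c(-s[1] / p$tau_s + (1 - s[1]) * p$gamma * meanfield_rate(I1, p),
    -s[2] / p$tau_s + (1 - s[2]) * p$gamma * meanfield_rate(I2, p))
}

#' Simulate decision trials from the mean-field attractor model
#'
#' Integrates the two-pool dynamics with Ornstein--Uhlenbeck noise on the
#' input currents (time constant `tau_noise`, stationary s.d. `noise_sd`, the
#' standard treatment of background-current fluctuations in this model
#' class), emits Poisson spikes from the pool rates (`units_per_pool` units
#' per pool), and defines the reaction time as the first crossing of
#' `rate_threshold` by a pool rate smoothed with a moving average of
#' `ma_window` seconds. Standard coherence presets are +/-0.175 (easy) and
#' +/-0.075 (hard).
#'
#' @param coherence Stimulus coherence for this condition.
#' @param n_trials Number of trials.
#' @param noise_sd Stationary s.d. of the input-current noise (nA).
#' @param tau_noise Noise time constant (s).
#' @param seed RNG seed.
#' @param dt Integration step (s).
#' @param units_per_pool Simulated units per pool.
#' @param rate_threshold,ma_window Reaction-time rule (30 Hz, 200 ms).
#' @param s0 Initial gating values.
#' @param t_max Duration cap (s); non-deciding trials are dropped.
#' @param condition Condition label attached to the trials.
#' @return List with `data` (an `sd_spikedata`; choice +1 if pool 1 wins),
#'   `rts`, and `rates` (one example trial's pool-rate traces).
#' @export
meanfield_simulate <- function(coherence, n_trials, noise_sd = 0.02,
                               tau_noise = 0.002,
                               seed = 1L, dt = 5e-4, units_per_pool = 2L,
                               rate_threshold = 30, ma_window = 0.2,
                               s0 = c(0.1, 0.1), t_max = 3,
                               condition = 1L) {
  p <- meanfield_params(coherence)
  set.seed(seed)
  n_steps <- ceiling(t_max / dt)
  ma_n <- max(1L, round(ma_window / dt))
  M <- 2L * units_per_pool
  trials <- list(); rts <- numeric(0); example <- NULL
  ou_decay <- exp(-dt / tau_noise)
  ou_sd <- noise_sd * sqrt(1 - ou_decay^2)
  for (k in seq_len(n_trials)) {
    s <- s0
    r_hist <- matrix(0, n_steps, 2)
    spikes_t <- c(); spikes_i <- c()
    rt <- NA; winner <- 0L
    eta <- stats::rnorm(2, 0, noise_sd)
    for (st in seq_len(n_steps)) {
      eta <- eta * ou_decay + stats::rnorm(2, 0, ou_sd)
      I1 <- p$J11 * s[1] + p$J12 * s[2] + p$I_stim_coef * (1 + coherence) + p$I_bg + eta[1]
      I2 <- p$J11 * s[2] + p$J12 * s[1] + p$I_stim_coef * (1 - coherence) + p$I_bg + eta[2]
      r <- c(meanfield_rate(I1, p), meanfield_rate(I2, p))
      r <- pmax(r, 0)
      r_hist[st, ] <- r
      s <- s + dt * c(-s[1] / p$tau_s + (1 - s[1]) * p$gamma * r[1],
                      -s[2] / p$tau_s + (1 - s[2]) * p$gamma * r[2])
      s <- pmin(pmax(s, 0), 1)
      # Poisson emission per unit
      for (pool in 1:2) for (u in seq_len(units_per_pool)) {
        if (stats::runif(1) < r[pool] * dt) {
          spikes_t <- c(spikes_t, (st - stats::runif(1)) * dt)
          spikes_i <- c(spikes_i, (pool - 1L) * units_per_pool + u)
        }
      }
      lo <- max(1L, st - ma_n + 1L)
      ma <- colMeans(r_hist[lo:st, , drop = FALSE])
      if (st * dt > 0.05 && max(ma) > rate_threshold) {
        rt <- st * dt
        winner <- if (ma[1] >= ma[2]) 1L else -1L
        break
      }
    }
    if (is.na(rt)) next
    keep <- spikes_t > 0 & spikes_t < rt
    trials[[length(trials) + 1L]] <-
      list(t0 = 0, tE = rt, times = spikes_t[keep], ids = spikes_i[keep],
           condition = condition, choice = winner,
           correct = (winner == ifelse(coherence >= 0, 1L, -1L)))
    rts <- c(rts, rt)
    if (is.null(example)) example <- r_hist[seq_len(round(rt / dt)), , drop = FALSE]
  }
  list(data = spike_data(trials, M), rts = rts, rates = example, dt = dt)
}

#' Fixed points and separatrix of the mean-field flow
#'
#' Finds zeros of the two-dimensional flow field from a lattice of starting
#' points, classifies them by the eigenvalues of the numerical Jacobian, and
#' traces the saddle's stable manifold (the separatrix, by following the
#' reversed flow from near the saddle) and unstable manifold (forward flow).
#'
#' @param coherence Stimulus coherence.
#' @param tol Residual norm accepted for a root.
#' @return List with `points` (data frame s1, s2, type), `separatrix` and
#'   `unstable_manifold` (two-column matrices, NULL when there is no saddle).
#' @export
find_fixed_points <- function(coherence = 0, tol = 1e-8) {
  p <- meanfield_params(coherence)
  f <- function(s) meanfield_flow(s, p)
  starts <- as.matrix(expand.grid(s1 = seq(0.05, 0.95, by = 0.15),
                                  s2 = seq(0.05, 0.95, by = 0.15)))
  roots <- list()
  for (k in seq_len(nrow(starts))) {
    sol <- tryCatch(
      suppressWarnings(pracma::fsolve(f, as.numeric(starts[k, ]), tol = 1e-12)),
      error = function(e) NULL)
    if (is.null(sol)) next
    s <- sol$x
    if (any(!is.finite(s)) || any(s < -0.05) || any(s > 1.05)) next
    if (sqrt(sum(f(s)^2)) > tol) next
    dup <- any(vapply(roots, function(r) sqrt(sum((r - s)^2)) < 1e-5, logical(1)))
    if (!dup) roots[[length(roots) + 1L]] <- s
  }
  classify <- function(s) {
    J <- pracma::jacobian(f, s)
    ev <- Re(eigen(J, only.values = TRUE)$values)
    if (all(ev < 0)) "stable" else if (any(ev > 0) && any(ev < 0)) "saddle" else "unstable"
  }
  types <- vapply(roots, classify, character(1))
  pts <- if (length(roots))
    data.frame(s1 = vapply(roots, `[`, numeric(1), 1),
               s2 = vapply(roots, `[`, numeric(1), 2), type = types)
  else data.frame(s1 = numeric(0), s2 = numeric(0), type = character(0))
  sep <- NULL; unst <- NULL
  si <- which(types == "saddle")
  if (length(si)) {
    saddle <- roots[[si[1]]]
    J <- pracma::jacobian(f, saddle)
    ev <- eigen(J)
    vstab <- Re(ev$vectors[, which.min(Re(ev$values))])
    vunst <- Re(ev$vectors[, which.max(Re(ev$values))])
    trace_path <- function(v, sign_flow) {
      path <- list()
      for (dir in c(1, -1)) {
        fn <- function(t, y, parms) list(sign_flow * meanfield_flow(y, p))
        ts <- seq(0, 6, by = 0.005)
        sol <- deSolve::ode(saddle + dir * 1e-4 * v, ts, fn, NULL,
                            method = "rk4")
        y <- sol[, 2:3]
        ok <- y[, 1] >= -0.02 & y[, 1] <= 1.05 & y[, 2] >= -0.02 & y[, 2] <= 1.05
        y <- y[seq_len(max(which(ok))), , drop = FALSE]
        path[[length(path) + 1L]] <- if (dir == 1) y else y[rev(seq_len(nrow(y))), ]
      }
      rbind(path[[2]], saddle, path[[1]])
    }
    sep <- trace_path(vstab, -1)     # reversed flow: stable manifold
    unst <- trace_path(vunst, +1)
  }
  list(points = pts, separatrix = sep, unstable_manifold = unst)
}

#' Build the rank-two distributed recurrent network
#'
#' Constructs an N-unit rectified-linear network dy/dt = -y + [J y + b]_+
#' whose rank-two connectivity J = M Q^T confines the mean-field dynamics
#' z = Q^T y to two dimensions while replicating the attractor flow field of
#' the two-pool mean-field model at zero coherence. Loadings are
#' m_{i,1} = cos(2 pi i / N), m_{i,2} = sin(2 pi i / N); inputs b_i are
#' uniform on [-b_range, b_range]; Q^T solves Q^T [M z + b]_+ = R(z) + z by
#' ridge regression (lambda = 0.01) over z sampled uniformly on [0, 1]^2.
#'
#' The offsets b place the rectification kinks of the units: the kink of unit
#' i is the line m_i . z = -b_i, at distance |b_i| from the origin. The
#' default range 0.6 disperses the kinks across the unit square, which is
#' necessary for the rectified basis to reproduce the curvature of the
#' attractor flow field (with offsets an order of magnitude smaller, all
#' kinks crowd one corner and the flow cannot be matched at any sample size).
#'
#' @param n_units Number of units N (default 500).
#' @param n_samples Number of regression sample points K (>= 100).
#' @param seed RNG seed.
#' @param lambda Ridge regularization.
#' @param b_range Half-width of the uniform input-offset distribution.
#' @return An `sd_lowrank` with `M`, `Qt` (2 x N), `b`, `J`, and the
#'   mean-field parameters the flow was matched to.
#' @export
lowrank_build <- function(n_units = 500L, n_samples = 2000L, seed = 1L,
                          lambda = 0.01, b_range = 0.6) {
  if (n_samples < 100L) stop("need at least 100 regression samples", call. = FALSE)
  set.seed(seed)
  p <- meanfield_params(0)
  i <- seq_len(n_units)
  M <- cbind(cos(2 * pi * i / n_units), sin(2 * pi * i / n_units))
  b <- stats::runif(n_units, -b_range, b_range)
  Z <- matrix(stats::runif(2L * n_samples), nrow = 2)
  A <- pmax(M %*% Z + b, 0)                      # N x K
  B <- apply(Z, 2, function(z) meanfield_flow(z, p) + z)  # 2 x K
  AtA <- A %*% t(A) + lambda * diag(n_units)
  Qt <- t(solve(AtA, A %*% t(B)))                # 2 x N
  structure(list(M = M, Qt = Qt, b = b, J = M %*% Qt, n_units = n_units,
                 lambda = lambda, params = p),
            class = "sd_lowrank")
}

#' Residual of the rank-two flow-field match on held-out points
#' @param net An `sd_lowrank`.
#' @param n_test Held-out sample count.
#' @param seed RNG seed.
#' @return Relative residual: mean flow mismatch norm over mean target norm.
#' @export
lowrank_residual <- function(net, n_test = 500L, seed = 99L) {
  set.seed(seed)
  Z <- matrix(stats::runif(2L * n_test), nrow = 2)
  target <- apply(Z, 2, function(z) meanfield_flow(z, net$params) + z)
  pred <- net$Qt %*% pmax(net$M %*% Z + net$b, 0)
  mean(sqrt(colSums((pred - target)^2))) / mean(sqrt(colSums(target^2)))
}

#' Integrate the full network and its mean-field reduction
#'
#' @param net An `sd_lowrank`.
#' @param z0 Initial mean-field state (the standard left-choice start is
#'   c(0.12, 0.106), right is the swap).
#' @param t_end,dt Integration horizon and step (s of network time units).
#' @return List with `times`, `z_full` (projection Q^T y of the full
#'   network), `z_reduced` (direct two-dimensional integration), and `rates`
#'   (units x time firing rates along the full-network trajectory).
#' @export
lowrank_simulate <- function(net, z0 = c(0.12, 0.106), t_end = 10, dt = 0.01) {
  times <- seq(0, t_end, by = dt)
  y0 <- as.numeric(pracma::pinv(net$Qt) %*% z0)
  dy <- function(t, y, parms) list(-y + pmax(net$J %*% y + net$b, 0))
  soly <- deSolve::ode(y0, times, dy, NULL, method = "ode45")
  Y <- t(unname(soly[, -1, drop = FALSE]))
  dz <- function(t, z, parms) list(-z + as.numeric(net$Qt %*% pmax(net$M %*% z + net$b, 0)))
  solz <- deSolve::ode(z0, times, dz, NULL, method = "ode45")
  rates <- pmax(net$M %*% (net$Qt %*% Y) + net$b, 0)
  list(times = times, z_full = net$Qt %*% Y,
       z_reduced = t(unname(solz[, -1, drop = FALSE])),
       rates = rates)
}

#' Decision-variable parametrization of left/right network trajectories
#'
#' Maps the two choice trajectories to a decision variable x in [-1, 1] that
#' grows linearly with cumulative arc length: 0 at the (near-)symmetric
#' start, -1 at the left-choice attractor, +1 at the right-choice attractor.
#' Per-unit tuning curves are the firing rates along the trajectories as a
#' function of x.
#'
#' @param traj_left,traj_right Lists from [lowrank_simulate()] for the left
#'   and right initial conditions.
#' @return List with `x_left`, `x_right` (per time point), and
#'   `tuning` (function(x) returning the units x length(x) rate matrix by
#'   interpolation along the trajectories).
#' @export
decision_variable_param <- function(traj_left, traj_right) {
  arc_x <- function(traj, sgn) {
    z <- traj$z_full
    seg <- sqrt(colSums((z[, -1, drop = FALSE] - z[, -ncol(z), drop = FALSE])^2))
    s <- c(0, cumsum(seg))
    if (s[length(s)] <= 0) stop("zero-length trajectory", call. = FALSE)
    sgn * s / s[length(s)]
  }
  xl <- arc_x(traj_left, -1)
  xr <- arc_x(traj_right, +1)
  tuning <- function(x) {
    x <- pmin(pmax(x, -1), 1)
    out <- matrix(0, nrow(traj_left$rates), length(x))
    for (k in seq_along(x)) {
      if (x[k] <= 0) {
        idx <- which.min(abs(xl - x[k]))
        out[, k] <- traj_left$rates[, idx]
      } else {
        idx <- which.min(abs(xr - x[k]))
        out[, k] <- traj_right$rates[, idx]
      }
    }
    out
  }
  list(x_left = xl, x_right = xr, tuning = tuning)
}
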