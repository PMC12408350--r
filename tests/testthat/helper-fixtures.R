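# Shared fixtures, built in code at test time.

toy_grid <- function(n = 32L) build_grid(n)

# A two-condition, two-neuron model with a tilted nonlinear force, a
# non-uniform initial density and opposite-preference tuning.
toy_model <- function(grid = toy_grid()) {
  n <- grid$n
  Fv <- -4 * grid$nodes * (grid$nodes^2 - 0.4) + 0.5
  latent_model(grid, forces = cbind(Fv, -Fv), D = 0.4,
               F0 = -6 * grid$nodes, C = c(10, 30),
               Fi = cbind(rep(0.8, n), rep(-0.6, n)))
}

# A handful of hand-written trials for exact likelihood work.
toy_trials <- function() {
  list(
    list(t0 = 0, tE = 0.42, times = c(0.1, 0.25, 0.3), ids = c(1L, 2L, 1L),
         condition = 1L),
    list(t0 = 0, tE = 0.3, times = c(0.12, 0.2), ids = c(2L, 2L),
         condition = 2L),
    list(t0 = 0, tE = 0.55, times = c(0.05, 0.3, 0.4, 0.5),
         ids = c(1L, 2L, 2L, 1L), condition = 1L))
}

toy_data <- function() spike_data(toy_trials(), 2L)

# Independent substepped propagator: second-order Taylor step raised to 2^k
# by repeated squaring. Independent of the eigendecomposition route used by
# the package.
substep_propagator <- function(H, delta, k = 18L) {
  Hh <- H * (delta / 2^k)
  T1 <- diag(nrow(H)) - Hh + (Hh %*% Hh) / 2
  for (i in seq_len(k)) T1 <- T1 %*% T1
  T1
}

# Inhomogeneous-Poisson spike trains by thinning.
sim_inhom_poisson <- function(n_trials, dur, rate_fn, rate_max, seed) {
  set.seed(seed)
  lapply(seq_len(n_trials), function(k) {
    cand <- sort(stats::runif(stats::rpois(1, rate_max * dur), 0, dur))
    cand[stats::runif(length(cand)) < rate_fn(cand) / rate_max]
  })
}

# Gamma-renewal spike trains with a (slowly varying) rate, built by drawing
# unit-mean gamma intervals in operational time and mapping back.
sim_gamma_renewal <- function(n_trials, dur, rate_fn, shape, seed) {
  set.seed(seed)
  tt <- seq(0, dur, length.out = 2000)
  rr <- rate_fn(tt)
  Lam <- c(0, cumsum(diff(tt) * (rr[-1] + rr[-length(rr)]) / 2))
  lapply(seq_len(n_trials), function(k) {
    ops <- cumsum(stats::rgamma(ceiling(Lam[2000] * 2) + 50,
                                shape = shape, rate = shape))
    ops <- ops[ops < Lam[2000]]
    stats::approx(Lam, tt, xout = ops)$y
  })
}
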