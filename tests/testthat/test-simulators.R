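test_that("pure-diffusion first-passage times match the closed form", {
  g <- build_grid(48)
  m <- latent_model(g, forces = matrix(0, g$n, 1), D = 0.4,
                    F0 = -g$nodes / 0.03^2,       # start near x = 0
                    C = 0, Fi = matrix(0, g$n, 1))
  d <- simulate_trials(m, n_trials = 10000, seed = 7, conditions = 1)
  rts <- attr(d, "rts")
  # MFPT from the centre with two absorbing walls: (1 - x0^2) / (2 D)
  expect_lt(abs(mean(rts) - 1 / (2 * 0.4)), 3 * stats::sd(rts) / sqrt(length(rts)) + 0.01)
  # symmetric potential and start: absorption sides balance
  ch <- vapply(d$trials, function(tr) as.numeric(tr$choice), numeric(1))
  p_right <- mean(ch == 1)
  expect_lt(abs(p_right - 0.5), 3 * sqrt(0.25 / length(ch)) + 0.001)
})

test_that("thinned spike counts match the expected tuning path integral", {
  g <- build_grid(48)
  truth <- ground_truth_library("flat", grid = g)   # constant 20 Hz tuning
  d <- simulate_trials(truth, n_trials = 4000, seed = 8, conditions = 1)
  counts <- vapply(d$trials, function(tr) sum(tr$ids == 1L), numeric(1))
  durs <- vapply(d$trials, function(tr) tr$tE, numeric(1))
  # E[N] = E[int f dt] = 20 * E[duration]
  expect_equal(mean(counts), 20 * mean(durs), tolerance = 0.02 * 20 * mean(durs))
})

test_that("simulation is reproducible under a fixed seed and caps runaways", {
  g <- build_grid(32)
  truth <- ground_truth_library("single_barrier_hard", grid = g)
  d1 <- simulate_trials(truth, n_trials = 10, seed = 123)
  d2 <- simulate_trials(truth, n_trials = 10, seed = 123)
  expect_identical(d1$trials, d2$trials)
  # a reflecting-ish model with a hard cap: truncated trials are excluded
  m <- latent_model(g, forces = matrix(-12 * g$nodes, g$n, 1), D = 0.05,
                    F0 = -g$nodes / 0.05^2, C = 5, Fi = matrix(0, g$n, 1))
  dd <- simulate_trials(m, n_trials = 10, seed = 5, conditions = 1, t_max = 0.5)
  expect_gt(attr(dd, "n_truncated"), 0)
  expect_equal(length(dd$trials) + attr(dd, "n_truncated"), 10L)
})

test_that("ground-truth library encodes the documented orderings", {
  g <- build_grid(64)
  easy <- ground_truth_library("single_barrier_easy", grid = g)
  hard <- ground_truth_library("single_barrier_hard", grid = g)
  flat <- ground_truth_library("flat", grid = g)
  ramp <- ground_truth_library("ramping_linear", grid = g)
  expect_error(ground_truth_library("nope"), "arg")
  for (l in 1:4) {
    expect_equal(count_barriers(easy$forces[, l], easy$forces[, l], g), 1L)
    expect_equal(count_barriers(ramp$forces[, l], ramp$forces[, l], g), 0L)
  }
  # easy has the steeper slope and higher barrier relative to the start
  height <- function(m, l) {
    phi <- model_potential(m, l)
    max(phi) - phi[which.min(abs(g$nodes))]
  }
  for (l in 1:4) expect_gt(height(easy, l), height(hard, l))
  expect_true(all(flat$forces == 0))
  expect_equal(model_p0(flat), rep(0.5, g$n))
  # ramping drifts monotonically toward the correct side
  ch <- vapply(ramp$forces[1, ], sign, numeric(1))
  expect_equal(ch, c(-1, 1, -1, 1))
})

test_that("mean-field transfer function has the removable-singularity limit", {
  p <- meanfield_params()
  expect_equal(meanfield_rate(p$b / p$a, p), 1 / p$d, tolerance = 1e-6)
  # continuous across the singularity
  eps <- 1e-6
  expect_equal(meanfield_rate(p$b / p$a + eps, p),
               meanfield_rate(p$b / p$a - eps, p), tolerance = 1e-3)
})

test_that("the symmetric mean-field flow is exchange-invariant without noise", {
  p <- meanfield_params(0)
  for (s in list(c(0.1, 0.1), c(0.3, 0.3), c(0.2, 0.5))) {
    f <- spikedrift:::meanfield_flow(s, p)
    fswap <- spikedrift:::meanfield_flow(rev(s), p)
    expect_equal(f, rev(fswap), tolerance = 1e-12)
  }
})

test_that("mean-field fixed points form the bistable attractor geometry", {
  fp <- find_fixed_points(0)
  expect_equal(sum(fp$points$type == "stable"), 2L)
  expect_equal(sum(fp$points$type == "saddle"), 1L)
  st <- fp$points[fp$points$type == "stable", ]
  # attractors are mirror images of each other
  expect_equal(sort(c(st$s1[1], st$s2[1])), sort(c(st$s1[2], st$s2[2])),
               tolerance = 1e-6)
  # every root satisfies the fixed-point equation tightly
  p <- meanfield_params(0)
  for (k in seq_len(nrow(fp$points))) {
    r <- spikedrift:::meanfield_flow(as.numeric(fp$points[k, 1:2]), p)
    expect_lt(sqrt(sum(r^2)), 1e-8)
  }
  # separatrix lies on the diagonal at zero coherence
  expect_lt(max(abs(fp$separatrix[, 1] - fp$separatrix[, 2])), 1e-6)
})

test_that("mean-field trials decide correctly at high coherence with sane RTs", {
  mf <- meanfield_simulate(coherence = 0.175, n_trials = 40, seed = 2)
  expect_gt(length(mf$rts), 30)
  co <- vapply(mf$data$trials, function(tr) tr$correct, logical(1))
  n <- length(co)
  expect_gt(mean(co), 0.5 + 5 * sqrt(0.25 / n))
  expect_gt(stats::median(mf$rts), 0.3)
  expect_lt(stats::median(mf$rts), 0.8)
})

test_that("the rank-two network reproduces the attractor flow", {
  net <- lowrank_build(n_units = 500, n_samples = 2000, seed = 1)
  expect_equal(qr(net$J)$rank, 2L)
  expect_lt(lowrank_residual(net), 0.05)
  traj <- lowrank_simulate(net, c(0.12, 0.106), t_end = 6)
  # the mean-field coordinates of the full network follow the reduced system
  expect_lt(max(abs(traj$z_full - traj$z_reduced)), 1e-3)
  expect_error(lowrank_build(n_samples = 10), "at least 100")
})

test_that("the decision-variable parametrization spans [-1, 1] monotonically", {
  net <- lowrank_build(seed = 1)
  trl <- lowrank_simulate(net, c(0.12, 0.106), t_end = 8)
  trr <- lowrank_simulate(net, c(0.106, 0.12), t_end = 8)
  dv <- decision_variable_param(trl, trr)
  expect_equal(dv$x_left[1], 0)
  expect_equal(dv$x_right[1], 0)
  expect_equal(dv$x_left[length(dv$x_left)], -1)
  expect_equal(dv$x_right[length(dv$x_right)], 1)
  expect_true(all(diff(dv$x_left) <= 1e-12))
  expect_true(all(diff(dv$x_right) >= -1e-12))
  # tuning curves: non-negative rates, round trip through uniform resampling
  xs <- seq(-1, 1, by = 0.05)
  tun <- dv$tuning(xs)
  expect_true(all(tun >= 0))
  expect_equal(dim(tun), c(500L, length(xs)))
  again <- dv$tuning(xs)
  expect_identical(tun, again)
})
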