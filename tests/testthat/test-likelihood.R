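test_that("trial likelihood equals exhaustive discretized-path enumeration", {
  # smallest admissible grid; enumeration over all interior-node paths with
  # independently substepped transition matrices
  g <- build_grid(8)
  n <- g$n; int <- g$interior
  m <- latent_model(g, forces = matrix(0.8 * g$nodes + 0.3, n, 1), D = 0.5,
                    F0 = -2 * g$nodes, C = c(8, 15),
                    Fi = cbind(rep(0.5, n), rep(-0.5, n)))
  gen <- assemble_generator(m, 1, TRUE)
  trial <- list(t0 = 0, tE = 0.5, times = c(0.15, 0.31, 0.40),
                ids = c(2L, 1L, 2L), condition = 1L)
  ll <- trial_loglik(m, trial, 1)

  Tm <- lapply(diff(c(trial$t0, trial$times, trial$tE)),
               function(d) substep_propagator(gen$Hint, d))
  p0 <- model_p0(m)[int]
  f <- model_tuning(m)[int, ]
  a <- gen$aL + gen$aR
  ni <- length(int)
  total <- 0
  for (i0 in 1:ni) for (i1 in 1:ni) for (i2 in 1:ni) for (i3 in 1:ni) {
    total <- total + p0[i0] *
      Tm[[1]][i1, i0] * f[i1, trial$ids[1]] *
      Tm[[2]][i2, i1] * f[i2, trial$ids[2]] *
      Tm[[3]][i3, i2] * f[i3, trial$ids[3]] *
      sum(a * Tm[[4]][, i3])
  }
  expect_equal(ll$log_full, log(total), tolerance = 1e-6)
})

test_that("with no spikes the likelihood is the Monte-Carlo first-passage density", {
  g <- build_grid(48)
  m <- latent_model(g, forces = matrix(1.5 * g$nodes, g$n, 1), D = 0.4,
                    F0 = -g$nodes / 0.14^2, C = 0, Fi = matrix(0, g$n, 1))
  # empirical first-passage density from the Euler-Maruyama simulator
  d <- simulate_trials(m, n_trials = 30000, seed = 4, conditions = 1,
                       dt = 2e-4)
  rts <- attr(d, "rts")
  for (te in c(0.4, 0.8)) {
    h <- 0.05
    dens_mc <- mean(abs(rts - te) < h) / (2 * h)
    ll <- trial_loglik(m, list(t0 = 0, tE = te, times = numeric(0),
                               ids = integer(0), condition = 1L), 1)
    expect_equal(exp(ll$log_full), dens_mc, tolerance = 0.06 * dens_mc)
    # with no spikes and no neurons, full and tE marginals coincide
    expect_equal(ll$log_normalized, 0, tolerance = 1e-9)
  }
})

test_that("a spike from a silenced neuron gives -Inf", {
  m <- toy_model()
  m$C[1] <- 0
  tr <- toy_trials()[[1]]     # contains spikes of neuron 1
  expect_identical(trial_loglik(m, tr, 1)$log_full, -Inf)
})

test_that("dataset likelihood is additive and order-invariant", {
  m <- toy_model()
  d <- toy_data()
  base <- dataset_loglik(m, d)
  one <- spike_data(toy_trials()[c(1, 1)], 2)
  expect_equal(dataset_loglik(m, one),
               2 * trial_loglik(m, toy_trials()[[1]], 1)$log_full,
               tolerance = 1e-10)
  perm <- spike_data(toy_trials()[c(3, 1, 2)], 2)
  expect_equal(dataset_loglik(m, perm), base, tolerance = 1e-10)
  expect_equal(dataset_loglik(m, d, "normalized") + dataset_loglik(m, d, "tE"),
               base, tolerance = 1e-9)
})

test_that("PSTH likelihood matches closed forms", {
  tr <- list(t0 = 0, tE = 1,
             times = sort(stats::runif(8, 0.01, 0.99)),
             ids = rep(1L, 8), condition = 1L)
  const <- list(time = c(0, 1), rate = c(10, 10))
  expect_equal(psth_loglik(const, tr, 1), -10 + 8 * log(10), tolerance = 1e-10)
  expect_equal(psth_loglik(const, list(t0 = 0, tE = 1, times = numeric(0),
                                       ids = integer(0)), 1), -10,
               tolerance = 1e-10)
  # linear ramp: trapezoid equals the analytic integral on the trace grid
  ramp <- list(time = seq(0, 1, by = 0.01), rate = 5 + 20 * seq(0, 1, by = 0.01))
  v <- psth_loglik(ramp, list(t0 = 0, tE = 1, times = numeric(0),
                              ids = integer(0)), 1)
  expect_equal(v, -(5 + 10), tolerance = 1e-10)
  # zero rate at a spike
  z <- list(time = c(0, 1), rate = c(0, 0))
  expect_identical(psth_loglik(z, tr, 1), -Inf)
})

test_that("analytic gradients match finite differences along random directions", {
  m <- toy_model()
  d <- toy_data()
  gr <- likelihood_gradients(m, d)
  expect_equal(gr$loglik, dataset_loglik(m, d), tolerance = 1e-10)
  perturb <- function(mm, v, h) {
    mm$forces <- mm$forces + h * v$dF; mm$F0 <- mm$F0 + h * v$dF0
    mm$Fi <- mm$Fi + h * v$dFi; mm$D <- mm$D + h * v$dD; mm$C <- mm$C + h * v$dC
    mm
  }
  set.seed(7)
  n <- m$grid$n
  errs <- vapply(1:10, function(r) {
    v <- list(dF = matrix(rnorm(n * 2), n), dF0 = rnorm(n),
              dFi = matrix(rnorm(n * 2), n), dD = 0.1 * rnorm(1), dC = rnorm(2))
    h <- 1e-5
    fd <- (dataset_loglik(perturb(m, v, h), d) -
             dataset_loglik(perturb(m, v, -h), d)) / (2 * h)
    an <- sum(v$dF * gr$dF) + sum(v$dF0 * gr$dF0) + sum(v$dFi * gr$dFi) +
      v$dD * gr$dD + sum(v$dC * gr$dC)
    abs(fd - an) / max(abs(fd), abs(an))
  }, numeric(1))
  expect_lt(max(errs), 1e-4)
})

test_that("shared-component gradients are sums of per-condition contributions", {
  m <- toy_model()
  d <- toy_data()
  g_all <- likelihood_gradients(m, d)
  g1 <- likelihood_gradients(m, d, conditions = 1L)
  g2 <- likelihood_gradients(m, d, conditions = 2L)
  expect_equal(g_all$dF0, g1$dF0 + g2$dF0, tolerance = 1e-9)
  expect_equal(g_all$dFi, g1$dFi + g2$dFi, tolerance = 1e-9)
  expect_equal(g_all$dD, g1$dD + g2$dD, tolerance = 1e-9)
  expect_equal(g_all$dC, g1$dC + g2$dC, tolerance = 1e-9)
  # per-condition force gradients do not mix
  expect_equal(g1$dF[, 2], rep(0, m$grid$n))
})

test_that("likelihood stays finite while tuning functions are scaled", {
  m <- toy_model()
  d <- toy_data()
  for (k in c(0.1, 0.5, 2, 10)) {
    mm <- m; mm$C <- m$C * k
    expect_true(is.finite(dataset_loglik(mm, d)))
  }
})
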