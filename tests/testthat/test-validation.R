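test_that("Viterbi equals exhaustive search over grid-valued paths", {
  g <- build_grid(8)
  n <- g$n; int <- g$interior; ni <- length(int)
  m <- latent_model(g, forces = matrix(1.2 * g$nodes - 0.2, n, 1), D = 0.5,
                    F0 = -2 * g$nodes, C = c(8, 15),
                    Fi = cbind(rep(0.5, n), rep(-0.5, n)))
  gen <- assemble_generator(m, 1, TRUE)
  trial <- list(t0 = 0, tE = 0.45, times = c(0.12, 0.2, 0.33),
                ids = c(2L, 1L, 2L), condition = 1L)
  path <- viterbi_path(m, trial, 1)

  # brute force over all grid paths with the model's own transition kernels
  dts <- diff(c(trial$t0, trial$times, trial$tE))
  Kd <- lapply(dts, function(d) {
    sapply(seq_len(ni), function(j) {
      e <- numeric(n); e[int[j]] <- 1 / g$weights[int[j]]
      propagate(e, d, gen)[int]
    })
  })
  p0 <- model_p0(m)[int]
  f <- model_tuning(m)[int, ]
  best <- -Inf; best_path <- NULL; best_b <- 0
  for (i0 in 1:ni) for (i1 in 1:ni) for (i2 in 1:ni) for (i3 in 1:ni) {
    base <- log(max(p0[i0], 1e-300)) +
      log(max(Kd[[1]][i1, i0], 1e-300)) + log(f[i1, 2]) +
      log(max(Kd[[2]][i2, i1], 1e-300)) + log(f[i2, 1]) +
      log(max(Kd[[3]][i3, i2], 1e-300)) + log(f[i3, 2])
    for (b in c(-1, 1)) {
      e <- numeric(n); e[int[i3]] <- 1 / g$weights[int[i3]]
      ab <- absorb(propagate(e, dts[4], gen), gen)
      v <- base + log(max(ab[[if (b < 0) "left" else "right"]], 1e-300))
      if (v > best) { best <- v; best_path <- c(i0, i1, i2, i3); best_b <- b }
    }
  }
  expect_equal(path$states[1:4], g$nodes[int][best_path], tolerance = 1e-12)
  expect_equal(path$boundary, best_b)
  expect_equal(path$logscore, best, tolerance = 1e-8)
})

test_that("Viterbi path beats random grid paths and ends on a boundary", {
  m <- toy_model()
  d <- simulate_trials(m, n_trials = 3, seed = 14, conditions = 1)
  g <- m$grid; int <- g$interior
  for (tr in d$trials) {
    path <- viterbi_path(m, tr, 1)
    expect_true(path$states[length(path$states)] %in% c(-1, 1))
    gen <- assemble_generator(m, 1, TRUE)
    dts <- diff(c(tr$t0, tr$times, tr$tE))
    score_of <- function(states_idx, b) {
      p0 <- model_p0(m)[int]; f <- model_tuning(m)[int, , drop = FALSE]
      v <- log(p0[states_idx[1]])
      for (j in seq_along(tr$times)) {
        e <- numeric(g$n); e[int[states_idx[j]]] <- 1 / g$weights[int[states_idx[j]]]
        kd <- propagate(e, dts[j], gen)[int]
        v <- v + log(max(kd[states_idx[j + 1]], 1e-300)) +
          log(max(f[states_idx[j + 1], tr$ids[j]], 1e-300))
      }
      e <- numeric(g$n)
      e[int[states_idx[length(states_idx)]]] <-
        1 / g$weights[int[states_idx[length(states_idx)]]]
      ab <- absorb(propagate(e, dts[length(dts)], gen), gen)
      v + log(max(ab[[if (b < 0) "left" else "right"]], 1e-300))
    }
    set.seed(1)
    for (r in 1:25) {
      rnd <- sample(length(int), length(tr$times) + 1, replace = TRUE)
      expect_gte(path$logscore + 1e-8, score_of(rnd, sample(c(-1, 1), 1)))
    }
  }
})

test_that("low noise makes the decoded path track the deterministic flow", {
  g <- build_grid(64)
  m <- latent_model(g, forces = matrix(4, g$n, 1), D = 0.05,
                    F0 = -g$nodes / 0.05^2, C = 20, Fi = matrix(0, g$n, 1))
  # deterministic flow: dx/dt = D * F = 0.2; from 0 the boundary is hit at 5 s.
  # Conditioning on first passage exactly at tE makes the most probable path
  # lag the flow slightly at finite D, so a modest envelope is allowed.
  tE <- 1 / (m$D * 4)
  trial <- list(t0 = 0, tE = tE, times = seq(0.5, tE - 0.5, by = 0.5),
                ids = rep(1L, length(seq(0.5, tE - 0.5, by = 0.5))),
                condition = 1L)
  path <- viterbi_path(m, trial, 1)
  states <- path$states[-length(path$states)]
  expected <- m$D * 4 * path$times[-length(path$times)]
  expect_lt(max(abs(states - expected)), 0.2)
  expect_true(all(diff(states) > -1e-9))
  expect_equal(path$boundary, 1L)
})

test_that("spike-time R^2 is exactly zero for a constant rate prediction", {
  m <- toy_model()
  d <- simulate_trials(m, n_trials = 25, seed = 3, conditions = 1:2)
  rates <- lapply(d$trials, function(tr)
    list(time = c(tr$t0, tr$tE), rate = c(13, 13)))
  out <- spike_time_r2(d, rates, neuron = 2)
  expect_equal(out$r2, 0, tolerance = 1e-12)
  ok <- is.finite(out$per_condition$r2)
  expect_equal(out$per_condition$r2[ok], rep(0, sum(ok)), tolerance = 1e-12)
})

test_that("rescaling with the true rate yields a unit-rate Poisson process", {
  lam <- function(t) 20 + 15 * sin(2 * pi * t)
  trains <- sim_inhom_poisson(40, 15, lam, 35, seed = 31)
  Lam <- function(t) 20 * t - 15 / (2 * pi) * (cos(2 * pi * t) - 1)
  resc <- lapply(trains, Lam)
  isis <- unlist(lapply(resc, diff))
  rate <- sum(lengths(resc)) / (40 * Lam(15))
  expect_equal(rate, 1, tolerance = 2 / sqrt(sum(lengths(resc))) * 2)
  expect_equal(cv2(isis), 1, tolerance = 0.05)
  # KS: rescaled ISIs are unit-mean exponential
  ks <- suppressWarnings(stats::ks.test(isis, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("phi solves the renewal quadratic with the documented root choice", {
  # exact homogeneous-Poisson moments: roots {1, 4 mu - 1}, phi = 1
  for (mu in c(0.5, 2, 5)) {
    out <- phi_from_moments(mu, mu, 2 * mu, 2 * mu)
    expect_equal(sort(out$roots), sort(c(1, 4 * mu - 1)), tolerance = 1e-12)
    expect_equal(out$phi, 1)
  }
  # complex roots flag an estimation failure
  bad <- phi_from_moments(1, 100, 2, 0.1)
  expect_true(bad$failed || all(is.finite(bad$roots)))
})

test_that("phi recovers renewal regularity and ignores rate variance", {
  # gamma-renewal, shape 4: operational-time CV^2 = 1/4
  rate_fn <- function(t) 20 + 5 * sin(2 * pi * t / 3)
  trains <- sim_gamma_renewal(120, 10, rate_fn, shape = 4, seed = 42)
  est <- estimate_phi(trains, durations = rep(10, 120), bin_size = 0.05)
  expect_false(est$failed)
  expect_equal(est$phi, 0.25, tolerance = 0.05)
  # doubly stochastic Poisson: phi = 1 while the raw ISI CV^2 is inflated
  set.seed(43)
  trains2 <- lapply(1:120, function(k) {
    amp <- stats::runif(1, 5, 35)
    sim_gamma_renewal(1, 10, function(t) amp + 10 * sin(pi * t), 1,
                      seed = 1000 + k)[[1]]
  })
  est2 <- estimate_phi(trains2, durations = rep(10, 120), bin_size = 0.05)
  expect_equal(est2$phi, 1, tolerance = 0.15)
  expect_gt(est2$plug_in, 1.5)
})

test_that("balanced accuracy is label-symmetric and handles degenerate predictors", {
  truth <- c(-1, -1, -1, 1, 1)
  expect_equal(balanced_accuracy(truth, truth), 1)
  expect_equal(balanced_accuracy(rep(1, 5), truth), 0.5)
  pred <- c(-1, 1, -1, 1, -1)
  expect_equal(balanced_accuracy(pred, truth),
               balanced_accuracy(-pred, -truth))
})

test_that("choice decoding from the generative model beats chance", {
  g <- build_grid(48)
  truth <- ground_truth_library("single_barrier_easy", grid = g)
  d <- simulate_trials(truth, n_trials = 60, seed = 17, conditions = c(1, 2))
  preds <- vapply(d$trials, function(tr) predict_choice(truth, tr), numeric(1))
  ch <- vapply(d$trials, function(tr) as.numeric(tr$choice), numeric(1))
  bacc <- balanced_accuracy(preds, ch)
  n <- length(ch)
  expect_gt(bacc, 0.5 + 5 * sqrt(0.25 / n))
})

test_that("LONO reduces to the closed form for constant held-out tuning", {
  g <- build_grid(32)
  m <- latent_model(g, forces = matrix(0.5, g$n, 2), D = 0.4,
                    F0 = -2 * g$nodes, C = c(10, 7),
                    Fi = cbind(rep(0.6, g$n), rep(0, g$n)))
  tr <- list(t0 = 0, tE = 0.8, times = c(0.1, 0.3, 0.35, 0.6),
             ids = c(1L, 2L, 1L, 2L), condition = 1L)
  out <- lono_rate(m, tr, held_out = 2)
  # neuron 2 fires at 7 Hz independent of the path
  expect_equal(out$loglik, -7 * 0.8 + 2 * log(7), tolerance = 1e-6)
  expect_error(lono_rate(latent_model(g, matrix(0, g$n, 1), 0.3, C = 5), tr, 1),
               "at least 2")
})

test_that("LONO rate prediction from a shared latent beats the PSTH baseline", {
  g <- build_grid(48)
  truth <- ground_truth_library("single_barrier_easy", grid = g)
  d <- simulate_trials(truth, n_trials = 40, seed = 19, conditions = c(1, 2))
  conds <- trial_conditions(d)
  ll_lono <- 0; ll_psth <- 0
  for (l in c(1, 2)) {
    idx <- which(conds == l)
    ps <- psth_rate(d, idx, neuron = 1)
    for (k in idx) {
      tr <- d$trials[[k]]
      ll_lono <- ll_lono + lono_rate(truth, tr, held_out = 1)$loglik
      ll_psth <- ll_psth + psth_loglik(ps, tr, 1)
    }
  }
  expect_gt(ll_lono, ll_psth)
})

test_that("the spike-count decoder separates separable data and not shuffled labels", {
  g <- build_grid(48)
  truth <- ground_truth_library("single_barrier_easy", grid = g)
  d <- simulate_trials(truth, n_trials = 110, seed = 12, dt = 2.5e-4)
  bd <- baseline_decoder(d)
  expect_equal(bd$n_bins, 42L)
  expect_gt(bd$balanced_accuracy, 0.6)
  # destroying the label-count association drops the decoder to chance
  d2 <- d
  set.seed(5)
  perm <- sample(length(d2$trials))
  for (k in seq_along(d2$trials)) {
    d2$trials[[k]]$choice <- d$trials[[perm[k]]]$choice
    d2$trials[[k]]$correct <- d$trials[[perm[k]]]$correct
  }
  expect_lt(abs(baseline_decoder(d2)$balanced_accuracy - 0.5), 0.1)
})

test_that("unit selection applies the three filters", {
  g <- build_grid(48)
  truth <- ground_truth_library("single_barrier_easy", grid = g)
  d <- simulate_trials(truth, n_trials = 150, seed = 13, dt = 2.5e-4)
  us <- unit_selection(d)
  expect_equal(nrow(us), 2L)
  expect_true(all(us$n_trials == length(d$trials)))
  # both units are active and selective, and the trial count exceeds 560
  expect_true(all(us$peak_rate >= 15))
  expect_true(all(us$selectivity > 0.6))
  expect_true(all(us$pass))
  # trial-count boundary: 559 trials fail criterion 2
  us559 <- unit_selection(subset_trials(d, 1:559))
  expect_false(any(us559$pass))
  # a silent unit fails the rate criterion
  dm <- d
  for (k in seq_along(dm$trials)) {
    keep <- dm$trials[[k]]$ids != 2L
    dm$trials[[k]]$times <- dm$trials[[k]]$times[keep]
    dm$trials[[k]]$ids <- dm$trials[[k]]$ids[keep]
  }
  us_sil <- unit_selection(dm)
  expect_false(us_sil$pass[2])
  # identical count distributions across choices: selectivity near 1/2
  set.seed(9)
  null_trials <- lapply(1:300, function(k) {
    nsp <- stats::rpois(1, 12)
    list(t0 = 0, tE = 1, times = sort(stats::runif(nsp, 0.01, 0.99)),
         ids = rep(1L, nsp), condition = 1L,
         choice = sample(c(-1, 1), 1))
  })
  us_null <- unit_selection(spike_data(null_trials, 1))
  expect_lt(us_null$selectivity, 0.6)
})
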