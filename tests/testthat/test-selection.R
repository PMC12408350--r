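test_that("the reference model has exactly zero feature complexity", {
  g <- build_grid(48)
  m <- latent_model(g, forces = matrix(0, g$n, 1), D = 0.5, C = 10)
  expect_identical(feature_complexity(m, 1), 0)
})

test_that("with zero force the complexity is the initial-density KL term", {
  g <- build_grid(48)
  m <- latent_model(g, forces = matrix(0, g$n, 1), D = 0.5,
                    F0 = -g$nodes / 0.2^2, C = 10)
  p0 <- model_p0(m)
  kl <- grid_integral(p0 * log(2 * p0), g)
  expect_equal(feature_complexity(m, 1), kl, tolerance = 1e-10)
})

test_that("the force term of the complexity matches a Monte-Carlo path integral", {
  g <- build_grid(48)
  m <- latent_model(g, forces = matrix(1.2 * g$nodes + 0.4, g$n, 1), D = 0.4,
                    F0 = -g$nodes / 0.14^2, C = 0, Fi = matrix(0, g$n, 1))
  d <- simulate_trials(m, n_trials = 8000, seed = 6, conditions = 1,
                       dt = 2e-4, track_f2 = TRUE)
  f2 <- attr(d, "f2int")
  mc <- (m$D / 4) * mean(f2)
  se <- (m$D / 4) * stats::sd(f2) / sqrt(length(f2))
  kl <- grid_integral(model_p0(m) * log(2 * model_p0(m)), g)
  force_term <- feature_complexity(m, 1) - kl
  expect_lt(abs(force_term - mc), 3 * se + 0.01 * mc)
})

test_that("complexity is non-negative, reflection-invariant and grows along fits", {
  m <- toy_model()
  expect_gte(feature_complexity(m, 1), 0)
  for (l in 1:2)
    expect_equal(feature_complexity(mirror_model(m), l),
                 feature_complexity(m, l), tolerance = 1e-8)
})

test_that("JS divergence is a bounded symmetric divergence, zero at identity", {
  m <- toy_model()
  m2 <- m; m2$forces <- m$forces * 1.6; m2$F0 <- m$F0 * 0.5
  for (method in c("occupancy", "joint")) {
    expect_equal(js_divergence(m, m, 1, method), 0, tolerance = 1e-10)
    d12 <- js_divergence(m, m2, 1, method)
    expect_equal(d12, js_divergence(m2, m, 1, method), tolerance = 1e-10)
    expect_gt(d12, 0)
    expect_lte(d12, log(2))
  }
  # near-disjoint occupancies approach the ln 2 bound
  g <- m$grid
  left <- latent_model(g, matrix(-8, g$n, 1), D = 0.3,
                       F0 = -(g$nodes + 0.7) / 0.03^2, C = 10)
  right <- latent_model(g, matrix(8, g$n, 1), D = 0.3,
                        F0 = -(g$nodes - 0.7) / 0.03^2, C = 10)
  expect_gt(js_divergence(left, right, 1), 0.6)
})

test_that("selection picks the last pair before the divergence leaves the band", {
  g <- build_grid(32)
  truth <- ground_truth_library("ramping_linear", grid = g)
  d <- simulate_trials(truth, n_trials = 30, seed = 8, conditions = 1:2)
  cfg <- fit_config(n_epochs = 6, n_line_searches = 0, seed = 4, n_modes = 8)
  sp <- two_split_fit(d, cfg, grid = g)
  # identical traces: the final (highest-complexity) pair is selected
  sel_same <- select_models(sp$trace1, sp$trace1, threshold = 0.0015)
  expect_equal(sel_same$epoch1, 6L)
  expect_true(sel_same$consistent)
  # infinite threshold: maximum complexity unconditionally
  sel_inf <- select_models(sp$trace1, sp$trace2, threshold = Inf)
  expect_equal(sel_inf$M_star, max(sel_inf$djs_curve$complexity))
  # impossible threshold: lowest-complexity pair with a warning
  expect_warning(sel0 <- select_models(sp$trace1, sp$trace2, threshold = -1),
                 "no model pair")
  expect_false(sel0$consistent)
  # selection is idempotent
  sel_a <- select_models(sp$trace1, sp$trace2)
  sel_b <- select_models(sp$trace1, sp$trace2)
  expect_identical(sel_a$M_star, sel_b$M_star)
})

test_that("divergence beyond a complexity caps the selected complexity", {
  g <- build_grid(32)
  truth <- ground_truth_library("ramping_linear", grid = g)
  d <- simulate_trials(truth, n_trials = 30, seed = 8, conditions = 1:2)
  cfg <- fit_config(n_epochs = 6, n_line_searches = 0, seed = 4, n_modes = 8)
  sp <- two_split_fit(d, cfg, grid = g)
  # corrupt the partner trace beyond epoch 3 so the halves disagree there
  # (negated forces keep the complexity but mirror the occupancy)
  spB <- sp$trace2
  for (ep in 4:6) spB$models[[ep]]$forces <- -spB$models[[ep]]$forces
  sel <- suppressWarnings(select_models(sp$trace1, spB, patience = 1L))
  # no corrupted member is selected, and the scan stopped below the top
  expect_lte(sel$epoch2, 3L)
  expect_lt(sel$M_star, max(sel$djs_curve$complexity))
})

test_that("outcome classification recognizes the three failure modes", {
  g <- build_grid(48)
  mk <- function(slopes, D = 0.5, C = c(10, 10)) {
    latent_model(g, forces = sapply(slopes, function(s) rep(s, g$n)),
                 D = D, C = C, Fi = matrix(0, g$n, 2))
  }
  fake_sel <- function(m1, m2) structure(
    list(model1 = m1, model2 = m2, M_star = 1, consistent = TRUE),
    class = "sd_selection")
  # tilts toward the same boundary in every condition: no decision signal
  s1 <- fake_sel(mk(c(2, 2, 1, 1)), mk(c(2, 2, 1, 1)))
  expect_equal(classify_outcome(s1), "underfit_no_signal")
  # halves tilt to opposite boundaries in one condition
  s2 <- fake_sel(mk(c(2, -2, 1, -1)), mk(c(-2, -2, 1, -1)))
  expect_equal(classify_outcome(s2), "underfit_split_disagreement")
  # pathological rates plus pathological noise magnitude
  m_over <- mk(c(2, -2, 1, -1), D = 4, C = c(500, 500))
  expect_equal(classify_outcome(fake_sel(m_over, m_over)), "overfit")
  # a healthy configuration
  s4 <- fake_sel(mk(c(2, -2, 1, -1)), mk(c(2, -2, 1, -1)))
  expect_equal(classify_outcome(s4), "good")
})

test_that("bootstrap with zero samples is a no-op and bands are finite otherwise", {
  empty <- bootstrap_bands(toy_data(), fit_config(), n_boot = 0L)
  expect_null(empty$phi_sd)
  expect_length(empty$models, 0)
  g <- build_grid(32)
  truth <- ground_truth_library("ramping_linear", grid = g)
  d <- simulate_trials(truth, n_trials = 16, seed = 9, conditions = 1:2)
  cfg <- fit_config(n_epochs = 3, n_line_searches = 0, seed = 5, n_modes = 8)
  bb <- suppressWarnings(bootstrap_bands(d, cfg, n_boot = 2L, grid = g))
  expect_length(bb$models, 4)
  expect_true(all(is.finite(bb$phi_sd)))
  expect_true(all(bb$phi_sd >= 0))
  expect_equal(dim(bb$tuning_sd), c(g$n, 2L))
})
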