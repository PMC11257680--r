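# Synapse populations, plasticity rules, recall and forgetting curves.

test_that("population initialization matches the stated distributions", {
  pp <- plasticity_params("binary_switch", p = 0.1)
  pop <- init_population(4000, pp, seed = 1)
  expect_true(all(pop$w %in% c(-1, 1)))
  expect_lt(abs(mean(pop$w)), 3 / sqrt(4000))

  mv <- init_population(3, plasticity_params("multivariable"), seed = 1)
  expect_equal(mv$w, rep(0, 3))
  mem <- sample_memory(3, "iid_binary", seed = 2)
  expect_error(recall_snr(mv, mem), "zero-variance")

  expect_error(init_population(0, pp), "positive")
})

test_that("cascade level occupancy matches the enumerated stationary chain", {
  k <- 3L
  pp <- plasticity_params("cascade", n_levels = k, alpha_cascade = 0.5)
  pop <- init_population(1e5, pp, seed = 3)
  occ <- tabulate(pop$lvl, k) / 1e5
  ref <- oracle_cascade_stationary(k, 0.5)
  lvl_ref <- ref[1:k] + ref[(k + 1):(2 * k)]
  se <- sqrt(lvl_ref * (1 - lvl_ref) / 1e5)
  expect_true(all(abs(occ - lvl_ref) < 3 * se + 1e-3))
})

test_that("binary switch updates obey the stated limits", {
  pp1 <- plasticity_params("binary_switch", p = 1)
  pop <- init_population(2, pp1)
  pop$w <- c(-1, -1)
  pop <- apply_memory(pop, c(1, -1), seed = 1)
  expect_equal(pop$w, c(1, -1))

  pp0 <- plasticity_params("binary_switch", p = 0)
  pop2 <- init_population(50, pp0, seed = 2)
  w0 <- pop2$w
  pop2 <- apply_memory(pop2, sample_memory(50, "iid_binary", seed = 3))
  expect_identical(pop2$w, w0)

  # sparse variant with f = 0.5 recovers the balanced depression rate
  expect_equal(
    memgate:::depression_prob(plasticity_params("binary_switch", p = 0.3,
                                                coding_level = 0.5)),
    0.3)
  expect_error(
    memgate:::depression_prob(plasticity_params("binary_switch", p = 1,
                                                coding_level = 0.9)),
    "exceeds 1")
})

test_that("binary-model weights remain in {-1, +1} under random event sequences", {
  for (model in c("binary_switch", "cascade")) {
    pp <- plasticity_params(model, p = 0.4, n_levels = 4)
    pop <- init_population(64, pp, seed = 5)
    set.seed(11)
    for (i in 1:60) {
      pop <- apply_memory(pop, sample_memory(64, "iid_binary"))
      expect_true(all(pop$w %in% c(-1, 1)))
    }
  }
})

test_that("cascade depression from a level-1 potentiated state always switches", {
  pp <- plasticity_params("cascade", n_levels = 4, alpha_cascade = 0.5)
  pop <- init_population(200, pp, seed = 7)
  pop$w <- rep(1, 200)
  pop$lvl <- rep(1L, 200)
  pop <- apply_memory(pop, rep(-1, 200), seed = 8)
  expect_true(all(pop$w == -1))
  expect_true(all(pop$lvl == 1L))
})

test_that("single-level cascade reduces to a deterministic binary switch", {
  # with k = 1, opposite-sign events switch with probability
  # min(1, alpha^0/(1-alpha)) = 1 and same-sign events do nothing: the
  # per-event transition law of a binary switch with p = 1.
  pp <- plasticity_params("cascade", n_levels = 1, alpha_cascade = 0.5)
  pop <- init_population(500, pp, seed = 9)
  mem <- sample_memory(500, "iid_binary", seed = 10)
  pop2 <- apply_memory(pop, mem, seed = 11)
  expect_equal(pop2$w, memory_entries(mem))
})

test_that("multivariable trajectory matches the exact linear recursion", {
  pp <- plasticity_params("multivariable", chain_length = 10)
  pop <- init_population(1, pp)
  # small impulse keeps the chain far from the saturation bound
  inputs <- c(0.1, rep(0, 20))
  ref <- oracle_mv_trajectory(inputs, m = 10)
  for (t in seq_along(inputs)) {
    pop <- if (inputs[t] != 0) apply_memory(pop, inputs[t]) else idle_step(pop)
    expect_equal(pop$U[[1]][1, 1], ref[t, 1], tolerance = 1e-12)
  }
  expect_equal(vapply(pop$U, function(u) u[1, 1], numeric(1)),
               ref[nrow(ref), ], tolerance = 1e-12)
})

test_that("multivariable dynamics superpose below the saturation bound", {
  pp <- plasticity_params("multivariable")
  run <- function(inputs) {
    pop <- init_population(1, pp)
    for (x in inputs) pop <- if (x != 0) apply_memory(pop, x) else idle_step(pop)
    vapply(pop$U, function(u) u[1, 1], numeric(1))
  }
  a <- c(0.05, 0, 0, 0.08, 0, 0, 0, 0)
  b <- c(0, 0.02, 0, 0, 0, -0.06, 0, 0)
  expect_equal(run(a + b), run(a) + run(b), tolerance = 1e-12)
})

test_that("recall SNR is normalized to unit variance for random memories", {
  pp <- plasticity_params("binary_switch", p = 0.1)
  pop <- init_population(2000, pp, seed = 13)
  expect_equal(recall_snr(pop, pop$w), sqrt(2000))
  ortho <- rep(c(1, -1, -1, 1), 500) * pop$w  # orthogonal by construction
  ortho <- ortho * rep(c(1, -1), 1000)
  expect_lt(abs(recall_snr(pop, pop$w * rep(c(1, -1), 1000))), 1e-12)

  set.seed(17)
  rs <- vapply(1:4000, function(i)
    recall_snr(pop, sample_memory(2000, "dense_balanced")), numeric(1))
  expect_lt(abs(stats::var(rs) - 1), 0.08)
  # Monte-Carlo normalization agrees with the analytic one
  probe <- sample_memory(2000, "dense_balanced", seed = 19)
  expect_equal(recall_snr(pop, probe, "monte_carlo", n_probes = 4000, seed = 23),
               recall_snr(pop, probe), tolerance = 0.1)
})

test_that("empirical forgetting curves are monotone within noise for all rules", {
  specs <- list(
    plasticity_params("binary_switch", p = 0.2),
    plasticity_params("cascade", n_levels = 4),
    plasticity_params("multivariable"))
  for (pp in specs) {
    fc <- empirical_forgetting_curve(pp, N = 800, horizon = 25, trials = 60,
                                     seed = 29, burn_in = if (pp$model == "multivariable") 300 else 0)
    # two-point smoothing removes the even/odd alternation that the
    # deterministic level-1 switch of the cascade introduces at short lags
    sm <- (fc$snr[-1] + fc$snr[-length(fc$snr)]) / 2
    se <- sqrt(fc$stderr[-1]^2 + fc$stderr[-length(fc$stderr)]^2) / 2
    rises <- diff(sm)
    se_d <- sqrt(se[-1]^2 + se[-length(se)]^2)
    expect_true(all(rises < 3 * se_d + 1e-8))
    expect_gt(fc$snr[1], 0)
  }
})

test_that("horizon zero gives a single point at the presentation", {
  pp <- plasticity_params("binary_switch", p = 0.3)
  fc <- empirical_forgetting_curve(pp, N = 500, horizon = 0, trials = 50, seed = 31)
  expect_length(fc$times, 1)
  expect_equal(fc$times, 0)
})

test_that("the analytic binary-switch curve tracks the empirical curve", {
  pp <- plasticity_params("binary_switch", p = 0.1)
  ac <- analytic_forgetting_curve(pp, N = 10000)
  emp <- empirical_forgetting_curve(pp, N = 10000, horizon = 30, trials = 150,
                                    seed = 37)
  pts <- seq(1, 31, by = 3)
  expect_true(all(abs(ac$fn(emp$times[pts]) - emp$snr[pts]) <
                    3 * emp$stderr[pts] + 1e-6))
  expect_equal(ac$fn(20) / ac$fn(0), (1 - 0.1)^20, tolerance = 1e-12)
  expect_equal(ac$fn(1e6), 0, tolerance = 1e-10)
  expect_error(analytic_forgetting_curve(plasticity_params("cascade"), 100),
               "binary switch")
})

test_that("slower-than-exponential tails distinguish multi-state synapses", {
  # cascade and multivariable models retain far more recall at long lags
  # than an exponential fitted to their early decay
  checks <- list(cascade = 45L, multivariable = 25L)
  for (model in names(checks)) {
    pp <- plasticity_params(model, n_levels = 6)
    fc <- empirical_forgetting_curve(pp, N = 3000, horizon = 50, trials = 200,
                                     seed = 41,
                                     burn_in = if (model == "multivariable") 500 else 0)
    early_rate <- (log(fc$snr[2]) - log(fc$snr[5])) / 3
    tt <- checks[[model]]
    pred_exp <- fc$snr[2] * exp(-early_rate * (tt - 1))
    expect_gt(fc$snr[tt + 1], 1.8 * pred_exp)
    expect_gt(fc$snr[tt + 1], 3 * fc$stderr[tt + 1])
  }
})
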