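# Memory sampling, interarrival models and stream generation.

test_that("memory sampling modes have the stated structure", {
  m <- sample_memory(100, "dense_balanced", seed = 1)
  expect_equal(sum(memory_entries(m)), 0)
  expect_error(sample_memory(7, "dense_balanced"), "even N")

  sp <- sample_memory(200, "sparse", f = 0.1, seed = 2)
  expect_equal(sum(memory_entries(sp) == 1), 20)
  # mean-centering applied at recall time only
  expect_equal(mean(memgate:::memory_entries_centered(sp)), 0, tolerance = 1e-12)
  expect_equal(memory_entries(sp)[memory_entries(sp) == 1], rep(1, 20))

  # sparse f = 0.5 has dense-balanced marginals
  s5 <- sample_memory(400, "sparse", f = 0.5, seed = 3)
  expect_equal(sum(memory_entries(s5)), 0)

  set.seed(4)
  dots <- replicate(500, {
    a <- memory_entries(sample_memory(256, "dense_balanced"))
    b <- memory_entries(sample_memory(256, "dense_balanced"))
    sum(a * b)
  })
  expect_lt(abs(mean(dots)), 3 * sqrt(256) / sqrt(500))
  expect_lt(abs(sd(dots) - sqrt(256)), 0.15 * sqrt(256))
})

test_that("interarrival CDF uses the mean-tau Weibull parameterization", {
  expo <- interarrival_model("exponential", tau = 1)
  expect_equal(interarrival_cdf(expo, 0), 0)
  expect_equal(interarrival_cdf(expo, 1), 1 - exp(-1))
  expect_error(interarrival_cdf(expo, -1), "nonnegative")

  wb <- interarrival_model("weibull", tau = 10, shape_k = 0.5)
  set.seed(5)
  x <- sample_interarrival(wb, 1e5)
  expect_lt(abs(mean(x) - 10) / 10, 0.02)

  det <- interarrival_model("deterministic", tau = 7)
  expect_equal(sample_interarrival(det, 5), rep(7, 5))
  expect_equal(interarrival_cdf(det, c(6.9, 7)), c(0, 1))

  # k = 1 Weibull is the exponential distribution
  w1 <- interarrival_model("weibull", tau = 3, shape_k = 1)
  set.seed(6)
  ks <- stats::ks.test(sample_interarrival(w1, 5000), "pexp", 1 / 3)
  expect_gt(ks$p.value, 0.01)

  # empirical CDF within the DKW band of the analytic CDF
  set.seed(7)
  n <- 5000
  xs <- sort(sample_interarrival(wb, n))
  ecdf_v <- seq_len(n) / n
  band <- sqrt(log(2 / 0.01) / (2 * n))
  expect_lt(max(abs(ecdf_v - interarrival_cdf(wb, xs))), band)
})

test_that("poisson streams have binomial reliable counts and are reproducible", {
  cfg <- environment_config(32, lambda = 1, horizon = 50, seed = 8)
  st <- generate_stream(cfg)
  expect_true(all(st$reliable))

  cfg2 <- environment_config(32, lambda = 0.25, horizon = 1e5, seed = 9)
  st2 <- generate_stream(cfg2)
  n_rel <- sum(st2$reliable)
  expect_lt(abs(n_rel - 0.25 * 1e5), 3 * sqrt(1e5 * 0.25 * 0.75))
  chi <- stats::chisq.test(c(n_rel, 1e5 - n_rel), p = c(0.25, 0.75))
  expect_gt(chi$p.value, 0.001)

  expect_identical(generate_stream(cfg2), st2)
  expect_identical(stream_memory(cfg2, 1)$entries, stream_memory(cfg2, 1)$entries)
})

test_that("renewal streams reproduce their interarrival law", {
  ia <- interarrival_model("exponential", tau = 8)
  cfg <- environment_config(16, mode = "renewal", interarrival = ia,
                            horizon = 30000, seed = 10)
  st <- generate_stream(cfg)
  gaps <- diff(st$time[st$reliable])
  # intervals are ceiled to the step grid; dithering recovers the law
  set.seed(99)
  ks <- suppressWarnings(stats::ks.test(gaps - stats::runif(length(gaps)),
                                        "pexp", 1 / 8))
  expect_gt(ks$p.value, 0.01)
})

test_that("multiscale streams fill unreliable background at the set fraction", {
  cfg <- environment_config(16, n_reliable = 3, mode = "multiscale",
                            p_unreliable = 0.9, log_tau_max = 5,
                            horizon = 20000, seed = 11)
  st <- generate_stream(cfg)
  n_rel <- sum(st$reliable)
  frac_un <- (nrow(st) - n_rel) / (20000 - n_rel)
  expect_lt(abs(frac_un - 0.9), 0.01)
})

test_that("unreliable recurrence window schedules geometric re-presentations", {
  cfg <- environment_config(16, lambda = 0, unreliable_window = 5,
                            unreliable_ratio = 0.5, horizon = 20000, seed = 12)
  st <- generate_stream(cfg)
  reps <- table(st$memory_id)
  # each unreliable memory recurs ~ sum_j 0.5^j = 0.97 times on average
  expect_gt(mean(reps) - 1, 0.6)
  expect_lt(mean(reps) - 1, 1.1)
})

test_that("log-uniform timescale marginal has a 1/t tail and unit mass", {
  A <- 8
  t_big <- c(20, 50, 100)
  d <- reliable_interarrival_marginal(A, t_big)
  expect_true(all(abs(d * A * t_big - 1) < 0.05))
  mass <- stats::integrate(function(t) reliable_interarrival_marginal(A, t),
                           lower = 1e-9, upper = Inf, rel.tol = 1e-8)$value
  expect_equal(mass, 1, tolerance = 1e-4)
  expect_error(reliable_interarrival_marginal(A, 0), "positive")
  # approximate (paper-display) form matches the exact one away from cutoff
  expect_equal(reliable_interarrival_marginal(A, 10, "approx"),
               reliable_interarrival_marginal(A, 10, "exact"), tolerance = 0.01)
})

test_that("config validation rejects out-of-range probabilities", {
  expect_error(environment_config(16, lambda = 1.5), "lambda")
  expect_error(environment_config(16, p_unreliable = -0.1), "p_unreliable")
  expect_error(interarrival_model("weibull", tau = -1), "positive")
})
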