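# Semi-analytic theory: forgetting-curve sums, consolidation probability,
# induced interarrivals, threshold selection, learnable timescale.

stm_curve <- analytic_forgetting_curve(plasticity_params("binary_switch", p = 0.1), 1e4)

test_that("repetition SNR sums forgetting-curve strengths", {
  expect_equal(snr_after_repetitions(stm_curve, 7), stm_curve$fn(7))
  # deterministic spacing: closed geometric form
  expect_equal(snr_after_repetitions(stm_curve, rep(5, 6)),
               snr_deterministic(stm_curve, 5, 6), tolerance = 1e-12)
  expect_error(snr_after_repetitions(stm_curve, c(3, -1)), "nonnegative")
})

test_that("repetition SNR matches a full population simulation", {
  pp <- plasticity_params("binary_switch", p = 0.1)
  N <- 4000L
  tau <- 6L; R <- 4L
  curve <- analytic_forgetting_curve(pp, N)
  pred <- snr_deterministic(curve, tau, R)
  set.seed(31)
  trials <- 150L
  W <- matrix(sample(c(-1, 1), trials * N, TRUE), trials)
  Mstar <- matrix(sample(c(-1, 1), trials * N, TRUE), trials)
  for (t in 0:(R * tau - 1)) {
    M <- if (t %% tau == 0) Mstar else matrix(sample(c(-1, 1), trials * N, TRUE), trials)
    U <- matrix(runif(trials * N), trials)
    flip <- ((M > 0) & (W < 0) & (U < 0.1)) | ((M < 0) & (W > 0) & (U < 0.1))
    W[flip] <- -W[flip]
  }
  # one more interference step so evaluation falls tau after the last
  # reinforcement (the loop above already ran tau - 1 steps past it)
  M <- matrix(sample(c(-1, 1), trials * N, TRUE), trials)
  U <- matrix(runif(trials * N), trials)
  flip <- ((M > 0) & (W < 0) & (U < 0.1)) | ((M < 0) & (W > 0) & (U < 0.1))
  W[flip] <- -W[flip]
  snr <- rowSums(W * Mstar) / sqrt(N)
  # the superposition is an approximation (reinforcements of the same trace
  # are counted as interference); it is stated to hold to ~10%
  expect_lt(abs(mean(snr) - pred), 3 * sd(snr) / sqrt(trials) + 0.1 * pred)
})

test_that("consolidation probability inverts the forgetting curve", {
  ia <- interarrival_model("exponential", tau = 30)
  expect_equal(consolidation_probability(stm_curve, -1, ia), 1)
  expect_equal(consolidation_probability(stm_curve, stm_curve$m0 * 1.01, ia), 0)
  theta <- 2
  q <- consolidation_probability(stm_curve, theta, ia)
  expect_equal(q, 1 - exp(-stm_curve$inv(theta) / 30), tolerance = 1e-10)
  # event-level Monte Carlo: reinforcement arrives while recall >= theta
  set.seed(33)
  n <- 20000L
  I <- rexp(n, 1 / 30)
  q_mc <- mean(stm_curve$fn(I) >= theta)
  expect_lt(abs(q - q_mc), 3 * sqrt(q * (1 - q) / n))
  # q is nonincreasing in theta
  qs <- vapply(seq(0.1, 8, length.out = 15), function(th)
    consolidation_probability(stm_curve, th, ia), numeric(1))
  expect_true(all(diff(qs) <= 1e-12))
})

test_that("threshold selection satisfies the repetition failure bound", {
  ia <- interarrival_model("exponential", tau = 20)
  sel <- select_threshold(stm_curve, ia, R = 2, epsilon = 0.1)
  expect_equal(sel$q, 1 - sqrt(0.1), tolerance = 1e-12)
  q_back <- consolidation_probability(stm_curve, sel$theta, ia)
  expect_equal(q_back, sel$q, tolerance = 1e-6)
  expect_lte((1 - q_back)^2, 0.1 + 1e-9)
  # theta is nondecreasing in R
  ths <- vapply(c(2, 4, 8, 16), function(R)
    select_threshold(stm_curve, ia, R = R)$theta, numeric(1))
  expect_true(all(diff(ths) >= -1e-12))
})

test_that("induced LTM interarrivals follow the thinned geometric mixture", {
  ia <- interarrival_model("exponential", tau = 50)
  theta <- 1
  ind <- induced_ltm_interarrival(stm_curve, theta, ia, n = 4e4, seed = 35,
                                  units = "scaled")
  expect_equal(ind$mean_span, ia$tau / ind$q, tolerance = 0.03)
  expect_equal(ind$mean_ltm, ind$tau_ltm, tolerance = 0.03)
  ks <- suppressWarnings(stats::ks.test(ind$samples, "pexp", 1 / ind$tau_ltm))
  expect_gt(ks$p.value, 0.01)
  # ungated limit: q -> 1 and no thinning recovers the raw distribution
  ind0 <- induced_ltm_interarrival(stm_curve, -Inf, ia, n = 2e4, seed = 36,
                                   units = "scaled")
  expect_equal(ind0$q, 1)
  expect_equal(ind0$nu, 1)
  expect_equal(ind0$mean_ltm, 50, tolerance = 0.05)
  expect_error(induced_ltm_interarrival(stm_curve, stm_curve$m0 * 2, ia),
               "q = 0")
})

test_that("learnable timescale behaves monotonically and reproducibly", {
  lt0 <- learnable_timescale(stm_curve, R = 2, beta = 3 * stm_curve$m0,
                             gated = FALSE, seed = 37)
  expect_equal(lt0$tau_star, 0)
  taus <- vapply(c(2, 5, 10), function(b)
    learnable_timescale(stm_curve, R = 4, beta = b, gated = FALSE,
                        n_mc = 1500, seed = 38)$tau_star, numeric(1))
  expect_true(all(diff(taus) <= 0))
  a <- learnable_timescale(stm_curve, R = 4, beta = 5, gated = FALSE,
                           n_mc = 1500, seed = 39)$tau_star
  b <- learnable_timescale(stm_curve, R = 4, beta = 5, gated = FALSE,
                           n_mc = 1500, seed = 39)$tau_star
  expect_identical(a, b)
  c2 <- learnable_timescale(stm_curve, R = 4, beta = 5, gated = FALSE,
                            n_mc = 3000, seed = 40)$tau_star
  expect_lt(abs(log(c2 / a)), log(1.1))
})

test_that("the deterministic-interval approximation upper-bounds random spacing", {
  beta <- 5; R <- 4L
  mc <- learnable_timescale(stm_curve, R = R, beta = beta, gated = FALSE,
                            n_mc = 2000, seed = 41)$tau_star
  det_bound <- stats::uniroot(function(tau) snr_deterministic(stm_curve, tau, R) - beta,
                              c(0.01, 1000))$root
  expect_lte(mc, det_bound * 1.05)
})
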