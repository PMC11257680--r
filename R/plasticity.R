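# Synapse-population models and plasticity rules.
#
# Three rules are implemented, all acting on a population of N synapses whose
# scalar strengths are collected in a weight vector w:
#
#  * binary switch -- weights in {-1,+1}; a potentiation (depression) target
#    activates (inactivates) the synapse with probability p. A sparse variant
#    potentiates a fraction f of synapses and depresses the rest with
#    probability f*p/(1-f), which balances potentiation and depression flux.
#  * cascade -- binary weights with a metaplastic depth level 1..k per synapse;
#    same-sign events push synapses deeper (harder to change), opposite-sign
#    events reset to level 1 of the other sign with level-dependent
#    probability.
#  * multivariable -- each synapse is a chain of m coupled continuous
#    variables u_1..u_m with geometrically slower timescales; the weight is
#    u_1. Memory events deliver an impulse to u_1; variables relax by one
#    explicit Euler step per global timestep and saturate at a hard bound,
#    which is what produces spacing effects under repeated presentation.

#' Plasticity rule parameters
#'
#' @param model one of `"binary_switch"`, `"cascade"`, `"multivariable"`.
#' @param p switching probability per candidate event (binary switch).
#' @param n_levels cascade depth (number of levels per sign).
#' @param alpha_cascade cascade transition base, in (0,1).
#' @param chain_length number of multivariable chain variables m.
#' @param n_mv multivariable timescale base n.
#' @param alpha_mv multivariable coupling strength, in (0,1).
#' @param coding_level fraction f of synapses targeted for potentiation by
#'   sparse memories; `0.5` recovers the balanced dense rule.
#' @param u_max hard saturation bound on multivariable chain variables.
#' @return an object of class `plasticity_params`.
#' @export
#' @examples
#' plasticity_params("binary_switch", p = 0.1)
#' plasticity_params("cascade", n_levels = 5)
plasticity_params <- function(model = c("binary_switch", "cascade", "multivariable"),
                              p = 0.1,
                              n_levels = 5L,
                              alpha_cascade = 0.5,
                              chain_length = 10L,
                              n_mv = 2,
                              alpha_mv = 0.5,
                              coding_level = 0.5,
                              u_max = 1) {
  model <- match.arg(model)
  if (!is.numeric(p) || p < 0 || p > 1) stop("'p' must lie in [0, 1]")
  if (n_levels < 1) stop("'n_levels' must be >= 1")
  if (chain_length < 1) stop("'chain_length' must be >= 1")
  if (coding_level <= 0 || coding_level >= 1) stop("'coding_level' must lie in (0, 1)")
  if (alpha_cascade <= 0 || alpha_cascade >= 1) stop("'alpha_cascade' must lie in (0, 1)")
  if (alpha_mv <= 0 || alpha_mv >= 1) stop("'alpha_mv' must lie in (0, 1)")
  structure(list(model = model, p = p,
                 n_levels = as.integer(n_levels),
                 alpha_cascade = alpha_cascade,
                 chain_length = as.integer(chain_length),
                 n_mv = n_mv, alpha_mv = alpha_mv,
                 coding_level = coding_level, u_max = u_max),
            class = "plasticity_params")
}

#' @export
print.plasticity_params <- function(x, ...) {
  cat("<plasticity_params>", x$model, "\n")
  switch(x$model,
    binary_switch = cat("  p =", x$p, " coding level f =", x$coding_level, "\n"),
    cascade = cat("  levels k =", x$n_levels, " alpha =", x$alpha_cascade, "\n"),
    multivariable = cat("  chain m =", x$chain_length, " n =", x$n_mv,
                        " alpha =", x$alpha_mv, " |u| <=", x$u_max, "\n"))
  invisible(x)
}

# Depression probability of the sparse binary-switch rule; errors when the
# (f, p) combination puts it outside [0, 1].
depression_prob <- function(params) {
  f <- params$coding_level
  pd <- f * params$p / (1 - f)
  if (pd > 1 + 1e-12) {
    stop("depression probability f*p/(1-f) = ", signif(pd, 4),
         " exceeds 1; invalid (coding_level, p) combination")
  }
  min(pd, 1)
}

# Stationary level occupancy of the cascade Markov chain under random
# (sign +/-1 with probability 1/2) memory events.
cascade_stationary <- function(k, alpha) {
  if (k == 1L) return(1)
  P <- matrix(0, k, k)
  adv <- alpha^(seq_len(k - 1))              # level i -> i+1, same-sign event
  sw <- alpha^(seq_len(k) - 1)               # level i -> 1 (other sign)
  sw[k] <- min(1, alpha^(k - 1) / (1 - alpha))
  for (i in seq_len(k)) {
    if (i < k) P[i, i + 1] <- 0.5 * adv[i]
    P[i, 1] <- P[i, 1] + 0.5 * sw[i]
    P[i, i] <- P[i, i] + 1 - 0.5 * (if (i < k) adv[i] else 0) - 0.5 * sw[i]
  }
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# Cascade switch probability per level (opposite-sign event).
cascade_switch_prob <- function(lvl, k, alpha) {
  p <- alpha^(lvl - 1)
  p[lvl == k] <- min(1, alpha^(k - 1) / (1 - alpha))
  p
}

## ---------------------------------------------------------------------------
## Vectorised kernels. Weight state is a (replicates x N) matrix so that
## Monte-Carlo trials share one BLAS-friendly update.

.bs_step <- function(W, M, p_pot, p_dep) {
  U <- matrix(stats::runif(length(W)), nrow(W))
  flip <- ((M > 0) & (W < 0) & (U < p_pot)) | ((M < 0) & (W > 0) & (U < p_dep))
  W[flip] <- -W[flip]
  W
}

.cascade_step <- function(Sgn, Lvl, M, k, alpha) {
  U <- matrix(stats::runif(length(Sgn)), nrow(Sgn))
  same <- (M * Sgn) > 0
  adv <- same & (Lvl < k) & (U < alpha^Lvl)
  Lvl[adv] <- Lvl[adv] + 1L
  opp <- (M * Sgn) < 0
  sw <- opp & (U < cascade_switch_prob(Lvl, k, alpha))
  Sgn[sw] <- -Sgn[sw]
  Lvl[sw] <- 1L
  list(Sgn = Sgn, Lvl = Lvl)
}

# One Euler relaxation step of the multivariable chain. `U` is a list of m
# equally-shaped matrices (variable index down the chain). Variable 1 has no
# leak to ground: its only silent coupling is to variable 2; variable m leaks
# to 0. All variables saturate at +/- u_max.
.mv_relax <- function(U, pars) {
  m <- pars$chain_length
  a <- pars$alpha_mv
  n <- pars$n_mv
  cin <- a * n^(-2 * seq_len(m) + 2)
  cout <- a * n^(-2 * seq_len(m) + 1)
  old <- U
  for (i in seq_len(m)) {
    up <- if (i > 1) cin[i] * (old[[i - 1]] - old[[i]]) else 0
    dn <- cout[i] * (old[[i]] - if (i < m) old[[i + 1]] else 0)
    U[[i]] <- pmin(pmax(old[[i]] + up - dn, -pars$u_max), pars$u_max)
  }
  U
}

.mv_impulse <- function(U, M, pars) {
  U[[1]] <- pmin(pmax(U[[1]] + M, -pars$u_max), pars$u_max)
  U
}

## ---------------------------------------------------------------------------

#' Initialize a synapse population
#'
#' Binary models start with each synapse independently active (weight +1) with
#' probability 0.5; cascade levels are drawn from the stationary occupancy of
#' the level chain under random events; multivariable chains start at zero.
#'
#' @param N number of synapses.
#' @param params a [plasticity_params()] object.
#' @param seed optional integer seed.
#' @return an object of class `synapse_population` with elements `N`,
#'   `params`, `w` (length-N weight vector) and model-specific auxiliary
#'   state (`lvl` for cascade, `U` for multivariable).
#' @export
init_population <- function(N, params, seed = NULL) {
  if (!inherits(params, "plasticity_params")) stop("'params' must be plasticity_params")
  if (!is.numeric(N) || N < 1) stop("'N' must be a positive count")
  N <- as.integer(N)
  with_seed(seed, {
    pop <- list(N = N, params = params)
    if (params$model == "multivariable") {
      pop$U <- replicate(params$chain_length, matrix(0, 1, N), simplify = FALSE)
      pop$w <- numeric(N)
    } else {
      pop$w <- sample(c(-1, 1), N, replace = TRUE)
      if (params$model == "cascade") {
        occ <- cascade_stationary(params$n_levels, params$alpha_cascade)
        pop$lvl <- sample.int(params$n_levels, N, replace = TRUE, prob = occ)
      }
    }
    structure(pop, class = "synapse_population")
  })
}

#' @export
print.synapse_population <- function(x, ...) {
  cat("<synapse_population> N =", x$N, "model =", x$params$model, "\n")
  invisible(x)
}

#' Apply one memory event to a synapse population
#'
#' The update always moves the weights toward the memory (target) vector in
#' expectation. Entries equal to 0 denote "no candidate event" at that
#' synapse. For the multivariable model this performs the impulse to `u_1`
#' followed by one relaxation step; use [idle_step()] for event-free
#' timesteps.
#'
#' @param pop a `synapse_population`.
#' @param mem a [memory_vector()] or plain numeric vector of length `pop$N`.
#' @param seed optional seed for the per-synapse switching draws.
#' @return the updated population.
#' @export
apply_memory <- function(pop, mem, seed = NULL) {
  m <- memory_entries(mem)
  if (length(m) != pop$N) stop("memory length ", length(m), " != population size ", pop$N)
  params <- pop$params
  with_seed(seed, {
    if (params$model == "binary_switch") {
      pop$w <- drop(.bs_step(matrix(pop$w, 1), matrix(m, 1),
                             params$p, depression_prob(params)))
    } else if (params$model == "cascade") {
      st <- .cascade_step(matrix(pop$w, 1), matrix(pop$lvl, 1), matrix(m, 1),
                          params$n_levels, params$alpha_cascade)
      pop$w <- drop(st$Sgn)
      pop$lvl <- drop(st$Lvl)
    } else {
      pop$U <- .mv_relax(.mv_impulse(pop$U, matrix(m, 1), params), params)
      pop$w <- drop(pop$U[[1]])
    }
    pop
  })
}

#' Advance a population one timestep without a memory event
#'
#' Only the multivariable model has intrinsic dynamics; the binary models are
#' returned unchanged.
#'
#' @param pop a `synapse_population`.
#' @return the updated population.
#' @export
idle_step <- function(pop) {
  if (pop$params$model == "multivariable") {
    pop$U <- .mv_relax(pop$U, pop$params)
    pop$w <- drop(pop$U[[1]])
  }
  pop
}

#' Ideal-observer recall signal-to-noise ratio
#'
#' Computes the recall factor `r = w . w*` (with sparse memories mean-centered
#' at recall time) normalized by the standard deviation of the recall factor
#' for randomly sampled memories, so that random memories score 0 +/- 1.
#'
#' The analytic normalization `sqrt(Var(entry) * sum(w^2))` is exact for
#' probe memories with independent entries; the Monte-Carlo mode estimates the
#' denominator from random probe memories of the same mode and coding level.
#'
#' @param pop a `synapse_population` (or any object with `w`).
#' @param mem a [memory_vector()] or numeric vector.
#' @param normalization `"analytic"` or `"monte_carlo"`.
#' @param n_probes number of random probes for the Monte-Carlo denominator.
#' @param seed optional seed for the probe draws.
#' @return a single numeric SNR value.
#' @export
recall_snr <- function(pop, mem, normalization = c("analytic", "monte_carlo"),
                       n_probes = 2000L, seed = NULL) {
  normalization <- match.arg(normalization)
  w <- if (is.list(pop)) pop$w else pop
  m <- memory_entries_centered(mem)
  if (length(m) != length(w)) stop("length mismatch between weights and memory")
  r <- sum(w * m)
  ss <- sum(w^2)
  if (normalization == "analytic") {
    v <- memory_entry_variance(mem)
    denom <- sqrt(v * ss)
    if (denom == 0) stop("zero-variance weights: analytic normalization undefined")
  } else {
    if (n_probes < 1000L) n_probes <- 1000L
    N <- length(w)
    mode <- memory_mode(mem)
    f <- memory_coding_level(mem)
    denom <- with_seed(seed, {
      r2 <- vapply(seq_len(n_probes), function(i) {
        probe <- sample_memory(N, mode = mode, f = f)
        sum(w * memory_entries_centered(probe))^2
      }, numeric(1))
      sqrt(mean(r2))
    })
    if (denom == 0) stop("zero-variance weights: recall normalization undefined")
  }
  r / denom
}

## ---------------------------------------------------------------------------
## Forgetting curves

new_forgetting_curve <- function(times, snr, stderr, fn, inv, model, N, params,
                                 provenance) {
  structure(list(times = times, snr = snr, stderr = stderr,
                 fn = fn, inv = inv, m0 = fn(0),
                 model = model, N = N, params = params,
                 provenance = provenance),
            class = "forgetting_curve")
}

#' @export
print.forgetting_curve <- function(x, ...) {
  cat("<forgetting_curve>", x$model, " N =", x$N, " provenance =", x$provenance,
      "\n  m(0) =", signif(x$m0, 4), "\n")
  invisible(x)
}

#' @export
as.data.frame.forgetting_curve <- function(x, ...) {
  data.frame(t = x$times, snr = x$snr, stderr = x$stderr,
             model = x$model, N = x$N, provenance = x$provenance)
}

#' Monte-Carlo forgetting curve
#'
#' Presents a target memory at `t = 0` to a population at its stationary
#' state, then presents a fresh random memory at every subsequent timestep,
#' recording the mean recall SNR of the target at each lag over independent
#' trials.
#'
#' @param params a [plasticity_params()] object.
#' @param N synapses per population.
#' @param horizon number of interfering timesteps after the presentation.
#' @param trials number of Monte-Carlo trials.
#' @param seed integer seed.
#' @param mode memory sampling mode (see [sample_memory()]).
#' @param f coding level for sparse memories.
#' @param burn_in interfering presentations before the target (multivariable
#'   populations start from zero and need one; binary models start at their
#'   stationary distribution and default to none).
#' @return a `forgetting_curve` object with empirical provenance; its `fn`
#'   element is a monotone nonincreasing interpolant with an exponential tail.
#' @export
empirical_forgetting_curve <- function(params, N, horizon, trials, seed = 1L,
                                       mode = c("dense_balanced", "iid_binary", "sparse"),
                                       f = params$coding_level,
                                       burn_in = if (params$model == "multivariable") 2000L else 0L) {
  mode <- match.arg(mode)
  if (trials < 1 || horizon < 0) stop("'trials' >= 1 and 'horizon' >= 0 required")
  N <- as.integer(N)
  trials <- as.integer(trials)
  with_seed(derive_seed(seed, "forgetting"), {
    rand_mem <- function() .sample_memory_matrix(trials, N, mode, f)
    center <- if (mode == "sparse") 2 * f - 1 else 0
    ventry <- if (mode == "sparse") 4 * f * (1 - f) else 1
    model <- params$model
    if (model == "binary_switch") {
      W <- matrix(sample(c(-1, 1), trials * N, TRUE), trials)
      pd <- depression_prob(params)
      step <- function(M) W <<- .bs_step(W, M, params$p, pd)
      weights <- function() W
    } else if (model == "cascade") {
      occ <- cascade_stationary(params$n_levels, params$alpha_cascade)
      Sgn <- matrix(sample(c(-1, 1), trials * N, TRUE), trials)
      Lvl <- matrix(sample.int(params$n_levels, trials * N, TRUE, prob = occ), trials)
      step <- function(M) {
        st <- .cascade_step(Sgn, Lvl, M, params$n_levels, params$alpha_cascade)
        Sgn <<- st$Sgn; Lvl <<- st$Lvl
      }
      weights <- function() Sgn
    } else {
      U <- replicate(params$chain_length, matrix(0, trials, N), simplify = FALSE)
      step <- function(M) U <<- .mv_relax(.mv_impulse(U, M, params), params)
      weights <- function() U[[1]]
    }
    for (b in seq_len(burn_in)) step(rand_mem())
    Mstar <- rand_mem()
    Mc <- Mstar - center
    denom <- sqrt(ventry * rowSums(weights()^2))
    if (model != "multivariable") denom <- rep(sqrt(ventry * N), trials)
    step(Mstar)
    snr <- matrix(NA_real_, trials, horizon + 1)
    snr[, 1] <- rowSums(weights() * Mc) / denom
    if (horizon > 0) {
      for (t in seq_len(horizon)) {
        step(rand_mem())
        snr[, t + 1] <- rowSums(weights() * Mc) / denom
      }
    }
    mu <- colMeans(snr)
    se <- apply(snr, 2, stats::sd) / sqrt(trials)
    times <- 0:horizon
    fc_empirical_interpolant(times, mu, se, model, N, params)
  })
}

# Build the monotone interpolant + inverse used by the theory layer.
fc_empirical_interpolant <- function(times, mu, se, model, N, params) {
  if (length(times) == 1L) {
    m0 <- mu[1]
    fn <- function(t) ifelse(t <= 0, m0, NA_real_)
    inv <- function(theta) ifelse(theta >= m0, 0, NA_real_)
    return(new_forgetting_curve(times, mu, se, fn, inv, model, N, params,
                                "empirical"))
  }
  iso <- stats::isoreg(times, -mu)
  dec <- -iso$yf
  floor_v <- max(dec[length(dec)], max(dec) * 1e-6, 1e-12)
  dec_f <- pmax(dec, floor_v)
  # exponential tail from the last resolvable decade of decay
  lo <- which(dec_f <= max(dec_f) * 0.2)
  tail_rate <- if (length(lo) >= 2) {
    idx <- range(lo)
    d <- (log(dec_f[idx[1]]) - log(dec_f[idx[2]])) / (times[idx[2]] - times[idx[1]])
    max(d, 1e-8)
  } else 1e-4
  lf <- stats::approxfun(times, log(dec_f), rule = 2)
  tmax <- max(times)
  fn <- function(t) {
    t <- pmax(t, 0)
    out <- exp(lf(pmin(t, tmax)))
    over <- t > tmax
    if (any(over)) out[over] <- exp(lf(tmax)) * exp(-tail_rate * (t[over] - tmax))
    out
  }
  m0 <- fn(0)
  inv <- function(theta) {
    vapply(theta, function(th) {
      if (th >= m0) return(0)
      if (th <= 0) return(Inf)
      if (th < fn(tmax)) return(tmax + (log(fn(tmax)) - log(th)) / tail_rate)
      stats::uniroot(function(t) fn(t) - th, c(0, tmax), tol = 1e-8)$root
    }, numeric(1))
  }
  new_forgetting_curve(times, mu, se, fn, inv, model, N, params, "empirical")
}

#' Analytic forgetting curve for the binary switch model
#'
#' The binary switch rule has forgetting curve
#' `m(t) = c * sqrt(N) * p * exp(-gamma * t)` with per-event decay rate
#' `gamma = -log(1 - p)` (equal to `p` for small `p`). The prefactor defaults
#' to the theoretical value `c = 1` and can be recalibrated against an
#' empirical curve.
#'
#' @param params binary-switch [plasticity_params()].
#' @param N synapse count.
#' @param calibrate if `TRUE`, rescale the prefactor to match a short
#'   Monte-Carlo estimate of `m(0)`.
#' @param seed seed for the calibration run.
#' @return a `forgetting_curve` object with analytic provenance and exact
#'   `fn`/`inv` closures.
#' @export
analytic_forgetting_curve <- function(params, N, calibrate = FALSE, seed = 1L) {
  if (params$model != "binary_switch") {
    stop("closed-form curve available only for the binary switch model; ",
         "use empirical_forgetting_curve() for '", params$model, "'")
  }
  p <- params$p
  gamma <- -log1p(-p)
  cal <- 1
  if (calibrate) {
    emp <- empirical_forgetting_curve(params, N, horizon = 0L,
                                      trials = 400L, seed = seed)
    cal <- emp$snr[1] / (sqrt(N) * p)
  }
  m0 <- cal * sqrt(N) * p
  fn <- function(t) m0 * exp(-gamma * pmax(t, 0))
  inv <- function(theta) {
    vapply(theta, function(th) {
      if (th >= m0) 0 else if (th <= 0) Inf else log(m0 / th) / gamma
    }, numeric(1))
  }
  times <- 0:ceiling(6 / gamma)
  new_forgetting_curve(times, fn(times), rep(0, length(times)), fn, inv,
                       "binary_switch", N, params, "analytic")
}
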