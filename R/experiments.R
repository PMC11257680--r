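# Experiment protocols: spacing effects, band gating, sparse coding levels,
# and consolidation-rate predictions.

#' Spacing-effect experiment for the multivariable synapse model
#'
#' Presents the same memory `repetitions` times at spacing `delta` and
#' evaluates recall SNR `delay` steps after the last presentation, with or
#' without fresh random patterns at the intervening timesteps. SNR is
#' normalized by the stationary noise floor of the model under ongoing random
#' input (estimated once by Monte Carlo), so the two conditions share a
#' common scale.
#'
#' @param deltas spacing intervals to probe.
#' @param repetitions presentations per protocol.
#' @param delay evaluation delay after the last presentation.
#' @param intervening logical; present fresh random patterns between
#'   repetitions.
#' @param trials Monte-Carlo trials.
#' @param N synapses.
#' @param params multivariable [plasticity_params()].
#' @param input_scale magnitude of memory entries (reference protocol: 1/2).
#' @param burn_in steps of random input used to estimate the noise floor.
#' @param seed integer seed.
#' @return a `data.frame` with columns `delta`, `intervening`, `snr`,
#'   `stderr`.
#' @export
spacing_experiment <- function(deltas = c(1, 2, 3, 4, 6, 8, 12, 16, 24, 32),
                               repetitions = 5L, delay = 8L,
                               intervening = c(FALSE, TRUE), trials = 20L,
                               N = 400L,
                               params = plasticity_params("multivariable",
                                                          chain_length = 10L,
                                                          n_mv = 2, alpha_mv = 0.5),
                               input_scale = 0.5, burn_in = 3000L, seed = 1L) {
  if (params$model != "multivariable") stop("spacing experiment requires the multivariable model")
  if (any(deltas < 1)) stop("'deltas' must be >= 1")
  m <- params$chain_length
  rand_pat <- function(rows) {
    matrix(sample(c(-1, 1), rows * N, TRUE) * input_scale, rows)
  }
  noise_floor <- with_seed(derive_seed(seed, "spacing-floor"), {
    U <- replicate(m, matrix(0, 1, N), simplify = FALSE)
    for (t in seq_len(burn_in)) U <- .mv_relax(.mv_impulse(U, rand_pat(1L), params), params)
    sqrt(input_scale^2 * sum(U[[1]]^2))
  })
  rows <- list()
  for (iv in intervening) {
    for (d in deltas) {
      snr <- with_seed(derive_seed(seed, paste0("spacing-", iv), d), {
        U <- replicate(m, matrix(0, trials, N), simplify = FALSE)
        Mstar <- rand_pat(trials)
        total <- (repetitions - 1L) * d + delay
        for (t in 0:total) {
          if (t %% d == 0L && t <= (repetitions - 1L) * d) {
            U <- .mv_relax(.mv_impulse(U, Mstar, params), params)
          } else if (iv) {
            U <- .mv_relax(.mv_impulse(U, rand_pat(trials), params), params)
          } else {
            U <- .mv_relax(U, params)
          }
        }
        rowSums(U[[1]] * Mstar) / noise_floor
      })
      rows[[length(rows) + 1L]] <- data.frame(
        delta = d, intervening = iv,
        snr = mean(snr), stderr = stats::sd(snr) / sqrt(trials))
    }
  }
  do.call(rbind, rows)
}

#' Band-gated consolidation probability versus interarrival interval
#'
#' Emulates an environment in which unreliable memories recur within a short
#' window (probability `ratio^lag` at lags `1..window`) while a reliable
#' memory recurs with exponential interarrivals of mean `tau_reliable`. The
#' recall (overlap) distributions of reliable and unreliable presentations
#' are estimated from one long run; the gating band is the contiguous recall
#' region where reliable presentations are at least `lr_threshold` times as
#' likely as unreliable ones. Probe memories presented twice at a controlled
#' interval yield `P(consolidate | interval)`.
#'
#' @param N synapses.
#' @param p binary-switch rate.
#' @param tau_reliable mean reliable interarrival.
#' @param window,ratio unreliable recurrence window and geometric ratio.
#' @param horizon run length (timesteps).
#' @param intervals probe intervals.
#' @param inject_prob probability of starting a probe pair on a free step.
#' @param lr_threshold likelihood-ratio criterion for the band.
#' @param seed integer seed.
#' @return a list with `band` (c(low, high)), `intervals`, `p_consolidate`,
#'   `n_pairs`, and `distributions` (recall samples by event class).
#' @export
band_gate_spacing <- function(N = 10000L, p = 0.1, tau_reliable = 15,
                              window = 5L, ratio = 0.5,
                              horizon = 12000L,
                              intervals = c(1, 2, 3, 5, 8, 12, 18, 27, 40),
                              inject_prob = 0.15, lr_threshold = 10,
                              seed = 1L) {
  with_seed(derive_seed(seed, "bandgate"), {
    rs <- function() sample(c(-1, 1), N, TRUE)
    w <- rs()
    sN <- sqrt(N)
    rel_mem <- rs()
    rel_next <- 1L + max(1L, round(stats::rexp(1, 1 / tau_reliable)))
    pend_rec_t <- integer(0); pend_rec_m <- list()
    pairs <- new.env(parent = emptyenv())  # probe pairs in flight, keyed by time
    r_rel <- numeric(0); r_unrel <- numeric(0)
    ni <- length(intervals)
    r2_by_int <- vector("list", ni)
    next_int <- 1L
    present <- function(mem) {
      r <- sum(w * mem) / sN
      u <- stats::runif(N)
      flip <- ((mem > 0) & (w < 0) & (u < p)) | ((mem < 0) & (w > 0) & (u < p))
      w[flip] <<- -w[flip]
      r
    }
    for (t in seq_len(horizon)) {
      key <- as.character(t)
      if (!is.null(pairs[[key]])) {
        pr <- pairs[[key]]
        r2 <- present(pr$mem)
        r2_by_int[[pr$i]] <- c(r2_by_int[[pr$i]], r2)
        rm(list = key, envir = pairs)
      } else if (t >= rel_next) {
        r_rel <- c(r_rel, present(rel_mem))
        rel_next <- t + max(1L, round(stats::rexp(1, 1 / tau_reliable)))
      } else if (length(pend_rec_t) && pend_rec_t[1] <= t) {
        r_unrel <- c(r_unrel, present(pend_rec_m[[1]]))
        pend_rec_t <- pend_rec_t[-1]; pend_rec_m <- pend_rec_m[-1]
      } else if (stats::runif(1) < inject_prob) {
        mem <- rs()
        present(mem)
        pairs[[as.character(t + intervals[next_int])]] <-
          list(mem = mem, i = next_int)
        next_int <- if (next_int == ni) 1L else next_int + 1L
      } else {
        mem <- rs()
        r_unrel <- c(r_unrel, present(mem))
        lag <- seq_len(window)
        rec <- lag[stats::runif(window) < ratio^lag]
        rec <- rec[!(t + rec) %in% pend_rec_t]
        if (length(rec)) {
          pend_rec_t <- c(pend_rec_t, t + rec)
          pend_rec_m <- c(pend_rec_m, replicate(length(rec), mem, simplify = FALSE))
          o <- order(pend_rec_t)
          pend_rec_t <- pend_rec_t[o]; pend_rec_m <- pend_rec_m[o]
        }
      }
    }
    breaks <- seq(floor(min(r_rel, r_unrel)) - 0.5,
                  ceiling(max(r_rel, r_unrel)) + 0.5, by = 0.5)
    h_rel <- graphics::hist(r_rel, breaks = breaks, plot = FALSE)
    h_un <- graphics::hist(r_unrel, breaks = breaks, plot = FALSE)
    dens_rel <- h_rel$counts / length(r_rel)
    dens_un <- h_un$counts / length(r_unrel)
    lr <- dens_rel / pmax(dens_un, 1e-12)
    ok <- which(lr >= lr_threshold & h_rel$counts >= 5)
    if (!length(ok)) stop("band empty: likelihood ratio never reaches ", lr_threshold)
    # contiguous block around the strongest bin
    top <- ok[which.max(lr[ok])]
    lo_i <- top; while ((lo_i - 1L) %in% ok) lo_i <- lo_i - 1L
    hi_i <- top; while ((hi_i + 1L) %in% ok) hi_i <- hi_i + 1L
    band <- c(breaks[lo_i], breaks[hi_i + 1L])
    p_cons <- vapply(seq_len(ni), function(i) {
      r2 <- r2_by_int[[i]]
      if (!length(r2)) return(NA_real_)
      mean(r2 >= band[1] & r2 < band[2])
    }, numeric(1))
    list(band = band, intervals = intervals, p_consolidate = p_cons,
         n_pairs = vapply(r2_by_int, length, integer(1)),
         distributions = list(reliable = r_rel, unreliable = r_unrel),
         config = list(N = N, p = p, tau_reliable = tau_reliable,
                       window = window, ratio = ratio, horizon = horizon,
                       seed = seed))
  })
}

## ---------------------------------------------------------------------------
## Sparse coding levels

# Steady-state SNR of one reliable sparse memory under the sparse binary
# switch rule, vectorised over trials. Returns the time-average over the last
# `tail_frac` of the run.
.sparse_steady_snr <- function(N, f, lambda, p, T_steps, trials, tail_frac = 0.2,
                               sample_every = 5L) {
  k <- max(1L, round(f * N))
  pd <- min(1, f * p / (1 - f))
  center <- 2 * f - 1
  denom <- sqrt(4 * f * (1 - f) * N)
  sp_mat <- function() {
    M <- matrix(-1, trials, N)
    for (i in seq_len(trials)) M[i, sample.int(N, k)] <- 1
    M
  }
  W <- matrix(sample(c(-1, 1), trials * N, TRUE), trials)
  Mstar <- sp_mat()
  Mc <- Mstar - center
  t_rec <- seq(sample_every, T_steps, by = sample_every)
  keep <- t_rec > (1 - tail_frac) * T_steps
  acc <- 0; n_acc <- 0L
  for (t in seq_len(T_steps)) {
    rel <- stats::runif(trials) < lambda
    M <- sp_mat()
    if (any(rel)) M[rel, ] <- Mstar[rel, ]
    W <- .bs_step(W, M, p, pd)
    if (t %% sample_every == 0L && t > (1 - tail_frac) * T_steps) {
      acc <- acc + mean(rowSums(W * Mc) / denom)
      n_acc <- n_acc + 1L
    }
  }
  acc / n_acc
}

#' Steady-state SNR over coding levels and reinforcement rates
#'
#' For each `(f, lambda)` pair, simulates a single population of sparse
#' binary-switch synapses with one reliable memory recurring at rate `lambda`
#' among unreliable sparse memories, and reports the steady-state recall SNR
#' (time-average over the final 20% of the run). The optimal coding level
#' `f*` per rate is located on the grid and refined by a quadratic fit in
#' `log f`; the returned slope is the least-squares slope of `log f*` on
#' `log lambda`.
#'
#' @param N synapses.
#' @param f_values coding levels (grid).
#' @param lambda_values reliable recurrence rates.
#' @param p binary-switch potentiation probability.
#' @param trials Monte-Carlo trials per cell.
#' @param T_max cap on simulated steps per cell (the run length adapts to
#'   `1/lambda`).
#' @param seed integer seed.
#' @return a list with the SNR `grid` (f x lambda), `f_star` per rate,
#'   `slope`, and the grids used.
#' @export
sparsity_snr <- function(N = 1024L,
                         f_values = 10^seq(-3, -0.3, by = 0.25),
                         lambda_values = 10^seq(-3, -1, by = 0.5),
                         p = 1, trials = 8L, T_max = 48000L, seed = 1L) {
  f_values <- f_values[round(f_values * N) >= 1]
  G <- matrix(NA_real_, length(f_values), length(lambda_values),
              dimnames = list(signif(f_values, 3), signif(lambda_values, 3)))
  for (j in seq_along(lambda_values)) {
    lam <- lambda_values[j]
    T_steps <- as.integer(min(T_max, max(2500, round(25 / lam))))
    for (i in seq_along(f_values)) {
      G[i, j] <- with_seed(derive_seed(seed, "sparsity", i * 1000L + j),
        .sparse_steady_snr(N, f_values[i], lam, p, T_steps, trials))
    }
  }
  f_star <- vapply(seq_along(lambda_values), function(j) {
    refine_log_argmax(f_values, G[, j])
  }, numeric(1))
  fit <- stats::lm(log(f_star) ~ log(lambda_values))
  list(grid = G, f_values = f_values, lambda_values = lambda_values,
       f_star = f_star, slope = unname(stats::coef(fit)[2]),
       config = list(N = N, p = p, trials = trials, seed = seed))
}

# Quadratic refinement of an argmax on a log-spaced grid.
refine_log_argmax <- function(x, y) {
  i <- which.max(y)
  if (i == 1L || i == length(x)) return(x[i])
  lx <- log(x[(i - 1):(i + 1)]); ly <- y[(i - 1):(i + 1)]
  d1 <- (ly[3] - ly[1]) / (lx[3] - lx[1])
  d2 <- ((ly[3] - ly[2]) / (lx[3] - lx[2]) - (ly[2] - ly[1]) / (lx[2] - lx[1])) /
    ((lx[3] - lx[1]) / 2)
  if (!is.finite(d2) || d2 >= 0) return(x[i])
  exp(lx[2] - d1 / d2 / 2)
}

#' Joint STM/LTM coding-level grid for the recall-gated system
#'
#' Simulates the two-module recall-gated system with sparse coding levels
#' `f_stm` and `f_ltm` and reports the steady-state total-system SNR of a
#' reliable memory, defined as the SNR of the sum of z-scored STM and LTM
#' recall factors. An ungated control (both modules update on every event) is
#' run on the same grid; by symmetry its optimum lies on the diagonal.
#'
#' @param N_total total synapse count (split evenly between modules).
#' @param f_values coding-level grid (both axes).
#' @param lambda reliable recurrence rate.
#' @param theta gate threshold (normalized STM recall units).
#' @param p binary-switch rate.
#' @param T_steps steps per cell.
#' @param trials trials per cell.
#' @param seed integer seed.
#' @return a list with `snr_gated` and `snr_control` matrices (rows `f_stm`,
#'   columns `f_ltm`), the argmax pairs, and the grid.
#' @export
joint_sparsity_grid <- function(N_total = 256L,
                                f_values = c(0.02, 0.04, 0.08, 0.16, 0.32, 0.5),
                                lambda = 0.05, theta = 1.5, p = 1,
                                T_steps = 4000L, trials = 8L, seed = 1L) {
  N <- N_total %/% 2L
  f_values <- f_values[round(f_values * N) >= 1]
  nf <- length(f_values)
  gated <- matrix(NA_real_, nf, nf, dimnames = list(f_values, f_values))
  control <- gated
  for (i in seq_len(nf)) for (j in seq_len(nf)) {
    res <- with_seed(derive_seed(seed, "joint", i * 100L + j), {
      .joint_cell(N, f_values[i], f_values[j], lambda, theta, p, T_steps, trials)
    })
    gated[i, j] <- res["gated"]
    control[i, j] <- res["control"]
  }
  am_g <- arrayInd(which.max(gated), dim(gated))
  am_c <- arrayInd(which.max(control), dim(control))
  list(snr_gated = gated, snr_control = control,
       f_values = f_values,
       argmax_gated = c(f_stm = f_values[am_g[1]], f_ltm = f_values[am_g[2]]),
       argmax_control = c(f_stm = f_values[am_c[1]], f_ltm = f_values[am_c[2]]),
       config = list(N_total = N_total, lambda = lambda, theta = theta,
                     p = p, T_steps = T_steps, trials = trials, seed = seed))
}

.joint_cell <- function(N, f1, f2, lambda, theta, p, T_steps, trials,
                        tail_frac = 0.2, sample_every = 5L) {
  k1 <- max(1L, round(f1 * N)); k2 <- max(1L, round(f2 * N))
  pd1 <- min(1, f1 * p / (1 - f1)); pd2 <- min(1, f2 * p / (1 - f2))
  c1 <- 2 * f1 - 1; c2 <- 2 * f2 - 1
  d1 <- sqrt(4 * f1 * (1 - f1) * N); d2 <- sqrt(4 * f2 * (1 - f2) * N)
  spm <- function(k) {
    M <- matrix(-1, trials, N)
    for (i in seq_len(trials)) M[i, sample.int(N, k)] <- 1
    M
  }
  Ws <- matrix(sample(c(-1, 1), trials * N, TRUE), trials)
  Wg <- matrix(sample(c(-1, 1), trials * N, TRUE), trials)
  Wc <- Wg
  Ms_star <- spm(k1); Ml_star <- spm(k2)
  Ms_c <- Ms_star - c1; Ml_c <- Ml_star - c2
  acc_g <- acc_c <- 0; n_acc <- 0L
  for (t in seq_len(T_steps)) {
    rel <- stats::runif(trials) < lambda
    Ms <- spm(k1); Ml <- spm(k2)
    if (any(rel)) { Ms[rel, ] <- Ms_star[rel, ]; Ml[rel, ] <- Ml_star[rel, ] }
    r <- rowSums(Ws * (Ms - c1)) / d1
    pass <- r >= theta
    Ws <- .bs_step(Ws, Ms, p, pd1)
    U <- matrix(stats::runif(trials * N), trials)
    Wg <- .bs_step_u(Wg, Ml, p, pd2, U, active = matrix(pass, trials, N))
    Wc <- .bs_step_u(Wc, Ml, p, pd2, U)
    if (t %% sample_every == 0L && t > (1 - tail_frac) * T_steps) {
      zs <- rowSums(Ws * Ms_c) / d1
      zg <- rowSums(Wg * Ml_c) / d2
      zc <- rowSums(Wc * Ml_c) / d2
      acc_g <- acc_g + mean(zs + zg) / sqrt(2)
      acc_c <- acc_c + mean(zs + zc) / sqrt(2)
      n_acc <- n_acc + 1L
    }
  }
  c(gated = acc_g / n_acc, control = acc_c / n_acc)
}

## ---------------------------------------------------------------------------
## Prediction curves (recall responsibility shift; consolidation rate)

#' Predicted recall and consolidation-rate curves
#'
#' Two families of predictions from the gated model: (a) true-positive recall
#' rate at 10% false-positive rate, over time, for the combined system
#' (sum of z-scored STM and LTM recalls) and for the LTM alone -- their
#' difference shrinks as consolidation shifts responsibility to the LTM; (b)
#' the probability that a reliable presentation is consolidated, over time,
#' for several reinforcement rates `lambda` -- increasing in both. With
#' `lambda = 0` the consolidation probability equals the unreliable pass rate
#' `1 - Phi(theta)` (computed at large N where the Gaussian null is
#' accurate).
#'
#' @param N synapses per module (recall curves).
#' @param lambda reliable rate for the recall curves.
#' @param lambdas rates for the consolidation-probability curves.
#' @param p_stm,p_ltm,theta module rates and gate threshold.
#' @param horizon,trials simulation size for the recall curves.
#' @param trials_rate trials for the consolidation-rate curves.
#' @param N_baseline,trials_baseline,horizon_baseline size of the
#'   `lambda = 0` baseline run.
#' @param fpr false-positive rate defining the decision threshold.
#' @param seed integer seed.
#' @return a list with `times`, `tpr_combined`, `tpr_ltm`, `tpr_diff`,
#'   `cons_prob` (one column per lambda), `baseline_rate` and
#'   `baseline_expected` (`1 - Phi(theta)`).
#' @export
prediction_curves <- function(N = 1000L, lambda = 0.25,
                              lambdas = c(0.05, 0.1, 0.25),
                              p_stm = 0.25, p_ltm = 0.05, theta = 2^-3,
                              horizon = 500L, trials = 200L,
                              trials_rate = 150L,
                              N_baseline = 10000L, trials_baseline = 20L,
                              horizon_baseline = 300L,
                              fpr = 0.1, seed = 1L) {
  tr <- run_consolidation_sim(N_stm = N, N_ltm = N, p_stm = p_stm,
                              p_ltm = p_ltm, lambda = lambda, theta = theta,
                              horizon = horizon, trials = trials, seed = seed)
  tpr_at_fpr <- function(sig, null) {
    thr <- stats::quantile(null, 1 - fpr, names = FALSE)
    colMeans(sig > matrix(thr, nrow(sig), ncol(sig), byrow = TRUE))
  }
  null_comb <- tr$probe_stm + tr$probe_gated
  sig_comb <- tr$stm + tr$ltm_gated
  nt <- length(tr$times)
  tpr_c <- vapply(seq_len(nt), function(k)
    tpr_at_fpr(sig_comb[, k, drop = FALSE], null_comb[, k]), numeric(1))
  tpr_l <- vapply(seq_len(nt), function(k)
    tpr_at_fpr(tr$ltm_gated[, k, drop = FALSE], tr$probe_gated[, k]), numeric(1))
  cons <- sapply(lambdas, function(l) {
    r <- run_consolidation_sim(N_stm = N, N_ltm = N, p_stm = p_stm,
                               p_ltm = p_ltm, lambda = l, theta = theta,
                               horizon = horizon, trials = trials_rate,
                               seed = seed + 1L)
    r$p_cons_rel
  })
  colnames(cons) <- lambdas
  base <- run_consolidation_sim(N_stm = N_baseline, N_ltm = 16L,
                                p_stm = p_stm, p_ltm = p_ltm, lambda = 0,
                                theta = theta, horizon = horizon_baseline,
                                trials = trials_baseline, seed = seed + 2L)
  list(times = tr$times, tpr_combined = tpr_c, tpr_ltm = tpr_l,
       tpr_diff = tpr_c - tpr_l,
       bin_times = tr$bin_times, cons_prob = cons, lambdas = lambdas,
       baseline_rate = mean(base$p_cons_unrel),
       baseline_expected = 1 - stats::pnorm(theta),
       config = list(N = N, lambda = lambda, p_stm = p_stm, p_ltm = p_ltm,
                     theta = theta, horizon = horizon, trials = trials,
                     seed = seed))
}
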