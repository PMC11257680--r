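# Recall-gated systems consolidation.
#
# A short-term module (STM) and one or more long-term modules (LTM) receive
# the same stream of memories through independent random sub-vectors. The STM
# always learns; LTM plasticity is enabled only when the (pre-update) STM
# recall of the incoming memory passes a gating function. Thresholds are in
# normalized-recall units: the recall of random memories has standard
# deviation 1.

#' Gating function
#'
#' @param kind `"threshold"` (consolidate iff `r >= theta`), `"band"`
#'   (consolidate iff `low <= r < high`), or `"ensemble"` (disjoint bands of
#'   log recall routing to indexed LTM subpopulations).
#' @param theta threshold, normalized recall units.
#' @param band numeric `c(low, high)` for the band kind.
#' @param edges increasing vector of band edges (on `log r`) for the ensemble
#'   kind; band `i` spans `[edges[i], edges[i+1])`.
#' @return an object of class `gating_function`.
#' @export
gating_function <- function(kind = c("threshold", "band", "ensemble"),
                            theta = 0.125, band = NULL, edges = NULL) {
  kind <- match.arg(kind)
  if (kind == "band") {
    if (is.null(band) || length(band) != 2L || band[1] >= band[2]) {
      stop("'band' must be c(low, high) with low < high")
    }
  }
  if (kind == "ensemble") {
    if (is.null(edges) || length(edges) < 2L || is.unsorted(edges, strictly = TRUE)) {
      stop("'edges' must be a strictly increasing vector of length >= 2")
    }
  }
  structure(list(kind = kind, theta = theta, band = band, edges = edges),
            class = "gating_function")
}

#' Evenly spaced ensemble band edges
#'
#' Edges on log recall spanning `[0, log(N)/2]`, the natural range between the
#' noise floor and the maximal recall `sqrt(N)` of a population of `N`
#' synapses.
#'
#' @param N synapse count of the STM.
#' @param n_bands number of LTM subpopulations.
#' @return numeric vector of `n_bands + 1` edges.
#' @export
auto_ensemble_edges <- function(N, n_bands) {
  seq(0, 0.5 * log(N), length.out = n_bands + 1L)
}

#' Gating decision for a recall value
#'
#' @param gate a [gating_function()].
#' @param r_stm normalized STM recall (finite scalar or vector).
#' @return integer vector: 0/1 for threshold and band gates; for ensemble
#'   gates the index of the containing band (0 if none).
#' @export
gate_decision <- function(gate, r_stm) {
  if (any(!is.finite(r_stm) & !is.infinite(r_stm))) stop("'r_stm' must be finite")
  switch(gate$kind,
    threshold = as.integer(r_stm >= gate$theta),
    band = as.integer(r_stm >= gate$band[1] & r_stm < gate$band[2]),
    ensemble = {
      lr <- suppressWarnings(log(pmax(r_stm, 0)))
      idx <- findInterval(lr, gate$edges, rightmost.closed = TRUE)
      as.integer(ifelse(is.finite(lr) & idx >= 1 & idx <= length(gate$edges) - 1L,
                        idx, 0L))
    })
}

#' Assemble a recall-gated consolidation system
#'
#' @param stm a `synapse_population` for the short-term module.
#' @param ltm a `synapse_population` or list of subpopulations (one per
#'   ensemble band).
#' @param gate a [gating_function()].
#' @return an object of class `consolidation_system`.
#' @export
consolidation_system <- function(stm, ltm, gate) {
  if (inherits(ltm, "synapse_population")) ltm <- list(ltm)
  if (gate$kind == "ensemble" && length(ltm) != length(gate$edges) - 1L) {
    stop("ensemble gate needs one LTM subpopulation per band")
  }
  structure(list(stm = stm, ltm = ltm, gate = gate),
            class = "consolidation_system")
}

#' Advance a consolidation system by one event
#'
#' STM recall of the incoming memory is computed on the pre-update STM
#' weights; the STM is then always updated, and the LTM (or the band-indexed
#' subpopulation) is updated iff the gate fires. The STM and LTM address the
#' memory through independent sub-vectors.
#'
#' @param system a [consolidation_system()].
#' @param mem_stm memory sub-vector for the STM.
#' @param mem_ltm memory sub-vector for the LTM (or list, one per
#'   subpopulation).
#' @param seed optional seed for the plasticity draws.
#' @return a list with elements `system`, `consolidated` (logical), `band`
#'   (integer) and `r_stm`.
#' @export
system_step <- function(system, mem_stm, mem_ltm, seed = NULL) {
  r <- recall_snr(system$stm, mem_stm)
  band <- gate_decision(system$gate, r)
  with_seed(seed, {
    system$stm <- apply_memory(system$stm, mem_stm)
    if (band >= 1L) {
      ml <- if (is.list(mem_ltm) && !inherits(mem_ltm, "memory_vector")) {
        mem_ltm[[band]]
      } else {
        mem_ltm
      }
      system$ltm[[band]] <- apply_memory(system$ltm[[band]], ml)
    }
    list(system = system, consolidated = band >= 1L, band = band, r_stm = r)
  })
}

#' Threshold giving a target consolidation rate
#'
#' Utility for the protocol that sets the gate so that a fixed fraction (e.g.
#' 10%) of reliable memory presentations is consolidated: the threshold is the
#' `(1 - target_rate)` quantile of observed reliable-presentation recalls.
#'
#' @param r_reliable recall values of reliable presentations.
#' @param target_rate fraction of presentations that should pass.
#' @return the threshold.
#' @export
calibrate_gate_threshold <- function(r_reliable, target_rate = 0.1) {
  if (target_rate <= 0 || target_rate >= 1) stop("'target_rate' must lie in (0,1)")
  unname(stats::quantile(r_reliable, 1 - target_rate, names = FALSE, type = 7))
}

## ---------------------------------------------------------------------------
## Vectorised two-module simulation (binary switch modules).

.bs_step_u <- function(W, M, p_pot, p_dep, U, active = NULL) {
  flip <- ((M > 0) & (W < 0) & (U < p_pot)) | ((M < 0) & (W > 0) & (U < p_dep))
  if (!is.null(active)) flip <- flip & active
  W[flip] <- -W[flip]
  W
}

#' Simulate recall-gated consolidation of a reliable memory
#'
#' The proof-of-concept protocol: a single reliable memory recurs with
#' probability `lambda` per timestep among fresh unreliable memories; binary
#' switch STM and LTM modules with independent memory sub-vectors; threshold
#' gating on normalized STM recall. A non-interacting parallel control (same
#' event stream, same plasticity draws, LTM updated on every event) is run in
#' lockstep.
#'
#' @param N_stm,N_ltm synapses per module.
#' @param p_stm,p_ltm binary-switch learning rates.
#' @param lambda reliable recurrence probability per timestep.
#' @param theta gating threshold (normalized recall units; `-Inf` disables
#'   gating, which makes the gated and parallel traces identical).
#' @param horizon timesteps.
#' @param trials Monte-Carlo trials (vectorized).
#' @param seed integer seed.
#' @param record_every record the tracked-memory SNR every this many steps.
#' @return an object of class `consolidation_trace`: a list with `times`,
#'   matrices `stm`, `ltm_gated`, `ltm_parallel` (trials x times), per-bin
#'   gate pass rates for reliable (`p_cons_rel`) and unreliable
#'   (`p_cons_unrel`) events, and `probe` recall (an unpresented random
#'   memory, the empirical null).
#' @export
run_consolidation_sim <- function(N_stm = 1000L, N_ltm = 1000L,
                                  p_stm = 0.25, p_ltm = 0.05,
                                  lambda = 0.25, theta = 2^-3,
                                  horizon = 500L, trials = 100L,
                                  seed = 1L, record_every = 10L) {
  stopifnot(lambda >= 0, lambda <= 1)
  with_seed(derive_seed(seed, "consolidation"), {
    rs <- function(n, N) matrix(sample(c(-1, 1), n * N, TRUE), n)
    Wstm <- rs(trials, N_stm)
    Wg <- rs(trials, N_ltm)              # gated LTM
    Wp <- Wg                             # parallel control starts identically
    Mrel_s <- rs(trials, N_stm)          # tracked reliable memory, STM part
    Mrel_l <- rs(trials, N_ltm)          # independent LTM part
    Probe_s <- rs(trials, N_stm)         # never-presented probe (null recall)
    Probe_l <- rs(trials, N_ltm)
    rec_t <- unique(c(0L, seq(record_every, horizon, by = record_every)))
    nr <- length(rec_t)
    S <- matrix(NA_real_, trials, nr)
    G <- matrix(NA_real_, trials, nr)
    P <- matrix(NA_real_, trials, nr)
    PrS <- matrix(NA_real_, trials, nr)
    PrG <- matrix(NA_real_, trials, nr)
    PrP <- matrix(NA_real_, trials, nr)
    nbin <- nr - 1L
    cons_rel <- integer(nbin); n_rel <- integer(nbin)
    cons_unrel <- integer(nbin); n_unrel <- integer(nbin)
    rec_i <- 1L
    take <- function() {
      S[, rec_i] <<- rowSums(Wstm * Mrel_s) / sqrt(N_stm)
      G[, rec_i] <<- rowSums(Wg * Mrel_l) / sqrt(N_ltm)
      P[, rec_i] <<- rowSums(Wp * Mrel_l) / sqrt(N_ltm)
      PrS[, rec_i] <<- rowSums(Wstm * Probe_s) / sqrt(N_stm)
      PrG[, rec_i] <<- rowSums(Wg * Probe_l) / sqrt(N_ltm)
      PrP[, rec_i] <<- rowSums(Wp * Probe_l) / sqrt(N_ltm)
      rec_i <<- rec_i + 1L
    }
    take()
    pd_s <- p_stm; pd_l <- p_ltm          # dense balanced: symmetric rates
    for (t in seq_len(horizon)) {
      rel <- stats::runif(trials) < lambda
      Ms <- rs(trials, N_stm); Ml <- rs(trials, N_ltm)
      if (any(rel)) {
        Ms[rel, ] <- Mrel_s[rel, ]
        Ml[rel, ] <- Mrel_l[rel, ]
      }
      r <- rowSums(Wstm * Ms) / sqrt(N_stm)
      pass <- r >= theta
      bin <- min(nbin, (t - 1L) %/% record_every + 1L)
      if (nbin > 0L) {
        n_rel[bin] <- n_rel[bin] + sum(rel)
        cons_rel[bin] <- cons_rel[bin] + sum(pass & rel)
        n_unrel[bin] <- n_unrel[bin] + sum(!rel)
        cons_unrel[bin] <- cons_unrel[bin] + sum(pass & !rel)
      }
      Wstm <- .bs_step_u(Wstm, Ms, p_stm, pd_s,
                         matrix(stats::runif(trials * N_stm), trials))
      U_l <- matrix(stats::runif(trials * N_ltm), trials)  # shared draws
      Wg <- .bs_step_u(Wg, Ml, p_ltm, pd_l, U_l, active = matrix(pass, trials, N_ltm))
      Wp <- .bs_step_u(Wp, Ml, p_ltm, pd_l, U_l)
      if (t %% record_every == 0L) take()
    }
    structure(list(times = rec_t, stm = S, ltm_gated = G, ltm_parallel = P,
                   probe_stm = PrS, probe_gated = PrG, probe_parallel = PrP,
                   p_cons_rel = ifelse(n_rel > 0, cons_rel / n_rel, NA_real_),
                   p_cons_unrel = ifelse(n_unrel > 0, cons_unrel / n_unrel, NA_real_),
                   bin_times = if (nbin > 0L) rec_t[-1] else numeric(0),
                   config = list(N_stm = N_stm, N_ltm = N_ltm, p_stm = p_stm,
                                 p_ltm = p_ltm, lambda = lambda, theta = theta,
                                 horizon = horizon, trials = trials, seed = seed)),
              class = "consolidation_trace")
  })
}

#' @export
print.consolidation_trace <- function(x, ...) {
  nt <- length(x$times)
  cat("<consolidation_trace>", nrow(x$stm), "trials,", max(x$times), "steps\n")
  cat("  final mean SNR: STM", signif(mean(x$stm[, nt]), 3),
      " LTM gated", signif(mean(x$ltm_gated[, nt]), 3),
      " LTM parallel", signif(mean(x$ltm_parallel[, nt]), 3), "\n")
  invisible(x)
}

#' @export
as.data.frame.consolidation_trace <- function(x, ...) {
  nt <- length(x$times)
  do.call(rbind, lapply(c("stm", "ltm_gated", "ltm_parallel"), function(v) {
    data.frame(t = x$times, variant = v,
               snr = colMeans(x[[v]]),
               sd = apply(x[[v]], 2, stats::sd))
  }))
}

## ---------------------------------------------------------------------------
## Ensemble gating with multiple memory timescales

#' Simulate consolidation into an ensemble of LTM subpopulations
#'
#' A tracked memory recurs at deterministic spacing `delta` within a
#' background of unreliable memories (presented at `p_unreliable` of the
#' remaining timesteps). The STM drives an ensemble gate whose bands on log
#' recall route consolidation into band-indexed binary-switch LTM
#' subpopulations. After the last reinforcement the run continues and the
#' memory's lifetime is measured as the time until the SNR in its
#' most-consolidated subpopulation falls below `target_snr`; the semi-analytic
#' estimate divides the STM lifetime by the fraction of all presentations
#' routed to that subpopulation.
#'
#' @param delta spacing between reinforcements of the tracked memory.
#' @param repetitions number of reinforcements.
#' @param N_stm,N_ltm synapses in the STM / in each LTM subpopulation.
#' @param p_stm,p_ltm binary-switch rates.
#' @param n_bands number of LTM subpopulations ([auto_ensemble_edges()]).
#' @param n_background number of background reliable memories with
#'   log-uniform timescales on `[0, log_tau_max]`.
#' @param log_tau_max log-timescale bound of the background memories.
#' @param p_unreliable background unreliable presentation probability.
#' @param target_snr lifetime criterion.
#' @param max_tail maximum post-training steps to wait for decay.
#' @param seed integer seed.
#' @return a list with the consolidation counts per band, measured
#'   `lifetime`, `lifetime_analytic`, the dominant `band`, and per-band
#'   presentation fractions.
#' @export
run_multiscale_sim <- function(delta, repetitions = 5L,
                               N_stm = 2000L, N_ltm = 1000L,
                               p_stm = 0.1, p_ltm = 0.1,
                               n_bands = 4L, n_background = 20L,
                               log_tau_max = 6, p_unreliable = 0.9,
                               target_snr = 1, max_tail = 4000L, seed = 1L) {
  gate <- gating_function("ensemble", edges = auto_ensemble_edges(N_stm, n_bands))
  with_seed(derive_seed(seed, "multiscale"), {
    rs <- function(N) sample(c(-1, 1), N, TRUE)
    Wstm <- rs(N_stm)
    Wl <- replicate(n_bands, rs(N_ltm), simplify = FALSE)
    mem_s <- rs(N_stm)
    mem_l <- replicate(n_bands, rs(N_ltm), simplify = FALSE)
    bg_tau <- exp(stats::runif(n_background, 0, log_tau_max))
    bg_s <- replicate(n_background, rs(N_stm), simplify = FALSE)
    bg_l <- lapply(seq_len(n_background), function(i)
      replicate(n_bands, rs(N_ltm), simplify = FALSE))
    cons <- integer(n_bands)
    band_count <- integer(n_bands)      # all presentations routed per band
    n_events <- 0L
    present_times <- seq(0L, by = as.integer(delta), length.out = repetitions)
    t_end <- present_times[repetitions]
    step_mod <- function(W, M, p) .bs_step(matrix(W, 1), matrix(M, 1), p, p)[1, ]
    do_event <- function(Ms, Ml_list, tracked) {
      r <- sum(Wstm * Ms) / sqrt(N_stm)
      b <- gate_decision(gate, r)
      n_events <<- n_events + 1L
      if (b >= 1L) {
        band_count[b] <<- band_count[b] + 1L
        Wl[[b]] <<- step_mod(Wl[[b]], Ml_list[[b]], p_ltm)
        if (tracked) cons[b] <<- cons[b] + 1L
      }
      Wstm <<- step_mod(Wstm, Ms, p_stm)
    }
    background_event <- function() {
      i <- which(stats::runif(n_background) < 1 / bg_tau)
      if (length(i)) {
        i <- i[1]
        do_event(bg_s[[i]], bg_l[[i]], FALSE)
        TRUE
      } else FALSE
    }
    for (t in 0:t_end) {
      if (t %in% present_times) {
        do_event(mem_s, mem_l, tracked = TRUE)
      } else if (!background_event() && stats::runif(1) < p_unreliable) {
        do_event(rs(N_stm), replicate(n_bands, rs(N_ltm), simplify = FALSE), FALSE)
      }
    }
    main_band <- if (any(cons > 0)) which.max(cons) else NA_integer_
    lifetime <- NA_real_
    if (!is.na(main_band)) {
      for (dt in seq_len(max_tail)) {
        if (!background_event() && stats::runif(1) < p_unreliable) {
          do_event(rs(N_stm), replicate(n_bands, rs(N_ltm), simplify = FALSE), FALSE)
        }
        snr_b <- sum(Wl[[main_band]] * mem_l[[main_band]]) / sqrt(N_ltm)
        if (snr_b < target_snr) { lifetime <- dt; break }
      }
    }
    frac <- band_count / max(n_events, 1L)
    stm_curve <- analytic_forgetting_curve(plasticity_params("binary_switch", p = p_stm), N_stm)
    stm_life <- stm_curve$inv(target_snr)
    lifetime_analytic <- if (!is.na(main_band) && frac[main_band] > 0) {
      stm_life / frac[main_band]
    } else NA_real_
    list(consolidations = cons, band = main_band,
         lifetime = lifetime, lifetime_analytic = lifetime_analytic,
         band_fractions = frac, edges = gate$edges,
         config = list(delta = delta, repetitions = repetitions,
                       N_stm = N_stm, N_ltm = N_ltm, seed = seed))
  })
}
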