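# Semi-analytic theory of repeatedly reinforced memories.
#
# Recall of a memory reinforced R times is approximated by summing forgetting
# curves, SNR = sum_i m(t_i), with t_i the elapsed time since reinforcement i
# and evaluation one interarrival after the most recent reinforcement. Gating
# changes the LTM's effective interarrival statistics: a reliable
# reinforcement consolidates with probability q = P(I < m^-1(theta)), and LTM
# "time" advances only on gate-passing unreliable events, i.e. at rate
# nu = 1 - Phi(theta) per real timestep.

#' Recall SNR after a sequence of reinforcements
#'
#' Sums forgetting-curve strengths over a reinforcement history. `intervals`
#' are the gaps between consecutive reinforcements, with the last entry the
#' gap between the final reinforcement and the evaluation time, so for
#' constant intervals `tau` this is `sum_i m(i * tau)`.
#'
#' @param curve a `forgetting_curve`.
#' @param intervals nonnegative interarrival gaps (length R).
#' @param warn_extrapolation warn when an elapsed time falls beyond an
#'   empirical curve's support.
#' @return the summed SNR.
#' @export
snr_after_repetitions <- function(curve, intervals, warn_extrapolation = TRUE) {
  if (any(intervals < 0)) stop("'intervals' must be nonnegative")
  t_el <- rev(cumsum(rev(intervals)))
  if (warn_extrapolation && curve$provenance == "empirical" &&
      any(t_el > max(curve$times))) {
    warning("elapsed times beyond the empirical curve support; using tail extrapolation")
  }
  sum(curve$fn(t_el))
}

#' Closed-form SNR for deterministic spacing (binary switch)
#'
#' Geometric-series evaluation of `sum_{i=1}^R m(i*tau)` for an analytic
#' binary-switch curve.
#'
#' @param curve an analytic binary-switch `forgetting_curve`.
#' @param tau reinforcement spacing.
#' @param R number of reinforcements.
#' @return the SNR.
#' @export
snr_deterministic <- function(curve, tau, R) {
  g <- -log1p(-curve$params$p)
  x <- exp(-g * tau)
  if (x == 1) return(R * curve$m0)
  curve$m0 * x * (1 - x^R) / (1 - x)
}

#' Consolidation probability
#'
#' `q = P(I < m^-1(theta))`: the probability that the next reinforcement
#' arrives while the STM trace of the memory still exceeds the gating
#' threshold.
#'
#' @param curve STM `forgetting_curve` (monotone nonincreasing).
#' @param theta gating threshold (normalized recall units).
#' @param interarrival an [interarrival_model()].
#' @return `q` in \[0, 1\].
#' @export
consolidation_probability <- function(curve, theta, interarrival) {
  if (!is.finite(theta)) {
    return(if (theta < 0) 1 else 0)
  }
  if (theta >= curve$m0) return(0)
  t_star <- curve$inv(theta)
  if (!is.finite(t_star)) return(1)
  interarrival_cdf(interarrival, t_star)
}

#' Select the gating threshold for R expected repetitions
#'
#' Returns the largest threshold for which the probability that none of R
#' reinforcements is consolidated stays below `epsilon`, i.e.
#' `(1-q)^R <= epsilon`, so `q >= 1 - epsilon^(1/R)`.
#'
#' @param curve STM `forgetting_curve`.
#' @param interarrival an [interarrival_model()].
#' @param R expected number of repetitions (defaults to 2, the minimum for
#'   consolidation to be meaningful).
#' @param epsilon allowed failure probability.
#' @return a list with `theta`, the achieved `q`, and the recall age
#'   `t_required = m^-1(theta)`.
#' @export
select_threshold <- function(curve, interarrival, R = 2L, epsilon = 0.1) {
  if (R < 1) stop("'R' must be >= 1")
  if (epsilon <= 0 || epsilon >= 1) stop("'epsilon' must lie in (0, 1)")
  q_req <- 1 - epsilon^(1 / R)
  t_req <- interarrival_quantile(interarrival, q_req)
  theta <- curve$fn(t_req)
  list(theta = theta, q = q_req, t_required = t_req)
}

#' Induced LTM interarrival distribution
#'
#' Under threshold gating, consecutive consolidations of a reliable memory
#' are separated by a geometric number `j ~ Geom(q)` of reinforcements; the
#' corresponding real-time span is a sum of `j` raw interarrivals, and LTM
#' time elapses only on gate-passing unreliable events (rate
#' `nu = 1 - Phi(theta)` per timestep). For exponential input the induced
#' distribution is again exponential with mean `tau_ltm = tau * nu / q`.
#'
#' @param curve STM `forgetting_curve` (used to compute `q`; pass `q`
#'   directly to skip).
#' @param theta gating threshold.
#' @param interarrival an [interarrival_model()].
#' @param n Monte-Carlo draws.
#' @param seed integer seed.
#' @param units `"events"` counts gate-passing unreliable events in the span
#'   (integer-valued samples); `"scaled"` multiplies the span by `nu`
#'   (continuous).
#' @param q optional precomputed consolidation probability.
#' @return a list with `q`, `nu`, `tau_ltm` (closed form `tau*nu/q`),
#'   `tau_raw_mixture` (closed form `tau/q`), `samples` (LTM interarrivals),
#'   `spans` (real-time mixture samples), and their means.
#' @export
induced_ltm_interarrival <- function(curve = NULL, theta, interarrival,
                                     n = 1e5, seed = 1L,
                                     units = c("events", "scaled"),
                                     q = NULL) {
  units <- match.arg(units)
  if (is.null(q)) {
    if (is.null(curve)) stop("provide either 'curve' or 'q'")
    q <- consolidation_probability(curve, theta, interarrival)
  }
  if (q <= 0) stop("q = 0: consolidation impossible at this threshold")
  nu <- 1 - stats::pnorm(theta)
  with_seed(derive_seed(seed, "induced"), {
    j <- stats::rgeom(n, q) + 1L
    draws <- sample_interarrival(interarrival, sum(j))
    grp <- rep.int(seq_len(n), j)
    spans <- as.vector(rowsum(draws, grp))
    samples <- if (units == "events") {
      stats::rbinom(n, pmax(round(spans), 0L), nu)
    } else {
      spans * nu
    }
    list(q = q, nu = nu, theta = theta,
         tau_ltm = interarrival$tau * nu / q,
         tau_raw_mixture = interarrival$tau / q,
         samples = samples, spans = spans,
         mean_ltm = mean(samples), mean_span = mean(spans))
  })
}

#' Learnable timescale
#'
#' The largest mean interarrival time `tau` for which recall SNR after `R`
#' reinforcements exceeds `beta` with probability `1 - epsilon`. The SNR
#' distribution is estimated by Monte Carlo over interarrival histories
#' (forgetting-curve sums); for gated systems the threshold is re-selected
#' per candidate `tau` by [select_threshold()] and the LTM sees induced
#' interarrivals in LTM event units. The search bisects on `log(tau)`.
#'
#' @param stm_curve STM `forgetting_curve` (the system curve when ungated).
#' @param R number of reinforcements.
#' @param beta target SNR.
#' @param epsilon allowed failure probability (the SNR quantile checked).
#' @param shape_k Weibull regularity of the interarrival family.
#' @param gated if `TRUE`, evaluate the recall-gated system.
#' @param ltm_curve LTM `forgetting_curve` (gated systems; defaults to
#'   `stm_curve`).
#' @param n_mc Monte-Carlo histories per feasibility check.
#' @param seed integer seed.
#' @param tol relative tolerance on `tau`.
#' @param tau_max upper search bound.
#' @return a list with `tau_star` (0 when the target is unreachable),
#'   `feasible`, and at the optimum: `theta`, `q`.
#' @export
learnable_timescale <- function(stm_curve, R = 2L, beta, epsilon = 0.1,
                                shape_k = 1, gated = FALSE, ltm_curve = NULL,
                                n_mc = 2000L, seed = 1L, tol = 0.01,
                                tau_max = 1e7) {
  if (epsilon <= 0 || epsilon >= 1) stop("'epsilon' must lie in (0, 1)")
  if (is.null(ltm_curve)) ltm_curve <- stm_curve
  sys_curve <- if (gated) ltm_curve else stm_curve
  if (beta > R * sys_curve$m0) {
    return(list(tau_star = 0, feasible = FALSE, theta = NA_real_, q = NA_real_))
  }
  eval_id <- 0L
  snr_quantile <- function(tau) {
    eval_id <<- eval_id + 1L
    ia <- interarrival_model(if (shape_k == 1) "exponential" else "weibull",
                             tau = tau, shape_k = shape_k)
    with_seed(derive_seed(seed, "lt", eval_id), {
      if (!gated) {
        I <- matrix(sample_interarrival(ia, n_mc * R), n_mc, R)
        fn <- stm_curve$fn
      } else {
        sel <- select_threshold(stm_curve, ia, R, epsilon)
        nu <- 1 - stats::pnorm(sel$theta)
        j <- stats::rgeom(n_mc * R, sel$q) + 1L
        draws <- sample_interarrival(ia, sum(j))
        spans <- as.vector(rowsum(draws, rep.int(seq_along(j), j)))
        I <- matrix(spans * nu, n_mc, R)
        fn <- ltm_curve$fn
      }
      snr <- numeric(n_mc)
      acc <- numeric(n_mc)
      for (i in R:1) {
        acc <- acc + I[, i]
        snr <- snr + fn(acc)
      }
      stats::quantile(snr, epsilon, names = FALSE, type = 1)
    })
  }
  feasible <- function(tau) snr_quantile(tau) >= beta
  lo <- 0.25
  if (!feasible(lo)) {
    return(list(tau_star = 0, feasible = FALSE, theta = NA_real_, q = NA_real_))
  }
  hi <- lo
  while (hi < tau_max && feasible(hi * 2)) hi <- hi * 2
  if (hi >= tau_max) {
    warning("learnable timescale reached the search bound tau_max")
    return(list(tau_star = tau_max, feasible = TRUE, theta = NA_real_, q = NA_real_))
  }
  lo <- hi; hi <- hi * 2
  while (log(hi / lo) > log1p(tol)) {
    mid <- sqrt(lo * hi)
    if (feasible(mid)) lo <- mid else hi <- mid
  }
  out <- list(tau_star = lo, feasible = TRUE, theta = NA_real_, q = NA_real_)
  if (gated) {
    ia <- interarrival_model(if (shape_k == 1) "exponential" else "weibull",
                             tau = lo, shape_k = shape_k)
    sel <- select_threshold(stm_curve, ia, R, epsilon)
    out$theta <- sel$theta
    out$q <- sel$q
  }
  out
}

#' Scaling exponent of learnable timescale with repetitions
#'
#' Least-squares slope of `log(tau*)` against `log(R)` over a set of
#' repetition counts; degenerate (`tau* = 0`) points are dropped with a
#' warning.
#'
#' @param R_values repetition counts (>= 4 values spanning >= 1 decade
#'   recommended).
#' @param ... passed to [learnable_timescale()] (curves, `beta`, `shape_k`,
#'   `gated`, ...).
#' @return a list with `slope`, the fitted `tau_star` values and `R_values`.
#' @export
scaling_exponent <- function(R_values, ...) {
  taus <- vapply(R_values, function(R) learnable_timescale(R = R, ...)$tau_star,
                 numeric(1))
  keep <- taus > 0
  if (any(!keep)) warning("dropping R values with tau* = 0: ",
                          paste(R_values[!keep], collapse = ", "))
  if (sum(keep) < 2) stop("not enough feasible points to estimate a slope")
  fit <- stats::lm(log(taus[keep]) ~ log(R_values[keep]))
  list(slope = unname(stats::coef(fit)[2]), tau_star = taus, R_values = R_values)
}
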