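# Memory vectors and structured event streams.
#
# A memory is a pattern of candidate potentiation/depression targets w*.
# Reliable memories recur over time according to a renewal process
# (exponential, Weibull or deterministic interarrivals); unreliable memories
# are one-off random patterns (optionally recurring within a short window).

#' Sample a memory vector
#'
#' @param N pattern length (number of synapses addressed).
#' @param mode `"dense_balanced"` (exactly N/2 entries +1 and N/2 entries -1),
#'   `"iid_binary"` (independent +/-1), or `"sparse"` (a fraction `f` of
#'   entries are potentiation targets, the rest depression targets).
#' @param f coding level for sparse memories, in (0,1).
#' @param seed optional seed.
#' @param reliable logical tag carried on the object.
#' @param id optional memory identifier.
#' @return an object of class `memory_vector`.
#' @export
#' @examples
#' m <- sample_memory(10, "dense_balanced", seed = 1)
#' sum(memory_entries(m))  # exactly zero by construction
sample_memory <- function(N, mode = c("dense_balanced", "iid_binary", "sparse"),
                          f = 0.5, seed = NULL, reliable = FALSE, id = NA_integer_) {
  mode <- match.arg(mode)
  N <- as.integer(N)
  if (mode == "dense_balanced" && N %% 2L != 0L) {
    stop("'dense_balanced' memories require even N")
  }
  if (f <= 0 || f >= 1) stop("'f' must lie in (0, 1)")
  entries <- with_seed(seed, {
    switch(mode,
      dense_balanced = sample(rep(c(-1, 1), each = N %/% 2L)),
      iid_binary = sample(c(-1, 1), N, replace = TRUE),
      sparse = {
        k <- max(1L, round(f * N))
        e <- rep(-1, N)
        e[sample.int(N, k)] <- 1
        e
      })
  })
  structure(list(entries = entries, mode = mode, coding_level = f,
                 reliable = isTRUE(reliable), memory_id = id),
            class = "memory_vector")
}

# Matrix of `rows` independent memories (rows) used by vectorised engines.
.sample_memory_matrix <- function(rows, N, mode, f = 0.5) {
  if (mode == "dense_balanced") {
    base <- rep(c(-1, 1), each = N %/% 2L)
    t(vapply(seq_len(rows), function(i) sample(base), numeric(N)))
  } else if (mode == "iid_binary") {
    matrix(sample(c(-1, 1), rows * N, TRUE), rows)
  } else {
    k <- max(1L, round(f * N))
    M <- matrix(-1, rows, N)
    for (i in seq_len(rows)) M[i, sample.int(N, k)] <- 1
    M
  }
}

#' @export
print.memory_vector <- function(x, ...) {
  cat("<memory_vector> N =", length(x$entries), " mode =", x$mode,
      if (x$reliable) " (reliable)" else " (unreliable)", "\n")
  invisible(x)
}

#' Raw entries of a memory vector
#' @param mem a `memory_vector` or numeric vector.
#' @return numeric vector of targets.
#' @export
memory_entries <- function(mem) {
  if (inherits(mem, "memory_vector")) mem$entries else as.numeric(mem)
}

# Mean-centered entries used at recall time: sparse memories have mean
# 2f - 1 subtracted so that random-memory recall has zero mean; plasticity
# always sees the raw +/-1 targets.
memory_entries_centered <- function(mem) {
  e <- memory_entries(mem)
  if (inherits(mem, "memory_vector") && mem$mode == "sparse") {
    e - (2 * mem$coding_level - 1)
  } else {
    e
  }
}

memory_entry_variance <- function(mem) {
  if (inherits(mem, "memory_vector") && mem$mode == "sparse") {
    f <- mem$coding_level
    4 * f * (1 - f)
  } else {
    1
  }
}

memory_mode <- function(mem) {
  if (inherits(mem, "memory_vector")) mem$mode else "iid_binary"
}

memory_coding_level <- function(mem) {
  if (inherits(mem, "memory_vector")) mem$coding_level else 0.5
}

## ---------------------------------------------------------------------------
## Interarrival models

#' Renewal model for reliable-memory recurrence
#'
#' Interarrival intervals follow a Weibull distribution parameterized by its
#' mean `tau` and regularity `k`: `P(I <= t) = 1 - exp(-(t*Gamma(1+1/k)/tau)^k)`.
#' `k = 1` is the exponential (Poisson recurrence with rate `lambda = 1/tau`),
#' `k < 1` is bursty, and the deterministic family returns constant intervals.
#'
#' @param family `"exponential"`, `"weibull"`, or `"deterministic"`.
#' @param tau mean interarrival time, > 0.
#' @param shape_k Weibull regularity parameter, > 0.
#' @return an object of class `interarrival_model`.
#' @export
interarrival_model <- function(family = c("exponential", "weibull", "deterministic"),
                               tau, shape_k = 1) {
  family <- match.arg(family)
  if (tau <= 0) stop("'tau' must be positive")
  if (shape_k <= 0) stop("'shape_k' must be positive")
  if (family == "exponential") shape_k <- 1
  structure(list(family = family, tau = tau, shape_k = shape_k, lam = 1 / tau),
            class = "interarrival_model")
}

weibull_scale <- function(model) model$tau / gamma(1 + 1 / model$shape_k)

#' Interarrival cumulative distribution function
#' @param model an [interarrival_model()].
#' @param t nonnegative times.
#' @return `P(I <= t)`.
#' @export
interarrival_cdf <- function(model, t) {
  if (any(t < 0)) stop("'t' must be nonnegative")
  if (model$family == "deterministic") return(as.numeric(t >= model$tau))
  stats::pweibull(t, shape = model$shape_k, scale = weibull_scale(model))
}

#' Interarrival quantile function
#' @param model an [interarrival_model()].
#' @param p probabilities in \[0, 1\].
#' @return quantiles of the interarrival distribution.
#' @export
interarrival_quantile <- function(model, p) {
  if (model$family == "deterministic") return(rep(model$tau, length(p)))
  stats::qweibull(p, shape = model$shape_k, scale = weibull_scale(model))
}

#' Sample interarrival intervals
#' @param model an [interarrival_model()].
#' @param n_samples number of intervals.
#' @param seed optional seed.
#' @return numeric vector of intervals.
#' @export
sample_interarrival <- function(model, n_samples, seed = NULL) {
  if (n_samples < 1) stop("'n_samples' must be >= 1")
  if (model$family == "deterministic") return(rep(model$tau, n_samples))
  with_seed(seed,
    stats::rweibull(n_samples, shape = model$shape_k, scale = weibull_scale(model)))
}

## ---------------------------------------------------------------------------
## Environment configuration and stream generation

#' Environment configuration for stream generation
#'
#' @param N pattern length per module.
#' @param n_reliable number of distinct reliable memories.
#' @param lambda per-timestep presentation probability of each reliable memory
#'   (Poisson mode).
#' @param interarrival optional [interarrival_model()] (renewal mode), or a
#'   list of one model per reliable memory.
#' @param mode `"poisson"`, `"renewal"`, or `"multiscale"`.
#' @param p_unreliable probability that a timestep without a reliable
#'   presentation carries an unreliable memory (1 = one event per step).
#' @param log_tau_max multiscale mode: reliable timescales tau_i are
#'   log-uniform on \[0, log_tau_max\] (the paper-style bound A).
#' @param unreliable_window,unreliable_ratio unreliable memories recur within
#'   `unreliable_window` steps of first presentation with probability
#'   `unreliable_ratio^lag` (0 window disables recurrence).
#' @param memory_mode,f memory sampling mode and coding level.
#' @param horizon number of timesteps.
#' @param seed integer seed.
#' @return an object of class `environment_config`.
#' @export
environment_config <- function(N, n_reliable = 1L, lambda = 0.25,
                               interarrival = NULL,
                               mode = c("poisson", "renewal", "multiscale"),
                               p_unreliable = 1,
                               log_tau_max = 8,
                               unreliable_window = 0L, unreliable_ratio = 0.5,
                               memory_mode = "dense_balanced", f = 0.5,
                               horizon = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  if (any(lambda < 0 | lambda > 1)) stop("'lambda' must lie in [0, 1]")
  if (p_unreliable < 0 || p_unreliable > 1) stop("'p_unreliable' must lie in [0, 1]")
  if (mode == "multiscale" && missing(p_unreliable)) p_unreliable <- 0.9
  structure(list(N = as.integer(N), n_reliable = as.integer(n_reliable),
                 lambda = rep_len(lambda, n_reliable),
                 interarrival = interarrival, mode = mode,
                 p_unreliable = p_unreliable, log_tau_max = log_tau_max,
                 unreliable_window = as.integer(unreliable_window),
                 unreliable_ratio = unreliable_ratio,
                 memory_mode = memory_mode, f = f,
                 horizon = as.integer(horizon), seed = as.integer(seed)),
            class = "environment_config")
}

#' Generate an event stream
#'
#' Produces a schedule of memory presentations. Reliable memories have
#' positive ids `1..n_reliable`; unreliable memories receive fresh negative
#' ids. Memory vectors are not stored in the schedule; they are derived
#' deterministically from `(config, id)` by [stream_memory()], so streams stay
#' light even for long horizons. Simultaneous reliable arrivals are resolved
#' reliable-first in id order.
#'
#' @param config an [environment_config()].
#' @return a `data.frame` with columns `time`, `memory_id`, `reliable`, of
#'   class `memory_stream` (attributes carry the config).
#' @export
generate_stream <- function(config) {
  stopifnot(inherits(config, "environment_config"))
  with_seed(derive_seed(config$seed, "stream"), {
    T_ <- config$horizon
    K <- config$n_reliable
    rel_at <- vector("list", K)
    if (config$mode == "poisson") {
      for (i in seq_len(K)) rel_at[[i]] <- which(stats::runif(T_) < config$lambda[i])
    } else if (config$mode == "renewal") {
      ia <- config$interarrival
      if (is.null(ia)) stop("renewal mode requires an 'interarrival' model")
      for (i in seq_len(K)) {
        m <- if (inherits(ia, "interarrival_model")) ia else ia[[i]]
        times <- cumsum(ceiling(sample_interarrival(m, ceiling(2 * T_ / m$tau) + 10L)))
        rel_at[[i]] <- times[times <= T_]
      }
    } else {
      taus <- exp(stats::runif(K, 0, config$log_tau_max))
      for (i in seq_len(K)) rel_at[[i]] <- which(stats::runif(T_) < 1 / taus[i])
      attr(rel_at, "taus") <- taus
    }
    slot <- integer(T_)            # 0 empty, >0 reliable id, <0 unreliable id
    for (i in seq_len(K)) {
      tt <- rel_at[[i]]
      tt <- tt[slot[tt] == 0L]     # reliable-first, id-order priority
      slot[tt] <- i
    }
    next_unrel <- -1L
    w <- config$unreliable_window
    pending <- NULL                # scheduled unreliable recurrences
    for (t in seq_len(T_)) {
      if (slot[t] != 0L) next
      if (!is.null(pending) && length(pending$t) && pending$t[1] <= t) {
        slot[t] <- pending$id[1]
        pending$t <- pending$t[-1]; pending$id <- pending$id[-1]
        next
      }
      if (stats::runif(1) < config$p_unreliable) {
        slot[t] <- next_unrel
        if (w > 0L) {
          lag <- seq_len(w)
          rec <- lag[stats::runif(w) < config$unreliable_ratio^lag]
          if (length(rec)) {
            pending <- list(t = c(pending$t, t + rec),
                            id = c(pending$id, rep(next_unrel, length(rec))))
            o <- order(pending$t)
            keep <- !duplicated(pending$t[o])
            pending <- list(t = pending$t[o][keep], id = pending$id[o][keep])
          }
        }
        next_unrel <- next_unrel - 1L
      }
    }
    idx <- which(slot != 0L)
    out <- data.frame(time = idx, memory_id = slot[idx], reliable = slot[idx] > 0L)
    attr(out, "config") <- config
    if (config$mode == "multiscale") attr(out, "taus") <- attr(rel_at, "taus")
    class(out) <- c("memory_stream", "data.frame")
    out
  })
}

#' Realize the memory vector for a stream id
#'
#' Deterministic in `(config$seed, id)`, so repeated presentations of the same
#' id yield the same pattern and regeneration is bit-reproducible.
#'
#' @param config the [environment_config()] of the stream.
#' @param id a memory id from the stream schedule.
#' @return a [memory_vector()].
#' @export
stream_memory <- function(config, id) {
  sample_memory(config$N, mode = config$memory_mode, f = config$f,
                seed = derive_seed(config$seed, "memory", as.integer(id)),
                reliable = id > 0, id = as.integer(id))
}

#' Marginal interarrival density of reliable memories under log-uniform timescales
#'
#' With reliable timescales log-uniform on \[0, A\], the marginal interarrival
#' density is `(exp(-t*exp(-A)) - exp(-t)) / (A*t)` (exact form, which
#' integrates to 1), approximately `(1 - exp(-t)) / (A*t)` and proportional to
#' `1/t` for large `t` below the `exp(A)` cutoff.
#'
#' @param A log-timescale bound (large).
#' @param t positive times.
#' @param form `"exact"` or `"approx"`.
#' @return density values.
#' @export
reliable_interarrival_marginal <- function(A, t, form = c("exact", "approx")) {
  form <- match.arg(form)
  if (any(t <= 0)) stop("'t' must be positive")
  if (form == "exact") {
    (exp(-t * exp(-A)) - exp(-t)) / (A * t)
  } else {
    (1 - exp(-t)) / (A * t)
  }
}
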