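# Circuit-level task demonstrations.
#
# Three online-learning settings in which the generic recall factor takes a
# task-specific meaning: prediction accuracy (supervised Hebbian
# classification), reward times action confidence (three-factor reinforcement
# learning), and familiarity (autoassociative storage with a familiarity
# readout). In each, the STM module learns from every event and the LTM
# module learns only when the STM-derived recall factor passes the gate.

# Binary-switch update of a +/-1 weight vector toward sign targets.
.bs_vec <- function(w, target, p) {
  u <- stats::runif(length(w))
  flip <- ((target > 0) & (w < 0) & (u < p)) | ((target < 0) & (w > 0) & (u < p))
  w[flip] <- -w[flip]
  w
}

#' Supervised Hebbian classification with gated consolidation
#'
#' A single binary readout `yhat = W x` over inputs with entries `+/- 1/N`
#' (so `yhat` is confined to `[-1, 1]`). Reliable stimuli carry consistent
#' labels and each recurs with probability `lambda_per` per timestep;
#' otherwise a fresh unreliable stimulus with a random label is presented.
#' Both modules learn the Hebbian memory `W* = y x^T` by the binary switch
#' rule; the LTM learns only when the STM prediction accuracy `y * yhat_stm`
#' reaches `theta`.
#'
#' @param n_stimuli number of reliable stimuli.
#' @param N input dimension per module.
#' @param lambda_per per-stimulus presentation probability per timestep.
#' @param p binary-switch rate (both modules).
#' @param theta consolidation threshold on `y * yhat_stm`.
#' @param horizon timesteps.
#' @param eval_every evaluation cadence (steps).
#' @param seed integer seed.
#' @return a list with `times`, `acc_stm`, `acc_ltm` (sign-agreement accuracy
#'   on the reliable set), `cons_rate` (fraction of events consolidated per
#'   evaluation bin) and the configuration.
#' @export
run_supervised <- function(n_stimuli = 20L, N = 1000L, lambda_per = 0.01,
                           p = 0.1, theta = 0.125, horizon = 12000L,
                           eval_every = 40L, seed = 1L) {
  with_seed(derive_seed(seed, "supervised"), {
    X <- matrix(sample(c(-1, 1), n_stimuli * N, TRUE) / N, n_stimuli)
    y <- sample(c(-1, 1), n_stimuli, TRUE)
    Ws <- sample(c(-1, 1), N, TRUE)
    Wl <- sample(c(-1, 1), N, TRUE)
    lam_tot <- n_stimuli * lambda_per
    if (lam_tot > 1) stop("n_stimuli * lambda_per must be <= 1")
    times <- seq(eval_every, horizon, by = eval_every)
    acc_s <- acc_l <- cons <- numeric(length(times))
    n_cons <- 0L; k <- 1L
    accuracy <- function(W) {
      yh <- as.vector(X %*% W)
      mean((sign(yh) == y) + 0.5 * (yh == 0))
    }
    for (t in seq_len(horizon)) {
      if (stats::runif(1) < lam_tot) {
        s <- sample.int(n_stimuli, 1L)
        x <- X[s, ]; lab <- y[s]
      } else {
        x <- sample(c(-1, 1), N, TRUE) / N
        lab <- sample(c(-1, 1), 1L)
      }
      r <- lab * sum(Ws * x)
      target <- lab * sign(x)
      Ws <- .bs_vec(Ws, target, p)
      if (r >= theta) {
        Wl <- .bs_vec(Wl, target, p)
        n_cons <- n_cons + 1L
      }
      if (t %% eval_every == 0L) {
        acc_s[k] <- accuracy(Ws)
        acc_l[k] <- accuracy(Wl)
        cons[k] <- n_cons / eval_every
        n_cons <- 0L; k <- k + 1L
      }
    }
    list(times = times, acc_stm = acc_s, acc_ltm = acc_l, cons_rate = cons,
         config = list(n_stimuli = n_stimuli, N = N, lambda_per = lambda_per,
                       p = p, theta = theta, horizon = horizon, seed = seed))
  })
}

#' Three-factor reinforcement learning with gated consolidation
#'
#' Action logits `pi = W x` with softmax temperature `beta_softmax`; actions
#' are selected from the STM policy. A rewarded action triggers the
#' three-factor memory `W* = reward * a x^T` (only the chosen action's row).
#' Consolidation requires `reward * pi_a >= theta`: reward coincident with
#' confidence in the chosen action. Unreliable stimuli are fresh patterns
#' with freshly sampled correct actions.
#'
#' @param n_stimuli number of reliable stimuli.
#' @param n_actions number of actions.
#' @param N input dimension.
#' @param lambda_per per-stimulus presentation probability.
#' @param p binary-switch rate.
#' @param theta consolidation threshold on `reward * pi_a`.
#' @param beta_softmax action-selection inverse temperature.
#' @param horizon timesteps.
#' @param eval_every evaluation cadence.
#' @param seed integer seed.
#' @return a list with `times`, `reward_stm`, `reward_ltm` (expected reward
#'   per step on the reliable set under each module's softmax policy),
#'   `cons_rate`, and the configuration.
#' @export
run_rl <- function(n_stimuli = 5L, n_actions = 3L, N = 1000L,
                   lambda_per = 0.01, p = 0.1, theta = 0.125,
                   beta_softmax = 10, horizon = 4000L, eval_every = 20L,
                   seed = 1L) {
  with_seed(derive_seed(seed, "rl"), {
    X <- matrix(sample(c(-1, 1), n_stimuli * N, TRUE) / N, n_stimuli)
    correct <- sample.int(n_actions, n_stimuli, replace = TRUE)
    Ws <- matrix(sample(c(-1, 1), n_actions * N, TRUE), n_actions)
    Wl <- matrix(sample(c(-1, 1), n_actions * N, TRUE), n_actions)
    lam_tot <- n_stimuli * lambda_per
    times <- seq(eval_every, horizon, by = eval_every)
    rew_s <- rew_l <- cons <- numeric(length(times))
    n_cons <- 0L; k <- 1L
    softmax <- function(v) { e <- exp(beta_softmax * (v - max(v))); e / sum(e) }
    expected_reward <- function(W) {
      mean(vapply(seq_len(n_stimuli), function(s) {
        softmax(as.vector(W %*% X[s, ]))[correct[s]]
      }, numeric(1)))
    }
    for (t in seq_len(horizon)) {
      if (stats::runif(1) < lam_tot) {
        s <- sample.int(n_stimuli, 1L)
        x <- X[s, ]; a_star <- correct[s]
      } else {
        x <- sample(c(-1, 1), N, TRUE) / N
        a_star <- sample.int(n_actions, 1L)
      }
      pi_s <- as.vector(Ws %*% x)
      a <- sample.int(n_actions, 1L, prob = softmax(pi_s))
      reward <- as.numeric(a == a_star)
      if (reward > 0) {
        target <- sign(x)
        Ws[a, ] <- .bs_vec(Ws[a, ], target, p)
        if (reward * pi_s[a] >= theta) {
          Wl[a, ] <- .bs_vec(Wl[a, ], target, p)
          n_cons <- n_cons + 1L
        }
      }
      if (t %% eval_every == 0L) {
        rew_s[k] <- expected_reward(Ws)
        rew_l[k] <- expected_reward(Wl)
        cons[k] <- n_cons / eval_every
        n_cons <- 0L; k <- k + 1L
      }
    }
    list(times = times, reward_stm = rew_s, reward_ltm = rew_l,
         cons_rate = cons,
         config = list(n_stimuli = n_stimuli, n_actions = n_actions, N = N,
                       lambda_per = lambda_per, p = p, theta = theta,
                       beta_softmax = beta_softmax, horizon = horizon,
                       seed = seed))
  })
}

#' Autoassociative storage with a familiarity-gated LTM
#'
#' Two recurrent networks (STM and LTM) with binary weights store patterns by
#' Hebbian co-activity: entries of `W` with both pre- and post-synaptic input
#' active are potentiation targets, all others depression targets (binary
#' switch, `p = 1` as in the reference protocol). A familiarity readout `u`
#' trained on the STM side (memory `u* = x`) gates LTM plasticity when
#' `u . x >= theta_familiarity`. An ungated LTM control learns from every
#' event. Retrieval presents a noise-corrupted copy of the reliable pattern
#' (Gaussian noise of variance `1/N`, binarized to the top 50% active) and
#' runs `h <- W phi(h) + x` for `T_dyn` steps, reporting the correlation of
#' the final activity with the uncorrupted pattern.
#'
#' @param N neurons per module.
#' @param lambda reliable presentation probability per trial.
#' @param p binary-switch rate for the recurrent and familiarity weights.
#' @param theta_familiarity familiarity gate threshold (on `u . x`, in
#'   `[-1, 1]`).
#' @param T_dyn recurrent settling steps at retrieval.
#' @param horizon number of stimulus presentations.
#' @param eval_every evaluation cadence.
#' @param n_probes noisy retrieval probes per evaluation.
#' @param seed integer seed.
#' @return a list with `times`, `corr_stm`, `corr_ltm`, `corr_control`
#'   (retrieval correlations), `cons_rate`, and the configuration.
#' @export
run_autoassociative <- function(N = 1000L, lambda = 0.25, p = 1,
                                theta_familiarity = 0.25, T_dyn = 5L,
                                horizon = 300L, eval_every = 10L,
                                n_probes = 3L, seed = 1L) {
  with_seed(derive_seed(seed, "autoassoc"), {
    x_rel <- sample(c(-1, 1), N, TRUE) / N
    a_rel <- x_rel > 0
    rand_x <- function() sample(c(-1, 1), N, TRUE) / N
    Wsgn <- function() matrix(sample(c(-1, 1), N * N, TRUE), N)
    Ws <- Wsgn(); Wl <- Wsgn(); Wc <- Wsgn()
    u <- sample(c(-1, 1), N, TRUE)
    half <- N %/% 2L
    topk <- function(h) {
      act <- logical(N)
      act[order(h, decreasing = TRUE)[seq_len(half)]] <- TRUE
      act
    }
    hebb_target <- function(act) 2 * tcrossprod(as.numeric(act)) - 1
    update_W <- function(W, target) {
      if (p >= 1) return(target)
      M <- matrix(stats::runif(N * N) < p, N)
      W[M] <- target[M]
      W
    }
    retrieve <- function(W) {
      mean(vapply(seq_len(n_probes), function(i) {
        xc <- x_rel + stats::rnorm(N, 0, sqrt(1 / N))
        act <- topk(xc)
        x_in <- (2 * as.numeric(act) - 1) / N
        h <- x_in
        for (s in seq_len(T_dyn)) {
          act <- topk(h)
          h <- as.vector(W %*% as.numeric(act)) + x_in
        }
        stats::cor(as.numeric(topk(h)), as.numeric(a_rel))
      }, numeric(1)))
    }
    times <- seq(eval_every, horizon, by = eval_every)
    cs <- cl <- cc <- cons <- numeric(length(times))
    n_cons <- 0L; k <- 1L
    for (t in seq_len(horizon)) {
      x <- if (stats::runif(1) < lambda) x_rel else rand_x()
      act <- x > 0
      fam <- sum(u * x)
      target <- hebb_target(act)
      Ws <- update_W(Ws, target)
      Wc <- update_W(Wc, target)
      if (fam >= theta_familiarity) {
        Wl <- update_W(Wl, target)
        n_cons <- n_cons + 1L
      }
      u <- .bs_vec(u, sign(x), p)
      if (t %% eval_every == 0L) {
        cs[k] <- retrieve(Ws); cl[k] <- retrieve(Wl); cc[k] <- retrieve(Wc)
        cons[k] <- n_cons / eval_every
        n_cons <- 0L; k <- k + 1L
      }
    }
    list(times = times, corr_stm = cs, corr_ltm = cl, corr_control = cc,
         cons_rate = cons,
         config = list(N = N, lambda = lambda, p = p,
                       theta_familiarity = theta_familiarity, T_dyn = T_dyn,
                       horizon = horizon, seed = seed))
  })
}
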