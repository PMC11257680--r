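# memgate

Simulation and theory toolkit for **recall-gated systems consolidation**:
a model of how a short-term memory system (STM) can act as a filter that
decides which synaptic changes are worth storing in a long-term system
(LTM).

## The problem

Learning systems face a tradeoff between acquiring new memories and
retaining old ones: plasticity writes, but it also overwrites. Across
species — hippocampus→neocortex, songbird AFP→song motor pathway, the fly
mushroom body's short- and long-term lobes — long-term storage is fed by a
short-term pathway, and consolidation is *selective*. This package
implements and analyzes a computational account of that selectivity: an
event is consolidated into the LTM only when the STM can already recall it,

```
r_STM = w_STM · w*        (recall factor of the incoming memory w*)
LTM learns  ⇔  g(r_STM) = 1
```

with `g` a threshold (`r ≥ θ`), a band, or an ensemble of bands feeding
separate LTM subpopulations. Reliable patterns of synaptic updates recur
while their STM trace survives; spurious one-off patterns almost never do.
Gating therefore enriches the LTM's input stream in reliable memories and
multiplies the signal-to-noise ratio (SNR) of long-term recall.

The quantitative framework rests on three objects:

* the **forgetting curve** `m(t)` of a synapse model — mean recall SNR of a
  memory `t` steps after presentation under ongoing random interference
  (binary switch: `m(t) = √N p (1−p)^t`; cascade and multivariable chain
  models decay slower than exponentially);
* the **interarrival distribution** of reliable-memory recurrence, a
  Weibull family with mean τ and regularity k (`k = 1` Poisson, `k < 1`
  bursty);
* the **consolidation probability** `q = P(I < m⁻¹(θ))`, from which follow
  the induced LTM interarrival law (exponential with mean `τ·(1−Φ(θ))/q`
  for Poisson input), threshold selection for `R` expected repetitions
  (`q ≥ 1 − ε^{1/R}`), and the **learnable timescale** — the largest τ at
  which SNR after `R` reinforcements exceeds a target β with probability
  `1 − ε`. Gated systems scale as `τ* ∝ R^{1/k}`; single-population binary
  synapses are nearly flat in `R`.

Beyond the ideal-observer theory, the package includes three circuit-level
demonstrations (supervised Hebbian classification gated on prediction
accuracy, three-factor reinforcement learning gated on reward × action
confidence, autoassociative storage gated on a familiarity readout) and
experiment protocols for spacing effects, band gating, and optimal sparse
coding levels in STM versus LTM.

## Worked example

```r
library(memgate)

# One reliable memory recurring with probability 0.25 per step among fresh
# unreliable memories; 1000 synapses per module; binary-switch rates
# 0.25 (STM) and 0.05 (LTM); threshold gate at 0.125 SD of the null.
tr <- run_consolidation_sim(trials = 100, seed = 3)
tr
#> <consolidation_trace> 100 trials, 500 steps
#>   final mean SNR: STM 7.24  LTM gated 12.7  LTM parallel 7.74
```

The gated LTM recalls the reliable memory at SNR ≈ 12.7 after 500 steps;
the parallel control — the identical slow module updated on *every* event,
sharing the same event stream and plasticity draws — reaches only ≈ 7.7.
Gating wins in 100 of 100 paired runs at these settings.

Theory-side, the same quantities come from closed forms plus Monte Carlo:

```r
stm <- analytic_forgetting_curve(plasticity_params("binary_switch", p = 0.005), N = 1e4)
ia  <- interarrival_model("exponential", tau = 500)
q   <- consolidation_probability(stm, theta = 0.0245, ia)   # ≈ 0.70
ind <- induced_ltm_interarrival(stm, 0.0245, ia, n = 1e5)
ind$tau_ltm    # ≈ 350 = tau * (1 - pnorm(theta)) / q
ind$mean_ltm   # Monte-Carlo mean ≈ 349
```

A YAML-driven entry point is installed as `exec/memgate`
(`memgate --config cfg.yaml --seed 1 --out results/`), wrapping
`run_from_config()`.

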