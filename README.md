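# fretcssr

Inference of hidden Markov models — causal-state machines — from noisy
time series that cluster around discrete levels, the situation typical of
single-molecule FRET (smFRET) trajectories, tethered-particle motion and
similar single-molecule recordings.

## The problem and the method

An smFRET trace reports a signal E(t) that ideally jumps between a few
discrete levels as the molecule switches conformation, but in practice is
blurred by Gaussian measurement noise, so neighbouring levels overlap and
many time bins cannot be attributed to a level with confidence.
Conventional HMM fitting fixes the model architecture in advance (one
state per level) and therefore cannot discover *degenerate* states —
distinct kinetic states that emit from the same level and differ only in
their transition behaviour.

`fretcssr` infers the architecture from the data:

1. **Discretisation with an explicit null symbol.** A Gaussian mixture
   with K components is fitted to the signal histogram by multi-start EM
   and K is selected by AIC (BIC optional).  Each component gets a
   *certain* region bounded by its q and 1−q normal quantiles (default
   q = 0.001, the permille quantiles).  Points in overlap regions or the
   extreme tails get the null symbol `U`.  The per-component certain mass
   is then equalised by shrinking the richer components' regions toward
   their means, so every level is retained at the same rate and relative
   symbol frequencies stay unbiased.
2. **Null-aware causal-state splitting (adapted CSSR).** Next-symbol
   statistics are counted only over windows of consecutive certain
   symbols; any window touching a null is discarded whole.  Histories are
   grouped into causal states: a history joins its parent's state unless a
   chi-squared test (significance level α, default 0.05) rejects it, in
   which case it joins the most compatible state or founds a new one.
   States are then split until the machine is unifilar (the emitted symbol
   determines the successor state), transient states are removed, and each
   symbol is bound to its fitted Gaussian so the machine is a generative
   model of the raw trace.
3. **Kinetics.** Transition rates are per-bin probabilities divided by the
   sampling interval Δt; multi-trace summaries are geometric means with
   log-space standard deviations; dwell-time distributions from the
   Viterbi path are fitted by exponential MLE; a split-half test checks
   the stationarity the method assumes.

Two inferred models are compared on one observation sequence O of length
T by the Rabiner model distance

    D = [log P(O | λ_gen) − log P(O | λ_inf)] / T   (nats per sample),

zero for statistically identical models, computed by the forward algorithm
with Gaussian per-symbol densities.

## Worked example

Simulate the canonical two-state benchmark (levels 0.3/0.7, noise sd 0.1,
stay probability 0.9, 1500 bins of 41 ms) and recover it:

```r
library(fretcssr)

gen <- two_state_machine()                       # the generating model
sim <- simulate_trace(gen, 1500, seed = 42, dt = 0.041)
fit <- infer_machine(sim$trace,
                     pipeline_config(max_length = 2, dt = 0.041, seed = 42))
print(fit)
#> Causal-state reconstruction (K = 2 levels, L_max = 2, alpha = 0.05)
#>   1136/1500 bins certain (75.7%)
#> Causal-state machine: 2 state(s), alphabet size 2, Gaussian emissions
#>   S2 --0 (p=0.8907)--> S2
#>   S2 --1 (p=0.1093)--> S3
#>   S3 --0 (p=0.1089)--> S2
#>   S3 --1 (p=0.8911)--> S3
#>   symbol 0 ~ N(0.3137, 0.1024^2)
#>   symbol 1 ~ N(0.7041, 0.1029^2)
```

The two states and all four transition probabilities are recovered (truth:
0.9/0.1 per row; levels 0.3/0.7, sd 0.1).  Physical rates and the model
distance:

```r
transition_rates(fit$machine, dt = 0.041)
#>   from to symbol probability     rate    dt
#> 1   S2 S3      1   0.1092637 2.664967 0.041
#> 2   S3 S2      0   0.1088889 2.655827 0.041

model_distance(gen, fit$machine, sim$trace)
#> Model distance: -0.00497109 nats/sample over 1500 samples
```

A per-sample log-likelihood difference of ~0.005 nats means the inferred
machine describes this trace essentially as well as the true generator.
`degenerate_machine()` provides the four-state system in which two states
share the 0.1 level; the same pipeline recovers four states from three
observable levels — more states than levels, which architecture-fixing
methods cannot do.

There is also a command line (`inst/cli/fret-cssr`) with subcommands
`simulate`, `fit`, `distance`, `rates` and `check`; see `?cli_main`.

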