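---
title: "Masked discrete flows for sequence-structure co-design: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masked discrete flows for sequence-structure co-design: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The generative model

maskflow models a protein as a pair of equal-length discrete token tracks
`x = (s, r)`: a sequence track over an amino-acid-like alphabet and a
structure track over a separate alphabet of local-backbone codes, each
extended by one absorbing mask symbol (`Ms`, `Mr`). Generation is a
continuous-time Markov chain over token states running from `t = 0` (all
masks) to `t = 1` (a fully observed protein).

The probability path is defined per position through a conditional
linear-interpolation flow: given the data token `x1`,

    p(xt | x1) = t * onehot(x1) + (1 - t) * onehot(M),

independently across positions and across the two tracks. Marginalising over
the data distribution gives the path `pt`; at `t = 0` it is pure mask noise,
at `t = 1` the data distribution itself. `interpolate_conditional()` and
`corrupt()` implement this path and sampling from it.

A time-conditioned denoiser `f(xt, t)` predicts, for every residue,
categorical distributions over the *non-mask* tokens of both tracks (mask
logits are removed before normalisation, so mask mass is exactly zero).
Sampling runs an Euler discretisation of the posterior transition kernel: at
a step of width `dt` from time `t`, a masked position unmasks with
coefficient

    c = min(1, dt * (1 + eta * t) / (1 - t)),

spreading `c` over the denoiser's row and keeping `1 - c` on the mask, while
an observed position re-masks with probability `eta * dt` (zero at the final
step, so the output is always mask-free). `eta = 0` recovers the pure
absorbing flow, in which an unmasked token never changes again; `eta > 0` is
"balanced noise" that lets the sampler revisit early decisions.

Conditioning never enters through the model: folding, inverse folding and
motif scaffolding are expressed purely by which tokens start observed
(`make_condition_mask()`), and those positions are frozen — never resampled
and exempt from `eta`-remasking, since the task definition fixes them.

## Numerical and design choices

**Time grid.** A uniform grid `t_k = k/steps`, `dt = 1/steps`. Nothing in
the kernel requires uniformity, but the steps-ablation reads most cleanly on
the simplest grid.

**The `t -> 1` singularity.** `dt/(1 - t)` exceeds 1 on coarse grids or on
per-track grids; the unmask coefficient is clamped at 1. Clamping preserves
a valid distribution and forces complete unmasking by the end of the
schedule. The alternative — shrinking the final `dt` — changes the grid and
buys nothing at the step counts used here.

**Track scheduling.** Four strategies decide which tracks a step updates:
`synchronous` (both every step), `asynchronous` (strict alternation,
sequence on even steps), `sequence_first` / `structure_first` (50/50 split
of the budget). The denoiser is conditioned on the *global* time, while each
track's transition kernel runs on its own internal clock over its active
steps (`t_j = j/m`, `dt = 1/m` for `m` active steps). Frozen bookkeeping per
track keeps `dt/(1 - t)` consistent within a track and guarantees every
track's grid reaches 1, so no strategy can strand masks. The alternation
convention (per-step, starting with sequence) and the 50/50 split are
declared conventions; nothing downstream depends on their phase.

**Temperature.** Denoiser rows are raised to `1/temperature` and
renormalised before the kernel is built, default 1. Recovery metrics
(inverse-folding NSR) are decoded at `temperature = 0.1`: recovery compares
a *decision* against the native sequence, and ancestral sampling at
temperature 1 from an exact posterior attains only the collision probability
`sum(p^2) < max(p)` per position, which no sampler can bring near the Bayes
ceiling `E[max p]`. Low-temperature (MAP-style) decoding is the field's
standard for recovery benchmarks.

**RNG discipline.** One seeded generator; within a step the sequence track
consumes its uniforms before the structure track, positions in index order,
one uniform per position. Trajectories are bit-reproducible given the seed,
and the batched sampler with one trajectory consumes the identical stream as
the single-trajectory sampler.

## The denoiser

A small bidirectional pre-norm transformer: summed token embeddings of both
tracks plus learned absolute positional embeddings; 4 blocks of multi-head
attention (4 heads) and a feed-forward layer (GELU, hidden width equal to
the model width); layer-wise time conditioning adds a learned linear
projection of Fourier time features — `dim/2` log-spaced frequencies in
`[1, 1000]`, sines then cosines — to every block's input. Two linear heads
produce the per-residue distributions over real tokens. Defaults: width 128,
4 blocks, 32 time features. This is an openly desk-scale trunk standing
where a production co-design model would put tens of blocks at width
1024+; the frequency set, embedding combination and block internals are the
package's own choices at that scale.

Training draws one `t ~ Uniform(0, 1)` per example and epoch, corrupts both
tracks to `xt`, and minimises cross-entropy against `x1` at masked positions
only (`loss_positions = "masked_only"`): under the flow factorisation the
unmasked positions are given, carry no learning signal, and would dilute the
loss scale; `"all"` is retained as an ablation switch, as is an independent
per-track corruption time. Losses are reported as the per-masked-position
mean per track, summed over tracks, so the uniform-prediction baseline is
`log(Ks - 1) + log(Kr - 1)` regardless of `t`. Optimisation is Adam at
1e-3, batch 500. Gradients are hand-derived; the test suite checks them
against central finite differences, and the attention contractions, GELU and
row softmax run as a small compiled kernel.

## The synthetic world and its oracles

The toy world is a hidden-state chain (3 states by default, mimicking
helix/sheet/coil) emitting one sequence token (of 6) and one structure token
(of 8) per residue — transitions diagonally dominant (0.8 stay), emissions
peaked (0.7 on a state-preferred token), uniform initial distribution. The
hidden state couples the two tracks, giving positive sequence-structure
mutual information, a Bayes ceiling for inverse-folding recovery strictly
above the majority baseline, and exact oracles:

- `enumerate_joint()` — the exact joint over all outcomes by the forward
  recursion (guarded to 1e6 outcomes);
- `position_marginals()` — exact per-position marginals at any length;
- `exact_posterior_denoiser()` — the ideal denoiser `p(x1 | observed)`, by
  summation over the enumerated joint;
- `cofold_oracle()` — the max-product (joint Viterbi) structure decode,
  standing in for a folding model in token-space self-consistency;
- `recovery_bounds()` — the inverse-folding Bayes ceiling
  `E[mean_i max_s p(s_i | r)]` via forward-backward, and the majority
  baseline.

Distribution-recovery checks use a sharper, smaller instance (2 hidden
states, 3 + 3 tokens, stay and peak 0.9, N = 3). The sharpness is
deliberate and chosen from the oracle, not from test outcomes: the
total-variation error of a *perfect* sampler estimated from n multinomial
draws is computable in closed form from the enumerated joint
(`0.5 * sum(sqrt(2 p (1 - p) / (pi n)))`), and at 20,000 draws over this
729-outcome space it is about 0.033 under the sharp parameters — leaving
real headroom under a 0.05 bound for the sampler's own `O(dt)`
discretisation bias — whereas the default 0.7-peaked parameters put the
floor at about 0.062, where no implementation could demonstrate recovery at
that sample size.

What the toy world does not emulate: real amino-acid composition, long-range
contacts beyond the Markov horizon, length variation, 3D geometry, or a
learned structure tokenizer. Passing its tests shows the flow machinery is
exact and the trainer functional — not that the model generates plausible
proteins.

## Problem sizes

The shipped validation runs at sizes a single CPU handles comfortably, and
states them explicitly: training on 5,000 proteins of length 16 for 20
epochs (~6 minutes); exact-recovery sampling of 20,000 trajectories at 200
steps; entropy ablations of 200 samples at 50 and 400 steps; recovery
metrics over 200 held-out structures. The per-residue generation entropy at
this scale moves by hundredths of a nat between step counts — the
step-count and strategy effects are directional, with standard errors
reported, not the paper-scale separations a 512-length model exhibits.

## Known limitations

- The Euler kernel treats positions independently within a step; exactness
  of distribution recovery is therefore `O(dt)` and degrades at small step
  counts (visible as a mild TV increase at `steps = 50`).
- `eta` is user-configurable with default 0; closed-form laws (mask
  fraction, absorption) hold at `eta = 0`, and `eta > 0` is validated
  behaviourally (transient re-masking, unchanged stationary recovery).
- The denoiser's positional table fixes a maximum length at initialisation;
  there is no length generalisation.
- Checkpoints are R serialisations, not portable across package format
  versions (`maskflow-checkpoint-1` guards the header).
- The co-fold oracle is a max-product decode; among exactly tied maximisers
  its choice is deterministic but convention-dependent.
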