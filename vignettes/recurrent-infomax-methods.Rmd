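---
title: "Methods: the recurrent Infomax learning rule and its readouts"
author: "RecurrentInfomax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the recurrent Infomax learning rule and its readouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RecurrentInfomax)
```

## The model and its assumptions

The network is a vector of `N` binary neurons evolving in discrete time.
Given the state `x(t)`, each recurrent neuron receives the membrane input
`s_i(t) = sum_{j != i} w_ij x_j(t) - h_i` and fires at the next step,
conditionally independently of the others, with probability
`p_max * sigma(s_i(t))`.  The logistic transfer with a ceiling `p_max < 1`
is not an arbitrary convenience: a leaky integrate-and-fire neuron driven
by a constant current plus white noise has an f--I curve of exactly this
saturating sigmoid shape, with the saturation level set by the refractory
period (`lifFICurve()` reproduces this check; the refractory bound
`f <= 1/t_ref` is enforced by construction).  One caveat is inherited from
the discrete-time formulation: no physical duration is assigned to a time
step, so all rates and leak constants are in units of steps.

Self-connections are excluded structurally (the recurrent diagonal of the
weight matrix is identically zero, and stays zero under learning).
External input neurons, when present, occupy the trailing indices; their
states are copied from the stimulus stream and never sampled.

## Objective and learning rule

Learning maximizes an approximation to the mutual information
`I[x(t); x(t-1)]` between consecutive network states, subject to soft
constraints.  The objective has four terms: per-neuron predictability
`sum_i log I[x_i(t); x(t-1)]`, a pairwise-covariance penalty (weight
`kappa`) that keeps the firing distribution near independence (and doubles
as a population-sparseness penalty), a rate penalty (weight `eta`) pinning
each neuron's mean rate at `p0`, and an input-fluctuation penalty (weight
`zeta`) confining `s_i` near the reference input
`s0 = log(p0/(p_max - p0))`, the input at which a neuron fires with
probability exactly `p0`.  Without the fluctuation term, strong reciprocal
weights eventually produce near-periodic firing in which the pairwise
approximation underlying the covariance penalty fails; the term is not
cosmetic.

The stochastic update gates a per-synapse eligibility trace with global
scalars:

```
dw_ij = eps (tau/T) (g1 - g2 - g3 - g4) <psi_i x_j>_tau  -  eps (zeta/T) (s_i - s0) x_j
dh_i  = -eps (tau/T) (g1 - g2 - g3 - g4) <psi_i>_tau     +  eps (zeta/T) (s_i - s0)
```

`psi_i` is the score of the transition likelihood — the derivative of
`log p(x_i(t+1) | s_i(t))` with respect to `s_i` — so `E[psi | s] = 0`
identically (tested analytically on a grid), and a spike that was
under-predicted makes `psi > 0`.  The pair trace `<psi_i x_j>_tau` is a
leaky integration (leak constant `tau`) of pre-before-post coincidences,
which is where the rule's STDP-like character lives.  The four global
signals are the per-step stochastic counterparts of the objective's four
terms; `gamma1` normalizes each neuron's momentary log surprise
`log p(x_i(t)|x(t-1))/Z_i` by its own long average, where `Z_i` is the
running estimate of the marginal firing probability.

The `a_prime` variant replaces the per-neuron normalization of `gamma1` by
a single population-level normalization (the log taken outside the sum of
information terms).  Both variants are implemented; the per-neuron form is
the default because it needs one fewer global substrate.

## The canonical step schedule

All running averages are strictly causal: every average used at step `t`
contains only quantities from steps up to `t - 1`.  Concretely, one step
executes: (1) compute `s(t)` from `x(t)`; (2) form the global signals from
`x(t)`, the previous input `s(t-1)` (which generated `x(t)`), the current
`s(t)` (fluctuation term only), and the long averages; (3) apply the
update to the masked parameter entries; (4) sample `x(t+1)` from `s(t)`;
(5) compute `psi(t)` and fold `(psi(t), x(t))` into the tau-traces;
(6) fold the step-`t` quantities into the T-averages.  The compiled loop
and a plain-R single-step reference implementation execute this schedule
independently and are tested to agree to 10 decimal places over hundreds
of steps, including with restricted global-signal scopes and plastic
masks.

Cold start: all averages start at zero.  A zero `Z_i` (a neuron firing
before its marginal estimate has formed) would make the log surprise
diverge, so `Z_i` is floored at the same `delta` that the rule already
applies to the `gamma1` denominator; this removes a removable startup
singularity and changes nothing once the averages have settled.

## Tunable parameters

| Parameter | Units | Default / typical | Role |
|---|---|---|---|
| `p_max` | probability | 0.4--0.98 | transmission ceiling; low values favor avalanches, high values repeated sequences |
| `p0` | probability/step | 0.0015--0.05 | target mean rate |
| `epsilon` | -- | 0.005--0.02 | learning rate, held constant (no annealing) |
| `tau` | steps | 5--20 | eligibility leak; the STDP coincidence window |
| `T` (`Tavg`) | steps | 50000 | long-average leak; also scales the effective step size `eps/T` |
| `delta` | -- | 1e-3 | floor on estimated denominators |
| `cKappa, cEta, cZeta` | -- | figure-legend values | scaled penalty coefficients |

The scaled coefficients are converted by
`kappa = 2/((N-1) cKappa p0^2)`, `eta = 1/(cEta^2 p0^4)`,
`zeta = 1/cZeta^2`.  The printed source for this conversion has lost its
grouping symbols, and this reading was adopted as a design decision: it is
the only one under which each penalty term scales linearly with `N` and is
dimensionless in `p0`, which is the stated purpose of the scaling.  The
worked value `kappa = 16.327` at `N = 50, cKappa = 1, p0 = 0.05` pins the
choice in the tests.

`T >> tau` is assumed by the derivation; the constructor warns when
`T < 10 tau`.

## Randomness and reproducibility

A run takes a single root seed, from which independent streams are derived
for initialization, dynamics, and stimulus generation.  Recording options
never perturb trajectories, and training can be resumed from a returned
state bit-identically (tested).  The compiled loops consume the R RNG
stream in the same order as the reference R implementations, so the two
routes are comparable draw for draw.

## Numerical choices

- The logistic is evaluated branch-wise so `exp` never overflows; the
  transition probability entering a log is clamped below at 1e-300 only to
  avoid `-Inf` in pathological saturated states.
- `psi` with `p_max = 1` and a silent outcome at saturation is a genuine
  domain error and is raised, not patched.
- `iGauss` drops neurons with zero variance in the window (their
  covariance contribution is singular and they carry no information) and
  raises an error when the covariance remains singular after removal.
  Log-determinants are used throughout.
- Power-law slopes are ordinary least squares on
  `(log s, log p_hat(s))` over occupied integer sizes in a configurable
  range (default 1--50); the source material overlays a reference line on
  a log-log plot and names no estimator, so OLS was chosen as the plainest
  reading and is validated by recovering planted exponents within 0.1.
- Bursts touching either end of a recording are censored (their extent is
  unknown) and discarded.
- The ISI coefficient of variation uses the population (1/U) normalization
  in the standard deviation; the printed SD formula in the source is
  dimensionally inconsistent and the intended standard deviation was
  assumed.
- Rescaled spike-triggered averages are kept numeric so the contract
  (pixel mean exactly 128, maximal absolute deviation exactly 127) holds
  exactly; quantization to integer gray levels 1..255 happens only on PGM
  export, since rounding first would break the contract.
- Sequence censuses use exact binary equality on whole-network
  configurations; windows slide with stride 1.  "Repeated" defaults to
  occurrence count at least 3 ("more than twice"), configurable.

## The synthetic stimulus generators

`episodicStimulus()` emulates episodic sensory input: three external
neurons fire in a fixed timetable (neuron 1 at offset 0, neuron 3 at
offset 2, neuron 2 at offset 4 — the published one-based step labels 1/3/5
mapped to zero-based offsets), each slot independently with probability
1/2, with onset-to-onset gaps uniform on [50, 100] steps.  This yields
exactly `2^3 - 1 = 7` distinct non-silent episode types (tested by
enumeration).

`syntheticImageFixture()` provides a download-free natural-image stand-in:
Gaussian random-phase images with a `1/f` radial amplitude spectrum, unit
variance.  It reproduces the second-order (spectral) statistics that the
whitening filter `L(f) = f exp(-(f/f_c)^4)` (cutoff 200 cycles per
picture, radial frequency on the standard FFT grid) is designed for, but
none of the higher-order structure of real scenes — edges, occlusions,
sparse contours.  Receptive fields learned on the fixture therefore test
the pipeline (whitening, i.i.d. patch sampling, ON/OFF encoding,
spike-triggered recovery), not the emergence of Gabor-like selectivity,
which requires the real image ensemble (supported via PGM input).  The
ON/OFF gain published for the original ensemble (`xi = 1.65`) produces the
stated input rate of about 0.15 only on that ensemble; on other image sets
`calibrateXi()` finds the gain by bisection (the rate is monotone in the
gain), and the published value remains available as a fixed option.  The
0.15 figure is treated as the population-average rate over ON and OFF
cells.

For the image experiment the global signals are computed over the
recurrent population only (`gammaScope`), because the input neurons'
firing is i.i.d. and carries no retainable information; the threshold
update follows the same row mask as the weights.

## Validation design

Three checks anchor the implementation to independent ground truth.

**Gradient agreement.**  For a 3-neuron network the objective is evaluated
exactly — transition kernel over all 8 states, stationary distribution,
per-neuron informations, penalties — and differentiated by central
differences.  The averaged stochastic update (accumulated over 10^6 steps
with frozen parameters, `tau = 15`, `T = 1e4`) is required to align with
this exact gradient at cosine similarity above 0.9.  The initial weights
for this check are drawn uniform on [-1, 1] rather than the developmental
[-0.1, 0.1]: at the smaller scale the per-neuron informations are ~1e-5
nats, two orders of magnitude below the `delta` floor, so the implemented
rule's `gamma1` is uniformly suppressed relative to the exact `1/I_i`
weighting and no run length can recover the direction — a property of the
rule's stated floor, not an implementation error.  At |w| <= 1 the
informations sit near or above the floor and the rule tracks the exact
gradient (cosine ~0.98).

**Gaussian information estimate.**  On weakly coupled networks
(|w| <= 1, N = 4..6, rates around 0.2) the covariance-based estimate
agrees with exact enumeration within a few percent at 10^6 samples; the
acceptance bound is 15%.  The agreement degrades with coupling strength
(at pairwise weights of 6 the Gaussian estimate overshoots by ~60%), which
is why the validation is specified in the weak-coupling regime.

**Critical avalanches.**  The avalanche testbed is a constructed network
in which each of 50 neurons sends one strong weight (15, transmitting at
>= 97% of `p_max`) to 2 or 3 random targets (mean 2.5), so that at
`p_max = 0.4` one spike evokes on average one spike — branching ratio one.
Avalanches are seeded by a very low spontaneous rate (4e-6 per
neuron-step) so that they rarely merge; this separation of timescales is
the standard condition for clean avalanche statistics, and merging
demonstrably flattens the fitted slope.  Because silent stretches are then
long, `avalancheCatalog()` skips them exactly (the silent state is
memoryless, so the gap is geometric and the initiating spike set a
conditioned Bernoulli draw), making 10^9-step horizons cost seconds.  Two
finite-size facts matter when interpreting the fit: the ideal
branching-process size law with this offspring distribution has an OLS
slope of -1.41 (not -1.50) over sizes 1--50, and quenched loops in a
50-node graph re-ignite avalanches and shallow the tail further; measured
slopes across graph realizations are -1.33 to -1.39, within the accepted
-1.5 +/- 0.2 band.

## Problem sizes of the scaled demonstrations

The published headline results come from runs of order 10^8 to 2x10^9
steps.  The package's scaled demonstrations use sizes chosen so the whole
suite runs in minutes: the learning-trend check trains the
50-neuron avalanche configuration for 10^7 steps and verifies (a) a
monotone-trend increase of the windowed information estimate (Spearman
rank correlation after discarding the first 10% of records as cold-start
burn-in) and (b) movement of the burst-size slope toward -3/2 relative to
initialization.  The burn-in exclusion reflects a real feature of the
rule: with zero-initialized averages, the `delta`-floored `gamma1` makes
the first ~10^5 steps violently plastic before the long averages settle;
the published runs are so long that this transient is invisible in their
information traces.  For the same reason the high-`p_max`
repeated-sequence configuration sits in a saturated transient at desk
scale (the rate-control relaxation time is `T/(eps zeta)`, about 10^8
steps for its parameters) and is exercised here at reduced scale for
pipeline correctness rather than for its converged phenomenology.

## Known limitations

- No physical time unit is attached to a step; comparisons with
  experimental ISI or avalanche statistics are in units of steps.
- Neurons may make both excitatory and inhibitory synapses; no Dale's-law
  pairing is implemented.
- No continuous-time extension of the rule is provided.
- Exact enumeration (`exactMutualInformation`, `exactObjective`) is capped
  at 12 neurons.
- The synthetic image fixture does not reproduce higher-order natural
  image statistics; Gabor-like receptive-field emergence requires real
  images and full-scale run lengths.
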