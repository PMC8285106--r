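---
title: "Reconciling spike-train and calcium-imaging response metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciling spike-train and calcium-imaging response metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calspike)
```

## The problem

Extracellular electrophysiology (ephys) and two-photon calcium imaging are
the two workhorse techniques for surveying visual responses in cortex, and
they systematically disagree: with the same stimuli and the same analysis
code, ephys surveys report more responsive neurons, and imaging surveys
report more selective ones. `calspike` implements the machinery needed to
study and reduce that disagreement on fully synthetic data: a ground-truth
spiking simulator, a spikes-to-fluorescence forward model, two calcium event
extractors, a shared metric layer, distribution-distance comparisons, and a
reliability-based functional-class clustering.

The pipeline is organized so that the *same* metric code consumes both
modalities. A response magnitude is a spike count (ephys) or a summed event
amplitude (imaging) in the half-open presentation interval; everything
downstream — responsiveness, selectivity, preference — is modality-blind.

## The forward model

The generative link between the modalities is a latent-calcium model with
cooperative indicator binding. Per 30 Hz frame of width $\Delta t$, with $s$
spikes in the frame,

$$c \leftarrow c_0 + (c + s - c_0)\,e^{-\Delta t/\tau},$$

so calcium jumps one normalized unit per spike and relaxes toward the
baseline $c_0$. Fluorescence applies a saturating Hill transform
$h(c) = c^n/(1 + \gamma c^n)$, normalized so that one unit of calcium at
baseline produces a transient of peak $A$:

$$F(c) = A\,\frac{h(c) - h(c_0)}{h(c_0 + 1) - h(c_0)},$$

low-pass filtered with the rise time $\tau_{ON}$ and disturbed by
per-frame Gaussian noise of SD $\sigma$. Defaults are the calibrated
values $\tau = 0.359$ s, $A = 0.021$, $\sigma = 0.047$, $n = 2.42$,
$\tau_{ON} = 0.0034$ s, $\gamma = 0.0021$, $c_0 = 0.46$. Because $n > 1$
and $\gamma$ is small, a $k$-spike burst produces a transient larger than
$k$ single-spike transients — the supralinearity that drives most of the
selectivity results. The published MLSpike code is a suitable external
spot-check oracle for this transform; exact numerical agreement with it is
not a design goal, and the normalization of $A$ (tied here to a unitary
calcium increment) is our choice where the convention was open.

Two discretization decisions are deliberate: spikes land in their
containing frame (at 30 Hz nothing finer is resolvable, and
$\tau_{ON} \ll \Delta t$), and the per-frame update decays the spike's
increment within its own frame, which keeps the relaxation exactly
exponential — `fit_decay_constant()` recovers $\tau$ to machine precision,
which the tests assert at 3 significant figures.

## Event extraction

**Exact L0.** `l0_exact_events()` minimizes
$\tfrac12\sum_t (y_t - c_t)^2 + \lambda\,\#\{t : c_t \ne \gamma c_{t-1}\}$
exactly, with $\gamma = 2^{-1/(f \cdot 0.315\,\mathrm{s})}$ fixed by the
315 ms transient half-time. The solver is a changepoint dynamic program
over last-segment starts with PELT pruning; pruning needs one subtlety —
the first segment carries no penalty, so its candidate is pruned only with
an extra $\lambda$ margin. Exactness is verified against exhaustive
enumeration over all changepoint subsets on traces up to length 12.
Events are changepoints with positive amplitude $c_t - \gamma c_{t-1}$.

**Sparsity calibration.** $\lambda$ is adjusted per trace so the smallest
detected event is at least 200% of the noise floor $\hat\sigma$, the
robust SD of the trace minus a 1 s running median
($1.4826 \times \mathrm{MAD}$). Starting at
$\lambda_0 = \hat\sigma^2 \log T$, $\lambda$ grows by the squared ratio of
the target floor to the current smallest amplitude (the smallest surviving
amplitude scales like $\sqrt{2\lambda(1-\gamma^2)}$, so this lands near the
target in a few solves), then bisects to a relative tolerance of $10^{-2}$.
If the constraint already holds at $\lambda_0$ the uncalibrated solution is
returned; if events vanish before it can hold, the empty series is returned
at the vanishing $\lambda$.

**Non-negative deconvolution (NND).** `nnd_events()` polyphase-upsamples
30 Hz traces to 150 Hz and solves
$\min_s \tfrac12\|y - Ks\|^2,\ s \ge 0$ with the same half-time decay
kernel (the kernel decay is not dictated by the protocol; we reuse 315 ms
for comparability with the L0 kernel). The problem is solved exactly by a
pool-adjacent-violators scheme; a final forward sweep clamps pools on
predominantly negative noise stretches, where amplitudes are ~0 anyway.
Amplitudes follow the multiply-by-max convention: the trace is normalized
by its maximum before deconvolution and event amplitudes are scaled back,
so thresholds expressed in noise-SD units stay meaningful; whether the
original convention multiplied or divided is ambiguous, and this choice is
recorded as ours. Post-hoc thresholding (`threshold_binned_events()`) bins
events in 100 ms windows and zeroes bins below $k\hat\sigma$, pro-rating
the final partial bin's threshold by its coverage.

## Metrics

* **Responsiveness.** The preferred condition is the argmax of mean
  response. Reliability is the percentage of preferred-condition trials
  whose magnitude is *strictly* larger than at least
  $\lceil 0.95\,n_{\mathrm{draws}}\rceil$ of 1000 same-duration intervals
  drawn uniformly from the spontaneous (gray-screen) epoch; responsive
  means reliability > 25% (a 40% alternative is used in class matching).
  Strictness matters: a silent unit ties the all-zero null and is not
  responsive. The generator places one spontaneous epoch, so the protocol's
  "nearest gray epoch" is trivially satisfied.
* **Selectivity.** Lifetime sparseness
  $S = \bigl(1 - (\sum r_i/n)^2 / (\sum r_i^2/n)\bigr) / (1 - 1/n)$,
  0 for flat tuning, 1 for single-condition tuning; and the global
  orientation selectivity index
  $\mathrm{gOSI} = |\sum_\theta r(\theta) e^{2i\theta}| / \sum_\theta r(\theta)$
  over the 8 drifting-grating directions.
* **Preference.** Argmax of per-condition means; marginal argmax for
  preferred temporal/spatial frequency; ties break to the lowest condition
  index. For movies the "conditions" are 1/30 s frames, and reliability is
  computed uniformly on frame trials — a convention we flag, since it is
  the least constrained by the protocol text.

Selectivity and preference are reported only for responsive units
(`lifetime_sparseness_raw` keeps the unconditional value for paired
before/after comparisons).

## What the synthetic world does and does not emulate

`simulate_population()` draws baseline rates lognormally
(`meanlog = log 2`, `sdlog = 1` — the classic cortical lognormal; chosen
once as realistic, not prescribed by the protocol), evoked gains
lognormally, and tuning as von Mises over direction/orientation,
log-Gaussian over temporal/spatial frequency, rank-sparse over scenes and
a Gaussian bump over movie frames. Any smooth unimodal family would do;
the real data only ever shows the *measured* tuning. Bursts
(`burst_size` spikes at 5 ms) are injected on strongly driven trials of
truly tuned units, making the forward model's supralinearity and LogISI
burst detection exercisable. Ephys biases are explicit operators:
`inject_contamination()` merges a fraction of a donor's spikes (collapsing
identical timestamps, as a sorter would), and `apply_selection_bias()`
retains units with logistic probability in log rate.

A green test on this world establishes that the *pipeline* reproduces the
qualitative mechanisms — supralinear sparsification, contamination-driven
responsiveness inflation, rate-dependent detection — not that the
published effect sizes are recovered: the published numbers (e.g. the
0.41 to 0.14 selectivity-distance reduction) are properties of the real
datasets. The generator also does not model running dynamics (only a
per-experiment running fraction), eye movements, neuropil contamination,
or prolonged depolarization events.

## Comparisons and clustering

Jensen-Shannon distances use 10 equal bins on $[0,1]$ (1.0 in the top
bin) for continuous metrics and one bin per condition for preferences.
The logarithm is base 2 so the distance spans exactly $[0,1]$; a natural
log (the default of common library implementations) would cap it at
$\sqrt{\ln 2} \approx 0.83$ and contradict the stated range. The
bootstrap null draws two *disjoint* subsamples from one modality, each of
size $\min(\lfloor n_a/2\rfloor, n_b)$ (sizes were unstated; this is our
convention), and reports $p = (\#\{D_{null} \ge D^*\} + 1)/(n + 1)$,
rendered "p < 0.001" at zero exceedances.

The functional-class analysis fits full-covariance Gaussian mixtures to
the $N \times 4$ reliability matrix (fractions; movie column is the max
over movie blocks), selecting the order by four-fold cross-validated
held-out BIC, $-2\,\mathrm{LL}_{\mathrm{held-out}} + p\ln n_{\mathrm{held-out}}$.
"BIC on held-out data" is nonstandard — BIC normally uses the training
likelihood — so the formula above is fixed here and exposed via
arguments. Clusters map to $2^4$ classes by thresholding mean member
reliability per stimulus type at 0.25; class fractions are averaged over
repeated fits, and `class_fraction_analysis()` sweeps the threshold on
one side to find the value that best matches the other side's class
distribution.

Default `k_range = 1:50` and `n_repeats = 100` mirror the protocol; the
tests scale these down (e.g. `k_range = 1:8`, a handful of repeats) to
stay within desk-scale budgets, which does not change any class-level
conclusion on the generative mixtures used there.

## Numerical conventions and degenerate inputs

* Half-open trial intervals `[start, stop)` everywhere; a spike exactly at
  `stop` belongs to the next trial.
* All-zero response vectors: sparseness and gOSI return `NA` with a flag;
  all-constant traces return a zero noise floor; traces shorter than 100
  frames are rejected for noise estimation.
* Fewer than two spikes: ISI violations score is 0 with a flag; fewer
  than four: no bursts.
* The LogISI histogram uses 10 bins per decade of ISI with a 3-bin moving
  average, the standard void parameter $v = 1 - h_{min}/\sqrt{h_{p1}h_{p2}}$
  with threshold 0.7, and reads "more than three spikes" literally as
  $\ge 4$ on the primary path ($\ge 3$ on the sub-50 ms fallback path);
  both are configurable because the wording is ambiguous.
* Every stochastic entry point takes an explicit seed and restores the
  caller's RNG state.

## Known limitations

The L0 solver's pruning degrades toward $O(T^2)$ on long, nearly
event-free traces (it remains exact; worst case ~10 s at 20k frames).
The selection-bias operator acts on realized spike counts, not true
rates. The true pre-measurement distribution of selectivity in cortex is
unknown; the generator exposes tuning sharpness as parameters rather than
fixing it, and no claim about the *true* selectivity distribution is made
by any test.
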