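---
title: "Models, parameters and design choices in vtsfear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in vtsfear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtsfear)
```

This vignette documents the models behind each pipeline stage, the
parameters that matter (with units and defaults), the world the synthetic
generator describes, and the choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The experimental protocol being modeled

Three sessions on consecutive days. Habituation: six 30 s blocks of tone
beeps (1 Hz within a block, 30 beeps per block), blocks 90 s apart.
Training: six CS blocks spaced pseudo-randomly 60–120 s apart, each block
immediately followed by a 1 s footshock. Recall: four CS blocks in a new
context, no shock. `build_schedule()` encodes exactly this; the only random
element is the training-day gap sequence (uniform on [60, 120] s from the
seed). Sessions get 60 s of quiet lead-in/lead-out so that peri-event
windows never leave the recording.

## Behavioral model

`simulate_behavior()` runs a two-state semi-Markov chain (moving vs
freezing) at the 30 Hz video rate with geometric frame-wise bout lengths:
the per-frame hazard of leaving a state is `1/(mean_bout × frame_rate)`, so
realized bout durations are geometric with the requested mean. This is the
simplest process that produces threshold-crossing bouts with controllable
mean lengths, which is all the freezing segmenter consumes.

Defaults describe a mouse that mostly moves: `mean_move_bout = 10` s,
`mean_freeze_bout = 2` s, index levels 200 (moving) and 10 (freezing) a.u.
with 8 a.u. Gaussian noise. With the 40 a.u. freezing threshold these
levels are > 10 noise SDs away from the boundary, so hidden state and
detected state coincide except at bout edges — deliberate, because the
segmenter's boundary arithmetic is tested separately with constructed
traces. `cs_freeze_bias` (default 0) scales the entering-freezing hazard by
`1 + bias` (and the leaving hazard by its inverse) during CS blocks to
emulate conditioned freezing when a scenario needs it.

## Fluorescence model and deconvolution

Each neuron's trace is a sum of transients `a · exp(−t/τ)` (single
exponential, `kernel_decay` default 1.0 s, the AR(1) model class assumed by
the deconvolution), a constant per-neuron baseline (uniform 80–120 a.u.),
and i.i.d. Gaussian noise (`noise_sd`, default 1 a.u.). Sampling is 10 Hz
per focal plane, the effective per-plane rate of a 30 Hz miniscope cycling
three planes; behavior frames are matched by nearest-frame lookup.

Planted responders receive one event per matching trigger (every footshock,
every beep, or every freezing→moving transition) at `response_latency`
(default 0.1 s) with amplitude `response_amplitude × noise_sd`. Background
events are Poisson with state-dependent rates (defaults 0.03/s moving,
0.01/s freezing; the benchmark worlds use 0.02/s in both states). The paper
trail behind those numbers is thin everywhere in this literature — real
background rates and response amplitudes of striatal neurons are not
published as such — so these are free parameters chosen once to give sparse,
clearly supra-noise transients, not estimates. Background amplitudes are
drawn uniformly on 1–3 × `noise_sd`: bounded support keeps a single
background event from mimicking a stimulus-locked response, which matches
how such events behave after σ-normalization of real recordings.

`deconvolve_ar1()` solves the non-negative sparse AR(1) problem

$$\min_c \tfrac12\lVert F - c\rVert^2 + \lambda \sum_t s_t,\qquad
  s_t = c_t - \gamma c_{t-1} \ge 0$$

with a single-pass pool-adjacent-violators scheme (Rcpp), exact for this
problem class; the test suite checks it against an independently written
active-set quadratic-programming oracle on short traces (objective gap
below 1e−8). Choices:

* **γ** is estimated per trace as the lag-2/lag-1 autocovariance ratio,
  clipped to [0.5, 0.99]. The ratio form cancels the white-noise inflation
  of the lag-0 term. Mean subtraction biases it low when transients are
  dense relative to the trace length; at the event rates above the bias is
  well under the clip width and irrelevant to event detection.
* **λ** defaults to the value (found by bisection; the residual SD is
  monotone in λ) at which the residual SD matches a noise estimate from the
  first-differenced trace, `mad(diff(F))/√2` — standard practice where the
  upstream literature delegates the choice to a package default.
* **σ_F is the whole-trace SD**, not a noise-floor estimate, and divides
  both the Z-scores and the deconvolved amplitudes, because downstream
  quantities (responder thresholds, amplitude-weighted frequencies) are
  defined against that same σ_F.
* **Baseline**: `deconvolve_ar1()` itself is baseline-free (its contract is
  the optimization above); `deconvolve_traceset()` subtracts the per-trace
  median first. With sparse activity the median tracks the true baseline to
  within a fraction of the noise SD.
* **Event floor**: inferred jumps below `0.1 σ_F` are discarded as
  numerical dust so event counts are deterministic.

## Responder classification

Z traces are averaged over peri-event snippets (storage window [−2, +4] s;
the onset sample is the nearest sample to the event time; events whose
window leaves the trace are dropped and counted). Classification uses only
the published sub-windows: mean Z over [0, 1] s > 1.0 for footshocks, mean
Z over [0, 0.5] s > 0.2 for beeps and movement-ONs; windows are half-open
in samples, thresholds strict.

Confound exclusion removes beeps followed within `w` s by a movement-ON
from the CS analysis, and movement-ONs preceded within `w` s by a beep from
the movement analysis. The source analyses state the rule but not `w`; the
default `w = 0.5` s matches the CS/movement classification window length,
and the exclusion is global (not per neuron). Movement-ON events are split
into within-block (`movON_CS`) and between-block (`movON_noCS`) analyses.

Duplicate rejection collapses cross-plane pairs closer than 20 µm with
Z-trace Pearson correlation above 0.7, iteratively removing the member with
lower mean raw fluorescence (the more out-of-focus copy) until no violating
pair remains — a deterministic replacement for the manual validation step
used with real data. Same-plane pairs are never merged. Two caveats the
tests make explicit: (i) with sparse activity the correlation of a true
duplicate pair is signal-to-noise limited, so the 0.7 gate only bites for
signal-dominated traces — the dedup tests therefore use high-rate neurons;
(ii) the rule can collapse two genuinely distinct neurons that happen to
sit within 20 µm on different planes *and* respond to every repetition of
the same stimulus; one planted-responder test documents this by running the
classification pipeline with dedup off, as the benchmark pipeline does.

## State-conditional activity

Every video frame carries one of four labels, {Frz, Mov} × {CS, noCS},
with CS defined by the half-open 30 s block intervals. On the training day,
frames from 1 s before each shock onset to 1 s after its offset are
excluded by default (`exclude_us = TRUE`): whether the source analyses
excluded shock periods is unstated, and a shock artifact is neither a
movement state nor a CS state; the flag makes the choice reversible.
Events are assigned to the label of the frame containing them (half-open),
so each event counts exactly once and the duration-weighted sum of the four
frequencies reconstructs the session total — an identity the tests verify
to 1e−9.

## Statistics

Conventions chosen to match the published statistical battery: Mann–Whitney
U reported as min(U₁, U₂) with the exact no-ties null for n ≤ 25 per group;
Kruskal–Wallis with tie correction; Dunn's z on pooled mean ranks with
Bonferroni adjustment over the *requested* comparisons only (the
within-session pairs, supplied as a configuration input, since the full
comparison list is figure-specific); the RM-ANOVA is the classical balanced
pooled-error mixed model without sphericity correction, which reproduces
the printed degrees of freedom (e.g. F₁,₂₀); Šidák adjustment is
`1 − (1 − p)^k`. Unbalanced or incomplete RM designs raise an explicit
unsupported-design error rather than silently switching model class.

CI reconstruction uses the t distribution (`mean ± t₀.₉₇₅,ₙ₋₁ · SEM`), not
the normal — validated by the worked examples in the acceptance tests — and
the reconstructed two-group comparison is the pooled-variance unpaired t
with df = n₁ + n₂ − 2.

The power routine targets the between-subjects effect of a
groups × m repeated-measures design with noncentrality
`λ = f²·N·m / (1 + (m−1)ρ)`, df (groups−1, N−groups), returning the
smallest admissible N (a multiple of the group count when equal groups are
required) whose noncentral-F upper tail beyond the central critical value
reaches the target power. Power is monotone increasing in N and f and
decreasing in ρ, which the tests check directly.

## Ephys metrics

The EPSC generator produces double-exponential transients (defaults: rise
1.5 ms, decay 8 ms, onset delay 3 ms, 10 kHz sampling) whose peak follows a
Hill function of light intensity, `A(I) = A_max I^h/(I^h + I₅₀^h)` (h = 2,
I₅₀ = 0.2); inward (negative) at −70 mV. NMDA companions at +50 mV are
outward and slow (rise 8 ms, decay 80 ms by default when requested).

Measurement choices where the source figures mark but do not state values:
the NMDA current is read at a fixed 50 ms post-stimulus (the dashed-line
time; configurable); the EPSC delay criterion is the 10 %-of-peak crossing
with linear interpolation (configurable; a 3×baseline-SD criterion is the
natural alternative); the PPR second peak is measured after subtracting the
extrapolated mono-exponential fit of the first EPSC's decay, which the
tests show recovers a planted PPR of 0.5 to within 2 % even with strongly
overlapping decays, and changes nothing (< 0.1 %) when decay is fast.
Detection flags use 5× the baseline SD; flagged AMPA/NMDA ratios are `NA`
rather than numbers. The excitation/inhibition ratio is a quotient of two
peak calls at two holding potentials and inherits their gain invariance.

## What the generator does and does not establish

The generator emulates: the three-day stimulus layout; two-state freezing
behavior with controllable bout statistics; stimulus-locked responses with
exact planted counts; state-dependent background activity; cross-plane
duplicates; saturating EPSC input–output behavior with paired-pulse
dynamics. It does **not** emulate photon/shot noise, baseline drift,
spatial footprints or neuropil contamination, correlated network activity,
darting or other non-freezing defensive behaviors, or heterogeneous
response amplitudes and latencies across responders. A green
planted-recovery test therefore establishes that the pipeline's arithmetic
(deconvolution, alignment, windows, thresholds, exclusions) is correct at a
realistic SNR — not that the thresholds would achieve any particular
sensitivity/specificity on real recordings, where response amplitudes are
graded and the noise is structured. Likewise the acceptance benchmarks
plant the published responder *counts* and verify the pipeline returns
them; they are recovery checks, not replications of the biological effect.

Classification is noise-limited when few events are available: the mean-Z
SE scales as `1/√(n_events × n_window_samples)`, so for the
movement-ON-during-CS analysis of a single short session (a handful of
usable events after confound exclusion) the 0.2 threshold sits within the
null noise band. Real analyses pool sessions and animals; single-session
synthetic tests assert exact recovery only for event kinds with adequate
counts (footshocks: 6 events × 10 samples; beeps: ~170 × 5).

## Numerical conventions

Half-open intervals everywhere (blocks, state labels, classification
windows) so boundary samples count exactly once. Freezing run length is
compared as `length ≥ ceiling(min_duration × frame_rate − ε)`, making the
0.5 s boundary at 30 Hz land exactly at 15 frames; runs truncated by either
trace end still count. All generators draw through an internal
seed-scoped RNG (`with_seed`), so identical spec + seed gives bit-identical
output without disturbing the caller's RNG stream; the pipeline derives
per-day, per-stage sub-seeds from the master seed. Degenerate inputs fail
loudly with typed conditions (`vtsfear_invalid_argument`,
`vtsfear_degenerate_input`, `vtsfear_dependency_error`) rather than
returning NAs, except where a flagged NA is the documented result (e.g.
below-noise NMDA currents, all-zero Wilcoxon differences).

## Known limitations

* AR(1) kernels only; no AR(2), no time-varying baseline.
* The duplicate-rejection intensity criterion presumes the dimmer copy is
  the out-of-focus one, which fails if gain differs between planes.
* The no-CS epoch builder places windows by a fixed rule (centered mid-gap,
  5 s shock guard); published analyses show such windows only graphically,
  so positions are a convention, not a reconstruction.
* The RM-ANOVA supports exactly one between and one within factor,
  balanced; the statistical battery deliberately stops at what the
  protocol's designs need.
* Exact event-level reproduction of any real session is out of reach by
  construction (the upstream extraction stack and its parameters are not
  part of this package); only the procedure class is reproduced.
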