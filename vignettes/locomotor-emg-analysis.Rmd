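---
title: "Locomotor EMG analysis: envelopes, bursts, phase coordination and the group battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locomotor EMG analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgait)
```

## The problem

After a complete spinal cord transection, treadmill-induced hindlimb
stepping in the rat can be quantified from the electromyogram (EMG) of an
ankle extensor (soleus, *Sol*, active during stance) and an ankle flexor
(tibialis anterior, *TA*, briefly active during swing), recorded bilaterally
at 2 kHz within a 0.1–1 kHz band. A well-organised locomotor pattern shows:

* left and right Sol bursts alternating (phase near 180°),
* Sol and TA of one limb alternating (phase near 180°),
* consistent step cycles (low step-to-step coefficient of variation), and
* concentrated burst-onset phases (a long mean resultant vector *r*).

`emgait` implements the full measurement chain from the raw multi-channel
signal to those quantities, plus the statistical battery used to compare
experimental groups and pre/post-drug conditions, and a synthetic-cohort
generator so that every stage can be validated against known ground truth.

## Signal chain

**Band-pass.** A 4th-order Butterworth (default 100–999 Hz, the upper edge
clamped to 98% of Nyquist) applied forward–backward so that burst onsets are
not delayed. `signal::filtfilt` does no edge padding, so the package extends
the signal by odd reflection — about 30 cycles of the low cutoff — before
filtering; a constant input then returns numerical zero everywhere, not just
away from the edges.

**Envelope.** The rectified signal averaged over consecutive,
non-overlapping bins (`emg_envelope`). Two presets matter: 5 ms bins for
burst timing and 50 ms (20 Hz) bins for amplitude analysis. "Integration"
is implemented as the bin *mean* (not RMS, not a leaky integrator): the
simplest reading, and it keeps envelope units linear in signal amplitude,
which the scale-equivariance tests rely on. A trailing partial bin is
dropped.

**Burst detection.** Interactive burst marking is replaced by a
deterministic dual-threshold hysteresis detector on the envelope, with the
baseline `b` at the 20th percentile and spread `s` the scaled median
absolute deviation (MAD):

* regions are maximal runs of bins at or above `b + k_off·s`
  (default `k_off = 1.5`);
* a region is a burst only if it *sustains* `b + k_on·s`
  (default `k_on = 3`) for half of `min_burst` — isolated single-bin
  excursions of the baseline neither create bursts nor pull onsets early;
* onset is the leading edge of that sustained run, offset where the
  envelope falls back below the off threshold; bursts separated by less
  than `min_gap` (50 ms) merge, bursts shorter than `min_burst` (50 ms)
  are discarded.

Two numerical guards make the detector total: both thresholds are clamped
into the envelope's dynamic range (on: `[b + 0.15·span, b + 0.5·span]`,
off: `[b + 0.07·span, b + 0.25·span]`, with `span` the 95th-percentile
excess over baseline). The lower clamp covers noise-free envelopes, where
the MAD is zero although bursts are obvious, and low-duty channels such as
TA, where the MAD reflects only baseline noise and `b + 3·MAD` would sit
inside the noise band. A genuinely flat envelope yields an empty train with
a warning rather than an error.

**Episodes.** Analysis is restricted to episodes of consistent activity:
at least 10 consecutive reference-muscle bursts of rhythmic activity, or at
least 10 s of irregular activity. "Rhythmic" is operationalised as a
cycle-duration CV at or below 0.5 within the run (no numeric criterion
exists in the source description; 0.5 cleanly separates the generator's
regular and irregular regimes). Runs are split at silent gaps longer than
`run_break_s` (2 s). The reference muscle defaults to Sol, whose burst
marks stance.

## Gait metrics

Per animal and muscle, within the selected episode: cycle duration
(onset-to-onset of consecutive bursts of the same muscle), burst duration
(onset to offset), and peak amplitude (envelope maximum inside the burst,
conventionally on the 20 Hz envelope of at least 10 consecutive steps).
Summaries report the mean, sample SD (n−1), SEM = SD/√n and CV = SD/mean.
Group statistics always operate on per-animal summaries, never on pooled
steps.

Amplitude is read as the burst *peak* of the selected envelope rather than
a burst integral; the peak is what the 20 Hz preset is flat enough to
estimate stably, and the choice is configurable upstream by handing a
different envelope to `peak_amplitudes`.

## Circular statistics

Burst-onset phases of a test muscle are expressed within the reference
muscle's cycles: `360·(t_test − onset_i)/(onset_{i+1} − onset_i)` degrees.
Cycles without a test onset are skipped; cycles with several use the first
and count a multiplicity flag. Angles are radians internally and degrees
`[0, 360)` externally, matching the polar-plot convention (0/360° synchrony,
180° alternation).

* **Mean vector** (`mean_vector`): resultant length `r` and mean angle; the
  Rayleigh p-value uses the standard finite-n approximation
  `p = exp(√(1 + 4n + 4(n² − R²)) − (1 + 2n))`, `R = n·r`, and the critical
  value `cR` solves that expression for the chosen α (default 0.05) by
  `uniroot`. "Coordinated" means `r > cR`. The calibration test measures
  the actual rejection rate under uniform angles at n = 10 over 10,000
  replicates and finds it within 0.6 percentage points of 5%.
* **Watson U²** (`watson_u2`): two-sample test from pooled cumulative
  fraction differences, ties handled by multiplicity weights. The p-value
  comes from the asymptotic alternating series by default, or from random
  relabeling (recorded seed, default 9,999 replicates). The two routes
  agree within 0.02 for p in [0.01, 0.5] at 40 angles per sample (checked
  over 50 seeded datasets with 19,999 relabelings each).
* **Moore's paired test** (`moore_paired`): pre-to-post difference vectors
  of the unit phase vectors, ranked by magnitude; the rank-weighted
  resultant R* is referred either to a sign-flip permutation null (default,
  recorded seed) or to an embedded critical-value table. The table is a
  Monte Carlo calibration (5 × 10⁵ replicates per n, frozen as a package
  constant) because the null distribution of R* depends only on n; the
  simulated n = 10, α = 0.05 entry (1.047) reproduces the published 1.048.
  Note that Moore's test detects a *consistent direction of change*: a
  fixed rotation applied to uniformly scattered pre-phases is invisible to
  it, which is the expected behaviour, not a defect.

## Group battery

* D'Agostino–Pearson omnibus K² (skewness and kurtosis transforms; below
  n = 8 an "untestable" marker is returned rather than a p-value).
* Unpaired pooled-variance Student's t for location contrasts. Pooled
  rather than Welch, the classical default where no variance heterogeneity
  is modelled.
* Mann–Whitney for coordination strength, since r is bounded in [0, 1].
  For min(n) ≤ 8 the p-value is exact, by full enumeration of the rank-sum
  null — enumeration rather than the shift algorithm so that tied data
  (common for bounded, rounded quantities) stay exact.
* One-sample t against 1 for post/pre-drug ratios; degenerate zero-variance
  inputs short-circuit to p = 1 (all ratios exactly 1) or a flagged p = 0.
* CV contrasts are Student's t on per-animal CVs.
* All tests are two-tailed; no multiple-testing correction is applied,
  matching the source battery.

## The synthetic generator

`generate_animal` draws a reference Sol-L rhythm (Gaussian cycle jitter,
truncated at 30% of the mean cycle), couples Sol-R and TA onsets at
configurable phases with von Mises noise (Best–Fisher sampler), and fills
each burst window with an amplitude-scaled unit-SD carrier: band-limited
Gaussian noise (150–400 Hz) for realism, or an alternating-sign rectangle
whose rectified envelope equals the amplitude exactly, used by the
exactness tests. Outside bursts, baseline Gaussian noise. Everything is
deterministic given `(seed, animal_index)`; true burst windows ride along
as an attribute for detector-fidelity checks.

Default study conditions, chosen once from the qualitative description of
the recordings and a design power analysis, then frozen:

| setting | treated (TTx2EB-like, n = 5) | control (TTnoEB-like, n = 7) |
|---|---|---|
| cycle mean / jitter SD | 1.0 s / 0.05 s | 1.0 s / 0.20 s |
| Sol / TA duty | 0.35 / 0.15 | 0.35 / 0.15 |
| interlimb & intralimb phase | 180° | 180° |
| phase concentration κ | 8 (r ≈ 0.94) | 0.3 (r ≈ 0.15) |
| duty jitter CV | 0.08 | 0.25 |

The drug transform regenerates the same animal with Sol amplitude × 0.45,
Sol duration × 0.65, TA duration × 2.2, TA amplitude × 0.5 and κ dropped to
0.5 — the direction and rough size of a 5-HT₂-antagonist perturbation, as a
generative convenience.

What the generator does **not** emulate: motor-unit structure, movement
artefacts, electrode cross-talk, treadmill-speed dependence, amplitude
drift, or any histological quantity. Passing tests therefore demonstrate
that the measurement chain is correct and well-calibrated on signals with
the assumed statistical structure, not that the biological effect sizes of
real recordings are reproduced — those depend on unreleased animal data.

## Problem sizes and aggregation used in the validation suite

The suite (and `scripts/acceptance.R`) uses: 25 s recordings (~24 step
cycles per animal); 10,000 replicates for Rayleigh calibration; 8,000
datasets × 199 relabelings for the uniformity of the Watson permutation p
(at 2,000 datasets the *expected* empirical Kolmogorov distance of a
perfectly uniform sample, ≈ 0.019, already sits at the 0.02 criterion, so
the larger replication is what makes the check informative); 100 replicates
for detector fidelity at SNR 5; and 20 seeds for cohort-level checks.
Per-seed checks are used for cycle and duration recovery (tolerances 5% and
10%); resultant-length recovery is asserted on the mean over seeds against
`I1(κ)/I0(κ)`, since a single animal's r̂ at ~24 cycles has a sampling SD of
about 0.025.

## Known limitations

* Burst onsets are quantised to the envelope bin (5 ms), bounding phase
  resolution at ~1.8° per 1 s cycle.
* The episode scanner classifies whole runs; it does not search for the
  best rhythmic sub-run inside a long mixed run.
* The tabulated route of Moore's test reports the smallest exceeded
  α-level (an upper bound), not an exact p; use the permutation route for
  numeric p-values.
* `find_episodes` assumes the reference channel is the stance-defining
  extensor; episode boundaries are not cross-checked against the flexor.
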