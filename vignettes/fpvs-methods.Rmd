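---
title: "Frequency-tagged oddball analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-tagged oddball analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpvs)
```

## The paradigm and the analysis model

In a fast periodic visual stimulation (FPVS) oddball experiment, stimuli
stream at a fixed base rate $f_b$ (here 6 Hz, via sinusoidal contrast
modulation), and every $n$-th item is a deviant ("oddball"), so deviants
arrive at $f_o = f_b / n$ (here 6/5 = 1.2 Hz). Any neural process that
responds differently to deviants than to base items — for instance, the
recognition of an embedded morpheme — is periodic at $f_o$ and therefore
concentrates its power at $f_o$ and integer multiples of it. The analysis
never models single trials: it measures spectral amplitude at a handful of
known frequencies and asks, per sensor, whether the oddball frequencies
carry more amplitude than the surrounding spectrum.

The package implements this chain end to end:

1. **Stimulus construction** (`build_combinations()`,
   `generate_sequence()`): 7-letter pseudowords are built by crossing
   4-letter stems or matched nonstems with 3-letter suffixes or matched
   non-morphemic endings, within subsets; with subset size $s$ and two
   subsets, each type yields $2s^2$ combinations (72 per type and 288
   stimuli for the full 12-per-role inventory; 18 per type and 54 for the
   reduced 6-per-role inventory). A 60-s, 6-Hz trial holds 360 tokens with
   oddballs at 1-based positions 5, 10, ..., 360 (72 oddballs, 288 base
   items), and no identical token may recur within one oddball cycle
   (distance < 5).
2. **Synthetic recordings** (`simulation_config()`, `simulate_cohort()`):
   sensor × time matrices containing the two periodic responses plus
   noise, with full ground truth retained for parameter-recovery tests.
3. **Spectral quantification** (`trim_and_average()`,
   `amplitude_spectrum()`, `snr_spectrum()`, `oddball_response()`): the
   per-condition trial average is Fourier transformed with no windowing or
   detrending; the spectrum is $\sqrt{\mathrm{Re}^2 + \mathrm{Im}^2}/N$ per
   bin; each bin is divided by the mean of its 20 surrounding bins (10 per
   side, skipping the immediately adjacent bin on each side) to give an SNR
   spectrum that is ≈ 1 in noise; the oddball response is the mean SNR over
   the oddball fundamental and its first three harmonics.
4. **Cluster statistics** (`cluster_permutation_test()`): a one-tailed
   one-sample cluster-based permutation test of the per-sensor responses
   against the known noise level of 1, with Delaunay-triangulation sensor
   adjacency, the minimum-two-neighbors cluster rule, and a sign-flip
   Monte Carlo null (5,000 randomizations by default).

## Reference timing and the frequency grid

Trials are 60 s. The reference preprocessing cuts the first two oddball
cycles (1.667 s) from the head of each trial, yielding 58.33-s epochs and
hence a frequency resolution of $1/58.33 = 0.0171$ Hz. Trim lengths are
rounded to whole samples (1.667 s at 250 Hz → 417 samples, epoch duration
58.332 s). A head trim of two oddball cycles plus a tail trim of one
(0.833 s) is the fuller edge-artifact convention; we default to head-only
trimming because the 58.33-s epoch — and with it the frequency grid every
downstream number depends on — is the reference quantity, and both trims
remain ordinary parameters (`head_trim`, `tail_trim`).

Target bins are chosen by `oddball_bins()`: the grid bin nearest the
nominal 1.2 Hz defines the *realized* fundamental, and harmonics are the
bins nearest 2×, 3×, 4× that realized value, with ties broken to the lower
bin. On a grid whose realized fundamental is 1.1962 Hz this puts the
targets at 2.3924, 3.5886 and 4.7848 Hz. The module always reports the
realized bins for whatever grid it is given rather than hard-coding any
frequency: a recording-dependent grid offset changes the realized values,
not the code path.

Two further conventions: bins whose full 20-bin baseline would extend
beyond the grid are flagged invalid rather than normalized against a
truncated baseline (targets must be interior bins, which they are by a wide
margin at these durations); and baseline windows by default do *not*
exclude other harmonic bins — an optional `exclude` mask is available since
with a 0.0171-Hz grid the harmonics are ~70 bins apart and never
contaminate one another's baselines.

## What the simulator emulates — and what it does not

`simulate_trial()` writes, per sensor,

$$x(t) = \sum_h a_h\, w^{(b)}\sin(2\pi h f_b t + \phi_h)
       + g \sum_h b_h\, w^{(o)}\sin(2\pi h f_o t + \phi'_h)
       + \varepsilon_{1/f}(t) + \varepsilon_w(t)$$

with per-harmonic amplitudes $a_h, b_h$, per-sensor topographies
$w^{(b)}, w^{(o)} \in [0,1]$, a subject gain $g$ drawn log-normally
(`subject_sd` on the log scale), phases drawn uniformly per subject, and
noise split into a $1/f^{\alpha}$ background (default $\alpha = 1$,
generated by spectral shaping of white noise) plus white sensor noise.
Oddball responses are modeled directly as sinusoids at $f_o$ and harmonics
rather than by convolving stimulus-locked transients: the analysis only
ever observes the frequency domain, and direct sinusoids give exact ground
truth at the bins the pipeline reads. Simulation runs natively at the
post-downsampling rate (250 Hz by default); a boxcar-prefiltered
`downsample()` hook exists for realism testing but the 1,000-Hz acquisition
chain is not emulated.

The default layout is a Fibonacci-sphere arrangement on the upper unit
hemisphere (160 sensors), with an azimuthal-equidistant 2D projection used
for plotting and triangulation; positive projected y is anterior by
convention. This reproduces the *geometry class* of a whole-head
gradiometer helmet, not any vendor's actual sensor positions.

Consequences for interpretation: passing tests show that the pipeline
measures what the generative model puts in (frequencies, amplitudes,
topographies) and that the statistics behave correctly on this model. They
do not certify performance against head-motion artifacts, cardiac/ocular
contamination, sensor drift, or source-level geometry — none of which are
simulated. Response amplitudes and topographies have no empirical calibration;
only SNR (which is scale-free) matters downstream, so amplitude units are
arbitrary.

## The cluster test

Per sensor, $t = (\bar{x} - 1)/(s/\sqrt{n})$ with the $n-1$ sample sd.
Zero-variance sensors with mean above the null get $t = +\infty$ and are
treated as suprathreshold (and flagged in reports) rather than dropped.
The cluster-forming threshold is the one-tailed Student quantile
$t_{1-\alpha_c}(n-1)$ at `cluster_alpha` = 0.05, computed numerically —
never a fixed constant. "A minimum of two neighboring channels" is
implemented as the `minnbchan = 2` rule: every cluster member must have at
least `min_neighbors` suprathreshold neighbors, applied iteratively to a
fixed point before connected components are formed; the cluster statistic
is the sum of member t values.

The null distribution flips the sign of each subject's deviation from 1
with probability ½ per permutation — the exact one-sample equivalent of
swapping a subject's data with the all-ones pseudo-condition in a
within-subject design — and records the maximum cluster statistic (0 when
no cluster survives). p-values use the +1 correction,
$p = (1 + \#\{\max_\pi \ge S\})/(1 + n_\pi)$, so they are never exactly 0,
and significance is $p \le \alpha$ with $\alpha = 0.05$ and 5,000
randomizations by default. Whether the original analysis thresholded
one-tailed at 0.05 or two-tailed-then-one-sided is not fully determined;
we use the one-tailed quantile at `cluster_alpha` and echo the choice in
every report.

Sensor adjacency comes from a Delaunay triangulation of the 2D projection
(triangle edges define neighbors), written here as a plain Bowyer–Watson
implementation — adequate for a few hundred sensors, deterministic for
cocircular groups, and validated in the tests against the
empty-circumcircle property directly.

## Statistical validation experiments

Two simulation experiments back the test's error rates; both are exposed
as functions so they can be rerun.

**Type-I calibration** (`null_calibration()`): 200 cohorts of 20 subjects
with the oddball amplitude set to 0 — every detection is a family-wise
false positive. Two scenario dimensions are load-bearing and are kept at
study scale: the 160-sensor layout (cluster formation under the
minimum-neighbor rule depends strongly on sensor count) and the 60-s trial
/ 58.33-s epoch (under $1/f$ noise the 20-bin baseline is a *convex*
function of frequency, so wider bins — shorter epochs — depress expected
SNR below 1 and make the test conservative; at the 0.0171-Hz resolution
this bias is small). Dimensions the null SNR distribution is provably
invariant to are reduced for runtime: sampling rate 25 Hz (bin spacing
depends on duration, not rate), one trial per cell (trial averaging scales
the noise floor, which SNR divides away), single base harmonic. With 1,000
randomizations per test, the family-wise rejection rate is ~0.07 (pooled
over 660 cohorts in our runs), with single 200-cohort estimates spreading
roughly 0.03–0.11. The experiment says something real about the method:
under pure noise the expected SNR is not exactly 1 but
$E[\mathrm{amp}]\,E[1/\overline{\mathrm{baseline}}] \approx 1.014$ (a
Jensen ratio bias of the 20-bin normalization), so the point null of 1 is
misspecified by ~1.4% and the test rejects slightly above alpha — an
anticonservatism that grows with sample size. Two opposing effects matter
at other problem sizes: null SNR responses are right-skewed (conservative
for a one-tailed t against a symmetrized sign-flip null), and at coarser
frequency grids the convex $1/f$ baseline depresses expected SNR below 1,
which at short epochs makes the test strongly conservative. At the
reference 0.0171-Hz resolution the ratio bias dominates.

**Spatial recovery** (`effect_recovery()`): an oddball response is seeded
on a contiguous 10-sensor posterior patch at an expected per-bin SNR of 3,
set analytically from the white-noise floor: averaging $k$ trials of $N$
samples with per-sample sd $\sigma$ gives a Rayleigh noise-floor mean
$m = \sigma\sqrt{\pi/(4N k)}$, and a sinusoid of amplitude $A$ contributes
$A/2$ at its bin, so $A = 2m\sqrt{\mathrm{SNR}^2 - 4/\pi}$
(`oddball_amplitude_for_snr()`). Across 20 cohorts of 20 subjects the
largest significant cluster overlaps the seeded patch with Jaccard ≥ 0.7
in ≥ 18/20 runs (typically 20/20, median Jaccard ≈ 0.95 — misses are
single boundary sensors pruned by the minimum-neighbor rule).

## Numerical and degenerate-input conventions

- Trim seconds are rounded to whole samples; epoch duration is
  `n_samples / sampling_rate` after rounding.
- No window, no detrending before the FFT; DC is retained but is never a
  target bin and is always edge-invalid for SNR.
- Nearest-bin ties break to the lower bin, documented and tested.
- Sequence generation replaces manual list editing by rejection sampling
  with a bounded retry count; exceeding the cap raises an error naming the
  violated constraint rather than silently relaxing it.
- `interpolate_channels()` uses inverse-distance weights over *good*
  triangulation neighbors only and errors on isolated bad sensors; it reads
  only pre-interpolation data, so results do not depend on the order of bad
  channels.
- Every random draw is keyed by `derive_seed(global_seed, labels...)`, a
  rolling hash mod $2^{31}-1$; adding subjects or conditions leaves
  existing cells bit-identical.

## Scenario presets and open choices

`run_config("adult")` is 28 subjects × 5 conditions × 5 trials;
`run_config("child")` is 17 × 3 (conditions 0, 1, 3) × 6 trials — the
study dimensions. Default per-condition effect multipliers reproduce the
qualitative response pattern this paradigm elicits (a strong whole-word response in condition 0
and one weaker morphological response: condition 3 for adults, condition 1
for children, zero elsewhere); they are demonstration defaults, not
estimates. Condition-0 word and consonant-string pools ship as a synthetic
fixture (only examples of the originals are available); the reduced child
inventory takes the first six items per role of the building-block table,
and subset partitions take the first half of each role — conventions, since
neither partition is recoverable from the building-block table. How base items
were scheduled across the 288 base slots is likewise not specified beyond
the repetition constraint; we sample uniformly with replacement under the
constraint, and the policy is configurable.

Test problem sizes: unit tests run on 4–40-sensor layouts with 10–20-s
trials at 50 Hz; the dataset-dimension checks run the full 28×5×160 and
17×3×160 designs with 12-s trials; the calibration and recovery
experiments use the sizes stated above. These are the package's validation
conditions; `simulation_config()` defaults stay at full study scale.

## Known limitations

- The permutation test assumes the subject-level response distribution is
  symmetric around the null value; for SNR data this holds only
  approximately (see the calibration discussion), leaving a small
  anticonservative bias at the reference resolution that grows with the
  number of subjects.
- The simulator's noise is stationary and artifact-free; robustness to
  non-stationary artifacts is untested by design.
- Adjacency from a 2D projection can differ from adjacency defined on the
  3D cap for extreme helmet geometries; for quasi-uniform layouts the
  triangulations agree.
- No source-space functionality: sensor-level inference only.
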