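# fpvs

Frequency-tagged oddball analysis for fast periodic visual stimulation
(FPVS) MEG/EEG experiments.

In an FPVS oddball design, stimuli stream at a fixed base rate (6 Hz) with
a deviant embedded every 5th item (1.2 Hz). Neural processes that
discriminate deviants from base items — e.g., recognizing an embedded
morpheme inside a pseudoword — produce spectral power exactly at 1.2 Hz
and its harmonics, where it can be measured without trial-level modelling.
`fpvs` is for researchers running or simulating such experiments. It covers
the whole chain:

- **Stimulus generation** — morpheme inventories (4-letter stems /
  nonstems × 3-letter suffixes / non-suffix endings) crossed within
  subsets into 7-letter pseudowords (2·s² combinations per type: 72 per
  type / 288 stimuli for the full inventory), and 360-item periodic
  sequences with oddballs at every 5th position and a minimum repetition
  distance of 5.
- **Synthetic MEG cohorts** — 160-sensor hemispheric layouts, steady-state
  responses at 6 Hz and 1.2 Hz (+ harmonics) with per-sensor topographies,
  1/f plus white noise, between-subject gain variability; full ground
  truth retained for parameter recovery.
- **Spectral quantification** — trial-averaged epochs (60-s trials with the
  first two oddball cycles trimmed → 58.33 s, frequency resolution
  1/58.33 = 0.0171 Hz), amplitude spectra `sqrt(Re² + Im²)/N`, SNR
  normalization of each bin by the mean of the 20 surrounding bins (10 per
  side, adjacent bins excluded), and the oddball response as the mean SNR
  over the fundamental and its first three harmonics:

  ```
  SNR(k) = amp(k) / mean{ amp(k ± 2), ..., amp(k ± 11) }
  response(sensor) = mean{ SNR at f_o, 2 f_o, 3 f_o, 4 f_o }
  ```

- **Cluster-based permutation test** — per sensor,
  `t = (mean − 1)/(sd/√n)` against the SNR noise level of 1 (one-tailed);
  suprathreshold sensors (Student quantile at cluster alpha 0.05) are
  pruned by the minimum-two-suprathreshold-neighbors rule and grouped into
  clusters under Delaunay-triangulation adjacency; cluster sums of t are
  compared to a sign-flip Monte Carlo null (5,000 randomizations) of
  maximum cluster statistics, with `p = (1 + #{max ≥ S})/(1 + n_perm)`.

## Worked example

Simulate a child-scale cohort (17 subjects × 3 conditions, 160 sensors)
with an oddball response seeded in conditions 0 and 1 but not 3, then run
the full spectra → cluster-test pipeline:

```r
library(fpvs)

cfg <- run_config("child", trial_duration = 20, sampling_rate = 50,
                  n_trials = 2, head_trim = 0.833,
                  cluster = cluster_test_config(n_permutations = 1000),
                  seed = 42)
report <- run_pipeline(cfg)
report
#> <run_report> 17 subjects x 3 conditions x 160 sensors = 8160 oddball responses
#>   frequency resolution 0.05219 Hz; targets 1.2004, 2.4008, 3.6013, 4.8017 Hz
#>   cond0: mean response 3.884, 1 significant cluster(s) [max sum t = 1356.52, p = 0.000999]
#>   cond1: mean response 2.574, 1 significant cluster(s) [max sum t = 1140.79, p = 0.000999]
#>   cond3: mean response 1.008, 0 significant cluster(s)
```

Reading the output: 17 × 3 × 160 = 8,160 per-sensor oddball responses; the
frequency grid is 1/19.17 s ≈ 0.052 Hz at these reduced trial lengths, and
the four target bins sit at the realized fundamental and its harmonics.
Conditions 0 and 1 (seeded effects) each produce one significant sensor
cluster; condition 3, simulated with zero oddball amplitude, stays at the
noise level (mean SNR ≈ 1, no cluster). Per-condition detail:

```r
report$cluster_results$cond0
#> <cluster_test_result> one-tailed one-sample cluster permutation test vs 1
#>   n = 17 (df = 16), threshold t = 1.746, 1000 randomizations
#>   cluster 1: 83 sensors, sum t(16) = 1356.52, p = 0.000999 *
```

At full study scale (`run_config("adult")`: 28 subjects × 5 conditions ×
5 × 60-s trials at 250 Hz) the same call produces the 22,400-point response
dataset.

Stimulus generation alone:

```r
combos <- build_combinations(adult_inventory(), STIM_TYPES)
table(combos$stim_type)   # 72 pseudowords per type, 288 total
cond <- condition_spec(1) # stem+suffix oddballs in nonstem+suffix bases
s <- generate_sequence(cond,
                       combos$text[combos$stim_type == cond$oddball_type],
                       combos$text[combos$stim_type == cond$base_type],
                       seed = 1)
s                         # 360 tokens, 72 oddballs at positions 5, 10, ...
```

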