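#' Type-I error calibration: cluster test on null cohorts
#'
#' Simulates `n_cohorts` cohorts with **zero** oddball amplitude — so any
#' rejection is a family-wise false positive — and runs the full spectral +
#' cluster-permutation chain on each. The scenario keeps the two parameters
#' the null behavior of the test actually depends on at study scale: the
#' full 160-sensor layout (cluster formation under the minimum-neighbor rule
#' depends on sensor count) and 60-s trials, whose 1.667-s head trim yields
#' 58.33-s epochs and the 0.0171-Hz frequency resolution (the width in Hz of
#' the 20-bin SNR baseline controls the small 1/f convexity bias of null
#' SNR). Dimensions the null SNR distribution is invariant to — sampling
#' rate, trial count, noise floor level — are reduced for runtime.
#'
#' @param n_cohorts number of simulated null cohorts.
#' @param n_subjects subjects per cohort.
#' @param n_sensors sensors (study scale by default).
#' @param n_permutations sign-flip randomizations per test.
#' @param alpha,cluster_alpha test levels.
#' @param seed global seed.
#' @return list with `rejections` (logical per cohort), `rate` (the
#'   family-wise rejection rate), and the scenario parameters.
#' @seealso [effect_recovery()]
#' @export
null_calibration <- function(n_cohorts = 200, n_subjects = 20,
                             n_sensors = 160, n_permutations = 1000,
                             alpha = 0.05, cluster_alpha = 0.05,
                             seed = 1L) {
  layout <- make_layout(n_sensors)
  adjacency <- build_adjacency(layout)
  rejections <- vapply(seq_len(n_cohorts), function(i) {
    cseed <- derive_seed(seed, "calibration", i)
    cfg <- simulation_config(
      n_sensors = n_sensors, sampling_rate = 25, trial_duration = 60,
      n_trials = 1, base_amplitudes = 0.3,
      oddball_amplitudes = rep(0, 4), topography = rep(0, n_sensors),
      base_topography = rep(1, n_sensors), noise_exponent = 1,
      noise_scale = 1, white_scale = 0.5, subject_sd = 0.2,
      layout = layout, seed = cseed)
    cohort <- simulate_cohort(n_subjects, cfg, condition_effects = c(null = 0),
                              seed = cseed)
    rd <- response_dataset(cohort, head_trim = 1.667, tail_trim = 0)
    res <- cluster_permutation_test(
      rd[, 1, ], adjacency,
      cluster_test_config(alpha = alpha, cluster_alpha = cluster_alpha,
                          n_permutations = n_permutations,
                          seed = derive_seed(cseed, "perm")))
    any(vapply(res$clusters, `[[`, logical(1), "significant"))
  }, logical(1))
  list(rejections = rejections, rate = mean(rejections),
       n_cohorts = n_cohorts, n_subjects = n_subjects,
       n_sensors = n_sensors, n_permutations = n_permutations,
       alpha = alpha, seed = as.integer(seed))
}

#' Spatial recovery of a seeded oddball effect
#'
#' Seeds an oddball response of known expected SNR (default 3) on a
#' contiguous patch of sensors (default 10, posterior), simulates cohorts,
#' runs the full pipeline, and measures the Jaccard overlap between the
#' largest significant cluster and the seeded patch in each run. The
#' per-harmonic sinusoid amplitude is set analytically from the white-noise
#' floor with [oddball_amplitude_for_snr()].
#'
#' @param n_runs number of independent simulated cohorts.
#' @param n_subjects subjects per cohort.
#' @param n_sensors sensors.
#' @param n_patch seeded patch size (contiguous sensors).
#' @param target_snr expected per-sensor SNR at each target bin.
#' @param n_permutations sign-flip randomizations per test.
#' @param seed global seed.
#' @return list with `jaccard` (per run; 0 when no significant cluster),
#'   `n_detected` (runs with Jaccard >= 0.7), `seeded` (patch indices), and
#'   the scenario parameters.
#' @export
effect_recovery <- function(n_runs = 20, n_subjects = 20, n_sensors = 160,
                            n_patch = 10, target_snr = 3,
                            n_permutations = 1000, seed = 1L) {
  layout <- make_layout(n_sensors)
  adjacency <- build_adjacency(layout)
  topo <- patch_topography(layout, n_core = n_patch, soft = FALSE)
  seeded <- which(topo == 1)
  fs <- 50; dur <- 20; n_trials <- 2; head_trim <- 0.833
  n_samples <- as.integer(round(dur * fs)) - as.integer(round(head_trim * fs))
  A <- oddball_amplitude_for_snr(target_snr, white_scale = 1,
                                 n_trials = n_trials, n_samples = n_samples)
  jaccard <- vapply(seq_len(n_runs), function(i) {
    rseed <- derive_seed(seed, "recovery", i)
    cfg <- simulation_config(
      n_sensors = n_sensors, sampling_rate = fs, trial_duration = dur,
      n_trials = n_trials, base_amplitudes = 0,
      oddball_amplitudes = rep(A, 4), topography = topo,
      base_topography = rep(0, n_sensors), noise_exponent = 0,
      noise_scale = 0, white_scale = 1, subject_sd = 0.2,
      layout = layout, seed = rseed)
    cohort <- simulate_cohort(n_subjects, cfg, condition_effects = c(eff = 1),
                              seed = rseed)
    rd <- response_dataset(cohort, head_trim = head_trim, tail_trim = 0)
    res <- cluster_permutation_test(
      rd[, 1, ], adjacency,
      cluster_test_config(n_permutations = n_permutations,
                          seed = derive_seed(rseed, "perm")))
    sig <- Filter(function(cl) cl$significant, res$clusters)
    if (!length(sig)) return(0)
    members <- sig[[1]]$members
    length(intersect(members, seeded)) / length(union(members, seeded))
  }, numeric(1))
  list(jaccard = jaccard, n_detected = sum(jaccard >= 0.7),
       seeded = seeded, n_runs = n_runs, target_snr = target_snr,
       amplitude = A, seed = as.integer(seed))
}
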