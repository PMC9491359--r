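#' Ground-truth configuration for synthetic FPVS recordings
#'
#' Collects every generative parameter of the simulator: geometry, timing,
#' the two periodic responses (base rate and oddball rate, each with
#' per-harmonic amplitudes and a per-sensor topography), and the noise
#' model (1/f "pink" background plus white sensor noise). Defaults mirror
#' the study conditions the simulator emulates: a 160-sensor whole-head
#' system, 60-s trials at 250 Hz, a 6-Hz base response and a 1.2-Hz oddball
#' response restricted to a posterior sensor patch. Amplitude units are
#' arbitrary; only the SNR matters downstream.
#'
#' @param n_sensors number of sensors.
#' @param sampling_rate sampling rate in Hz.
#' @param trial_duration trial length in seconds.
#' @param n_trials trials per subject and condition.
#' @param base_freq base stimulation frequency in Hz.
#' @param oddball_freq oddball frequency in Hz; `base_freq / oddball_freq`
#'   must be an integer (the oddball period in items).
#' @param base_amplitudes per-harmonic amplitudes of the base response.
#' @param oddball_amplitudes per-harmonic amplitudes of the oddball
#'   response.
#' @param topography per-sensor weights in `[0, 1]` for the oddball
#'   response; default: a soft posterior patch of 30 sensors on the
#'   default layout (see [patch_topography()]).
#' @param base_topography per-sensor weights for the base response;
#'   default: 1 everywhere (broad response).
#' @param noise_exponent spectral slope a of the 1/f^a background noise.
#' @param noise_scale sd of the pink-noise component per sample.
#' @param white_scale sd of the white-noise component per sample.
#' @param subject_sd sd (log scale) of the multiplicative between-subject
#'   gain on the oddball response.
#' @param layout optional `sensor_layout`; generated with [make_layout()]
#'   when `NULL`.
#' @param seed integer seed stored with the config.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_sensors = 160,
                              sampling_rate = 250,
                              trial_duration = 60,
                              n_trials = 5,
                              base_freq = 6,
                              oddball_freq = 1.2,
                              base_amplitudes = c(1, 0.5),
                              oddball_amplitudes = c(1, 0.6, 0.4, 0.25),
                              topography = NULL,
                              base_topography = NULL,
                              noise_exponent = 1,
                              noise_scale = 1,
                              white_scale = 0.5,
                              subject_sd = 0.2,
                              layout = NULL,
                              seed = 1L) {
  if (is.null(layout)) layout <- make_layout(n_sensors)
  if (nrow(layout) != n_sensors)
    stop("layout size (", nrow(layout), ") != n_sensors (", n_sensors, ")")
  period <- base_freq / oddball_freq
  if (abs(period - round(period)) > 1e-9)
    stop("base_freq / oddball_freq must be an integer oddball period")
  if (any(base_amplitudes < 0) || any(oddball_amplitudes < 0))
    stop("amplitudes must be non-negative")
  if (is.null(topography))
    topography <- patch_topography(layout, n_core = min(30, n_sensors))
  if (is.null(base_topography)) base_topography <- rep(1, n_sensors)
  if (length(topography) != n_sensors ||
      length(base_topography) != n_sensors)
    stop("topography length must equal n_sensors")
  if (any(topography < 0 | topography > 1) ||
      any(base_topography < 0 | base_topography > 1))
    stop("topography weights must lie in [0, 1]")
  fmax <- max(length(base_amplitudes) * base_freq,
              length(oddball_amplitudes) * oddball_freq)
  if (fmax >= sampling_rate / 2)
    stop("Nyquist violation: harmonic at ", fmax, " Hz >= ",
         sampling_rate / 2, " Hz")
  structure(list(
    n_sensors = as.integer(n_sensors), sampling_rate = sampling_rate,
    trial_duration = trial_duration, n_trials = as.integer(n_trials),
    base_freq = base_freq, oddball_freq = oddball_freq,
    base_amplitudes = base_amplitudes,
    oddball_amplitudes = oddball_amplitudes,
    topography = topography, base_topography = base_topography,
    noise_exponent = noise_exponent, noise_scale = noise_scale,
    white_scale = white_scale, subject_sd = subject_sd,
    layout = layout, seed = as.integer(seed)),
    class = "simulation_config")
}

#' Multi-channel 1/f (pink) noise by spectral shaping
#'
#' White Gaussian noise is Fourier transformed, each frequency component is
#' scaled by `f^(-exponent/2)` (DC set to 0), and the inverse transform is
#' standardized to the requested per-sample sd. Each channel is
#' independent.
#'
#' @param n_channels,n_samples matrix dimensions.
#' @param exponent spectral slope a of the power spectrum `~ f^-a`.
#' @param scale per-sample standard deviation of the output.
#' @return a `n_channels x n_samples` matrix.
#' @export
colored_noise <- function(n_channels, n_samples, exponent = 1, scale = 1) {
  if (scale == 0) return(matrix(0, n_channels, n_samples))
  w <- matrix(rnorm(n_channels * n_samples), n_samples, n_channels)
  if (exponent == 0) return(t(w) * scale)
  W <- mvfft(w)
  k <- seq_len(n_samples) - 1L
  k2 <- pmin(k, n_samples - k)         # symmetric frequency index
  g <- c(0, k2[-1]^(-exponent / 2))    # kill DC, shape the rest
  x <- Re(mvfft(W * g, inverse = TRUE)) / n_samples
  x <- sweep(x, 2, apply(x, 2, sd), "/") * scale
  t(x)
}

#' Simulate one multi-sensor FPVS trial
#'
#' Generates a sensor x time matrix as the sum of (i) the base steady-state
#' response, sinusoids at the base frequency and its harmonics weighted by
#' the base topography, (ii) the oddball response, sinusoids at the oddball
#' frequency and harmonics weighted by the oddball topography and the
#' subject gain, and (iii) 1/f plus white noise. Response phases are fixed
#' per subject (arguments), noise is drawn fresh per trial (`trial_seed`).
#'
#' @param config a [simulation_config()].
#' @param subject_gain multiplicative gain on the oddball amplitudes
#'   (between-subject variability and condition effects fold in here).
#' @param phase_base,phase_oddball per-harmonic phases in radians (recycled
#'   to the number of harmonics).
#' @param trial_seed seed for the noise draws.
#' @return a list of class `trial_recording` with `data` (sensor x time),
#'   `sampling_rate`, `t0`.
#' @export
simulate_trial <- function(config, subject_gain = 1,
                           phase_base = 0, phase_oddball = 0,
                           trial_seed = 1L) {
  fs <- config$sampling_rate
  n <- as.integer(round(config$trial_duration * fs))
  tt <- (seq_len(n) - 1L) / fs
  ns <- config$n_sensors
  data <- matrix(0, ns, n)
  phase_base <- rep_len(phase_base, length(config$base_amplitudes))
  phase_oddball <- rep_len(phase_oddball, length(config$oddball_amplitudes))
  for (h in seq_along(config$base_amplitudes)) {
    a <- config$base_amplitudes[h]
    if (a > 0)
      data <- data + outer(a * config$base_topography,
                           sin(2 * pi * h * config$base_freq * tt +
                                 phase_base[h]))
  }
  for (h in seq_along(config$oddball_amplitudes)) {
    a <- subject_gain * config$oddball_amplitudes[h]
    if (a > 0)
      data <- data + outer(a * config$topography,
                           sin(2 * pi * h * config$oddball_freq * tt +
                                 phase_oddball[h]))
  }
  if (config$noise_scale > 0 || config$white_scale > 0) {
    set.seed(as.integer(trial_seed))
    if (config$noise_scale > 0)
      data <- data + colored_noise(ns, n, config$noise_exponent,
                                   config$noise_scale)
    if (config$white_scale > 0)
      data <- data + matrix(rnorm(ns * n, 0, config$white_scale), ns, n)
  }
  trial_recording(data, fs)
}

#' Construct a trial recording
#'
#' @param data sensor x time numeric matrix.
#' @param sampling_rate Hz.
#' @param t0 time of the first sample in seconds.
#' @return a list of class `trial_recording`.
#' @export
trial_recording <- function(data, sampling_rate, t0 = 0) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("trial data must be finite")
  structure(list(data = data, sampling_rate = sampling_rate, t0 = t0),
            class = "trial_recording")
}

#' Pass-through downsampling hook
#'
#' Decimates a trial recording by an integer factor after a moving-average
#' anti-alias prefilter. The reference pipeline simulates directly at the
#' target rate, so this hook exists for realism testing (e.g., simulating
#' at 1000 Hz and analysing at 250 Hz).
#'
#' @param trial a `trial_recording`.
#' @param factor integer decimation factor; 1 returns the input unchanged.
#' @return a `trial_recording` at `sampling_rate / factor`.
#' @export
downsample <- function(trial, factor = 1L) {
  factor <- as.integer(factor)
  if (factor == 1L) return(trial)
  if (factor < 1L) stop("decimation factor must be a positive integer")
  n <- ncol(trial$data)
  m <- floor(n / factor)
  idx <- seq_len(m * factor)
  # boxcar average within each decimation window as anti-alias prefilter
  grp <- rep(seq_len(m), each = factor)
  agg <- t(apply(trial$data[, idx, drop = FALSE], 1,
                 function(r) tapply(r, grp, mean)))
  trial_recording(agg, trial$sampling_rate / factor, trial$t0)
}

#' Simulate a cohort of subjects with per-condition effect sizes
#'
#' Draws, per subject, a multiplicative oddball gain
#' `exp(rnorm(1, 0, subject_sd))` and uniform response phases, then
#' simulates `n_trials` trials per subject and condition. The oddball
#' amplitude in condition `c` is scaled by `condition_effects[c]` (0 turns
#' the oddball response off entirely, making the condition pure
#' noise-plus-base). Every random draw is keyed by
#' [derive_seed()] on `(seed, stage, subject, condition, trial)` so cohorts
#' are bit-reproducible and extensible.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param config a [simulation_config()].
#' @param condition_effects named or unnamed numeric vector of oddball
#'   amplitude multipliers, one per condition.
#' @param seed global seed.
#' @return a list of class `fpvs_cohort` with elements `trials` (nested
#'   list `[[subject]][[condition]]` of `trial_recording`s), `ground_truth`
#'   (gains, phases, config, condition_effects, seed), `layout`.
#' @export
simulate_cohort <- function(n_subjects, config, condition_effects = 1,
                            seed = 1L) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  n_cond <- length(condition_effects)
  cond_names <- names(condition_effects)
  if (is.null(cond_names)) cond_names <- paste0("cond", seq_len(n_cond))
  gains <- numeric(n_subjects)
  phases <- vector("list", n_subjects)
  trials <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    set.seed(derive_seed(seed, "subject", s))
    gains[s] <- exp(rnorm(1, 0, config$subject_sd))
    phases[[s]] <- list(
      base = runif(length(config$base_amplitudes), 0, 2 * pi),
      oddball = runif(length(config$oddball_amplitudes), 0, 2 * pi))
    trials[[s]] <- vector("list", n_cond)
    names(trials[[s]]) <- cond_names
    for (ci in seq_len(n_cond)) {
      tl <- vector("list", config$n_trials)
      for (tr in seq_len(config$n_trials)) {
        tl[[tr]] <- simulate_trial(
          config,
          subject_gain = gains[s] * condition_effects[ci],
          phase_base = phases[[s]]$base,
          phase_oddball = phases[[s]]$oddball,
          trial_seed = derive_seed(seed, "trial", s, cond_names[ci], tr))
      }
      trials[[s]][[ci]] <- tl
    }
  }
  structure(list(
    trials = trials,
    ground_truth = list(gains = gains, phases = phases, config = config,
                        condition_effects = stats::setNames(
                          as.numeric(condition_effects), cond_names),
                        seed = as.integer(seed)),
    layout = config$layout),
    class = "fpvs_cohort")
}

#' Per-harmonic oddball amplitude yielding a target bin SNR
#'
#' For a white-noise background of per-sample sd `white_scale`, averaging
#' `n_trials` independent trials of `n_samples` samples, the expected
#' amplitude-spectrum noise floor at one bin is
#' `m = white_scale / sqrt(n_trials) * sqrt(pi / (4 * n_samples))` (Rayleigh
#' mean), and a sinusoid of amplitude A contributes A/2 at its bin. Solving
#' the Rice mean `sqrt((A/2)^2 + m^2 * 4/pi)` / m = target gives the
#' amplitude whose expected single-bin SNR is approximately `target_snr`.
#' Used to seed effects of controlled size in calibration and recovery
#' simulations.
#'
#' @param target_snr desired expected SNR at the target bin.
#' @param white_scale per-sample white-noise sd.
#' @param n_trials trials averaged before the FFT.
#' @param n_samples samples per epoch entering the FFT.
#' @return sinusoid amplitude A.
#' @export
oddball_amplitude_for_snr <- function(target_snr, white_scale, n_trials,
                                      n_samples) {
  m <- white_scale / sqrt(n_trials) * sqrt(pi / (4 * n_samples))
  if (target_snr <= 1) stop("target_snr must exceed the noise level 1")
  2 * m * sqrt(pmax(target_snr^2 - 4 / pi, 0))
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config> ", x$n_sensors, " sensors, ",
      x$trial_duration, " s @ ", x$sampling_rate, " Hz, ",
      x$n_trials, " trials\n", sep = "")
  cat("  base ", x$base_freq, " Hz (", length(x$base_amplitudes),
      " harmonics); oddball ", x$oddball_freq, " Hz (",
      length(x$oddball_amplitudes), " harmonics)\n", sep = "")
  cat("  noise: 1/f^", x$noise_exponent, " x ", x$noise_scale,
      " + white x ", x$white_scale, "; subject_sd ", x$subject_sd,
      "\n", sep = "")
  invisible(x)
}

#' @export
print.fpvs_cohort <- function(x, ...) {
  cat("<fpvs_cohort> ", length(x$trials), " subjects x ",
      length(x$trials[[1]]), " conditions x ",
      length(x$trials[[1]][[1]]), " trials (",
      x$ground_truth$config$n_sensors, " sensors)\n", sep = "")
  invisible(x)
}
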