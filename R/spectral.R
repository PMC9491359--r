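#' Trim edge artifacts and average trials into one epoch
#'
#' Crops each trial to `[head_trim, duration - tail_trim)` (trim lengths are
#' rounded to whole samples) and averages the cropped trials element-wise.
#' In the reference configuration the first two oddball cycles (1.667 s)
#' are cut from the head of each 60-s trial, producing 58.33-s epochs and
#' hence a frequency resolution of 1/58.33 = 0.0171 Hz downstream.
#' Averaging in the time domain preserves phase-locked responses while
#' attenuating non-phase-locked noise by ~ 1/sqrt(n_trials).
#'
#' @param trials a list of `trial_recording`s with identical shapes and
#'   sampling rates.
#' @param head_trim,tail_trim seconds removed from the start / end.
#' @return a list of class `epoch` with `data` (sensor x time),
#'   `sampling_rate`, `duration`, `n_samples`.
#' @export
trim_and_average <- function(trials, head_trim = 1.667, tail_trim = 0) {
  if (length(trials) == 0L) stop("empty trial list")
  if (inherits(trials, "trial_recording")) trials <- list(trials)
  fs <- trials[[1]]$sampling_rate
  dims <- dim(trials[[1]]$data)
  for (tr in trials) {
    if (tr$sampling_rate != fs || !identical(dim(tr$data), dims))
      stop("trials have mismatched shapes or sampling rates")
  }
  if (head_trim < 0 || tail_trim < 0)
    stop("trims must be non-negative")
  n <- dims[2]
  h <- as.integer(round(head_trim * fs))
  tl <- as.integer(round(tail_trim * fs))
  if (h + tl >= n)
    stop("trims remove the whole trial")
  keep <- (h + 1L):(n - tl)
  acc <- matrix(0, dims[1], length(keep))
  for (tr in trials) acc <- acc + tr$data[, keep, drop = FALSE]
  acc <- acc / length(trials)
  structure(list(data = acc, sampling_rate = fs,
                 duration = length(keep) / fs,
                 n_samples = length(keep)),
            class = "epoch")
}

#' Amplitude spectrum of an epoch
#'
#' Computes, per sensor and frequency bin, the modulus of the discrete
#' Fourier transform divided by the number of data points —
#' `sqrt(Re^2 + Im^2) / N` — with no windowing or detrending. Only the
#' one-sided grid `k / duration`, `k = 0 .. floor(N/2)`, is returned. A
#' sinusoid of amplitude A at an exact bin frequency yields A/2 at that bin.
#'
#' @param epoch an `epoch` from [trim_and_average()] (or any list with
#'   `data`, `sampling_rate`).
#' @return a list of class `amplitude_spectrum` with `values`
#'   (sensor x bin), `freq` (Hz per bin, bin spacing `1/duration`),
#'   `n_points`, `duration`.
#' @export
amplitude_spectrum <- function(epoch) {
  x <- epoch$data
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  if (n < 2) stop("epoch too short")
  X <- mvfft(t(x))
  nb <- floor(n / 2) + 1L
  vals <- t(Mod(X[seq_len(nb), , drop = FALSE])) / n
  duration <- n / epoch$sampling_rate
  structure(list(values = vals,
                 freq = (seq_len(nb) - 1L) / duration,
                 n_points = n, duration = duration),
            class = "amplitude_spectrum")
}

#' SNR spectrum by surrounding-bin normalization
#'
#' Divides each frequency bin's amplitude by the mean of the 20 surrounding
#' bins (with defaults: `n_side = 10` on either side, excluding the `gap =
#' 1` immediately adjacent bin on each side). In background noise the ratio
#' is ~1; stimulus-locked responses stand out as values > 1. Bins whose
#' full baseline window would extend beyond the grid are flagged invalid
#' (`NA`) rather than normalized by a truncated baseline.
#'
#' @param amp an [amplitude_spectrum()].
#' @param n_side baseline bins per side.
#' @param gap adjacent bins excluded per side.
#' @param exclude optional integer bins excluded from every baseline window
#'   (e.g., other harmonic bins); excluded bins reduce the baseline count.
#' @return a list of class `snr_spectrum` with `values` (sensor x bin,
#'   `NA` outside `valid_mask`), `freq`, `valid_mask`, `n_side`, `gap`.
#' @export
snr_spectrum <- function(amp, n_side = 10, gap = 1, exclude = integer()) {
  v <- amp$values
  nb <- ncol(v)
  span <- n_side + gap
  if (nb < 2 * span + 1)
    stop("spectrum too short for a ", 2 * n_side, "-bin baseline (", nb,
         " bins, need ", 2 * span + 1, ")")
  use <- matrix(1, nrow(v), nb)
  if (length(exclude)) use[, exclude] <- 0
  base_sum <- matrix(0, nrow(v), nb)
  base_cnt <- matrix(0, nrow(v), nb)
  for (o in (gap + 1L):span) {
    for (sgn in c(-1L, 1L)) {
      src <- seq_len(nb) + sgn * o
      inside <- src >= 1L & src <= nb
      base_sum[, inside] <- base_sum[, inside] +
        v[, src[inside], drop = FALSE] * use[, src[inside], drop = FALSE]
      base_cnt[, inside] <- base_cnt[, inside] + use[, src[inside],
                                                     drop = FALSE]
    }
  }
  valid <- seq_len(nb) > span & seq_len(nb) <= nb - span
  snr <- v / (base_sum / pmax(base_cnt, 1))
  snr[, !valid] <- NA_real_
  structure(list(values = snr, freq = amp$freq, valid_mask = valid,
                 n_side = n_side, gap = gap, exclude = exclude),
            class = "snr_spectrum")
}

#' Locate the oddball fundamental and harmonic bins on a frequency grid
#'
#' Finds the grid bin nearest to the nominal oddball frequency; its *realized*
#' frequency defines the fundamental, and the targets are the bins nearest
#' to `h x` the realized fundamental for `h = 1 .. n_harmonics` (the
#' fundamental plus its first `n_harmonics - 1` harmonics). Ties between
#' two equidistant bins break to the lower bin.
#'
#' @param freq_grid ascending numeric vector of bin frequencies (Hz).
#' @param oddball_freq nominal oddball frequency (Hz).
#' @param n_harmonics number of target bins (default 4: the fundamental and
#'   its first three harmonics).
#' @return a list of class `oddball_targets` with integer `bins`, realized
#'   `freqs`, and `fundamental` (realized, Hz).
#' @export
oddball_bins <- function(freq_grid, oddball_freq, n_harmonics = 4) {
  nearest <- function(target) {
    d <- abs(freq_grid - target)
    which(d <= min(d) + 1e-12)[1]      # ties -> lower bin
  }
  spacing <- if (length(freq_grid) > 1) diff(freq_grid[1:2]) else Inf
  k1 <- nearest(oddball_freq)
  f1 <- freq_grid[k1]
  targets <- (1:n_harmonics) * f1
  if (max(targets) > max(freq_grid) + spacing / 2)
    stop("harmonic target ", max(targets), " Hz beyond the frequency grid")
  bins <- vapply(targets, nearest, integer(1))
  structure(list(bins = bins, freqs = freq_grid[bins], fundamental = f1),
            class = "oddball_targets")
}

#' Per-sensor oddball response: mean SNR over the target bins
#'
#' @param snr an [snr_spectrum()].
#' @param targets an [oddball_bins()] result (or integer bin vector).
#' @return a named numeric vector (one value per sensor) with attributes
#'   `target_bins` and `target_freqs`, of class `oddball_response`.
#' @export
oddball_response <- function(snr, targets) {
  bins <- if (inherits(targets, "oddball_targets")) targets$bins
  else as.integer(targets)
  bad <- bins[!snr$valid_mask[bins]]
  if (length(bad))
    stop("target bin(s) without a full baseline window: ",
         paste(bad, collapse = ", "))
  out <- rowMeans(snr$values[, bins, drop = FALSE])
  structure(out, target_bins = bins, target_freqs = snr$freq[bins],
            class = "oddball_response")
}

#' Interpolate bad channels from their neighbors
#'
#' Replaces each bad sensor's time course by the inverse-distance-weighted
#' mean (3D sensor distances) of its *good* neighbors under the adjacency
#' graph. Good channels are untouched. Interpolation uses only original
#' (pre-interpolation) data, so the result does not depend on the order of
#' bad channels.
#'
#' @param trial a `trial_recording`.
#' @param bad character sensor ids or integer indices of bad channels.
#' @param adjacency an [build_adjacency()] graph over the same layout.
#' @param layout the `sensor_layout` (for distances).
#' @return a `trial_recording` with bad rows replaced.
#' @export
interpolate_channels <- function(trial, bad, adjacency, layout) {
  if (length(bad) == 0L) return(trial)
  idx <- if (is.character(bad)) match(bad, layout$sensor) else as.integer(bad)
  if (anyNA(idx) || any(idx < 1 | idx > nrow(layout)))
    stop("bad channels not in layout")
  P <- as.matrix(layout[, c("x", "y", "z")])
  good <- setdiff(seq_len(nrow(layout)), idx)
  A <- adjacency$matrix
  out <- trial$data
  for (b in idx) {
    nb <- intersect(which(A[b, ]), good)
    if (length(nb) == 0L)
      stop("isolated bad sensor ", layout$sensor[b],
           ": no good neighbor to interpolate from")
    d <- sqrt(colSums((t(P[nb, , drop = FALSE]) - P[b, ])^2))
    w <- 1 / pmax(d, .Machine$double.eps)
    w <- w / sum(w)
    out[b, ] <- crossprod(trial$data[nb, , drop = FALSE], w)[, 1]
  }
  trial_recording(out, trial$sampling_rate, trial$t0)
}

#' Assemble a subjects x conditions x sensors response dataset
#'
#' Runs the full spectral chain (trim and average, amplitude spectrum, SNR
#' normalization, harmonic targeting, mean over target bins) for every
#' subject and condition of a simulated cohort. The adult-scale design
#' (28 subjects x 5 conditions x 160 sensors) yields 22,400 scalars, the
#' child-scale design (17 x 3 x 160) 8,160.
#'
#' @param cohort an [simulate_cohort()] result.
#' @param head_trim,tail_trim passed to [trim_and_average()].
#' @param n_side,gap passed to [snr_spectrum()].
#' @param n_harmonics passed to [oddball_bins()].
#' @return a 3D array (subject x condition x sensor) of class
#'   `response_dataset`, with attributes `target_freqs` and `freq_resolution`.
#' @export
response_dataset <- function(cohort, head_trim = 1.667, tail_trim = 0,
                             n_side = 10, gap = 1, n_harmonics = 4) {
  cfg <- cohort$ground_truth$config
  n_sub <- length(cohort$trials)
  cond_names <- names(cohort$trials[[1]])
  n_cond <- length(cond_names)
  out <- array(NA_real_, c(n_sub, n_cond, cfg$n_sensors),
               dimnames = list(paste0("subj", seq_len(n_sub)), cond_names,
                               cohort$layout$sensor))
  tf <- NULL
  fres <- NULL
  for (s in seq_len(n_sub)) {
    for (ci in seq_len(n_cond)) {
      ep <- trim_and_average(cohort$trials[[s]][[ci]], head_trim, tail_trim)
      amp <- amplitude_spectrum(ep)
      snr <- snr_spectrum(amp, n_side = n_side, gap = gap)
      targets <- oddball_bins(amp$freq, cfg$oddball_freq, n_harmonics)
      out[s, ci, ] <- as.numeric(oddball_response(snr, targets))
      if (is.null(tf)) {
        tf <- targets$freqs
        fres <- amp$freq[2] - amp$freq[1]
      }
    }
  }
  structure(out, target_freqs = tf, freq_resolution = fres,
            class = c("response_dataset", "array"))
}

#' Long-format export of a response dataset
#'
#' @param x a `response_dataset` array.
#' @param ... unused.
#' @return data.frame with columns `subject`, `condition`, `sensor`,
#'   `response`.
#' @export
as.data.frame.response_dataset <- function(x, ...) {
  dn <- dimnames(x)
  g <- expand.grid(subject = dn[[1]], condition = dn[[2]], sensor = dn[[3]],
                   stringsAsFactors = FALSE)
  g$response <- as.vector(unclass(x))
  g
}

#' Write a response dataset as tab-delimited long-format text
#'
#' @param x a `response_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_response_dataset <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
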