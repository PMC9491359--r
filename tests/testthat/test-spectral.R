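test_that("trim arithmetic reproduces the 58.33-s epoch and 0.0171-Hz grid", {
  # 60-s trials at 250 Hz, first two oddball cycles (1.667 s) cut
  cfg <- noise_config(n_sensors = 4, fs = 250, dur = 60, white = 0, pink = 0)
  tr <- simulate_trial(cfg, trial_seed = 1)
  ep <- trim_and_average(list(tr), head_trim = 1.667, tail_trim = 0)
  expect_equal(ep$duration, 58.332, tolerance = 1e-9)
  amp <- amplitude_spectrum(ep)
  expect_equal(round(amp$freq[2] - amp$freq[1], 4), 0.0171)
})

test_that("averaging identical trials is the identity; x and -x cancel", {
  set.seed(5)
  x <- matrix(rnorm(40), 4, 10)
  tr <- trial_recording(x, 10)
  ep <- trim_and_average(list(tr, tr, tr), 0, 0)
  expect_equal(ep$data, x)
  tr2 <- trial_recording(-x, 10)
  ep2 <- trim_and_average(list(tr, tr2), 0, 0)
  expect_true(all(ep2$data == 0))
})

test_that("trim_and_average validates inputs", {
  x <- trial_recording(matrix(0, 2, 10), 10)
  y <- trial_recording(matrix(0, 3, 10), 10)
  expect_error(trim_and_average(list()), "empty")
  expect_error(trim_and_average(list(x, y)), "mismatched")
  expect_error(trim_and_average(list(x), head_trim = 1, tail_trim = 1),
               "whole trial")
})

test_that("amplitude spectrum implements |FFT|/N with DC and exact bins", {
  fs <- 100; dur <- 10
  tt <- (0:(fs * dur - 1)) / fs
  A <- 2.4; c0 <- 1.3
  x <- rbind(A * cos(2 * pi * 3 * tt + 0.7), rep(c0, fs * dur))
  amp <- amplitude_spectrum(matrix_epoch(x, fs))
  k <- which(amp$freq == 3)
  expect_equal(amp$values[1, k], A / 2, tolerance = 1e-12)
  expect_equal(amp$values[2, 1], c0, tolerance = 1e-12)  # DC bin
  expect_lt(max(amp$values[1, -k][-1]), 1e-12)
  expect_equal(amp$freq[2], 1 / dur)
})

test_that("flat spectra normalize to SNR 1 at every interior bin", {
  amp <- structure(list(values = matrix(2.5, 3, 200),
                        freq = (0:199) / 10, n_points = 400, duration = 10),
                   class = "amplitude_spectrum")
  snr <- snr_spectrum(amp)
  expect_true(all(abs(snr$values[, snr$valid_mask] - 1) < 1e-12))
  expect_true(all(is.na(snr$values[, !snr$valid_mask])))
  # edge bins lack a full baseline: 11 on each side
  expect_equal(sum(!snr$valid_mask), 22L)
})

test_that("a single peak over a unit baseline gets SNR equal to its height", {
  v <- matrix(1, 1, 100)
  v[1, 50] <- 21
  amp <- structure(list(values = v, freq = (0:99) / 10, n_points = 200,
                        duration = 10), class = "amplitude_spectrum")
  snr <- snr_spectrum(amp, n_side = 10, gap = 1)
  expect_equal(snr$values[1, 50], 21)
  # far-away bins are untouched
  expect_equal(snr$values[1, 30], 1)
  # the peak sits in the baseline of bins 2..11 bins away, deflating them
  expect_equal(snr$values[1, 45], 1 / ((21 + 19) / 20), tolerance = 1e-12)
  # ... but not of the immediately adjacent bin (gap exclusion)
  expect_equal(snr$values[1, 49], 1, tolerance = 1e-12)
})

test_that("SNR is invariant to rescaling the epoch", {
  set.seed(8)
  x <- matrix(rnorm(2 * 1000), 2, 1000)
  a1 <- amplitude_spectrum(matrix_epoch(x, 50))
  a2 <- amplitude_spectrum(matrix_epoch(x * 37.5, 50))
  s1 <- snr_spectrum(a1)
  s2 <- snr_spectrum(a2)
  expect_equal(s1$values[, s1$valid_mask], s2$values[, s2$valid_mask],
               tolerance = 1e-12)
})

test_that("baseline exclusion mask removes chosen bins from baselines", {
  v <- matrix(1, 1, 100)
  v[1, 52] <- 41   # a contaminating peak near the bin under test
  amp <- structure(list(values = v, freq = (0:99) / 10, n_points = 200,
                        duration = 10), class = "amplitude_spectrum")
  plain <- snr_spectrum(amp)
  masked <- snr_spectrum(amp, exclude = 52L)
  expect_lt(plain$values[1, 50], 1)
  expect_equal(masked$values[1, 50], 1, tolerance = 1e-12)
})

test_that("white-noise SNR averages to 1 over seeds (Monte Carlo)", {
  ms <- vapply(1:50, function(seed) {
    cfg <- noise_config(n_sensors = 4, fs = 50, dur = 20)
    tr <- simulate_trial(cfg, trial_seed = derive_seed(1234, "wn", seed))
    s <- snr_spectrum(amplitude_spectrum(trim_and_average(list(tr), 0, 0)))
    mean(s$values[, s$valid_mask])
  }, numeric(1))
  expect_lt(abs(mean(ms) - 1), 0.05)
})

test_that("harmonic targets derive from the realized fundamental bin", {
  grid <- (0:2000) * (1.1962 / 70)   # grid whose bin 71 is 1.1962 Hz
  ob <- oddball_bins(grid, 1.2, 4)
  expect_equal(ob$fundamental, 1.1962, tolerance = 1e-9)
  expect_equal(round(ob$freqs, 4), c(1.1962, 2.3924, 3.5886, 4.7848))
  # nearest-bin arithmetic and the documented lower tie-break
  expect_equal(oddball_bins(seq(0, 10, 0.1), 0.26, 1)$freqs, 0.3)
  expect_equal(oddball_bins(seq(0, 10, 0.1), 0.25, 1)$freqs, 0.2)
  expect_error(oddball_bins(seq(0, 2, 0.1), 1.2, 4), "beyond")
})

test_that("oddball response is the mean SNR over target bins", {
  v <- matrix(1, 2, 120)
  v[1, c(30, 40, 50, 60)] <- c(2, 2, 2, 2)
  v[2, c(30, 40, 50, 60)] <- c(1, 2, 3, 4)
  snr <- list(values = v, freq = (0:119) / 10,
              valid_mask = c(rep(FALSE, 11), rep(TRUE, 98), rep(FALSE, 11)))
  class(snr) <- "snr_spectrum"
  r <- oddball_response(snr, c(30L, 40L, 50L, 60L))
  expect_equal(as.numeric(r), c(2, 2.5))
  expect_error(oddball_response(snr, c(5L, 40L)), "baseline")
})

test_that("trial averaging shrinks noise bins ~1/sqrt(N), not signal bins", {
  lay <- make_layout(4)
  cfg <- simulation_config(n_sensors = 4, sampling_rate = 50,
                           trial_duration = 20, n_trials = 1,
                           base_amplitudes = 0, oddball_amplitudes = 1,
                           topography = rep(1, 4),
                           base_topography = rep(0, 4),
                           noise_scale = 0, white_scale = 1, layout = lay)
  noise_level <- function(N) {
    m <- vapply(1:12, function(rep) {
      trials <- lapply(1:N, function(i)
        simulate_trial(cfg, phase_oddball = 0.9,
                       trial_seed = derive_seed(55, "avg", N, rep, i)))
      amp <- amplitude_spectrum(trim_and_average(trials, 0, 0))
      k <- oddball_bins(amp$freq, 1.2, 1)$bins
      c(noise = mean(amp$values[, setdiff(100:300, k)]),
        signal = mean(amp$values[, k]))
    }, numeric(2))
    rowMeans(m)
  }
  l1 <- noise_level(1); l4 <- noise_level(4); l16 <- noise_level(16)
  expect_equal(unname(l1["noise"] / l4["noise"]), 2, tolerance = 0.15)
  expect_equal(unname(l4["noise"] / l16["noise"]), 2, tolerance = 0.15)
  expect_equal(unname(l1["signal"]), 0.5, tolerance = 0.05)
  expect_equal(unname(l16["signal"]), 0.5, tolerance = 0.01)
})

test_that("bad channels are rebuilt from inverse-distance-weighted neighbors", {
  lay <- make_layout(12)
  adj <- build_adjacency(lay)
  set.seed(3)
  x <- matrix(rnorm(12 * 50), 12, 50)
  tr <- trial_recording(x, 50)
  # neighbors all carrying the same signal -> exact reconstruction
  b <- 5L
  nb <- which(adj$matrix[b, ])
  x2 <- x
  x2[nb, ] <- matrix(rep(sin(1:50), length(nb)), length(nb), byrow = TRUE)
  tr2 <- trial_recording(x2, 50)
  out <- interpolate_channels(tr2, b, adj, lay)
  expect_equal(out$data[b, ], sin(1:50), tolerance = 1e-12)
  expect_equal(out$data[-b, ], x2[-b, ])  # good rows untouched
  # empty bad set is the identity
  expect_identical(interpolate_channels(tr, integer(), adj, lay), tr)
  # all neighbors bad -> isolated error
  expect_error(interpolate_channels(tr, c(b, nb), adj, lay), "isolated")
})

test_that("two equidistant neighbors with values 0 and 2 average to 1", {
  lay <- data.frame(sensor = paste0("S", 1:4),
                    x = c(0, 1, -1, 0), y = c(0, 0, 0, 1),
                    z = c(1, 0, 0, 0),
                    px = c(0, 1, -1, 0), py = c(0, 0, 0, 1))
  class(lay) <- c("sensor_layout", "data.frame")
  adj <- build_adjacency(lay)
  x <- rbind(rep(9, 10), rep(0, 10), rep(2, 10), rep(9, 10))
  # restrict sensor 1's neighbors to 2 and 3 (equidistant)
  adj$matrix[1, ] <- c(FALSE, TRUE, TRUE, FALSE)
  adj$matrix[, 1] <- c(FALSE, TRUE, TRUE, FALSE)
  out <- interpolate_channels(trial_recording(x, 10), 1L, adj, lay)
  expect_equal(out$data[1, ], rep(1, 10))
})

test_that("response datasets have subjects x conditions x sensors scalars", {
  lay <- make_layout(6)
  cfg <- simulation_config(n_sensors = 6, sampling_rate = 50,
                           trial_duration = 10, n_trials = 2,
                           base_amplitudes = 0.2,
                           oddball_amplitudes = rep(0.2, 4),
                           topography = rep(1, 6),
                           base_topography = rep(1, 6),
                           noise_scale = 0.5, white_scale = 0.5,
                           layout = lay)
  co <- simulate_cohort(3, cfg, condition_effects = c(a = 1, b = 0), seed = 4)
  rd <- response_dataset(co, head_trim = 0.833)
  expect_equal(dim(rd), c(3L, 2L, 6L))
  expect_equal(length(rd), 36L)
  long <- as.data.frame(rd)
  expect_equal(nrow(long), 36L)
  expect_true(all(is.finite(long$response)))
  f <- tempfile(fileext = ".tsv")
  write_response_dataset(rd, f)
  expect_equal(nrow(read.delim(f)), 36L)
  unlink(f)
})
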