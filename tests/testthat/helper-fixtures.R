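# Shared small fixtures, built in code at test time.

# tiny inventory: 2 items per role, subsets of 1
tiny_inventory <- function() {
  morpheme_inventory(data.frame(
    text = c("abcd", "efgh", "ijkl", "mnop",
             "qrs", "tuv", "wxy", "zab"),
    role = rep(c("stem", "nonstem", "suffix", "nonsuffix"), each = 2),
    subset = rep(c("A", "B"), 4)))
}

# synthetic inventory with s items per role per subset (2 subsets)
sized_inventory <- function(s) {
  mk <- function(n, len, prefix) {
    stopifnot(n <= 26)
    vapply(seq_len(n), function(i)
      paste(rep(letters[i], len - nchar(prefix)), collapse = ""), "")
  }
  roles <- c("stem", "nonstem", "suffix", "nonsuffix")
  pre <- c(stem = "s", nonstem = "n", suffix = "u", nonsuffix = "x")
  rows <- do.call(rbind, lapply(roles, function(r) {
    len <- if (r %in% c("stem", "nonstem")) 4L else 3L
    txt <- paste0(pre[r], vapply(seq_len(2 * s), function(i)
      paste(rep(letters[i], len - 1L), collapse = ""), ""))
    data.frame(text = txt, role = r,
               subset = rep(c("A", "B"), each = s))
  }))
  morpheme_inventory(rows)
}

# epoch wrapping a plain matrix
matrix_epoch <- function(data, fs) {
  structure(list(data = data, sampling_rate = fs,
                 duration = ncol(data) / fs, n_samples = ncol(data)),
            class = "epoch")
}

# noise-only simulation config on a small layout
noise_config <- function(n_sensors = 4, fs = 50, dur = 20,
                         pink = 0, white = 1, layout = NULL) {
  simulation_config(
    n_sensors = n_sensors, sampling_rate = fs, trial_duration = dur,
    n_trials = 1, base_amplitudes = 0, oddball_amplitudes = 0,
    topography = rep(0, n_sensors), base_topography = rep(0, n_sensors),
    noise_exponent = 1, noise_scale = pink, white_scale = white,
    layout = layout %||% make_layout(n_sensors))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
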