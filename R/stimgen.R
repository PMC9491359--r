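#' Morpheme roles and pseudoword types
#'
#' Stimuli are 7-letter pseudowords built from a 4-letter left constituent
#' (a real English stem such as "soft", or a matched nonstem such as "terp")
#' and a 3-letter right constituent (a real derivational suffix such as
#' "ity", or a matched non-morphemic ending such as "ert"). The four
#' crossings of left x right roles define the stimulus types.
#'
#' @format Character vectors.
#' @name morpheme-roles
NULL

#' @rdname morpheme-roles
#' @export
MORPHEME_ROLES <- c("stem", "nonstem", "suffix", "nonsuffix")

#' @rdname morpheme-roles
#' @export
STIM_TYPES <- c("stem+suffix", "nonstem+suffix", "stem+nonsuffix",
                "nonstem+nonsuffix")

.role_lengths <- c(stem = 4L, nonstem = 4L, suffix = 3L, nonsuffix = 3L)

#' Construct a morpheme inventory
#'
#' An inventory is a table of morphemes (columns `text`, `role`, `subset`)
#' validated against the design constraints: stems/nonstems are 4 lowercase
#' letters, suffixes/nonsuffixes 3; every role has the same number of items;
#' each role is partitioned into equally sized subsets; no duplicated text
#' within a role. Pseudowords are later formed only within a subset, so that
#' each subset's full crossing yields `s^2` combinations per type.
#'
#' @param x a data.frame with character columns `text`, `role`, `subset`.
#' @return the validated data.frame with class `morpheme_inventory` and an
#'   attribute `subset_size` (items per role per subset).
#' @seealso [read_inventory()], [adult_inventory()], [child_inventory()],
#'   [build_combinations()]
#' @export
morpheme_inventory <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("text", "role", "subset")
  if (!all(need %in% names(x)))
    stop("invalid inventory: need columns ", paste(need, collapse = ", "))
  x$text <- as.character(x$text)
  x$role <- as.character(x$role)
  x$subset <- as.character(x$subset)
  if (!all(x$role %in% MORPHEME_ROLES))
    stop("invalid inventory: unknown role(s): ",
         paste(setdiff(unique(x$role), MORPHEME_ROLES), collapse = ", "))
  if (!all(grepl("^[a-z]+$", x$text)))
    stop("invalid inventory: text must be lowercase alphabetic")
  bad_len <- nchar(x$text) != .role_lengths[x$role]
  if (any(bad_len))
    stop("invalid inventory: wrong length for ",
         paste(x$text[bad_len], collapse = ", "),
         " (stems/nonstems are 4 letters, suffixes/nonsuffixes 3)")
  per_role <- table(x$role)
  if (length(unique(as.vector(per_role))) != 1L)
    stop("invalid inventory: every role must have the same item count")
  for (r in unique(x$role)) {
    xr <- x[x$role == r, ]
    if (anyDuplicated(xr$text))
      stop("invalid inventory: duplicated text within role ", r)
    sizes <- table(xr$subset)
    if (length(unique(as.vector(sizes))) != 1L)
      stop("invalid inventory: role ", r,
           " has unequally sized subsets")
  }
  subs <- sort(unique(x$subset))
  attr(x, "subset_size") <- sum(x$role == x$role[1] & x$subset == subs[1])
  class(x) <- c("morpheme_inventory", "data.frame")
  x
}

#' Read a morpheme inventory from delimited text
#'
#' Expects a tab-delimited file with columns `text`, `role`, `subset` (extra
#' columns are kept but ignored by the validator).
#'
#' @param path file path.
#' @return a [morpheme_inventory()].
#' @export
read_inventory <- function(path) {
  morpheme_inventory(read.delim(path, stringsAsFactors = FALSE))
}

#' Bundled morpheme inventories
#'
#' `adult_inventory()` returns the full inventory (12 items per role, two
#' subsets of 6). `child_inventory()` returns the reduced inventory used
#' with developing readers (6 items per role, two subsets of 3). Both are
#' read from the building-block table shipped in `inst/extdata/`.
#'
#' @return a [morpheme_inventory()].
#' @export
adult_inventory <- function() {
  path <- system.file("extdata", "morpheme_inventory.tsv", package = "fpvs",
                      mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  morpheme_inventory(tab[, c("text", "role", "subset")])
}

#' @rdname adult_inventory
#' @export
child_inventory <- function() {
  path <- system.file("extdata", "morpheme_inventory.tsv", package = "fpvs",
                      mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab <- tab[!is.na(tab$child_subset) & tab$child_subset != "", ]
  tab$subset <- tab$child_subset
  morpheme_inventory(tab[, c("text", "role", "subset")])
}

.split_type <- function(stim_type) {
  parts <- strsplit(stim_type, "+", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% c("stem", "nonstem") ||
      !parts[2] %in% c("suffix", "nonsuffix"))
    stop("unknown stimulus type: ", stim_type)
  parts
}

#' Build pseudoword combinations from an inventory
#'
#' For each requested stimulus type, crosses every left constituent with
#' every right constituent *within the same subset*. With subset size `s`
#' and two subsets this yields exactly `2 * s^2` unique pseudowords per
#' type: 72 per type (288 total over the four types) for the full
#' 12-per-role inventory, 18 per type for the reduced 6-per-role inventory.
#' Output order is deterministic given the inventory row order.
#'
#' @param inventory a [morpheme_inventory()].
#' @param stim_types character vector, a subset of [STIM_TYPES].
#' @return a data.frame of class `pseudoword_set` with columns `left`,
#'   `right`, `text` (the 7-letter concatenation), `stim_type`, `subset`.
#' @examples
#' combos <- build_combinations(adult_inventory(), STIM_TYPES)
#' table(combos$stim_type) # 72 of each
#' @export
build_combinations <- function(inventory, stim_types = STIM_TYPES) {
  if (!inherits(inventory, "morpheme_inventory"))
    inventory <- morpheme_inventory(inventory)
  stim_types <- unique(stim_types)
  out <- vector("list", length(stim_types))
  for (i in seq_along(stim_types)) {
    parts <- .split_type(stim_types[i])
    pieces <- list()
    for (s in sort(unique(inventory$subset))) {
      left <- inventory$text[inventory$role == parts[1] &
                               inventory$subset == s]
      right <- inventory$text[inventory$role == parts[2] &
                                inventory$subset == s]
      if (length(left) == 0L || length(right) == 0L)
        stop("invalid inventory: role ", parts[1], " or ", parts[2],
             " missing from subset ", s)
      g <- expand.grid(right = right, left = left,
                       stringsAsFactors = FALSE)[, c("left", "right")]
      g$subset <- s
      pieces[[s]] <- g
    }
    g <- do.call(rbind, pieces)
    g$text <- paste0(g$left, g$right)
    g$stim_type <- stim_types[i]
    out[[i]] <- g
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (anyDuplicated(out$text))
    stop("collision: duplicated rendered text across combinations: ",
         paste(unique(out$text[duplicated(out$text)]), collapse = ", "))
  stopifnot(all(nchar(out$text) == 7L))
  out <- out[, c("left", "right", "text", "stim_type", "subset")]
  class(out) <- c("pseudoword_set", "data.frame")
  out
}

#' Experimental condition specifications
#'
#' Five oddball/base pairings are defined. Condition 0 is the
#' manipulation-check condition (real 4-letter words embedded in
#' non-pronounceable consonant strings). Conditions 1-4 embed one
#' pseudoword type in another so that an oddball response indexes stem
#' identification (1: stem+suffix in nonstem+suffix; 2: stem+nonsuffix in
#' nonstem+nonsuffix) or suffix identification (3: stem+suffix in
#' stem+nonsuffix; 4: nonstem+nonsuffix in nonstem+suffix).
#'
#' @param id integer 0-4.
#' @return a list with elements `id`, `oddball_type`, `base_type`, of class
#'   `condition_spec`.
#' @export
condition_spec <- function(id) {
  id <- as.integer(id)
  specs <- list(
    `0` = c("word", "consonant_string"),
    `1` = c("stem+suffix", "nonstem+suffix"),
    `2` = c("stem+nonsuffix", "nonstem+nonsuffix"),
    `3` = c("stem+suffix", "stem+nonsuffix"),
    `4` = c("nonstem+nonsuffix", "nonstem+suffix")
  )
  if (!as.character(id) %in% names(specs))
    stop("condition id must be 0-4, got ", id)
  s <- specs[[as.character(id)]]
  stopifnot(s[1] != s[2])
  structure(list(id = id, oddball_type = s[1], base_type = s[2]),
            class = "condition_spec")
}

#' Word and consonant-string pools for the manipulation-check condition
#'
#' Returns the stimulus pools for condition 0: 72 four-letter words (ending
#' in a consonant) as oddballs and 72 four-consonant strings as base items;
#' the child scenario uses the first 18 of each. These lists are a synthetic
#' stand-in shipped with the package (see
#' `inst/extdata/condition0_pools_synthetic.tsv`); their lexical statistics
#' are not matched to any database.
#'
#' @param scenario `"adult"` (72 + 72) or `"child"` (18 + 18).
#' @return a list with character vectors `words` and `consonant_strings`.
#' @export
condition0_pools <- function(scenario = c("adult", "child")) {
  scenario <- match.arg(scenario)
  path <- system.file("extdata", "condition0_pools_synthetic.tsv",
                      package = "fpvs", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  words <- tab$text[tab$role == "word"]
  cons <- tab$text[tab$role == "consonant_string"]
  if (scenario == "child") {
    words <- words[1:18]
    cons <- cons[1:18]
  }
  list(words = words, consonant_strings = cons)
}

#' Generate a periodic oddball stimulation sequence
#'
#' Builds a `duration * base_rate`-item stream in which every
#' `oddball_period`-th item (1-based positions `n, 2n, ...`) is drawn from
#' `oddball_pool` and all other items from `base_pool`, subject to the
#' repetition constraint that identical texts never occur at an index
#' distance smaller than `oddball_period` (no repetition within one oddball
#' cycle, i.e. within 1 s at 6 Hz / period 5).
#'
#' Two oddball policies are supported. `"unique"` fills the oddball slots
#' with distinct items (a random permutation when the pool size equals the
#' slot count, as in the adult design: 72 unique oddballs). `"k_repeats"`
#' requires `length(oddball_pool) * k == n_slots` and delivers each oddball
#' exactly `k` times (child design: 18 oddballs x 4). Base items are drawn
#' uniformly with replacement subject to the distance constraint, by
#' rejection sampling with a bounded number of retries.
#'
#' @param cond a [condition_spec()] (recorded in the output; pools are
#'   passed explicitly).
#' @param oddball_pool,base_pool character vectors of stimulus texts.
#' @param duration trial duration in seconds.
#' @param base_rate stimulation rate in Hz.
#' @param oddball_period oddball every n-th item.
#' @param repetition_policy `"unique"` or `"k_repeats"`.
#' @param seed integer seed; the same seed reproduces the same sequence.
#' @param max_retries rejection-sampling cap per slot before failing.
#' @return a list of class `stimulus_sequence` with elements `tokens`,
#'   `is_oddball`, `oddball_positions`, `onsets_s`, `base_rate`,
#'   `oddball_period`, `duration`, `condition`, `seed`.
#' @examples
#' cond <- condition_spec(1)
#' combos <- build_combinations(adult_inventory(), STIM_TYPES)
#' odd <- combos$text[combos$stim_type == cond$oddball_type]
#' base <- combos$text[combos$stim_type == cond$base_type]
#' s <- generate_sequence(cond, odd, base, duration = 60, seed = 1)
#' length(s$tokens) # 360
#' @export
generate_sequence <- function(cond, oddball_pool, base_pool,
                              duration = 60, base_rate = 6,
                              oddball_period = 5,
                              repetition_policy = c("unique", "k_repeats"),
                              seed = 1L, max_retries = 1000L) {
  repetition_policy <- match.arg(repetition_policy)
  if (length(oddball_pool) == 0L || length(base_pool) == 0L)
    stop("stimulus pools must be non-empty")
  n_tokens <- duration * base_rate
  if (abs(n_tokens - round(n_tokens)) > 1e-9)
    stop("duration * base_rate must be an integer token count")
  n_tokens <- as.integer(round(n_tokens))
  positions <- seq_len(n_tokens)
  oddball_positions <- positions[positions %% oddball_period == 0L]
  n_odd <- length(oddball_positions)
  n_base <- n_tokens - n_odd

  set.seed(as.integer(seed))
  if (repetition_policy == "unique") {
    if (length(oddball_pool) < n_odd)
      stop("generation failure (unique-oddball policy): pool of ",
           length(oddball_pool), " cannot fill ", n_odd, " oddball slots")
    odd_tokens <- sample(oddball_pool, n_odd, replace = FALSE)
  } else {
    k <- n_odd / length(oddball_pool)
    if (abs(k - round(k)) > 1e-9)
      stop("generation failure (k-repetition policy): pool size ",
           length(oddball_pool), " does not divide ", n_odd, " slots")
    k <- as.integer(round(k))
    odd_tokens <- sample(rep(oddball_pool, k))
  }

  tokens <- character(n_tokens)
  tokens[oddball_positions] <- odd_tokens
  # base slots, filled left to right; each draw must differ from every
  # already-placed token within oddball_period - 1 positions on either side
  for (i in positions[positions %% oddball_period != 0L]) {
    lo <- max(1L, i - (oddball_period - 1L))
    hi <- min(n_tokens, i + (oddball_period - 1L))
    nearby <- tokens[lo:hi]
    ok <- FALSE
    for (r in seq_len(max_retries)) {
      cand <- sample(base_pool, 1L)
      if (!cand %in% nearby) {
        tokens[i] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("generation failure: min-repetition-distance constraint ",
           "unsatisfiable at position ", i, " after ", max_retries,
           " retries")
  }

  seq_out <- structure(
    list(tokens = tokens,
         is_oddball = positions %in% oddball_positions,
         oddball_positions = oddball_positions,
         onsets_s = (positions - 1L) / base_rate,
         base_rate = base_rate,
         oddball_period = as.integer(oddball_period),
         duration = duration,
         condition = if (inherits(cond, "condition_spec")) cond else NULL,
         seed = as.integer(seed)),
    class = "stimulus_sequence")
  viol <- check_repetition_distance(seq_out)
  if (nrow(viol) > 0L)
    stop("generation failure: min-repetition-distance constraint violated ",
         "at positions ", viol$i[1], "/", viol$j[1])
  seq_out
}

#' Exhaustively check the minimum repetition distance of a sequence
#'
#' Brute-force scan over all index pairs closer than the oddball period;
#' returns the violating pairs (empty for a valid sequence). Used as an
#' independent verification of [generate_sequence()].
#'
#' @param seq a `stimulus_sequence`.
#' @param min_distance minimum allowed distance between identical texts;
#'   defaults to the sequence's oddball period.
#' @return data.frame with columns `i`, `j`, `text`.
#' @export
check_repetition_distance <- function(seq, min_distance = seq$oddball_period) {
  tokens <- seq$tokens
  n <- length(tokens)
  viol <- list()
  for (d in seq_len(min_distance - 1L)) {
    idx <- which(tokens[seq_len(n - d)] == tokens[seq_len(n - d) + d])
    if (length(idx))
      viol[[length(viol) + 1L]] <-
        data.frame(i = idx, j = idx + d, text = tokens[idx])
  }
  if (length(viol)) do.call(rbind, viol)
  else data.frame(i = integer(), j = integer(), text = character())
}

#' Sinusoidal contrast envelope within one stimulation cycle
#'
#' Each stimulus appears through sinusoidal contrast modulation: contrast
#' rises from 0 at cycle onset to full contrast at half cycle (83.5 ms into
#' the 167-ms cycle at 6 Hz) and back to 0, following
#' `(1 - cos(2 * pi * t / cycle_duration)) / 2`.
#'
#' @param t time(s) in seconds within the cycle, `0 <= t <= cycle_duration`.
#' @param cycle_duration cycle length in seconds (1/6 s at 6 Hz).
#' @return contrast value(s) in `[0, 1]`.
#' @export
contrast_envelope <- function(t, cycle_duration = 1 / 6) {
  if (any(t < 0 | t > cycle_duration))
    stop("t outside the stimulation cycle [0, ", cycle_duration, "]")
  (1 - cos(2 * pi * t / cycle_duration)) / 2
}

#' Write a stimulation sequence to delimited text
#'
#' Writes a tab-delimited table (`index`, `token`, `is_oddball`, `onset_s`)
#' plus a JSON sidecar `<path>.json` echoing the generation parameters.
#'
#' @param seq a `stimulus_sequence`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  tab <- data.frame(index = seq_along(seq$tokens),
                    token = seq$tokens,
                    is_oddball = seq$is_oddball,
                    onset_s = seq$onsets_s)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(base_rate = seq$base_rate,
               oddball_period = seq$oddball_period,
               duration = seq$duration,
               seed = seq$seed,
               condition = if (!is.null(seq$condition))
                 unclass(seq$condition) else NULL)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat("<stimulus_sequence> ", length(x$tokens), " tokens @ ", x$base_rate,
      " Hz (", x$duration, " s), ", length(x$oddball_positions),
      " oddballs every ", x$oddball_period, "th item\n", sep = "")
  cat("  head:", paste(head(x$tokens, 10), collapse = " "), "...\n")
  invisible(x)
}
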