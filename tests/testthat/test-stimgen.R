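test_that("combination counts follow 2*s^2 per type for subset sizes 1..6", {
  for (s in 1:6) {
    inv <- sized_inventory(s)
    combos <- build_combinations(inv, STIM_TYPES)
    counts <- table(combos$stim_type)
    expect_true(all(counts == 2 * s^2))
    expect_equal(nrow(combos), 4 * 2 * s^2)
    expect_false(anyDuplicated(combos$text) > 0)
  }
})

test_that("every pseudoword is the 7-letter left+right concatenation", {
  combos <- build_combinations(adult_inventory(), STIM_TYPES)
  expect_true(all(combos$text == paste0(combos$left, combos$right)))
  expect_true(all(nchar(combos$text) == 7L))
})

test_that("combinations cross within subsets only and are deterministic", {
  inv <- adult_inventory()
  combos <- build_combinations(inv, "stem+suffix")
  for (i in seq_len(nrow(combos))) {
    left_sub <- inv$subset[inv$text == combos$left[i] & inv$role == "stem"]
    right_sub <- inv$subset[inv$text == combos$right[i] & inv$role == "suffix"]
    expect_identical(left_sub, right_sub)
  }
  expect_identical(combos, build_combinations(inv, "stem+suffix"))
})

test_that("degenerate inventory with subsets of 1 yields exactly 2 pseudowords", {
  combos <- build_combinations(tiny_inventory(), "stem+suffix")
  expect_equal(nrow(combos), 2L)
})

test_that("invalid inventories are rejected with informative errors", {
  bad <- data.frame(text = c("abcd", "efgh", "ijk"),
                    role = c("stem", "stem", "suffix"),
                    subset = c("A", "B", "A"))
  expect_error(morpheme_inventory(bad), "same item count")
  bad2 <- data.frame(text = c("abcde", "qrs"),
                     role = c("stem", "suffix"), subset = "A")
  expect_error(morpheme_inventory(bad2), "length")
  bad3 <- data.frame(text = c("abcd", "abcd", "qrs", "tuv"),
                     role = c("stem", "stem", "suffix", "suffix"),
                     subset = c("A", "B", "A", "B"))
  expect_error(morpheme_inventory(bad3), "duplicated")
})

test_that("rendered-text collisions across combinations are detected", {
  # the same ending text in both right-hand roles makes stem+suffix and
  # stem+nonsuffix render identically
  inv <- morpheme_inventory(data.frame(
    text = c("abab", "cdcd", "qrs", "qrs"),
    role = c("stem", "nonstem", "suffix", "nonsuffix"),
    subset = "A"))
  expect_error(
    build_combinations(inv, c("stem+suffix", "stem+nonsuffix")),
    "collision")
})

test_that("sequences have the exact token/oddball arithmetic", {
  combos <- build_combinations(adult_inventory(), STIM_TYPES)
  cond <- condition_spec(1)
  odd <- combos$text[combos$stim_type == cond$oddball_type]
  base <- combos$text[combos$stim_type == cond$base_type]
  s <- generate_sequence(cond, odd, base, duration = 60, base_rate = 6,
                         oddball_period = 5, seed = 7)
  expect_length(s$tokens, 360L)
  expect_length(s$oddball_positions, 72L)
  expect_identical(s$oddball_positions, seq(5L, 360L, by = 5L))
  expect_equal(sum(!s$is_oddball), 288L)
  expect_setequal(s$tokens[s$is_oddball], odd)  # 72 unique oddballs
  expect_true(all(s$tokens[!s$is_oddball] %in% base))
})

test_that("k-repetition policy delivers each oddball exactly k times", {
  ci <- child_inventory()
  combos <- build_combinations(ci, STIM_TYPES[1:3])
  cond <- condition_spec(1)
  odd <- combos$text[combos$stim_type == cond$oddball_type]
  base <- combos$text[combos$stim_type == cond$base_type]
  expect_length(odd, 18L)
  s <- generate_sequence(cond, odd, base, repetition_policy = "k_repeats",
                         seed = 3)
  reps <- table(s$tokens[s$is_oddball])
  expect_length(reps, 18L)
  expect_true(all(reps == 4L))
})

test_that("min-repetition distance holds for all seeds (brute force)", {
  combos <- build_combinations(child_inventory(), STIM_TYPES[1:3])
  cond <- condition_spec(3)
  odd <- combos$text[combos$stim_type == cond$oddball_type]
  base <- combos$text[combos$stim_type == cond$base_type]
  for (seed in 1:10) {
    s <- generate_sequence(cond, odd, base, repetition_policy = "k_repeats",
                           seed = seed)
    expect_equal(nrow(check_repetition_distance(s)), 0L)
  }
})

test_that("same seed reproduces the same sequence; pools are validated", {
  pools <- condition0_pools("adult")
  cond <- condition_spec(0)
  s1 <- generate_sequence(cond, pools$words, pools$consonant_strings,
                          seed = 11)
  s2 <- generate_sequence(cond, pools$words, pools$consonant_strings,
                          seed = 11)
  expect_identical(s1$tokens, s2$tokens)
  expect_error(
    generate_sequence(cond, pools$words[1:10], pools$consonant_strings,
                      seed = 1),
    "unique-oddball")
  expect_error(
    generate_sequence(cond, pools$words[1:20], pools$consonant_strings,
                      repetition_policy = "k_repeats", seed = 1),
    "k-repetition")
  expect_error(generate_sequence(cond, character(), pools$words), "non-empty")
})

test_that("an unsatisfiable distance constraint fails with a named error", {
  cond <- condition_spec(0)
  expect_error(
    generate_sequence(cond, condition0_pools("adult")$words, "solo",
                      duration = 10, seed = 1, max_retries = 20),
    "min-repetition-distance")
})

test_that("contrast envelope follows the raised-cosine shape", {
  cyc <- 1 / 6
  expect_equal(contrast_envelope(0, cyc), 0)
  expect_equal(contrast_envelope(cyc / 2, cyc), 1)
  expect_equal(contrast_envelope(cyc, cyc), 0, tolerance = 1e-12)
  # peak contrast is reached 83.5 ms into a 167-ms cycle
  expect_equal(contrast_envelope(0.0835, 0.167), 1, tolerance = 1e-6)
  expect_error(contrast_envelope(0.2, cyc), "outside")
  # integrates to cycle_duration / 2 over one cycle
  q <- integrate(contrast_envelope, 0, cyc, cycle_duration = cyc)
  expect_equal(q$value, cyc / 2, tolerance = 1e-8)
})

test_that("condition specs pair distinct oddball and base classes", {
  for (id in 0:4) {
    cs <- condition_spec(id)
    expect_true(cs$oddball_type != cs$base_type)
  }
  expect_identical(condition_spec(0)$oddball_type, "word")
  expect_identical(condition_spec(0)$base_type, "consonant_string")
  expect_error(condition_spec(5), "0-4")
})

test_that("sequence round-trips through the delimited-text writer", {
  combos <- build_combinations(adult_inventory(), STIM_TYPES)
  cond <- condition_spec(2)
  odd <- combos$text[combos$stim_type == cond$oddball_type]
  base <- combos$text[combos$stim_type == cond$base_type]
  s <- generate_sequence(cond, odd, base, seed = 5)
  f <- tempfile(fileext = ".tsv")
  write_sequence(s, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 360L)
  expect_identical(tab$token, s$tokens)
  expect_identical(which(tab$is_oddball), as.integer(s$oddball_positions))
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$base_rate, 6)
  unlink(c(f, paste0(f, ".json")))
})
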