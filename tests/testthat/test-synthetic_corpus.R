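# synthetic_corpus: grammar enumeration, generator, gold consistency

test_that("enumeration size equals the independent combinatorial count", {
  enum <- enumerate_phrase_grammar()
  # closed form computed from the allowed-value sets, independently of the
  # enumerator's own loops
  av <- tnm_allowed_values()
  written <- vapply(av, length, 1L)
  written[["H"]] <- written[["H"]] + 4L      # Roman numeral spellings I-IV
  total_tokens <- sum(written)               # 74
  n_roman <- 4L
  n_is <- 1L
  n_zero_vals <- sum(vapply(av, function(v) "0" %in% v, TRUE))  # 8
  n_prefixes <- length(tnm_config()$prefix_whitelist)
  numeric_per_cat <- vapply(av, function(v) sum(grepl("^[0-4][a-d]?$", v)), 1L)
  expected <- (total_tokens - n_roman) +     # lower
    total_tokens +                           # nogap
    (total_tokens - n_is) +                  # gap
    n_zero_vals +                            # osub
    written[["T"]] * n_prefixes +            # prefix (T only)
    total_tokens +                           # comment
    total_tokens +                           # reorder
    total_tokens +                           # cue
    sum(numeric_per_cat)                     # multi
  expect_equal(nrow(enum), expected)
  # spot entries from the dialect table
  expect_true("Staged as T2" %in% enum$phrase_text)
  yp <- enum[enum$phrase_text == "ypT2 N0", ]
  expect_equal(nrow(yp), 1L)
  expect_equal(yp$expected[[1]]$prefix, c("yp", ""))
  expect_true(any(enum$dialect == "multi" & enum$category == "T"))
  expect_true(any(grepl("^NO ", enum$phrase_text) | grepl(" NO$", enum$phrase_text)))
})

test_that("generator config validates probabilities and weights", {
  expect_error(generator_config(p_tnm_phrase = 1.4), class = "crctnm_validation_error")
  expect_error(generator_config(n_reports = -1), class = "crctnm_validation_error")
  expect_error(generator_config(dialect_weights = c(gap = -1)),
               class = "crctnm_validation_error")
  expect_error(generator_config(modifier_mix = c(bogus_class = 1)),
               class = "crctnm_validation_error")
  expect_error(generator_config(dialect_weights = c(gap = 0)),
               class = "crctnm_validation_error")
})

test_that("n_reports = 0 yields empty corpus and gold; seeds reproduce bytes", {
  sim0 <- generate_corpus(generator_config(n_reports = 0))
  expect_equal(nrow(sim0$corpus), 0L)
  expect_equal(nrow(sim0$gold), 0L)

  a <- generate_corpus(generator_config(n_reports = 25, seed = 408))
  b <- generate_corpus(generator_config(n_reports = 25, seed = 408))
  expect_identical(a, b)
  c2 <- generate_corpus(generator_config(n_reports = 25, seed = 409))
  expect_false(identical(a$corpus$text, c2$corpus$text))
  # the generator does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_corpus(generator_config(n_reports = 5)))
  expect_identical(runif(1), before)
})

test_that("reports are sectioned and distractors live in the technique section", {
  sim <- generate_corpus(generator_config(n_reports = 60, seed = 410,
                                          distractor_rate = 2))
  path <- sim$corpus$report_type == "pathology"
  expect_true(all(grepl("CLINICAL DETAILS:", sim$corpus$text[path])))
  expect_true(all(grepl("MICROSCOPY:", sim$corpus$text[path])))
  expect_true(all(grepl("CONCLUSION:", sim$corpus$text[path])))
  expect_true(all(grepl("TECHNIQUE:", sim$corpus$text[!path])))
  expect_true(all(grepl("IMPRESSION:", sim$corpus$text[!path])))
})

test_that("gold phrase spans re-parse to the gold maxima (gold consistency)", {
  sim <- generate_corpus(generator_config(n_reports = 150, seed = 411,
                                          p_tnm_phrase = 1))
  cols <- c("t_prefix", "t", "n", "m", "v", "r", "l", "pn", "g", "sm", "h")
  n_checked <- 0L
  for (i in seq_len(nrow(sim$gold))) {
    g <- sim$gold[i, ]
    if (is.na(g$phrase_start)) next
    txt <- substr(sim$corpus$text[i], g$phrase_start + 1, g$phrase_end)
    tokens <- parse_phrase(txt)
    expect_gt(nrow(tokens), 0L)
    agg <- aggregate_max(find_tnm_phrases(paste0("Staged as follows. TNM: ", txt)), "x")
    for (cc in cols) {
      expect_identical(agg[[cc]], g[[cc]],
                       label = sprintf("%s [%s] %s", cc, g$dialect, txt))
    }
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 100L)
})

test_that("corpus statistics match the configured rates within 3 SE", {
  n <- 1200L
  cfg <- generator_config(n_reports = n, seed = 412)
  sim <- generate_corpus(cfg)
  se <- function(p) sqrt(p * (1 - p) / n)
  pos_rate <- mean(sim$gold$crc_status)
  expect_lt(abs(pos_rate - cfg$crc_positive_rate), 3 * se(cfg$crc_positive_rate))
  path_rate <- mean(sim$corpus$report_type == "pathology")
  expect_lt(abs(path_rate - cfg$report_type_mix), 3 * se(cfg$report_type_mix))
  stage_rate <- mean(!is.na(sim$gold$t) | !is.na(sim$gold$m) |
                       sim$gold$implicit_json != "{}")
  expect_lt(abs(stage_rate - cfg$p_tnm_phrase), 3 * se(cfg$p_tnm_phrase) + 0.02)
})

test_that("distractor bank contains the canonical look-alikes", {
  bank <- distractor_bank()
  expect_true("T1-weighted" %in% bank)
  expect_true(any(grepl("T1-T12", bank)))
  expect_true(any(grepl("\\d+ x \\d+ mm", bank)))
})
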