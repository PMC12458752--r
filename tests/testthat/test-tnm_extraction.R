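# tnm_extraction: grammar, normalisation, guards, aggregation, corpus driver

test_that("documentation variants parse to their specified token sets", {
  cases <- list(
    list("T1/2/3 N0 V0", c("T||1", "T||2", "T||3", "N||0", "V||0")),
    list("T1N0M0",       c("T||1", "N||0", "M||0")),
    list("T 1 N0M0",     c("T||1", "N||0", "M||0")),
    list("ymrT1",        c("T|ymr|1")),
    list("pT1",          c("T|p|1")),
    list("ypT1",         c("T|yp|1")),
    list("T1a (solitary tumour) N0", c("T||1a", "N||0")),
    list("T1 n1",        c("T||1", "N||1"))
  )
  for (cs in cases) {
    got <- parse_phrase(cs[[1]])
    expect_setequal(paste(got$category, got$prefix, got$value, sep = "|"), cs[[2]])
  }
})

test_that("token spans index the source text correctly (0-based half-open)", {
  txt <- "Conclusion: R0 pT3 L0 V0 N0 Mx."
  ph <- find_tnm_phrases(txt)
  expect_equal(nrow(ph), 1L)
  expect_equal(substr(txt, ph$start + 1, ph$end), ph$text)
  tok <- ph$tokens[[1]]
  expect_equal(nrow(tok), 6L)
  expect_equal(tok$category, c("R", "T", "L", "V", "N", "M"))
  # spans are in document order, non-overlapping, within the phrase
  expect_true(all(diff(tok$start) > 0))
  expect_true(all(tok$start >= ph$start & tok$end <= ph$end))
  expect_true(all(tok$end > tok$start))
})

test_that("normalize_value corrects O/x/substage case and rejects outsiders", {
  expect_equal(normalize_value(c("O", "o", "x", "1A", "is"), "T"),
               c("0", "0", "X", "1a", "is"))
  expect_true(is.na(normalize_value("5", "T")))
  expect_true(is.na(normalize_value("2", "Pn")))
  expect_true(is.na(normalize_value("X", "SM")))
  expect_equal(normalize_value(c("I", "II", "III", "IV"), "H"), c("1", "2", "3", "4"))
  expect_true(is.na(normalize_value("ii", "H")))  # lower-case roman is prose
  # O-for-zero equivalence oracle: parse the corrected string and compare
  a <- parse_phrase("pT3 NO MX")
  b <- parse_phrase("pT3 N0 MX")
  expect_identical(a[, c("category", "prefix", "value")],
                   b[, c("category", "prefix", "value")])
})

test_that("letter-O tokens need an adjacent TNM neighbour; lone 'No' is prose", {
  expect_equal(nrow(parse_phrase("No evidence of disease")), 0L)
  expect_equal(nrow(find_tnm_phrases("No evidence of tumour. Staged as T2.")), 1L)
  got <- parse_phrase("T0 NO")
  expect_setequal(paste0(got$category, got$value), c("T0", "N0"))
})

test_that("false-positive guards reject MRI and vertebral look-alikes", {
  expect_true(guard_false_positive(0, 2, "T1-weighted images", tnm_config()))
  expect_true(guard_false_positive(25, 27, "first thoracic vertebra (T1)", tnm_config()))
  expect_false(guard_false_positive(0, 2, "T0 N0", tnm_config()))
  expect_equal(nrow(find_tnm_phrases("Axial T1 and T2 weighted sequences were acquired")), 0L)
  expect_equal(nrow(find_tnm_phrases("metastases at T1-T12 levels")), 0L)
  # guard terms are configurable
  cfg <- tnm_config(guard_mri_terms = "nonsenseword")
  ph <- find_tnm_phrases("Staged as T2 weighted", cfg)
  expect_equal(nrow(ph), 1L)
})

test_that("single-category candidates require a staging cue", {
  expect_equal(nrow(find_tnm_phrases("T2")), 0L)
  expect_equal(nrow(find_tnm_phrases("the ward T3 room")), 0L)
  ph <- find_tnm_phrases("Staged as T2")
  expect_equal(nrow(ph), 1L)
  expect_true(ph$anchored_by_cue)
  expect_identical(ph$tokens[[1]]$value, "2")
  # multi-category phrases need no cue but record anchoring honestly
  ph2 <- find_tnm_phrases("T2 N0")
  expect_equal(nrow(ph2), 1L)
  expect_false(ph2$anchored_by_cue)
})

test_that("aggregate_max ranks values like the exhaustive pairwise oracle", {
  # spec'd spot checks, expected values computed with oracle_max_value
  expect_equal(oracle_max_value(c("1a", "1d", "2"), "T"), "2")
  expect_equal(oracle_max_value(c("X", "0"), "T"), "0")
  expect_equal(oracle_max_value(c("is", "1"), "T"), "1")
  mk <- function(...) find_tnm_phrases(paste(..., sep = ". "))
  r <- aggregate_max(mk("Staged as T1a", "Staged as T1d", "Staged as T2"), "r")
  expect_equal(r$t, "2")
  r <- aggregate_max(mk("Staged as TX", "Staged as T0"), "r")
  expect_equal(r$t, "0")
  r <- aggregate_max(mk("Staged as Tis", "Staged as T1"), "r")
  expect_equal(r$t, "1")
  # randomised agreement with the oracle
  set.seed(402)
  vals <- setdiff(tnm_allowed_values()$T, character(0))
  for (rep in 1:50) {
    obs <- sample(vals, sample(2:5, 1), replace = TRUE)
    ph <- find_tnm_phrases(paste(sprintf("Staged as T%s.", obs), collapse = " "))
    r <- aggregate_max(ph, "r")
    expect_equal(r$t, oracle_max_value(obs, "T"), label = paste(obs, collapse = ","))
  }
})

test_that("aggregate_max combines phrases and reports prefixes (variable order)", {
  ph <- find_tnm_phrases("R0 pT3 L0 V0 N0 Mx. Then pT2 N1 Mx L0 V0 R1.")
  r <- aggregate_max(ph, "r1")
  expect_equal(r[, c("t_prefix", "t", "n", "m", "l", "v", "r")],
               data.frame(t_prefix = "p", t = "3", n = "1", m = "X",
                          l = "0", v = "0", r = "1", stringsAsFactors = FALSE))
  # single phrase: identity
  r2 <- aggregate_max(find_tnm_phrases("T2 N0"), "r2")
  expect_equal(r2$t, "2"); expect_equal(r2$n, "0")
  expect_true(all(is.na(r2[, c("m", "v", "r", "l", "pn", "g", "sm", "h")])))
  # permutation invariance of phrase order
  ph_rev <- ph[rev(seq_len(nrow(ph))), ]
  r_rev <- aggregate_max(ph_rev, "r1")
  expect_identical(r_rev[, result_cols <- c("t", "n", "m", "v", "r", "l")],
                   r[, result_cols])
})

test_that("Tpre tie-break: the last T-maximum occurrence in document order wins", {
  ph <- find_tnm_phrases("ypT3 N0. Later pT3 N1.")
  expect_equal(aggregate_max(ph, "r")$t_prefix, "p")
  ph2 <- find_tnm_phrases("pT3 N1. Later ypT3 N0.")
  expect_equal(aggregate_max(ph2, "r")$t_prefix, "yp")
})

test_that("extract_tnm is order-preserving, deterministic and local", {
  corpus <- data.frame(
    report_id = c("a", "b", "c"),
    report_type = "pathology",
    text = c("T1 N0 M0", "", "Nothing staged here."),
    stringsAsFactors = FALSE)
  res <- extract_tnm(corpus)
  expect_equal(res$values$report_id, c("a", "b", "c"))
  expect_equal(res$values$t[1], "1")
  expect_equal(res$values$n[1], "0")
  expect_equal(res$values$m[1], "0")
  expect_true(all(is.na(res$values[2, c("t", "n", "m")])))
  expect_equal(res$values$n_phrases, c(1L, 0L, 0L))
  # locality: appending the distractor bank never changes the values
  corpus2 <- corpus
  corpus2$text <- paste(corpus2$text, paste0(distractor_bank(), ".", collapse = " "),
                        sep = "\n")
  res2 <- extract_tnm(corpus2)
  expect_identical(res2$values[, result_columns_test <- c("t_prefix", "t", "n", "m",
                                                          "v", "r", "l", "pn", "g", "sm", "h")],
                   res$values[, result_columns_test])
  # idempotence
  expect_identical(extract_tnm(corpus)$values, res$values)
})

test_that("parallel extraction equals the serial run", {
  sim <- generate_corpus(generator_config(n_reports = 40, seed = 403))
  serial <- extract_tnm(sim$corpus, workers = 1L)
  par4 <- extract_tnm(sim$corpus, workers = 4L)
  expect_identical(par4$values, serial$values)
  expect_identical(par4$phrases, serial$phrases)
})

test_that("historical post-filter drops phrases in historical scope", {
  corpus <- data.frame(report_id = "r", report_type = "pathology",
                       text = "Previously staged as T4 N2. Now staged as T2 N0.",
                       stringsAsFactors = FALSE)
  all_stages <- extract_tnm(corpus)
  expect_equal(all_stages$values$t, "4")
  current <- extract_tnm(corpus, tnm_config(drop_historical = TRUE),
                         trigger_rules = default_trigger_rules())
  expect_equal(current$values$t, "2")
  expect_error(extract_tnm(corpus, tnm_config(drop_historical = TRUE)),
               class = "crctnm_config_error")
})
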