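# evaluation: confusion counts, micro metrics, Wilson intervals, scenarios

test_that("wilson_interval is exact at the boundaries and matches the root oracle", {
  expect_equal(wilson_interval(0, 50)[["lower"]], 0)
  expect_equal(wilson_interval(50, 50)[["upper"]], 1)
  expect_true(all(is.na(wilson_interval(0, 0))))
  expect_error(wilson_interval(5, 3), class = "crctnm_validation_error")
  for (n in c(1, 8, 50, 100, 423)) {
    for (x in unique(pmin(n, c(0, 1, floor(n / 3), n - 1, n)))) {
      got <- wilson_interval(x, n)
      want <- oracle_wilson(x, n)
      expect_equal(got[["lower"]], want[["lower"]], tolerance = 1e-9)
      expect_equal(got[["upper"]], want[["upper"]], tolerance = 1e-9)
    }
  }
})

test_that("confusion tallies value classes and the none class as defined", {
  # perfect predictions: no errors anywhere
  cc <- confusion(c("2", "3", NA), c("2", "3", NA))
  expect_equal(sum(cc$classes$fp) + sum(cc$classes$fn), 0L)
  expect_equal(cc$none[["tn_none"]], 1L)
  # wrong value: one FP for the predicted class, one FN for the gold class
  cc2 <- confusion("2", "3")
  expect_equal(cc2$classes$fp[cc2$classes$value == "2"], 1L)
  expect_equal(cc2$classes$fn[cc2$classes$value == "3"], 1L)
  expect_error(confusion(data.frame(report_id = "a", value = "1"),
                         data.frame(report_id = "b", value = "1")),
               class = "crctnm_validation_error")
})

test_that("confusion equals the brute-force recount oracle on random tables", {
  set.seed(413)
  vals <- c("0", "1", "2", "3", "X", NA)
  for (rep in 1:300) {
    n <- sample(1:40, 1)
    p <- sample(vals, n, replace = TRUE)
    g <- sample(vals, n, replace = TRUE)
    cc <- confusion(p, g)
    want <- oracle_confusion(p, g)
    expect_equal(cc$none[["tn_none"]], want$tn_none %||% 0L)
    expect_equal(cc$none[["fn_none"]], want$fn_none %||% 0L)
    expect_equal(cc$none[["fp_none"]], want$fp_none %||% 0L)
    for (v in setdiff(vals, NA)) {
      row <- cc$classes[cc$classes$value == v, ]
      expect_equal(if (nrow(row)) row$tp else 0L, want[[paste0("tp:", v)]] %||% 0L)
      expect_equal(if (nrow(row)) row$fp else 0L, want[[paste0("fp:", v)]] %||% 0L)
      expect_equal(if (nrow(row)) row$fn else 0L, want[[paste0("fn:", v)]] %||% 0L)
    }
  }
})

test_that("micro metrics pool counts and report undefined ratios as NA", {
  perfect <- micro_metrics(confusion(c("1", "2", NA), c("1", "2", NA)))
  expect_equal(unlist(perfect[, c("ppv", "npv", "sensitivity", "specificity")]),
               c(ppv = 1, npv = 1, sensitivity = 1, specificity = 1))
  # hand-built counts: TP=9, FP=1 (spurious detection), FN=3 (missed)
  p <- c(rep("1", 9), "1", rep(NA, 3))
  g <- c(rep("1", 9), NA, rep("1", 3))
  m <- micro_metrics(confusion(p, g))
  expect_equal(m$ppv, 0.9)
  expect_equal(m$sensitivity, 0.75)
  # zero gold and zero predicted values: PPV/sensitivity undefined,
  # NPV = specificity = 1 with the printed Wilson bounds
  h <- micro_metrics(confusion(rep(NA_character_, 200), rep(NA_character_, 200)))
  expect_true(is.na(h$ppv) && is.na(h$sensitivity))
  expect_equal(h$npv, 1); expect_equal(h$specificity, 1)
  expect_equal(round(100 * h$npv_lo, 1), 98.1)
  fm <- format_metrics(h)
  expect_equal(fm$ppv, "-")
  expect_equal(fm$npv, "100.0 (98.1, 100.0)")
})

test_that("wilson bounds bracket the point estimate and narrow with trials", {
  set.seed(414)
  for (rep in 1:100) {
    n <- sample(2:500, 1); x <- sample(0:n, 1)
    ci <- wilson_interval(x, n)
    expect_true(ci[["lower"]] <= x / n + 1e-12 && x / n <= ci[["upper"]] + 1e-12)
    ci2 <- wilson_interval(x * 4L, n * 4L)
    expect_lt(ci2[["upper"]] - ci2[["lower"]], ci[["upper"]] - ci[["lower"]])
  }
})

test_that("evaluate_tnm scenarios differ exactly on implicit/historical gold", {
  sim <- generate_corpus(generator_config(n_reports = 400, seed = 415,
                                          p_tnm_phrase = 1, p_implicit = 0.1,
                                          p_historical = 0.1))
  pred <- extract_tnm(sim$corpus)$values
  explicit <- evaluate_tnm(pred, sim$gold, "explicit_only")
  strict <- evaluate_tnm(pred, sim$gold, "strict")
  t_e <- explicit[explicit$category == "T", ]
  t_s <- strict[strict$category == "T", ]
  expect_lt(t_s$sensitivity, t_e$sensitivity)  # implicit T0 misses count
  expect_lt(t_s$ppv, t_e$ppv)                  # historical retrievals count

  # without implicit/historical reports both scenarios coincide
  sim2 <- generate_corpus(generator_config(n_reports = 150, seed = 416,
                                           p_tnm_phrase = 1, p_implicit = 0,
                                           p_historical = 0))
  pred2 <- extract_tnm(sim2$corpus)$values
  e2 <- evaluate_tnm(pred2, sim2$gold, "explicit_only")
  s2 <- evaluate_tnm(pred2, sim2$gold, "strict")
  expect_identical(e2, s2)

  # metrics are invariant to report ordering
  shuffled <- sim2$gold[sample(nrow(sim2$gold)), ]
  expect_identical(evaluate_tnm(pred2, shuffled, "explicit_only")[, -1],
                   e2[, -1])
})

test_that("evaluate_crc on perfect predictions yields 1.0 with upper bound 1", {
  gold <- data.frame(report_id = c("a", "b", "c", "d"),
                     crc_status = c(TRUE, FALSE, TRUE, FALSE))
  m <- evaluate_crc(gold, gold)
  expect_equal(unlist(m[, c("ppv", "npv", "sensitivity", "specificity")]),
               c(ppv = 1, npv = 1, sensitivity = 1, specificity = 1))
  expect_equal(m$ppv_hi, 1)
  expect_equal(m$num_value, 2L)
})
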