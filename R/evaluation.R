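# Evaluation harness: per-category confusion counts against gold maxima,
# micro-averaged PPV/sensitivity over value classes, NPV/specificity against
# the "no value detected" class, and 95% Wilson score intervals.

#' Wilson score interval for a binomial proportion
#'
#' Inverts the normal-approximation score test: the interval is
#' \deqn{\frac{\hat p + z^2/2n \pm z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}}{1 + z^2/n}}
#' with \eqn{z} the exact normal quantile for the requested confidence
#' (not 1.96 rounded). Well behaved at 0 and 1: the lower bound is exactly 0
#' when no successes are observed, the upper exactly 1 when all trials
#' succeed.
#'
#' @param successes,trials Non-negative counts, `successes <= trials`.
#' @param confidence Confidence level, default 0.95.
#' @return Named numeric vector `c(lower, upper)`; both `NA` when
#'   `trials == 0`.
#' @examples
#' round(wilson_interval(94, 100) * 100, 1)  # 87.5 97.2
#' @export
wilson_interval <- function(successes, trials, confidence = 0.95) {
  if (trials == 0) return(c(lower = NA_real_, upper = NA_real_))
  if (successes < 0 || successes > trials) {
    validation_error("successes must lie in [0, trials]")
  }
  z <- qnorm(1 - (1 - confidence) / 2)
  n <- trials; p <- successes / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Per-category confusion counts of predicted vs gold maxima
#'
#' For each report the predicted maximum value is compared with the gold
#' maximum. Value-level counts: a correct value is a TP of its class; a
#' predicted value differing from gold is an FP of the predicted class and
#' (when gold carries a value) an FN of the gold class; a missed gold value
#' is an FN of its class. The "no value" class is tallied separately:
#' `tn_none` (neither side has a value), `fn_none` (predicted none, gold has
#' one), `fp_none` (predicted one, gold none).
#'
#' @param predictions,gold Character vectors of maxima (NA = no value),
#'   aligned by report; or data.frames with `report_id` plus a `value`
#'   column, joined on `report_id` (a prediction without gold is an error).
#' @param category Label carried through to the output.
#' @return List of class `"confusion_counts"`: `category`, `classes`
#'   (data.frame value/tp/fp/fn), `none` (named vector), `n` reports.
#' @export
confusion <- function(predictions, gold, category = "value") {
  if (is.data.frame(predictions) || is.data.frame(gold)) {
    if (!all(c("report_id", "value") %in% names(predictions)) ||
        !all(c("report_id", "value") %in% names(gold))) {
      validation_error("prediction/gold frames need report_id and value columns")
    }
    extra <- setdiff(predictions$report_id, gold$report_id)
    if (length(extra)) {
      validation_error("predictions for reports absent from gold: %s", commas(extra))
    }
    idx <- match(gold$report_id, predictions$report_id)
    predictions <- predictions$value[idx]
    gold <- gold$value
  }
  if (length(predictions) != length(gold)) {
    validation_error("predictions and gold must have equal length")
  }
  p <- as.character(predictions); g <- as.character(gold)
  values <- sort(unique(c(p[!is.na(p)], g[!is.na(g)])))
  classes <- data.frame(value = values, tp = rep(0L, length(values)),
                        fp = rep(0L, length(values)), fn = rep(0L, length(values)),
                        stringsAsFactors = FALSE)
  none <- c(tn_none = 0L, fn_none = 0L, fp_none = 0L)
  for (i in seq_along(p)) {
    pv <- p[i]; gv <- g[i]
    if (is.na(pv) && is.na(gv)) { none["tn_none"] <- none["tn_none"] + 1L; next }
    if (is.na(pv)) {
      none["fn_none"] <- none["fn_none"] + 1L
      classes$fn[classes$value == gv] <- classes$fn[classes$value == gv] + 1L
      next
    }
    if (is.na(gv)) {
      none["fp_none"] <- none["fp_none"] + 1L
      classes$fp[classes$value == pv] <- classes$fp[classes$value == pv] + 1L
      next
    }
    if (pv == gv) {
      classes$tp[classes$value == pv] <- classes$tp[classes$value == pv] + 1L
    } else {
      classes$fp[classes$value == pv] <- classes$fp[classes$value == pv] + 1L
      classes$fn[classes$value == gv] <- classes$fn[classes$value == gv] + 1L
    }
  }
  structure(list(category = category, classes = classes, none = none,
                 n = length(p)),
            class = "confusion_counts")
}

#' Micro-averaged metrics from confusion counts
#'
#' Pools counts across value classes before forming ratios:
#' `ppv = sum(TP)/(sum(TP)+sum(FP))`, `sensitivity = sum(TP)/(sum(TP)+sum(FN))`;
#' the no-value class supplies `npv = TN/(TN+FN_none)` and
#' `specificity = TN/(TN+FP_none)`. A ratio with zero denominator is
#' reported `NA` (printed as "-" in the display formats).
#'
#' @param counts A [confusion()] result.
#' @param confidence Wilson interval confidence level.
#' @return One-row data.frame of class `"metrics_row"`: `category`,
#'   `num_report`, `num_value`, then `ppv`, `npv`, `sensitivity`,
#'   `specificity`, each with `_lo`/`_hi` Wilson bounds (proportions in
#'   [0, 1]).
#' @export
micro_metrics <- function(counts, confidence = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  cl <- counts$classes; no <- counts$none
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  tp <- sum(cl$tp); fp <- sum(cl$fp); fn <- sum(cl$fn)
  # every gold-valued report contributes exactly one TP or one FN
  out <- data.frame(category = counts$category, num_report = counts$n,
                    num_value = tp + fn, stringsAsFactors = FALSE)
  add <- function(df, name, num, den) {
    df[[name]] <- ratio(num, den)
    ci <- if (den > 0) wilson_interval(num, den, confidence) else c(NA_real_, NA_real_)
    df[[paste0(name, "_lo")]] <- ci[[1]]
    df[[paste0(name, "_hi")]] <- ci[[2]]
    df
  }
  out <- add(out, "ppv", tp, tp + fp)
  out <- add(out, "npv", no[["tn_none"]], no[["tn_none"]] + no[["fn_none"]])
  out <- add(out, "sensitivity", tp, tp + fn)
  out <- add(out, "specificity", no[["tn_none"]], no[["tn_none"]] + no[["fp_none"]])
  class(out) <- c("metrics_row", "data.frame")
  out
}

# gold vector for one category under an evaluation scenario
scenario_gold <- function(gold, col, scenario) {
  g <- gold[[col]]
  if (scenario == "strict") {
    # historical retrievals are errors: the historical value leaves the gold
    g[gold$historical] <- NA_character_
    # implicit stages are real but unwritten: missing them is an error
    imp <- lapply(gold$implicit_json, function(x) jsonlite::fromJSON(x))
    iv <- vapply(imp, function(l) l[[col]] %||% NA_character_, "")
    sel <- !is.na(iv) & is.na(g)
    g[sel] <- iv[sel]
  }
  g
}

#' Evaluate TNM predictions against a gold table
#'
#' Scores the per-category maxima of [extract_tnm()] against a gold table
#' (e.g. from [generate_corpus()]), producing one metrics row per category.
#' Two scenarios mirror the two ways implicit and historical staging can be
#' treated: `"explicit_only"` scores only what is explicitly written
#' (historical stages count as correct retrievals, implicit stages are not
#' the extractor's job); `"strict"` counts the retrieval of a
#' historical-only stage as a false positive and the non-retrieval of an
#' implicit stage as a miss.
#'
#' @param pred Data.frame with `report_id` and the value columns
#'   `t_prefix`, `t`, `n`, ..., `h` (as returned in
#'   `extract_tnm()$values`).
#' @param gold Data.frame with the same value columns plus optional
#'   `historical` flag and `implicit_json` (both used only by `"strict"`).
#' @param scenario `"explicit_only"` or `"strict"`.
#' @param confidence Wilson interval confidence level.
#' @return Data.frame with one [micro_metrics()] row per category
#'   (categories: Tpre, T, N, M, V, R, L, Pn, G, SM, H).
#' @export
evaluate_tnm <- function(pred, gold, scenario = c("explicit_only", "strict"),
                         confidence = 0.95) {
  scenario <- match.arg(scenario)
  missing_cols <- setdiff(c("report_id", result_columns), names(pred))
  if (length(missing_cols)) {
    validation_error("pred is missing columns: %s", commas(missing_cols))
  }
  missing_cols <- setdiff(c("report_id", result_columns), names(gold))
  if (length(missing_cols)) {
    validation_error("gold is missing columns: %s", commas(missing_cols))
  }
  extra <- setdiff(pred$report_id, gold$report_id)
  if (length(extra)) validation_error("predictions for reports absent from gold: %s", commas(extra))
  if (!"historical" %in% names(gold)) gold$historical <- FALSE
  if (!"implicit_json" %in% names(gold)) gold$implicit_json <- "{}"
  idx <- match(gold$report_id, pred$report_id)
  labels <- c(t_prefix = "Tpre", t = "T", n = "N", m = "M", v = "V", r = "R",
              l = "L", pn = "Pn", g = "G", sm = "SM", h = "H")
  rows <- lapply(result_columns, function(col) {
    p <- pred[[col]][idx]
    g <- scenario_gold(gold, col, scenario)
    micro_metrics(confusion(p, g, category = labels[[col]]), confidence)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate CRC detection against gold status
#'
#' Binary PPV/NPV/sensitivity/specificity with Wilson intervals, through the
#' same machinery as the TNM metrics (a positive report is the single value
#' class, a negative report is the "no value" class).
#'
#' @param pred Data.frame with `report_id`, `crc_status` (logical).
#' @param gold Data.frame with `report_id`, `crc_status`.
#' @param confidence Wilson interval confidence level.
#' @return One-row metrics data.frame, `category = "CRC"`.
#' @export
evaluate_crc <- function(pred, gold, confidence = 0.95) {
  for (df in list(pred, gold)) {
    if (!all(c("report_id", "crc_status") %in% names(df))) {
      validation_error("pred/gold need report_id and crc_status columns")
    }
  }
  extra <- setdiff(pred$report_id, gold$report_id)
  if (length(extra)) validation_error("predictions for reports absent from gold: %s", commas(extra))
  idx <- match(gold$report_id, pred$report_id)
  p <- ifelse(pred$crc_status[idx], "crc", NA_character_)
  g <- ifelse(gold$crc_status, "crc", NA_character_)
  micro_metrics(confusion(p, g, category = "CRC"), confidence)
}

#' Format a metrics table the way staging-performance tables are printed
#'
#' Percentages to one decimal (half-up), Wilson bounds in brackets,
#' undefined ratios as "-".
#'
#' @param metrics Data.frame from [evaluate_tnm()] or [evaluate_crc()].
#' @return Data.frame of formatted strings.
#' @export
format_metrics <- function(metrics) {
  fmt <- function(p, lo, hi) {
    ifelse(is.na(p), "-",
           sprintf("%.1f (%.1f, %.1f)", round_half_up(100 * p, 1),
                   round_half_up(100 * lo, 1), round_half_up(100 * hi, 1)))
  }
  data.frame(
    category = metrics$category,
    num_report = metrics$num_report,
    num_value = metrics$num_value,
    ppv = fmt(metrics$ppv, metrics$ppv_lo, metrics$ppv_hi),
    npv = fmt(metrics$npv, metrics$npv_lo, metrics$npv_hi),
    sensitivity = fmt(metrics$sensitivity, metrics$sensitivity_lo, metrics$sensitivity_hi),
    specificity = fmt(metrics$specificity, metrics$specificity_lo, metrics$specificity_hi),
    stringsAsFactors = FALSE
  )
}
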