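# Synthetic clinical-report generator: sectioned pathology/imaging reports
# with exhaustive ground truth (CRC status, per-category TNM maxima, phrase
# spans), a deterministic enumeration of the staging-phrase grammar, and the
# distractor bank of TNM look-alikes that must never parse.

# written (surface) forms per category; Haggitt may be written in Roman
written_value_forms <- function() {
  av <- tnm_allowed_values()
  forms <- lapply(av, function(v) setdiff(v, "X"))
  forms$T <- av$T[av$T != "X"]
  for (nm in names(forms)) if ("X" %in% av[[nm]]) forms[[nm]] <- c(forms[[nm]], "X")
  forms$H <- c("0", "1", "2", "3", "4", "I", "II", "III", "IV")
  forms
}

tnm_dialects <- function() {
  c("multi", "osub", "lower", "nogap", "gap", "prefix", "comment", "reorder", "cue")
}

render_token <- function(cat, val, lower = FALSE, gap = FALSE,
                         osub = FALSE, prefix = "") {
  catstr <- cat
  if (lower) { catstr <- tolower(catstr); if (!val %in% c("I", "II", "III", "IV")) val <- tolower(val) }
  if (osub) val <- if (lower) "o" else "O"
  paste0(prefix, catstr, if (gap && val != "is") " ", val)
}

expected_row <- function(cat, val, prefix = "") {
  data.frame(category = cat, prefix = prefix,
             value = normalize_value(val, cat), stringsAsFactors = FALSE)
}

# numeric-ish written forms eligible for the multi-value dialect
multi_eligible <- function(vals) vals[grepl("^[0-4][a-d]?$", vals)]

#' Enumerate the staging-phrase grammar
#'
#' Deterministically renders every allowed (category, written value) token
#' under each applicable documentation variant (multi-value, O-for-zero,
#' lower case, no gap, letter-value gap, prefixes, bracketed comment,
#' reordering, cue-anchored singleton), each paired with its expected parse.
#' Single-token entries are cue-anchored and multi-token entries carry a
#' partner token ("T2" or "N0") so that every entry is a phrase the
#' extractor claims to support. Used by the grammar round-trip test: the
#' extractor must recover every expected (category, prefix, value) multiset
#' exactly.
#'
#' @param cfg A [tnm_config()] (supplies the prefix whitelist).
#' @return Data.frame: `phrase_text`, `dialect`, `category`, `written`, and
#'   an `expected` list-column of data.frames (`category`, `prefix`,
#'   `value`).
#' @export
enumerate_phrase_grammar <- function(cfg = tnm_config()) {
  forms <- written_value_forms()
  partner <- function(cat) if (cat == "T") c("N", "0") else c("T", "2")
  entries <- list()
  add <- function(text, dialect, cat, written, expected) {
    entries[[length(entries) + 1L]] <<- {
      e <- data.frame(phrase_text = text, dialect = dialect, category = cat,
                      written = written, stringsAsFactors = FALSE)
      e$expected <- list(expected)
      e
    }
  }
  for (cat in names(forms)) {
    p <- partner(cat)
    pexp <- expected_row(p[1], p[2])
    ptok <- render_token(p[1], p[2])
    for (val in forms[[cat]]) {
      texp <- expected_row(cat, val)
      tok <- render_token(cat, val)
      roman <- val %in% c("I", "II", "III", "IV")
      both <- function(a, b) rbind(a, b)
      # partner-first for non-T categories mirrors "R0 pT3 ..." style order
      base_pair <- function(t) if (cat == "T") paste(t, ptok) else paste(ptok, t)
      base_exp <- if (cat == "T") both(texp, pexp) else both(pexp, texp)

      if (!roman) {
        add(base_pair(render_token(cat, val, lower = TRUE)), "lower", cat, val,
            base_exp)
      }
      add(if (cat == "T") paste0(tok, ptok) else paste0(ptok, tok),
          "nogap", cat, val, base_exp)
      if (val != "is") {
        add(base_pair(render_token(cat, val, gap = TRUE)), "gap", cat, val, base_exp)
      }
      if (val == "0") {
        add(base_pair(render_token(cat, val, osub = TRUE)), "osub", cat, val, base_exp)
      }
      if (cat == "T") {
        for (pre in cfg$prefix_whitelist) {
          add(paste(render_token(cat, val, prefix = pre), ptok), "prefix", cat, val,
              both(expected_row(cat, val, prefix = pre), pexp))
        }
      }
      add(if (cat == "T") paste0(tok, " (solitary tumour) ", ptok)
          else paste0(ptok, " (see comment) ", tok),
          "comment", cat, val, base_exp)
      add(if (cat == "T") paste(ptok, tok) else paste(tok, ptok),
          "reorder", cat, val,
          if (cat == "T") both(pexp, texp) else both(texp, pexp))
      add(paste("Staged as", tok), "cue", cat, val, texp)
      mv <- multi_eligible(forms[[cat]])
      if (val %in% mv && length(mv) >= 2L) {
        v2 <- mv[(match(val, mv) %% length(mv)) + 1L]
        add(base_pair(paste0(cat, val, "/", v2)), "multi", cat, val,
            if (cat == "T") rbind(texp, expected_row(cat, v2), pexp)
            else rbind(pexp, texp, expected_row(cat, v2)))
      }
    }
  }
  out <- do.call(rbind, entries)
  rownames(out) <- NULL
  out
}

#' Distractor bank: TNM look-alikes that must never parse
#'
#' A fixed library of strings that resemble staging tokens but mean
#' something else: MRI sequences, vertebral levels and ranges, measurements,
#' times, dates, administrative strings and drug doses. The defining
#' property (enforced by the acceptance tests) is that extraction over the
#' bank yields zero tokens.
#'
#' @return Character vector.
#' @export
distractor_bank <- function() {
  c(
    "T1-weighted",
    "T2-weighted",
    "T1 weighted imaging was performed",
    "T2 FLAIR",
    "Axial T2 weighted sequences",
    "Sagittal T1 and T2 weighted sequences were acquired",
    "T1 signal drop on out-of-phase imaging",
    "high T2 signal centrally",
    "T1-T12",
    "T4-T7",
    "C7-T1 level",
    "L1 vertebral body",
    "T12/L1",
    "the first thoracic vertebra (T1)",
    "degenerative change at L1",
    "loss of disc height at T4",
    "10 x 2 mm",
    "15 x 10 x 8 mm nodule",
    "measuring 3 x 2 cm",
    "at T1 and T2 post-contrast",
    "reviewed at 10:30",
    "12/03/2021",
    "ward T3 extension 1234",
    "tel 01865 200 300",
    "oxaliplatin 85 mg/m2",
    "capecitabine 1250 mg/m2 twice daily"
  )
}

#' Synthetic-corpus generator configuration
#'
#' The defaults state the emulated world once: a mixed imaging/pathology
#' CRC-patient corpus where roughly half the reports carry explicit staging,
#' about one in ten staging reports stages only implicitly (prose such as
#' "no residual tumour" with no written T0), a twentieth of explicit stages
#' are historical, a majority of reports mention a colorectal tumour, and
#' every report picks up around one look-alike distractor.
#'
#' @param n_reports Number of reports.
#' @param report_type_mix Proportion of pathology reports (rest imaging).
#' @param p_tnm_phrase Probability a report carries staging information.
#' @param dialect_weights Named non-negative weights over the nine
#'   documentation variants of [tnm_dialects()].
#' @param distractor_rate Expected distractors per report (Poisson).
#' @param crc_positive_rate Probability a report describes current primary
#'   CRC.
#' @param modifier_mix Named weights over the seven modifier classes used
#'   for CRC-negative reports that still mention a tumour.
#' @param p_implicit Probability that staging is implicit (given staging).
#' @param p_historical Probability an explicit stage is historical-only.
#' @param seed Integer seed driving the single pseudo-random stream.
#' @return Validated list of class `"generator_config"`.
#' @export
generator_config <- function(n_reports = 100L,
                             report_type_mix = 0.5,
                             p_tnm_phrase = 0.5,
                             dialect_weights = NULL,
                             distractor_rate = 1,
                             crc_positive_rate = 0.6,
                             modifier_mix = NULL,
                             p_implicit = 0.10,
                             p_historical = 0.05,
                             seed = 1L) {
  if (is.null(dialect_weights)) {
    dialect_weights <- setNames(rep(1, length(tnm_dialects())), tnm_dialects())
  }
  if (is.null(modifier_mix)) {
    modifier_mix <- setNames(rep(1, length(modifier_classes())), modifier_classes())
  }
  probs <- c(report_type_mix = report_type_mix, p_tnm_phrase = p_tnm_phrase,
             crc_positive_rate = crc_positive_rate, p_implicit = p_implicit,
             p_historical = p_historical)
  if (any(probs < 0 | probs > 1)) {
    validation_error("probabilities must lie in [0, 1]: %s",
                     commas(names(probs)[probs < 0 | probs > 1]))
  }
  if (n_reports < 0) validation_error("n_reports must be >= 0")
  if (distractor_rate < 0) validation_error("distractor_rate must be >= 0")
  check_w <- function(w, universe, what) {
    if (!all(names(w) %in% universe) || anyNA(w) || any(w < 0) || !any(w > 0)) {
      validation_error("%s must be named, non-negative, not all zero", what)
    }
    full <- setNames(rep(0, length(universe)), universe)
    full[names(w)] <- w
    full
  }
  structure(list(
    n_reports = as.integer(n_reports), report_type_mix = report_type_mix,
    p_tnm_phrase = p_tnm_phrase,
    dialect_weights = check_w(dialect_weights, tnm_dialects(), "dialect_weights"),
    distractor_rate = distractor_rate, crc_positive_rate = crc_positive_rate,
    modifier_mix = check_w(modifier_mix, modifier_classes(), "modifier_mix"),
    p_implicit = p_implicit, p_historical = p_historical,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# sampling helpers -------------------------------------------------------------

sample_w <- function(x, weights = NULL) {
  if (length(x) == 1L) return(x)
  x[sample.int(length(x), 1L, prob = weights)]
}

crc_tumour_terms <- c("adenocarcinoma", "carcinoma", "tumour",
                      "mucinous adenocarcinoma", "invasive adenocarcinoma")
crc_site_terms <- c("sigmoid colon", "rectum", "caecum", "transverse colon",
                    "descending colon", "ascending colon", "rectosigmoid junction")
crc_compound_terms <- c("colorectal cancer", "rectal adenocarcinoma",
                        "colon cancer", "colorectal carcinoma")

crc_positive_sentence <- function() {
  if (runif(1) < 0.3) {
    paste0(sample_w(c("Appearances are in keeping with ", "Confirmed ")),
           sample_w(crc_compound_terms), ".")
  } else {
    paste0(sample_w(c("Moderately differentiated ", "Well differentiated ",
                      "Poorly differentiated ", "")),
           sample_w(crc_tumour_terms), " of the ", sample_w(crc_site_terms), ".")
  }
}

crc_modifier_sentence <- function(modifier) {
  tum <- sample_w(crc_tumour_terms); site <- sample_w(crc_site_terms)
  switch(modifier,
    negated = sprintf("No evidence of %s in the %s.", tum, site),
    historical = sprintf("History of %s of the %s, resected in 2015.", tum, site),
    general = sprintf("Screening for %s of the %s.", tum, site),
    nondefinite = sprintf("Possible %s of the %s.", tum, site),
    metastasis = sprintf("Metastatic %s in the liver from the %s primary.", tum, site),
    recurrence = sprintf("Recurrent %s of the %s.", tum, site),
    treatment_response = sprintf("Interval decrease in the %s %s following chemoradiotherapy.", site, tum)
  )
}

# sample a random explicit staging phrase under one dialect; returns the
# phrase text plus expected (category, prefix, value) tokens
sample_tnm_phrase <- function(dialect, report_type) {
  forms <- written_value_forms()
  pick <- function(cat, numeric_only = FALSE) {
    v <- forms[[cat]]
    if (numeric_only || dialect == "lower") v <- setdiff(v, c("I", "II", "III", "IV"))
    if (dialect %in% c("gap", "multi")) v <- setdiff(v, "is")
    if (dialect == "multi") v <- multi_eligible(v)
    sample_w(v)
  }
  cats <- c("T", "N")
  if (runif(1) < 0.7) cats <- c(cats, "M")
  if (report_type == "pathology") {
    for (extra in c("V", "L", "R")) if (runif(1) < 0.4) cats <- c(cats, extra)
    if (runif(1) < 0.3) cats <- c(cats, "Pn")
    if (runif(1) < 0.2) cats <- c(cats, "G")
    if (runif(1) < 0.05) cats <- c(cats, "SM")
    if (runif(1) < 0.02) cats <- c(cats, "H")
  }
  if (dialect == "cue") cats <- "T"
  vals <- vapply(cats, pick, "")
  prefix <- if (dialect == "prefix") {
    sample_w(c("p", "yp", "c", "mr", "ymr", "y"))
  } else ""
  toks <- character(length(cats)); exp <- list()
  for (i in seq_along(cats)) {
    cat <- cats[i]; val <- vals[i]
    lower <- dialect == "lower"
    gap <- dialect == "gap"
    osub <- dialect == "osub" && val == "0"
    pre <- if (cat == "T") prefix else ""
    if (dialect == "multi" && cat == "T") {
      mv <- multi_eligible(forms$T)
      v2 <- sample_w(setdiff(mv, val))
      toks[i] <- paste0("T", val, "/", v2)
      exp[[i]] <- rbind(expected_row("T", val), expected_row("T", v2))
    } else {
      toks[i] <- render_token(cat, val, lower = lower, gap = gap,
                              osub = osub, prefix = pre)
      exp[[i]] <- expected_row(cat, val, prefix = pre)
    }
  }
  if (dialect == "osub" && !"0" %in% vals) {
    # guarantee the dialect is visible: force the N token to zero
    i <- match("N", cats)
    toks[i] <- render_token("N", "0", osub = TRUE)
    exp[[i]] <- expected_row("N", "0")
  }
  if (dialect == "reorder") {
    ord <- sample.int(length(toks))
    toks <- toks[ord]; exp <- exp[ord]
  }
  if (dialect == "comment" && length(toks) > 1L) {
    toks[1] <- paste0(toks[1], " (solitary tumour)")
  }
  text <- if (dialect == "nogap") paste(toks, collapse = "") else paste(toks, collapse = " ")
  if (dialect == "cue") text <- paste("Staged as", text)
  list(text = text, expected = do.call(rbind, exp), dialect = dialect)
}

# expected per-category maxima for a set of expected tokens, under the same
# ranking as aggregate_max (gold is defined through the documented ranking)
expected_maxima <- function(expected, cfg = tnm_config()) {
  out <- setNames(as.list(rep(NA_character_, length(result_columns))), result_columns)
  if (is.null(expected) || !nrow(expected)) return(out)
  for (cat in names(category_to_column)) {
    rows <- expected[expected$category == cat, , drop = FALSE]
    if (!nrow(rows)) next
    rk <- tnm_value_rank(rows$value, cat, cfg$ranking)
    out[[category_to_column[[cat]]]] <- cfg$ranking[[cat]][max(rk)]
    if (cat == "T") {
      winners <- rows[rk == max(rk), , drop = FALSE]
      pre <- winners$prefix[nrow(winners)]
      out$t_prefix <- if (nzchar(pre)) pre else NA_character_
    }
  }
  out
}

#' Generate a synthetic corpus with exhaustive ground truth
#'
#' Builds sectioned pathology reports (CLINICAL DETAILS / MACROSCOPY /
#' MICROSCOPY / CONCLUSION) and imaging reports (TECHNIQUE / FINDINGS /
#' IMPRESSION), with MRI-sequence and other distractors in the
#' TECHNIQUE/CLINICAL DETAILS section, CRC mentions (asserted or under a
#' sampled modifier), and explicit TNM phrases rendered in a sampled
#' dialect. The gold record describes the emitted text exactly: CRC status,
#' per-category maxima under the [aggregate_max()] ranking, phrase spans,
#' historical flag and implicit-stage values.
#'
#' @param config A [generator_config()].
#' @return List with `corpus` (report_id, report_type, text, date) and
#'   `gold` (report_id, crc_status, modifier, dialect, t_prefix, t, ..., h,
#'   historical, implicit_json, phrase_start, phrase_end).
#' @export
generate_corpus <- function(config = generator_config()) {
  if (!inherits(config, "generator_config")) config <- do.call(generator_config, config)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  n <- config$n_reports
  corpus <- vector("list", n); gold <- vector("list", n)
  bank <- distractor_bank()
  for (i in seq_len(n)) {
    rid <- sprintf("synth-%05d", i)
    type <- if (runif(1) < config$report_type_mix) "pathology" else "imaging"
    crc_pos <- runif(1) < config$crc_positive_rate
    modifier <- ""
    crc_sentence <- if (crc_pos) {
      crc_positive_sentence()
    } else if (runif(1) < 0.5) {
      modifier <- sample_w(modifier_classes(), config$modifier_mix)
      crc_modifier_sentence(modifier)
    } else ""

    has_stage <- runif(1) < config$p_tnm_phrase
    implicit <- has_stage && runif(1) < config$p_implicit
    historical <- FALSE
    phrase <- NULL; implicit_vals <- list()
    stage_sentence <- ""
    if (has_stage && implicit) {
      if (runif(1) < 0.5) {
        stage_sentence <- "There is no residual tumour at the primary site."
        implicit_vals <- list(t = "0")
      } else {
        stage_sentence <- "There is nothing to suggest distant metastatic disease."
        implicit_vals <- list(m = "0")
      }
    } else if (has_stage) {
      dialect <- sample_w(tnm_dialects(), config$dialect_weights)
      phrase <- sample_tnm_phrase(dialect, type)
      historical <- runif(1) < config$p_historical
      stage_sentence <- if (historical) {
        paste0("Previously staged as ", phrase$text, ".")
      } else {
        paste0(phrase$text, ".")
      }
    }

    k <- stats::rpois(1, config$distractor_rate)
    distractors <- if (k > 0) paste0(sample(bank, k, replace = TRUE), ".") else character(0)

    filler <- sample_w(c("The specimen was received fresh.",
                         "Comparison was made with the previous examination.",
                         "The margins are clear.",
                         "The appearances are otherwise unremarkable."))
    if (type == "pathology") {
      secs <- c(paste(c("CLINICAL DETAILS:", distractors), collapse = " "),
                paste("MACROSCOPY:", filler),
                paste(c("MICROSCOPY:", crc_sentence), collapse = " "),
                "CONCLUSION:")
    } else {
      secs <- c(paste(c("TECHNIQUE:", distractors), collapse = " "),
                paste(c("FINDINGS:", crc_sentence, filler), collapse = " "),
                "IMPRESSION:")
    }
    head_txt <- paste(secs, collapse = "\n")
    text <- if (nzchar(stage_sentence)) paste0(head_txt, " ", stage_sentence) else head_txt
    phrase_start <- NA_integer_; phrase_end <- NA_integer_
    if (!is.null(phrase)) {
      off <- nchar(head_txt) + 1L +
        (if (historical) nchar("Previously staged as ") else 0L)
      phrase_start <- off
      phrase_end <- off + nchar(phrase$text)
    }

    corpus[[i]] <- data.frame(report_id = rid, report_type = type, text = text,
                              date = NA_character_, stringsAsFactors = FALSE)
    gmax <- expected_maxima(phrase$expected)
    g <- data.frame(report_id = rid, crc_status = crc_pos, modifier = modifier,
                    dialect = if (is.null(phrase)) "" else phrase$dialect,
                    stringsAsFactors = FALSE)
    for (col in result_columns) g[[col]] <- gmax[[col]]
    g$historical <- historical
    g$implicit_json <- if (length(implicit_vals)) {
      as.character(jsonlite::toJSON(implicit_vals, auto_unbox = TRUE))
    } else "{}"
    g$phrase_start <- phrase_start; g$phrase_end <- phrase_end
    gold[[i]] <- g
  }
  corpus <- if (n) do.call(rbind, corpus) else
    data.frame(report_id = character(0), report_type = character(0),
               text = character(0), date = character(0), stringsAsFactors = FALSE)
  gold <- if (n) do.call(rbind, gold) else
    data.frame(report_id = character(0), stringsAsFactors = FALSE)
  list(corpus = corpus, gold = gold)
}
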