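# TNM phrase detection, token parsing, false-positive guards and per-report
# aggregation.
#
# Strategy: one PCRE pass finds candidate tokens (optional lower-case prefix,
# category letter(s), optional small gap, one or more values joined by the
# configured separators). Candidates then go through value normalisation,
# look-alike guards, phrase assembly (tokens merge while the text between
# them is short punctuation or a single bracketed comment), the
# letter-O-adjacency rule, and the single-token staging-cue rule.

# ---- token scanning ---------------------------------------------------------

tnm_value_core <- "[0-4][a-d]?|is|IV|I{1,3}|[xo]"

tnm_token_pattern <- function(cfg) {
  seps <- vapply(cfg$separators, function(s) {
    if (s == "or") " ?or ?" else paste0(" ?", rx_escape(s), " ?")
  }, "")
  rest <- sprintf("(?:(?:%s)(?:%s))*",
                  paste(seps, collapse = "|"), tnm_value_core)
  sprintf(paste0(
    # a token must not continue a word, except right after another token's
    # value-final letter (substage "1a", "is", "X") in no-gap sequences
    "(?i)(?:(?<![[:alpha:]])|(?<=[0-9][abcd])|(?<=is)|(?<=[[:alpha:]]x))",
    # prefixes are lower-case by convention; only T/N/M may carry one
    "(?:(?<pre>(?-i:[acmpry]{1,3}))?(?<cat1>T|N|M)|(?<cat2>SM|PN|V|R|L|G|H))",
    "(?<gap> {0,2})",
    "(?<vals>(?:%s)%s)",
    # a token may be followed by a non-word character or by another token
    # ("T1N0M0" has no gaps), never by a stray digit or letter ("T12")
    "(?=$|[^[:alnum:]]|[acmpry]{0,3}(?:SM|PN|T|N|M|V|R|L|G|H) {0,2}(?:[0-4]|is|[xoI]))"
  ), tnm_value_core, rest)
}

# split a "vals" capture ("1/2/3", "0", "1 or 2a") into raw values + offsets
split_values <- function(vals, cfg) {
  sep_rx <- paste(vapply(cfg$separators, function(s) {
    if (s == "or") "^ ?or ?" else paste0("^ ?", rx_escape(s), " ?")
  }, ""), collapse = "|")
  val_rx <- paste0("^(?i)(?:", tnm_value_core, ")")
  raws <- character(0); offs <- integer(0)
  pos <- 1L
  while (pos <= nchar(vals)) {
    rest <- substr(vals, pos, nchar(vals))
    m <- regexpr(val_rx, rest, perl = TRUE)
    if (m == -1L) break
    raws <- c(raws, substr(rest, 1L, attr(m, "match.length")))
    offs <- c(offs, pos - 1L)
    pos <- pos + attr(m, "match.length")
    if (pos > nchar(vals)) break
    s <- regexpr(sep_rx, substr(vals, pos, nchar(vals)), perl = TRUE)
    if (s == -1L) break
    pos <- pos + attr(s, "match.length")
  }
  list(raw = raws, offset = offs)
}

empty_tokens <- function() {
  data.frame(token = integer(0), category = character(0),
             prefix = character(0), value = character(0),
             raw = character(0), o_sub = logical(0),
             start = integer(0), end = integer(0),
             tok_start = integer(0), tok_end = integer(0),
             stringsAsFactors = FALSE)
}

# scan all candidate tokens; returns one row per accepted value (0-based spans)
scan_tnm_tokens <- function(text, cfg = tnm_config(), offset = 0L) {
  if (!is_string(text) || !nzchar(text)) return(empty_tokens())
  pat <- tnm_token_pattern(cfg)
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty_tokens())
  cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
  nm <- colnames(cs)
  out <- vector("list", length(m))
  for (i in seq_along(m)) {
    grab <- function(g) {
      if (cl[i, g] == 0L) "" else substr(text, cs[i, g], cs[i, g] + cl[i, g] - 1L)
    }
    pre <- grab("pre")
    cat_raw <- if (cl[i, "cat1"] > 0L) grab("cat1") else grab("cat2")
    cat_start <- if (cl[i, "cat1"] > 0L) cs[i, "cat1"] else cs[i, "cat2"]
    gap_len <- cl[i, "gap"]
    vals <- grab("vals"); vals_start <- cs[i, "vals"]
    cu <- toupper(cat_raw)
    category <- if (cu == "PN") "Pn" else cu
    sv <- split_values(vals, cfg)
    if (!length(sv$raw)) next
    norm <- normalize_value(sv$raw, category, cfg$ranking)
    # "is" (in situ) only without a gap: "T is" is prose, "Tis" is staging
    if (gap_len > 0L) norm[tolower(sv$raw) == "is"] <- NA_character_
    # all-lower-case "pn0"/"pn1"/"pnx" is perineural, not prefix-p + nodal
    if (pre == "p" && cat_raw == "n") {
      as_pn <- normalize_value(sv$raw, "Pn", cfg$ranking)
      if (!anyNA(as_pn)) { category <- "Pn"; norm <- as_pn; pre <- "" }
    }
    tok_start <- as.integer(m[i])
    if (nzchar(pre)) {
      ok_cat <- category == "T" || (cfg$allow_prefix_nm && category %in% c("N", "M"))
      if (!ok_cat || !(tolower(pre) %in% cfg$prefix_whitelist)) {
        pre <- ""                       # unknown/unattached combination: drop
        tok_start <- as.integer(cat_start)
      }
    }
    keep <- !is.na(norm)
    if (!any(keep)) next
    v_start <- as.integer(vals_start + sv$offset) # 1-based
    v_end <- v_start + nchar(sv$raw) - 1L
    # the first value's span covers the category letter too
    sp_start <- ifelse(seq_along(norm) == 1L, tok_start, v_start)
    out[[i]] <- data.frame(
      token = i, category = category,
      prefix = tolower(pre), value = norm, raw = sv$raw,
      o_sub = tolower(sv$raw) == "o",
      start = sp_start - 1L, end = v_end,
      tok_start = tok_start - 1L,
      tok_end = as.integer(m[i]) + attr(m, "match.length")[i] - 1L,
      stringsAsFactors = FALSE
    )[keep, , drop = FALSE]
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res) || !nrow(res)) return(empty_tokens())
  res$start <- res$start + offset; res$end <- res$end + offset
  res$tok_start <- res$tok_start + offset; res$tok_end <- res$tok_end + offset
  rownames(res) <- NULL
  res
}

# ---- false-positive guards --------------------------------------------------

#' Reject a TNM look-alike based on its local context
#'
#' Inspects the text around a candidate token and returns `TRUE` (reject)
#' when the context marks it as a distractor rather than staging: MRI
#' sequence context for T1/T2 ("T1-weighted", "T2 FLAIR", "axial T1 ...")
#' and vertebral context for T1-T4 and L1 ("first thoracic vertebra (T1)",
#' ranges such as "T1-T12" or "C7-T1"). Both term lists are configurable via
#' [tnm_config()]. Candidates that are not plain single-digit T/L tokens, or
#' that carry a staging prefix, are never rejected here.
#'
#' @param start,end 0-based half-open span of the candidate token.
#' @param text Full report text.
#' @param cfg A [tnm_config()].
#' @return `TRUE` if the candidate must be rejected.
#' @examples
#' guard_false_positive(6, 8, "Axial T1 weighted images", tnm_config())  # TRUE
#' guard_false_positive(0, 2, "T0 N0", tnm_config())                     # FALSE
#' @export
guard_false_positive <- function(start, end, text, cfg = tnm_config()) {
  cand <- span_text(text, start, end)
  m <- regexec("^([TtLl]) {0,2}([0-4])$", cand)
  if (m[[1]][1] == -1L) return(FALSE)
  parts <- regmatches(cand, m)[[1]]
  category <- toupper(parts[2]); value <- parts[3]
  n <- nchar(text)
  left <- span_text(text, max(0L, start - cfg$guard_window), start)
  right <- span_text(text, end, min(n, end + cfg$guard_window))
  # distractor context never crosses a sentence boundary
  left <- sub(".*[.;\n]", "", left)
  right <- sub("[.;\n].*", "", right)
  word_rx <- function(terms) paste0("(?i)\\b(", paste(rx_escape(terms), collapse = "|"), ")\\b")
  if (category == "T" && value %in% c("1", "2") &&
      (grepl(word_rx(cfg$guard_mri_terms), left, perl = TRUE) ||
       grepl(word_rx(cfg$guard_mri_terms), right, perl = TRUE))) {
    return(TRUE)
  }
  if ((category == "T" && value %in% as.character(1:4)) ||
      (category == "L" && value == "1")) {
    if (grepl(word_rx(cfg$guard_vertebral_terms), left, perl = TRUE) ||
        grepl(word_rx(cfg$guard_vertebral_terms), right, perl = TRUE)) {
      return(TRUE)
    }
    # vertebral ranges: token flanked by "-T12", "/L5", or preceded by "C7-"
    if (grepl("^ ?[-–/] ?(?:[TLCStlcs] ?[0-9]|[0-9]{2})", right, perl = TRUE)) return(TRUE)
    if (grepl("[TLCStlcs] ?[0-9]{1,2} ?[-–/] ?$", left, perl = TRUE)) return(TRUE)
  }
  FALSE
}

# vectorised internal guard over a token table
apply_guards <- function(tokens, text, cfg) {
  if (!nrow(tokens)) return(tokens)
  drop_tok <- integer(0)
  for (tid in unique(tokens$token)) {
    rows <- tokens[tokens$token == tid, , drop = FALSE]
    # only plain single-value unprefixed tokens are look-alikes
    if (nrow(rows) != 1L || nzchar(rows$prefix)) next
    if (guard_false_positive(rows$tok_start, rows$tok_end, text, cfg)) {
      drop_tok <- c(drop_tok, tid)
    }
  }
  tokens[!tokens$token %in% drop_tok, , drop = FALSE]
}

# ---- phrase assembly --------------------------------------------------------

phrase_gap_ok <- function(gap, cfg) {
  if (nchar(gap) > cfg$max_gap) return(FALSE)
  # allow one bracketed comment ("T1a (solitary tumour) N0"); the remainder
  # must be free of word characters and sentence terminators
  rest <- sub("\\([^()\n]*\\)", "", gap)
  !grepl("[[:alnum:].;\n]", rest)
}

group_tokens <- function(tokens, text, cfg) {
  tids <- unique(tokens$token)
  ext <- do.call(rbind, lapply(tids, function(tid) {
    r <- tokens[tokens$token == tid, ]
    data.frame(token = tid, start = min(r$tok_start), end = max(r$end))
  }))
  ext <- ext[order(ext$start), , drop = FALSE]
  grp <- integer(nrow(ext)); g <- 1L; grp[1] <- 1L
  if (nrow(ext) > 1L) for (i in 2:nrow(ext)) {
    gap <- span_text(text, ext$end[i - 1L], ext$start[i])
    if (!phrase_gap_ok(gap, cfg)) g <- g + 1L
    grp[i] <- g
  }
  ext$group <- grp
  ext
}

has_cue <- function(text, start, cfg) {
  left <- span_text(text, max(0L, start - cfg$cue_window), start)
  rx <- paste0("(?i)\\b(", paste(rx_escape(cfg$cues), collapse = "|"), ")\\b")
  grepl(rx, left, perl = TRUE)
}

empty_phrases <- function() {
  out <- data.frame(start = integer(0), end = integer(0),
                    text = character(0), anchored_by_cue = logical(0),
                    n_tokens = integer(0), stringsAsFactors = FALSE)
  out$tokens <- list()
  out
}

#' Find TNM staging phrases in a report
#'
#' Scans the whole report for candidate TNM tokens, rejects look-alikes via
#' [guard_false_positive()], merges nearby tokens into phrases, drops
#' letter-O-for-zero tokens that are not immediately adjacent to another TNM
#' token, and keeps single-category phrases only when anchored by a staging
#' cue ("staged as", "stage", "TNM", ...).
#'
#' @param report A `ClinicalReport` row (any list/data.frame with a `text`
#'   element) or a plain string.
#' @param cfg A [tnm_config()].
#' @return A data.frame with one row per phrase: 0-based `start`/`end`,
#'   `text`, `anchored_by_cue`, `n_tokens`, and a `tokens` list-column of
#'   data.frames (`category`, `prefix`, `value`, `raw`, `start`, `end`).
#' @examples
#' find_tnm_phrases("Conclusion: R0 pT3 L0 V0 N0 Mx.")
#' find_tnm_phrases("Axial T1 and T2 weighted sequences were acquired")
#' @export
find_tnm_phrases <- function(report, cfg = tnm_config()) {
  text <- if (is_string(report)) report else as.character(report$text)
  if (is.na(text) || !nzchar(text)) return(empty_phrases())
  tokens <- scan_tnm_tokens(text, cfg)
  tokens <- apply_guards(tokens, text, cfg)
  if (!nrow(tokens)) return(empty_phrases())

  ext <- group_tokens(tokens, text, cfg)

  # letter-O-for-zero values need an immediate TNM neighbour ("T0 NO MX"
  # keeps NO; a lone prose "No" never becomes N0)
  osub_tok <- unique(tokens$token[tokens$o_sub])
  if (length(osub_tok)) {
    ws_adjacent <- function(a, b) { # a before b
      gap <- span_text(text, a, b)
      nchar(gap) <= cfg$adjacency_gap && !grepl("[^ \t]", gap)
    }
    drop <- integer(0)
    for (tid in osub_tok) {
      i <- which(ext$token == tid)
      ok <- (i > 1L && ws_adjacent(ext$end[i - 1L], ext$start[i])) ||
        (i < nrow(ext) && ws_adjacent(ext$end[i], ext$start[i + 1L]))
      if (!ok) drop <- c(drop, tid)
    }
    if (length(drop)) {
      keep_o <- !(tokens$token %in% drop & tokens$o_sub)
      tokens <- tokens[keep_o, , drop = FALSE]
      if (!nrow(tokens)) return(empty_phrases())
      ext <- group_tokens(tokens, text, cfg) # regroup: a bridge may be gone
    }
  }

  phrases <- lapply(split(ext, ext$group), function(e) {
    ph_start <- min(e$start); ph_end <- max(e$end)
    tok <- tokens[tokens$token %in% e$token, , drop = FALSE]
    tok <- tok[order(tok$start), , drop = FALSE]
    anchored <- has_cue(text, ph_start, cfg)
    if (length(unique(tok$category)) < 2L && !anchored) return(NULL)
    out <- data.frame(start = ph_start, end = ph_end,
                      text = span_text(text, ph_start, ph_end),
                      anchored_by_cue = anchored,
                      n_tokens = nrow(tok), stringsAsFactors = FALSE)
    out$tokens <- list(tok[, c("category", "prefix", "value", "raw", "start", "end")])
    out
  })
  phrases <- phrases[!vapply(phrases, is.null, TRUE)]
  if (!length(phrases)) return(empty_phrases())
  out <- do.call(rbind, phrases)
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}

#' Parse a candidate phrase into category/prefix/value tokens
#'
#' Tokenises `candidate_text` with the same grammar as [find_tnm_phrases()]
#' but without guards or cue anchoring: every documentation variant is
#' normalised (case-folded letters, O read as 0 in value position,
#' whitespace between letter and value absorbed) and multi-valued tokens
#' ("T1/2/3") are expanded to one row per value. Unparseable residue is
#' skipped, never an error.
#'
#' @param candidate_text Phrase text.
#' @param offset 0-based offset of the phrase within its report, added to
#'   all returned spans.
#' @param cfg A [tnm_config()].
#' @return A data.frame: `category`, `prefix`, `value`, `raw`, 0-based
#'   `start`/`end`.
#' @examples
#' parse_phrase("T1/2/3 N0 V0")
#' parse_phrase("ymrT1")
#' @export
parse_phrase <- function(candidate_text, offset = 0L, cfg = tnm_config()) {
  tokens <- scan_tnm_tokens(candidate_text, cfg)
  if (nrow(tokens) && any(tokens$o_sub)) {
    ext <- group_tokens(tokens, candidate_text, cfg)
    ws_adjacent <- function(a, b) {
      gap <- span_text(candidate_text, a, b)
      nchar(gap) <= cfg$adjacency_gap && !grepl("[^ \t]", gap)
    }
    drop <- integer(0)
    for (tid in unique(tokens$token[tokens$o_sub])) {
      i <- which(ext$token == tid)
      ok <- (i > 1L && ws_adjacent(ext$end[i - 1L], ext$start[i])) ||
        (i < nrow(ext) && ws_adjacent(ext$end[i], ext$start[i + 1L]))
      if (!ok) drop <- c(drop, tid)
    }
    tokens <- tokens[!(tokens$token %in% drop & tokens$o_sub), , drop = FALSE]
  }
  tokens$start <- tokens$start + as.integer(offset)
  tokens$end <- tokens$end + as.integer(offset)
  rownames(tokens) <- NULL
  tokens[, c("category", "prefix", "value", "raw", "start", "end")]
}

# ---- aggregation ------------------------------------------------------------

result_columns <- c("t_prefix", "t", "n", "m", "v", "r", "l", "pn", "g", "sm", "h")

category_to_column <- c(T = "t", N = "n", M = "m", V = "v", R = "r",
                        L = "l", Pn = "pn", G = "g", SM = "sm", H = "h")

#' Aggregate phrases to per-report maximum TNM values
#'
#' Reduces all tokens found in a report to one maximum value per category
#' under the clinical severity ranking of [tnm_allowed_values()] (X ranks
#' below every informative value, so X is reported only when it is the sole
#' observation). The T prefix reported is the one attached to the token that
#' supplied the T maximum; when several tokens tie, the last in document
#' order wins.
#'
#' @param phrases A phrase data.frame from [find_tnm_phrases()].
#' @param report_id Report identifier to stamp on the result row.
#' @param cfg A [tnm_config()].
#' @return One-row data.frame: `report_id`, `t_prefix`, `t`, `n`, `m`, `v`,
#'   `r`, `l`, `pn`, `g`, `sm`, `h` (NA where no value observed),
#'   `n_phrases`.
#' @examples
#' ph <- find_tnm_phrases("R0 pT3 L0 V0 N0 Mx. Previously pT2 N1 Mx L0 V0 R1.")
#' aggregate_max(ph, "r1")
#' @export
aggregate_max <- function(phrases, report_id, cfg = tnm_config()) {
  out <- as.data.frame(c(list(report_id = report_id),
                         setNames(as.list(rep(NA_character_, length(result_columns))),
                                  result_columns),
                         list(n_phrases = nrow(phrases))),
                       stringsAsFactors = FALSE)
  if (!nrow(phrases)) return(out)
  tok <- do.call(rbind, phrases$tokens)
  for (cat in names(category_to_column)) {
    rows <- tok[tok$category == cat, , drop = FALSE]
    if (!nrow(rows)) next
    rk <- tnm_value_rank(rows$value, cat, cfg$ranking)
    best <- max(rk)
    out[[category_to_column[[cat]]]] <- cfg$ranking[[cat]][best]
    if (cat == "T") {
      winners <- rows[rk == best, , drop = FALSE]
      last <- winners[which.max(winners$start), ]
      out$t_prefix <- if (nzchar(last$prefix)) last$prefix else NA_character_
    }
  }
  out
}

# ---- corpus-level driver ----------------------------------------------------

extract_one <- function(report_id, text, cfg, rules) {
  phrases <- find_tnm_phrases(text, cfg)
  if (cfg$drop_historical && nrow(phrases)) {
    if (is.null(rules)) {
      config_error("drop_historical requires trigger rules (see default_trigger_rules())")
    }
    hist <- rules[rules$modifier == "historical", , drop = FALSE]
    asg <- scope_modifiers(text, phrases[, c("start", "end")], hist)
    scoped <- unique(asg$concept[asg$modifier == "historical"])
    if (length(scoped)) phrases <- phrases[-scoped, , drop = FALSE]
  }
  list(values = aggregate_max(phrases, report_id, cfg), phrases = phrases)
}

#' Extract TNM staging from a corpus of reports
#'
#' Runs the full pipeline ([find_tnm_phrases()] then [aggregate_max()]) on
#' each report, in order, optionally in parallel. Output is deterministic
#' and independent of the number of workers.
#'
#' @param corpus Data.frame with `report_id` and `text` columns (see
#'   [read_corpus()]).
#' @param cfg A [tnm_config()]. With `drop_historical = TRUE`, phrases inside
#'   a historical trigger scope are discarded before aggregation.
#' @param workers Number of parallel workers (forked; results are
#'   reassembled in input order).
#' @param trigger_rules Trigger lexicon for the historical post-filter.
#' @return Object of class `"tnm_results"`: list with `values` (one row per
#'   report, columns as [aggregate_max()]) and `phrases` (one row per
#'   phrase: `report_id`, `start`, `end`, `text`, `anchored_by_cue`,
#'   `tokens_json`).
#' @examples
#' corpus <- data.frame(report_id = "r1", report_type = "pathology",
#'                      text = "Invasive adenocarcinoma, pT3 N1 M0 R0 V1 L1.")
#' extract_tnm(corpus)$values
#' @export
extract_tnm <- function(corpus, cfg = tnm_config(), workers = 1L,
                        trigger_rules = NULL) {
  validate_corpus(corpus)
  n <- nrow(corpus)
  run <- function(i) extract_one(corpus$report_id[i], corpus$text[i], cfg, trigger_rules)
  res <- if (workers > 1L && n > 1L) {
    parallel::mclapply(seq_len(n), run, mc.cores = workers)
  } else {
    lapply(seq_len(n), run)
  }
  values <- do.call(rbind, lapply(res, `[[`, "values"))
  phr <- lapply(seq_len(n), function(i) {
    p <- res[[i]]$phrases
    if (!nrow(p)) return(NULL)
    data.frame(report_id = corpus$report_id[i],
               phrase_start = p$start, phrase_end = p$end,
               phrase_text = p$text, anchored_by_cue = p$anchored_by_cue,
               tokens_json = vapply(p$tokens, function(t) {
                 as.character(jsonlite::toJSON(t, dataframe = "rows"))
               }, ""),
               stringsAsFactors = FALSE)
  })
  phrases <- do.call(rbind, phr[!vapply(phr, is.null, TRUE)])
  if (is.null(phrases)) {
    phrases <- data.frame(report_id = character(0), phrase_start = integer(0),
                          phrase_end = integer(0), phrase_text = character(0),
                          anchored_by_cue = logical(0), tokens_json = character(0),
                          stringsAsFactors = FALSE)
  }
  rownames(values) <- NULL
  structure(list(values = values, phrases = phrases), class = "tnm_results")
}

#' @export
print.tnm_results <- function(x, ...) {
  n_any <- sum(x$values$n_phrases > 0)
  cat(sprintf("TNM extraction over %d report(s): %d with staging phrases, %d phrase(s) total\n",
              nrow(x$values), n_any, nrow(x$phrases)))
  print(head(x$values, 10))
  invisible(x)
}
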