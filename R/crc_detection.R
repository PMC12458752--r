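# Primary-CRC report detection: tumour keywords linked to colorectal sites,
# then modifier exclusion via the context engine.

read_term_file <- function(path) {
  if (!file.exists(path)) config_error("lexicon file not found: %s", path)
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  unique(tolower(lines[!grepl("^(#|$)", lines)]))
}

#' Load the CRC keyword lexicons
#'
#' Reads three plain-text lexicons from a directory: `tumour_terms.txt`
#' (tumour keywords needing a site link), `sites.txt` (colorectal anatomical
#' sites) and `compound_terms.txt` (self-sufficient terms such as
#' "colorectal cancer"). One term per line, `#` comments.
#'
#' @param dir Directory path; defaults to the lexicons shipped with the
#'   package.
#' @return List of class `"crc_lexicons"` with elements `tumour`, `sites`,
#'   `compound`.
#' @export
load_crc_lexicons <- function(dir = system.file("extdata", "lexicons", "crc",
                                                package = "crctnm", mustWork = TRUE)) {
  structure(list(
    tumour = read_term_file(file.path(dir, "tumour_terms.txt")),
    sites = read_term_file(file.path(dir, "sites.txt")),
    compound = read_term_file(file.path(dir, "compound_terms.txt"))
  ), class = "crc_lexicons")
}

crc_config <- function(link_window = 120L, context_chars = 60L) {
  list(link_window = as.integer(link_window),
       context_chars = as.integer(context_chars))
}

locate_terms <- function(text, terms) {
  out <- lapply(terms, function(tm) {
    rx <- paste0("(?i)\\b", rx_escape(tm), "\\b")
    m <- gregexpr(rx, text, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(term = tm, start = as.integer(m) - 1L,
               end = as.integer(m) + attr(m, "match.length") - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) {
    return(data.frame(term = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  out[order(out$start, -out$end), , drop = FALSE]
}

# drop matches nested inside (or overlapping) a longer, earlier match
drop_overlaps <- function(hits) {
  if (nrow(hits) < 2L) return(hits)
  keep <- logical(nrow(hits)); limit <- -1L
  for (i in seq_len(nrow(hits))) {
    if (hits$start[i] >= limit) { keep[i] <- TRUE; limit <- hits$end[i] }
  }
  hits[keep, , drop = FALSE]
}

# 0-based start of the sentence containing position p, and its end
sentence_bounds <- function(text) {
  br <- gregexpr("[.;\n]", text)[[1]]
  ends <- if (br[1] == -1L) integer(0) else as.integer(br) # 1-based terminator
  starts <- c(0L, ends)                                    # 0-based starts
  ends <- c(ends - 1L, nchar(text))                        # 0-based, half-open ends
  data.frame(start = starts, end = ends)[starts < ends, , drop = FALSE]
}

same_sentence <- function(bounds, a, b) {
  sa <- findInterval(a, bounds$start)
  sb <- findInterval(b, bounds$start)
  sa == sb
}

empty_matches <- function() {
  data.frame(term = character(0), tumour_start = integer(0),
             tumour_end = integer(0), site = character(0),
             site_start = integer(0), site_end = integer(0),
             linked = logical(0), compound = logical(0),
             modifiers = character(0), included = logical(0),
             left_context = character(0), right_context = character(0),
             stringsAsFactors = FALSE)
}

#' Locate colorectal tumour keyword matches in a report
#'
#' Finds every tumour-keyword and compound-term occurrence. A tumour term is
#' `linked` when a site term occurs in the same sentence with term starts at
#' most the linkage window apart (120 characters by default); compound terms
#' are linked by construction. Context modifiers are not yet assigned
#' (`modifiers` empty, `included` reflects linkage only); see
#' [classify_crc()].
#'
#' @param report A `ClinicalReport` row or a plain string.
#' @param lexicons A [load_crc_lexicons()] result.
#' @param cfg Internal options: `link_window`, `context_chars`.
#' @return Data.frame with one row per keyword mention: `term`,
#'   `tumour_start`, `tumour_end` (0-based), `site`, `site_start`,
#'   `site_end` (NA when unlinked), `linked`, `compound`, `modifiers`,
#'   `included`, `left_context`, `right_context`.
#' @examples
#' lex <- load_crc_lexicons()
#' find_keyword_matches("Adenocarcinoma of the sigmoid colon.", lex)
#' @export
find_keyword_matches <- function(report, lexicons, cfg = crc_config()) {
  text <- if (is_string(report)) report else as.character(report$text)
  if (is.na(text) || !nzchar(text)) return(empty_matches())
  comp <- locate_terms(text, lexicons$compound)
  tum <- locate_terms(text, lexicons$tumour)
  comp$compound <- rep(TRUE, nrow(comp))
  tum$compound <- rep(FALSE, nrow(tum))
  hits <- rbind(comp, tum)
  if (!nrow(hits)) return(empty_matches())
  # compound terms shade the tumour terms they contain ("colorectal cancer"
  # suppresses the bare "cancer"); among ties, longest-first
  hits <- hits[order(hits$start, -(hits$end - hits$start), -hits$compound), ]
  hits <- drop_overlaps(hits)
  sites <- locate_terms(text, lexicons$sites)
  bounds <- sentence_bounds(text)
  n <- nchar(text)
  out <- hits
  out$site <- NA_character_; out$site_start <- NA_integer_; out$site_end <- NA_integer_
  out$linked <- out$compound
  for (i in seq_len(nrow(out))) {
    if (out$compound[i] || !nrow(sites)) next
    ok <- abs(sites$start - out$start[i]) <= cfg$link_window &
      same_sentence(bounds, sites$start, out$start[i])
    # a site nested in the keyword itself (defensive; overlaps already pruned)
    ok <- ok & !(sites$start >= out$start[i] & sites$end <= out$end[i])
    if (any(ok)) {
      j <- which(ok)[which.min(abs(sites$start[ok] - out$start[i]))]
      out$site[i] <- sites$term[j]
      out$site_start[i] <- sites$start[j]; out$site_end[i] <- sites$end[j]
      out$linked[i] <- TRUE
    }
  }
  out$modifiers <- ""
  out$included <- out$linked
  out$left_context <- span_text(text, pmax(0L, out$start - cfg$context_chars), out$start)
  out$right_context <- span_text(text, out$end, pmin(n, out$end + cfg$context_chars))
  names(out)[names(out) == "start"] <- "tumour_start"
  names(out)[names(out) == "end"] <- "tumour_end"
  rownames(out) <- NULL
  out[, names(empty_matches())]
}

#' Classify a report for current primary colorectal cancer
#'
#' Composes [find_keyword_matches()] with [scope_modifiers()]: every linked
#' tumour mention inside the scope of a negation, historical, general,
#' non-definite, metastasis, recurrence or treatment-response trigger is
#' excluded; the report is positive when at least one linked, unmodified
#' mention survives.
#'
#' @param report A `ClinicalReport` row or a plain string.
#' @param lexicons A [load_crc_lexicons()] result.
#' @param trigger_rules A trigger lexicon ([default_trigger_rules()]).
#' @param cfg Internal options, see [find_keyword_matches()].
#' @return List of class `"crc_result"`: `report_id`, `crc_status`,
#'   `matches` (all mentions with `modifiers` and `included` filled in).
#'   `included` and `!included` partition the matches.
#' @examples
#' lex <- load_crc_lexicons(); rules <- default_trigger_rules()
#' classify_crc("Moderately differentiated adenocarcinoma of the rectum.",
#'              lex, rules)$crc_status
#' @export
classify_crc <- function(report, lexicons, trigger_rules, cfg = crc_config()) {
  text <- if (is_string(report)) report else as.character(report$text)
  rid <- if (is_string(report)) NA_character_ else as.character(report$report_id)
  matches <- find_keyword_matches(report, lexicons, cfg)
  if (nrow(matches)) {
    concepts <- data.frame(start = matches$tumour_start, end = matches$tumour_end)
    asg <- scope_modifiers(text, concepts, trigger_rules)
    mods <- modifiers_by_concept(asg, nrow(matches))
    matches$modifiers <- vapply(mods, paste, "", collapse = ",")
    matches$included <- matches$linked & !nzchar(matches$modifiers)
  }
  structure(list(report_id = rid,
                 crc_status = any(matches$included),
                 matches = matches),
            class = "crc_result")
}

#' @export
print.crc_result <- function(x, ...) {
  cat(sprintf("CRC report %s: status=%s, %d included / %d excluded mention(s)\n",
              x$report_id, x$crc_status, sum(x$matches$included),
              sum(!x$matches$included)))
  invisible(x)
}

#' Detect primary CRC across a corpus
#'
#' Applies [classify_crc()] to every report, in order, optionally in
#' parallel.
#'
#' @param corpus Data.frame with `report_id` and `text` (see
#'   [read_corpus()]).
#' @param lexicons,trigger_rules,cfg See [classify_crc()]; defaults load the
#'   shipped lexicons.
#' @param workers Number of forked workers.
#' @return List of class `"crc_results"`: `status` (report_id, crc_status,
#'   n_included, n_excluded) and `matches` (per-mention rows with
#'   report_id).
#' @export
detect_crc <- function(corpus, lexicons = load_crc_lexicons(),
                       trigger_rules = default_trigger_rules(),
                       cfg = crc_config(), workers = 1L) {
  validate_corpus(corpus)
  n <- nrow(corpus)
  run <- function(i) classify_crc(corpus[i, ], lexicons, trigger_rules, cfg)
  res <- if (workers > 1L && n > 1L) {
    parallel::mclapply(seq_len(n), run, mc.cores = workers)
  } else {
    lapply(seq_len(n), run)
  }
  status <- data.frame(
    report_id = corpus$report_id,
    crc_status = vapply(res, `[[`, TRUE, "crc_status"),
    n_included = vapply(res, function(r) sum(r$matches$included), 1L),
    n_excluded = vapply(res, function(r) sum(!r$matches$included), 1L),
    stringsAsFactors = FALSE
  )
  matches <- do.call(rbind, lapply(seq_len(n), function(i) {
    m <- res[[i]]$matches
    if (!nrow(m)) return(NULL)
    cbind(data.frame(report_id = corpus$report_id[i], stringsAsFactors = FALSE), m)
  }))
  if (is.null(matches)) {
    matches <- cbind(data.frame(report_id = character(0), stringsAsFactors = FALSE),
                     empty_matches())
  }
  structure(list(status = status, matches = matches), class = "crc_results")
}

#' @export
print.crc_results <- function(x, ...) {
  cat(sprintf("CRC detection over %d report(s): %d positive\n",
              nrow(x$status), sum(x$status$crc_status)))
  print(head(x$status, 10))
  invisible(x)
}
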