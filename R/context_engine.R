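# ConText-style modifier scoping: trigger terms project a directional scope
# over the text; concept mentions inside a scope inherit the trigger's
# modifier (negated, historical, general, nondefinite, metastasis,
# recurrence, treatment_response).

modifier_classes <- function() {
  c("negated", "historical", "general", "nondefinite",
    "metastasis", "recurrence", "treatment_response")
}

trigger_directions <- function() c("forward", "backward", "bidirectional")

#' Load a trigger lexicon
#'
#' One rule per line, tab-separated: `pattern  modifier  direction  scope`,
#' with `#` starting a comment. `pattern` is a case-insensitive literal
#' matched at word boundaries; `modifier` is one of `negated`, `historical`,
#' `general`, `nondefinite`, `metastasis`, `recurrence`,
#' `treatment_response`; `direction` is `forward`, `backward` or
#' `bidirectional`; `scope` is the maximum scope length in characters.
#' Duplicate rules collapse to one.
#'
#' @param path Path to the lexicon file.
#' @return Data.frame of class `"trigger_rules"`: `pattern`, `modifier`,
#'   `direction`, `max_scope_chars`.
#' @seealso [default_trigger_rules()] for the lexicon shipped with the
#'   package.
#' @export
load_trigger_lexicon <- function(path) {
  if (!file.exists(path)) config_error("trigger lexicon not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  rules <- lapply(keep, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4L) {
      config_error("line %d: expected 4 tab-separated fields, got %d", i, length(f))
    }
    if (!f[2] %in% modifier_classes()) {
      config_error("line %d: unknown modifier '%s'", i, f[2])
    }
    if (!f[3] %in% trigger_directions()) {
      config_error("line %d: unknown direction '%s'", i, f[3])
    }
    sc <- suppressWarnings(as.integer(f[4]))
    if (is.na(sc) || sc <= 0L) config_error("line %d: scope must be a positive integer", i)
    data.frame(pattern = trimws(f[1]), modifier = f[2], direction = f[3],
               max_scope_chars = sc, stringsAsFactors = FALSE)
  })
  out <- if (length(rules)) unique(do.call(rbind, rules)) else {
    data.frame(pattern = character(0), modifier = character(0),
               direction = character(0), max_scope_chars = integer(0),
               stringsAsFactors = FALSE)
  }
  if (nrow(out) && any(!nzchar(out$pattern))) config_error("empty trigger pattern")
  rownames(out) <- NULL
  class(out) <- c("trigger_rules", "data.frame")
  out
}

#' Default trigger lexicon shipped with the package
#'
#' Curated from the ConText literature and the modifier taxonomy used in
#' colorectal-cancer report screening. The original study's exact trigger
#' lists are not public; this lexicon is the package's own curation and is
#' plain-text editable (see `system.file("extdata", "lexicons",
#' "triggers.tsv", package = "crctnm")`).
#'
#' @return A `trigger_rules` data.frame (see [load_trigger_lexicon()]).
#' @export
default_trigger_rules <- function() {
  load_trigger_lexicon(system.file("extdata", "lexicons", "triggers.tsv",
                                   package = "crctnm", mustWork = TRUE))
}

# sentence terminators end every scope: ".", ";", newline and "but"
scope_breaks <- function(text) {
  m <- gregexpr("(?i)[.;\n]|\\bbut\\b", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

locate_triggers <- function(text, rules) {
  out <- lapply(seq_len(nrow(rules)), function(i) {
    rx <- paste0("(?i)\\b", rx_escape(rules$pattern[i]), "\\b")
    m <- gregexpr(rx, text, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(rule = i, start = as.integer(m) - 1L,
               end = as.integer(m) + attr(m, "match.length") - 1L,
               modifier = rules$modifier[i], direction = rules$direction[i],
               max_scope_chars = rules$max_scope_chars[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(rule = integer(0), start = integer(0), end = integer(0),
                      modifier = character(0), direction = character(0),
                      max_scope_chars = integer(0), stringsAsFactors = FALSE)
  }
  out[order(out$start, out$end), , drop = FALSE]
}

# scope of one trigger occurrence: [start, end) intervals, possibly two for
# bidirectional rules
trigger_scopes <- function(trig, i, breaks, same_class, text_len) {
  t <- trig[i, ]
  scopes <- list()
  if (t$direction %in% c("forward", "bidirectional")) {
    # a later same-class trigger that also projects forward takes over the
    # scope; backward-only triggers do not truncate a forward scope
    fwd <- same_class[same_class$direction %in% c("forward", "bidirectional"), ]
    lim <- min(t$end + t$max_scope_chars, text_len)
    b <- breaks$start[breaks$start >= t$end]
    if (length(b)) lim <- min(lim, b[1])
    s <- fwd$start[fwd$start >= t$end]
    if (length(s)) lim <- min(lim, s[1])
    if (lim > t$end) scopes <- c(scopes, list(c(t$end, lim)))
  }
  if (t$direction %in% c("backward", "bidirectional")) {
    bwd <- same_class[same_class$direction %in% c("backward", "bidirectional"), ]
    lim <- max(t$start - t$max_scope_chars, 0L)
    b <- breaks$end[breaks$end <= t$start]
    if (length(b)) lim <- max(lim, b[length(b)])
    s <- bwd$end[bwd$end <= t$start]
    if (length(s)) lim <- max(lim, s[length(s)])
    if (lim < t$start) scopes <- c(scopes, list(c(lim, t$start)))
  }
  scopes
}

#' Assign context modifiers to concept mentions
#'
#' For every trigger occurrence, a scope runs from the trigger in its
#' direction until the first sentence terminator (".", ";", newline, the
#' conjunction "but"), the rule's character limit, or the next trigger of
#' the same modifier class. A concept wholly inside a scope receives that
#' modifier.
#'
#' @param text Report text.
#' @param concepts Data.frame of 0-based half-open concept spans (`start`,
#'   `end`), e.g. tumour-keyword spans.
#' @param rules A `trigger_rules` data.frame ([load_trigger_lexicon()]).
#' @return Long data.frame: `concept` (row index into `concepts`),
#'   `modifier`, `trigger_start`, `trigger_end`. Concepts under no scope are
#'   absent.
#' @examples
#' rules <- default_trigger_rules()
#' scope_modifiers("No evidence of tumour.",
#'                 data.frame(start = 15, end = 21), rules)
#' @export
scope_modifiers <- function(text, concepts, rules) {
  empty <- data.frame(concept = integer(0), modifier = character(0),
                      trigger_start = integer(0), trigger_end = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(concepts) || !nrow(rules)) return(empty)
  if (any(concepts$start < 0 | concepts$end > nchar(text) |
          concepts$start > concepts$end)) {
    validation_error("concept spans out of bounds for text of length %d", nchar(text))
  }
  trig <- locate_triggers(text, rules)
  if (!nrow(trig)) return(empty)
  breaks <- scope_breaks(text)
  out <- list()
  for (i in seq_len(nrow(trig))) {
    same <- trig[trig$modifier == trig$modifier[i] & seq_len(nrow(trig)) != i, , drop = FALSE]
    for (sc in trigger_scopes(trig, i, breaks, same, nchar(text))) {
      inside <- which(concepts$start >= sc[1] & concepts$end <= sc[2])
      if (length(inside)) {
        out[[length(out) + 1L]] <- data.frame(
          concept = inside, modifier = trig$modifier[i],
          trigger_start = trig$start[i], trigger_end = trig$end[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- unique(out)
  out <- out[order(out$concept, out$modifier, out$trigger_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# set of modifiers per concept index (helper used by crc_detection)
modifiers_by_concept <- function(assignments, n_concepts) {
  lapply(seq_len(n_concepts), function(i) {
    sort(unique(assignments$modifier[assignments$concept == i]))
  })
}
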