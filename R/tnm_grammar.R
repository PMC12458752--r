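# TNM category grammar: allowed value sets, severity rankings, and the
# extractor configuration object.

#' TNM categories and their allowed values
#'
#' The 11 categories extracted by the package and the closed value sets each
#' may take: the UICC T/N/M triplet with substages, venous (V), lymphatic (L)
#' and perineural (Pn) invasion, residual tumour status (R), grade (G), and
#' the Kikuchi (SM) and Haggitt (H) depth-of-invasion levels reported
#' alongside TNM in early colorectal lesions. Haggitt levels written as Roman
#' numerals are normalised to Arabic at parse time, so the sets below hold
#' normalised tokens. The T prefix ("Tpre") is a combination of the letters
#' a, c, m, p, r, y (e.g. "yp", "ymr") and is validated against
#' a whitelist rather than a value set (see [tnm_config()]).
#'
#' @return Named list of character vectors, one per category, in severity
#'   order from least to most severe; `"X"` (not assessable) is ranked below
#'   every informative value.
#' @examples
#' tnm_allowed_values()$T
#' @export
tnm_allowed_values <- function() {
  sub4 <- function(l) as.vector(t(outer(1:4, c("", l), paste0)))
  list(
    # ranking per category: X < 0 < is < 1 < 1a < ... (clinical severity)
    T  = c("X", "0", "is", sub4(c("a", "b", "c", "d"))),
    N  = c("X", "0", "1", "1a", "1b", "1c", "2", "2a", "2b", "2c",
           "3", "3a", "3b", "3c"),
    M  = c("X", "0", "1", "1a", "1b", "1c"),
    V  = c("X", "0", "1", "2"),
    R  = c("X", "0", "1", "2"),
    L  = c("X", "0", "1"),
    Pn = c("X", "0", "1"),
    G  = c("X", "1", "2", "3", "4"),
    SM = c("1", "2", "3"),
    H  = c("0", "1", "2", "3", "4")
  )
}

tnm_category_names <- function() names(tnm_allowed_values())

# rank of a value within its category's severity order; NA if invalid
tnm_value_rank <- function(values, category, ranking = tnm_allowed_values()) {
  match(values, ranking[[category]])
}

#' Extractor configuration
#'
#' All tunable knobs of the TNM extractor, with defaults chosen to be
#' conservative on prose. Every parameter can also be set from a YAML config
#' file through the command-line interface.
#'
#' @param cues Case-insensitive staging cues that license a single-category
#'   phrase (e.g. "Staged as T2"); a lone token without a nearby cue is
#'   always discarded, because single TNM look-alikes are unreliable.
#' @param cue_window Characters before a token within which a cue counts.
#' @param max_gap Maximum characters of punctuation/whitespace (or a single
#'   bracketed comment) allowed between consecutive tokens of one phrase.
#' @param separators Multi-value separators within one category letter
#'   ("T1/2/3"). `"-"` is recognised but off by default: it collides with
#'   vertebral ranges such as "T1-T12".
#' @param prefix_whitelist Known prefix letter combinations; an unknown
#'   combination is dropped (the stage token itself is kept).
#' @param allow_prefix_nm Also attach prefixes to N and M (default: T only).
#' @param guard_mri_terms,guard_vertebral_terms Context words that reject a
#'   T1/T2-like candidate as an MRI sequence or vertebral level.
#' @param guard_window Characters of context each side inspected by guards.
#' @param adjacency_gap Maximum whitespace between a letter-O-for-zero token
#'   (e.g. "NO" read as N0) and its nearest genuine TNM neighbour; "No"
#'   standing alone is always prose.
#' @param ranking Optional named list overriding the per-category severity
#'   order of [tnm_allowed_values()].
#' @param drop_historical Drop phrases inside historical-modifier scope
#'   (requires `trigger_rules` when extracting); by default all explicit
#'   stages, current or historical, are returned.
#' @return An object of class `"tnm_config"` (a named list).
#' @examples
#' cfg <- tnm_config(separators = c("/", ",", "or", "-"))
#' cfg$separators
#' @export
tnm_config <- function(cues = c("staged as", "staging", "stage", "tnm"),
                       cue_window = 30L,
                       max_gap = 40L,
                       separators = c("/", ",", "or"),
                       prefix_whitelist = c("c", "p", "y", "r", "a", "m",
                                            "yp", "mr", "ymr", "cp"),
                       allow_prefix_nm = FALSE,
                       guard_mri_terms = c("weighted", "w", "sequence",
                                           "sequences", "signal", "flair",
                                           "stir", "axial", "sagittal",
                                           "coronal", "echo"),
                       guard_vertebral_terms = c("vertebra", "vertebrae",
                                                 "vertebral", "spinous",
                                                 "pedicle", "level", "spine",
                                                 "disc"),
                       guard_window = 30L,
                       adjacency_gap = 2L,
                       ranking = NULL,
                       drop_historical = FALSE) {
  stopifnot(cue_window > 0, max_gap > 0, guard_window > 0, adjacency_gap >= 0)
  bad <- setdiff(separators, c("/", ",", "or", "-"))
  if (length(bad)) config_error("unsupported separators: %s", commas(bad))
  rk <- tnm_allowed_values()
  if (!is.null(ranking)) {
    unknown <- setdiff(names(ranking), names(rk))
    if (length(unknown)) config_error("ranking override for unknown category: %s", commas(unknown))
    for (nm in names(ranking)) {
      if (!setequal(ranking[[nm]], rk[[nm]]))
        config_error("ranking override for %s must permute its allowed values", nm)
      rk[[nm]] <- ranking[[nm]]
    }
  }
  structure(list(
    cues = tolower(cues), cue_window = as.integer(cue_window),
    max_gap = as.integer(max_gap), separators = separators,
    prefix_whitelist = tolower(prefix_whitelist),
    allow_prefix_nm = isTRUE(allow_prefix_nm),
    guard_mri_terms = tolower(guard_mri_terms),
    guard_vertebral_terms = tolower(guard_vertebral_terms),
    guard_window = as.integer(guard_window),
    adjacency_gap = as.integer(adjacency_gap),
    ranking = rk,
    drop_historical = isTRUE(drop_historical)
  ), class = "tnm_config")
}

#' Normalise a raw captured value for one TNM category
#'
#' Applies the documentation-variant corrections before validating against
#' the category's closed value set: the letter O in value position becomes 0
#' (zero mis-spelt as O), x is upper-cased to X, substage letters are
#' lower-cased, and Haggitt Roman numerals (which must be upper-case in the
#' raw text) are mapped to Arabic. Values outside the allowed set are
#' rejected.
#'
#' @param raw Character vector of raw value captures.
#' @param category Single category name, e.g. `"T"`, `"Pn"`.
#' @param allowed Allowed value sets, `tnm_allowed_values()` by default.
#' @return Character vector of normalised tokens, `NA` where rejected.
#' @examples
#' normalize_value(c("O", "x", "1A", "5"), "T")  # "0" "X" "1a" NA
#' normalize_value("II", "H")                    # "2"
#' @export
normalize_value <- function(raw, category, allowed = tnm_allowed_values()) {
  if (!category %in% names(allowed)) config_error("unknown TNM category: %s", category)
  out <- character(length(raw))
  for (i in seq_along(raw)) {
    v <- raw[[i]]
    if (is.na(v)) { out[[i]] <- NA_character_; next }
    if (v %in% c("I", "II", "III", "IV")) {
      # Roman only valid for Haggitt and only upper-case in the source
      out[[i]] <- if (category == "H") as.character(match(v, c("I", "II", "III", "IV"))) else NA_character_
      next
    }
    lv <- tolower(v)
    if (grepl("^i", lv)) { # lower-case roman / "is"
      out[[i]] <- if (category == "T" && lv == "is") "is" else NA_character_
      next
    }
    if (lv == "o") lv <- "0"
    if (lv == "x") lv <- "X"
    out[[i]] <- lv
  }
  ifelse(out %in% allowed[[category]], out, NA_character_)
}
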