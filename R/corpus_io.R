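# Readers and writers for the tabular report formats (CSV / JSON-lines) and
# the corpus validation shared by all pipelines.

report_types <- function() c("pathology", "imaging")

#' Validate a corpus data.frame
#'
#' Checks the `ClinicalReport` invariants: `report_id` present, non-empty
#' and unique; `text` present (NA normalised to "" with a warning, never
#' dropped, so corpus size is deterministic).
#'
#' @param corpus A data.frame.
#' @return The corpus, invisibly, after normalisation.
#' @keywords internal
validate_corpus <- function(corpus) {
  if (!is.data.frame(corpus)) validation_error("corpus must be a data.frame")
  for (col in c("report_id", "text")) {
    if (!col %in% names(corpus)) config_error("corpus is missing column '%s'", col)
  }
  if (any(is.na(corpus$report_id) | !nzchar(corpus$report_id))) {
    validation_error("empty report_id in corpus")
  }
  dup <- unique(corpus$report_id[duplicated(corpus$report_id)])
  if (length(dup)) {
    validation_error("duplicate report_id values: %s", commas(dup))
  }
  invisible(corpus)
}

normalize_corpus <- function(df, column_map) {
  for (target in names(column_map)) {
    src <- column_map[[target]]
    if (!src %in% names(df)) {
      if (target == "date") next # optional
      config_error("input is missing column '%s'", src)
    }
    names(df)[names(df) == src] <- target
  }
  if (!"date" %in% names(df)) df$date <- NA_character_
  df <- df[, c("report_id", "report_type", "text", "date"), drop = FALSE]
  df$report_id <- as.character(df$report_id)
  df$report_type <- as.character(df$report_type)
  if (anyNA(df$text)) {
    warning(sprintf("%d report(s) with missing text normalised to empty string",
                    sum(is.na(df$text))), call. = FALSE)
    df$text[is.na(df$text)] <- ""
  }
  df$text <- as.character(df$text)
  unknown <- setdiff(unique(df$report_type[!is.na(df$report_type)]), report_types())
  if (length(unknown)) {
    warning(sprintf("unknown report_type value(s): %s", commas(unknown)), call. = FALSE)
  }
  validate_corpus(df)
  df
}

#' Read a report corpus from CSV or JSON-lines
#'
#' One `ClinicalReport` per row/line, in file order, decoded as UTF-8.
#' Embedded newlines, quotes and commas in text cells are supported through
#' standard CSV quoting.
#'
#' @param path Input file.
#' @param format `"csv"` or `"jsonl"`.
#' @param column_map Named character vector mapping the canonical names
#'   (`report_id`, `report_type`, `text`, `date`) to the columns in the
#'   file, e.g. `c(report_id = "id", text = "body")`.
#' @return Data.frame with columns `report_id`, `report_type`, `text`,
#'   `date`.
#' @export
read_corpus <- function(path, format = c("csv", "jsonl"), column_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) io_error("input file not found: %s", path)
  map <- c(report_id = "report_id", report_type = "report_type",
           text = "text", date = "date")
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  df <- if (format == "csv") {
    read.csv(path, colClasses = "character", check.names = FALSE,
             fileEncoding = "UTF-8", na.strings = NULL)
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
      data.frame(report_id = character(0), report_type = character(0),
                 text = character(0), stringsAsFactors = FALSE)
    } else {
      rows <- lapply(lines, function(l) {
        r <- jsonlite::fromJSON(l)
        r[vapply(r, is.null, TRUE)] <- NA
        as.data.frame(r, stringsAsFactors = FALSE)
      })
      cols <- unique(unlist(lapply(rows, names)))
      do.call(rbind, lapply(rows, function(r) {
        for (c0 in setdiff(cols, names(r))) r[[c0]] <- NA_character_
        r[, cols, drop = FALSE]
      }))
    }
  }
  if (nrow(df) == 0L) {
    for (target in names(map)) {
      if (!target %in% names(df) && !map[[target]] %in% names(df)) df[[map[[target]]]] <- character(0)
    }
  }
  normalize_corpus(df, as.list(map))
}

#' Write result rows to CSV or JSON-lines
#'
#' The CSV dialect is UTF-8, comma-separated, minimally quoted with
#' double-quote escaping; newlines inside cells survive via quoting. List
#' columns are serialised as JSON strings.
#'
#' @param records Data.frame of result rows sharing one schema.
#' @param path Output file.
#' @param format `"csv"` or `"jsonl"`.
#' @export
write_results <- function(records, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (!is.data.frame(records)) validation_error("records must be a data.frame")
  is_list_col <- vapply(records, is.list, TRUE)
  for (col in names(records)[is_list_col]) {
    records[[col]] <- vapply(records[[col]], function(x) {
      as.character(jsonlite::toJSON(x, dataframe = "rows", auto_unbox = TRUE))
    }, "")
  }
  ok <- tryCatch({
    if (format == "csv") {
      con <- file(path, open = "w", encoding = "UTF-8")
      on.exit(close(con))
      write.csv(records, con, row.names = FALSE, na = "")
    } else {
      con <- file(path, open = "w", encoding = "UTF-8")
      on.exit(close(con))
      writeLines(vapply(seq_len(nrow(records)), function(i) {
        as.character(jsonlite::toJSON(as.list(records[i, , drop = FALSE]),
                                      auto_unbox = TRUE, na = "null"))
      }, ""), con)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) io_error("cannot write %s: %s", path, conditionMessage(ok))
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path Input file.
#' @param format `"csv"` or `"jsonl"`.
#' @return Data.frame with character columns (empty string for missing CSV
#'   cells).
#' @export
read_results <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) io_error("input file not found: %s", path)
  if (format == "csv") {
    read.csv(path, colClasses = "character", check.names = FALSE,
             fileEncoding = "UTF-8", na.strings = NULL)
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    rows <- lapply(lines, function(l) {
      r <- jsonlite::fromJSON(l)
      r[vapply(r, is.null, TRUE)] <- NA
      as.data.frame(r, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
}
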