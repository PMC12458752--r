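# Internal helpers: condition classes, 0-based span arithmetic, misc.

cond_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "crctnm_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

config_error <- function(msg, ...) cond_stop("crctnm_config_error", msg, ...)
validation_error <- function(msg, ...) cond_stop("crctnm_validation_error", msg, ...)
io_error <- function(msg, ...) cond_stop("crctnm_io_error", msg, ...)

# All user-facing spans are 0-based, half-open, in character (code point)
# units: text equals substring at [start, end). R's substr is 1-based closed.
span_text <- function(text, start, end) {
  if (length(start) == 0L) return(character(0))
  substr(rep_len(text, length(start)), start + 1L, end)
}

rx_escape <- function(x) gsub("([][^$.|?*+(){}\\\\-])", "\\\\\\1", x)

# round-half-up to `digits`, used for display formatting that must match
# printed tables (base round() is round-half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# collapse a character vector to "a, b, c" for messages
commas <- function(x, max = 10L) {
  if (length(x) > max) x <- c(head(x, max), "...")
  paste(x, collapse = ", ")
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
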