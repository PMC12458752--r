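# Independent oracles used by the property and acceptance tests. These stay
# deliberately naive (per-pair loops, root finding, recounting) and never
# call the code paths they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Wilson bounds by numeric root finding on the score-test equality:
# (phat - p)^2 = z^2 * p (1 - p) / n
oracle_wilson <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  phat <- x / n
  f <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / n
  # at x = 0 (x = n) the point estimate itself is a root; search away from it
  lower <- if (x == 0) 0 else {
    uniroot(f, c(1e-12, if (x == n) 1 - 1e-12 else phat), tol = 1e-14)$root
  }
  upper <- if (x == n) 1 else {
    uniroot(f, c(if (x == 0) 1e-12 else phat, 1 - 1e-12), tol = 1e-14)$root
  }
  c(lower = lower, upper = upper)
}

# per-pair containment oracle for modifier scoping: for every (trigger
# occurrence, concept) pair, recompute the scope naively and check
# containment
oracle_scope <- function(text, concepts, rules) {
  n <- nchar(text)
  brk <- gregexpr("(?i)[.;\n]|\\bbut\\b", text, perl = TRUE)[[1]]
  brk_start <- if (brk[1] == -1L) integer(0) else as.integer(brk) - 1L
  brk_end <- if (brk[1] == -1L) integer(0) else as.integer(brk) + attr(brk, "match.length") - 1L
  occ <- list()
  for (r in seq_len(nrow(rules))) {
    m <- gregexpr(paste0("(?i)\\b", gsub("([][^$.|?*+(){}\\\\-])", "\\\\\\1", rules$pattern[r]), "\\b"),
                  text, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    for (k in seq_along(m)) {
      occ[[length(occ) + 1L]] <- list(start = as.integer(m[k]) - 1L,
                                      end = as.integer(m[k]) + attr(m, "match.length")[k] - 1L,
                                      modifier = rules$modifier[r],
                                      direction = rules$direction[r],
                                      scope = rules$max_scope_chars[r])
    }
  }
  hits <- list()
  for (t in occ) {
    scopes <- list()
    if (t$direction %in% c("forward", "bidirectional")) {
      lim <- min(t$end + t$scope, n)
      for (b in brk_start) if (b >= t$end && b < lim) lim <- b
      for (u in occ) {
        if (u$modifier == t$modifier && u$direction %in% c("forward", "bidirectional") &&
            !(u$start == t$start && u$end == t$end) && u$start >= t$end && u$start < lim) {
          lim <- u$start
        }
      }
      if (lim > t$end) scopes[[length(scopes) + 1L]] <- c(t$end, lim)
    }
    if (t$direction %in% c("backward", "bidirectional")) {
      lim <- max(t$start - t$scope, 0L)
      for (b in brk_end) if (b <= t$start && b > lim) lim <- b
      for (u in occ) {
        if (u$modifier == t$modifier && u$direction %in% c("backward", "bidirectional") &&
            !(u$start == t$start && u$end == t$end) && u$end <= t$start && u$end > lim) {
          lim <- u$end
        }
      }
      if (lim < t$start) scopes[[length(scopes) + 1L]] <- c(lim, t$start)
    }
    for (sc in scopes) {
      for (ci in seq_len(nrow(concepts))) {
        if (concepts$start[ci] >= sc[1] && concepts$end[ci] <= sc[2]) {
          hits[[length(hits) + 1L]] <- data.frame(concept = ci, modifier = t$modifier,
                                                  stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- unique(do.call(rbind, hits))
  if (is.null(out)) out <- data.frame(concept = integer(0), modifier = character(0))
  out[order(out$concept, out$modifier), , drop = FALSE]
}

# brute-force recount of confusion counts from raw prediction/gold vectors
oracle_confusion <- function(p, g) {
  counts <- new.env()
  bump <- function(key) assign(key, (get0(key, envir = counts) %||% 0L) + 1L, envir = counts)
  `%||%` <- function(a, b) if (is.null(a)) b else a
  for (i in seq_along(p)) {
    if (is.na(p[i]) && is.na(g[i])) bump("tn_none")
    else if (is.na(p[i])) { bump("fn_none"); bump(paste0("fn:", g[i])) }
    else if (is.na(g[i])) { bump("fp_none"); bump(paste0("fp:", p[i])) }
    else if (p[i] == g[i]) bump(paste0("tp:", p[i]))
    else { bump(paste0("fp:", p[i])); bump(paste0("fn:", g[i])) }
  }
  as.list(counts)
}

# severity key for the maximum-value oracle: exhaustive pairwise comparison
# via an independent numeric encoding of the documented ranking
oracle_value_key <- function(value, category) {
  if (value == "X") return(-1)
  if (value == "is") return(0.5)
  base <- as.numeric(substr(value, 1, 1))
  sub <- substr(value, 2, 2)
  base + if (nzchar(sub)) match(sub, letters) / 100 else 0
}

oracle_max_value <- function(values, category) {
  keys <- vapply(values, oracle_value_key, 0, category = category)
  values[which.max(keys)]
}

# random corpus text for round-trip property tests: newlines, tabs, quotes,
# commas, non-ASCII
random_nasty_text <- function(n = 1) {
  pool <- c(letters, LETTERS, 0:9, " ", ",", "\"", "'", "\n", "\t", ";",
            "é", "ü", "α", "(", ")", "/")
  vapply(seq_len(n), function(i) {
    paste(sample(pool, sample(0:40, 1), replace = TRUE), collapse = "")
  }, "")
}

# multiset comparison of parsed tokens vs expectation
token_multiset <- function(df) sort(paste(df$category, df$prefix, df$value, sep = "|"))
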