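#' The degron motif pattern dialect
#'
#' Degron motifs are short linear motifs, so the pattern language is a
#' deliberately restricted regex subset that keeps every match enumerable:
#'
#' * a literal upper-case residue letter (`K`, `R`, ...)
#' * `x` — any canonical residue
#' * `[KR]` — character class; `[^P]` — negated class
#' * `{n}` or `{m,n}` — bounded repeat of the preceding token
#'
#' No alternation, grouping, anchors or unbounded quantifiers. Location
#' semantics (N-terminal / C-terminal / internal) are carried by the motif's
#' `location_class`, not by anchors; anchoring is enforced by the scanner so
#' one motif row stays valid for both initiator-Met variants.
#'
#' @name motif_dialect
NULL

LOCATION_CLASSES <- c("N_TERMINAL", "C_TERMINAL", "INTERNAL")

# Tokenize a dialect pattern into a list of tokens:
# list(kind = "literal"|"class"|"nclass"|"any", chars, min, max)
tokenize_pattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern) || !nzchar(pattern)) {
    stop("empty pattern")
  }
  chars <- strsplit(pattern, "")[[1]]
  i <- 1L
  n <- length(chars)
  tokens <- list()
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      neg <- FALSE
      if (j <= n && chars[j] == "^") {
        neg <- TRUE
        j <- j + 1L
      }
      k <- j
      while (k <= n && chars[k] != "]") k <- k + 1L
      if (k > n) stop("pattern dialect error in '", pattern, "': unclosed '[' at position ", i)
      members <- chars[seq.int(j, k - 1L)]
      if (length(members) == 0L) {
        stop("pattern dialect error in '", pattern, "': empty character class at position ", i)
      }
      if (!all(members %in% LETTERS)) {
        stop(
          "pattern dialect error in '", pattern, "': class member(s) ",
          paste(setdiff(members, LETTERS), collapse = ""), " not residue letters"
        )
      }
      tokens[[length(tokens) + 1L]] <- list(
        kind = if (neg) "nclass" else "class", chars = members, min = 1L, max = 1L
      )
      i <- k + 1L
    } else if (ch == "x") {
      tokens[[length(tokens) + 1L]] <- list(kind = "any", chars = character(), min = 1L, max = 1L)
      i <- i + 1L
    } else if (ch %in% LETTERS) {
      tokens[[length(tokens) + 1L]] <- list(kind = "literal", chars = ch, min = 1L, max = 1L)
      i <- i + 1L
    } else if (ch == "{") {
      if (length(tokens) == 0L) {
        stop("pattern dialect error in '", pattern, "': repeat with no preceding token")
      }
      k <- i + 1L
      while (k <= n && chars[k] != "}") k <- k + 1L
      if (k > n) stop("pattern dialect error in '", pattern, "': unclosed '{' at position ", i)
      body <- paste(chars[seq.int(i + 1L, k - 1L)], collapse = "")
      if (grepl("^[0-9]+$", body)) {
        m <- as.integer(body)
        mx <- m
      } else if (grepl("^[0-9]+,[0-9]+$", body)) {
        parts <- as.integer(strsplit(body, ",")[[1]])
        m <- parts[1]
        mx <- parts[2]
        if (m > mx) stop("pattern dialect error in '", pattern, "': repeat range {", body, "} inverted")
      } else {
        stop("pattern dialect error in '", pattern, "': malformed repeat {", body, "}")
      }
      if (mx == 0L) stop("pattern dialect error in '", pattern, "': zero-width repeat {", body, "}")
      last <- tokens[[length(tokens)]]
      if (last$min != 1L || last$max != 1L) {
        stop("pattern dialect error in '", pattern, "': double repeat at position ", i)
      }
      last$min <- m
      last$max <- mx
      tokens[[length(tokens)]] <- last
      i <- k + 1L
    } else {
      stop(
        "pattern dialect error in '", pattern, "': token '", ch, "' at position ", i,
        " is outside the dialect (literals, x, [..], [^..], {n}, {m,n})"
      )
    }
  }
  tokens
}

# Translate one token to a PCRE fragment. Negated classes and the wildcard are
# restricted to upper-case letters so alignment gaps ('-') and the placeholder
# X behave as configured, never by accident.
token_regex <- function(tok, allow_x = FALSE) {
  alpha <- if (allow_x) "[A-Z]" else "[A-WYZ]" # X never satisfies a class by default
  base <- switch(tok$kind,
    literal = tok$chars,
    class = paste0("[", paste(tok$chars, collapse = ""), "]"),
    nclass = paste0("(?:(?![", paste(tok$chars, collapse = ""), "])", alpha, ")"),
    any = alpha
  )
  if (tok$min == 1L && tok$max == 1L) {
    base
  } else if (tok$min == tok$max) {
    paste0(base, "{", tok$min, "}")
  } else {
    paste0(base, "{", tok$min, ",", tok$max, "}")
  }
}

#' Compile a degron motif pattern
#'
#' Compiles a pattern in the restricted dialect (see [motif_dialect]) into a
#' position-reporting matcher.
#'
#' @param pattern Pattern string, or a one-row motif tibble.
#' @return An object of class `degron_matcher` with elements `pattern`,
#'   `regex`, `min_len`, `max_len`.
#' @examples
#' m <- compile_pattern("[KR]xxL")
#' match_pattern(m, "AKAAL")
#' @export
compile_pattern <- function(pattern) {
  if (is.data.frame(pattern)) pattern <- pattern$pattern[1]
  tokens <- tokenize_pattern(pattern)
  regex <- paste(vapply(tokens, token_regex, character(1)), collapse = "")
  structure(
    list(
      pattern = pattern,
      regex = regex,
      min_len = sum(vapply(tokens, `[[`, integer(1), "min")),
      max_len = sum(vapply(tokens, `[[`, integer(1), "max"))
    ),
    class = "degron_matcher"
  )
}

#' @export
print.degron_matcher <- function(x, ...) {
  cat("<degron_matcher> pattern:", x$pattern, " length:", x$min_len,
    if (x$max_len != x$min_len) paste0("-", x$max_len) else "", "\n")
  invisible(x)
}

#' Find all occurrences of a compiled motif in a sequence
#'
#' Reports every `(start, end)` occurrence, 1-based inclusive, including
#' overlapping and (for ranged repeats) nested occurrences. Candidate starts
#' are found with a zero-width look-ahead scan; each candidate is then
#' confirmed at every admissible match length, so patterns with `{m,n}`
#' repeats report one row per realized length.
#'
#' @param matcher A `degron_matcher` from [compile_pattern()].
#' @param sequence A single sequence string.
#' @param anchor `"none"` (scan all positions), `"start"` (matches must begin
#'   at position 1) or `"end"` (matches must end at the last residue).
#' @return Tibble with columns `start`, `end`, `matched_seq`, ordered by
#'   `start` then `end`.
#' @export
match_pattern <- function(matcher, sequence, anchor = c("none", "start", "end")) {
  stopifnot(inherits(matcher, "degron_matcher"), is.character(sequence), length(sequence) == 1L)
  anchor <- match.arg(anchor)
  L <- nchar(sequence)
  empty <- tibble::tibble(start = integer(), end = integer(), matched_seq = character())
  if (L < matcher$min_len) return(empty)

  starts <- switch(anchor,
    start = 1L,
    end = seq.int(max(1L, L - matcher$max_len + 1L), L - matcher$min_len + 1L),
    none = {
      hits <- gregexpr(paste0("(?=", matcher$regex, ")"), sequence, perl = TRUE)[[1]]
      if (hits[1] == -1L) integer() else as.integer(hits)
    }
  )
  if (length(starts) == 0L) return(empty)

  anchored_regex <- paste0("^(?:", matcher$regex, ")$")
  out <- purrr::map_dfr(starts, function(s) {
    lens <- seq.int(matcher$min_len, min(matcher$max_len, L - s + 1L))
    if (length(lens) == 0L) return(NULL)
    ok <- vapply(lens, function(len) {
      grepl(anchored_regex, substr(sequence, s, s + len - 1L), perl = TRUE)
    }, logical(1))
    lens <- lens[ok]
    if (anchor == "end") lens <- lens[s + lens - 1L == L]
    if (length(lens) == 0L) return(NULL)
    tibble::tibble(start = s, end = s + lens - 1L)
  })
  if (nrow(out) == 0L) return(empty)
  out$matched_seq <- substring(sequence, out$start, out$end)
  dplyr::arrange(out, .data$start, .data$end)
}

validate_motif_table <- function(df, provenance = "user") {
  required <- c("motif_id", "name", "pattern", "location_class", "pathway", "source")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("motif table lacks column(s): ", paste(missing, collapse = ", "))
  }
  df <- tibble::as_tibble(df[required])
  dup <- df$motif_id[duplicated(df$motif_id)]
  if (length(dup) > 0L) {
    stop("duplicate motif_id(s): ", paste(unique(dup), collapse = ", "))
  }
  bad_loc <- !df$location_class %in% LOCATION_CLASSES
  if (any(bad_loc)) {
    stop(
      "unknown location_class in row(s) ", paste(which(bad_loc), collapse = ", "),
      " (motif_id ", paste(df$motif_id[bad_loc], collapse = ", "), "): must be one of ",
      paste(LOCATION_CLASSES, collapse = ", ")
    )
  }
  # compile every pattern once; report the offending motif on failure
  for (i in seq_len(nrow(df))) {
    tryCatch(compile_pattern(df$pattern[i]), error = function(e) {
      stop("motif ", df$motif_id[i], ": ", conditionMessage(e), call. = FALSE)
    })
  }
  attr(df, "provenance") <- provenance
  class(df) <- c("motif_set", class(df))
  df
}

#' Load a degron motif table
#'
#' Reads a motif set from TSV (tab-separated, header row, UTF-8) or a JSON
#' array of objects. Required columns/keys: `motif_id`, `name`, `pattern`,
#' `location_class` (one of `N_TERMINAL`, `C_TERMINAL`, `INTERNAL`),
#' `pathway`, `source`. Every pattern is compiled once at load; errors name
#' the offending motif.
#'
#' @param path File path.
#' @param format `"tsv"`, `"json"` or `"auto"` (by file extension).
#' @return A `motif_set` tibble.
#' @export
load_motifs <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  df <- if (format == "json") {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
      colClasses = "character", quote = "", comment.char = "")
  }
  validate_motif_table(df, provenance = path)
}

#' Write a motif set to TSV or JSON
#'
#' @param motifs A `motif_set` tibble.
#' @param path Output path.
#' @param format `"tsv"`, `"json"` or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_motifs <- function(motifs, path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  cols <- c("motif_id", "name", "pattern", "location_class", "pathway", "source")
  df <- as.data.frame(motifs)[cols]
  if (format == "json") {
    jsonlite::write_json(df, path, auto_unbox = FALSE, pretty = TRUE)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' The packaged starter set of degron motifs
#'
#' A small, documented, user-replaceable motif set covering the Arg/N-degron
#' pathway N-terminal residue classes, representative C-degron motifs and
#' representative internal degrons (APC/C D-box and KEN-box, SCF/beta-TrCP
#' phosphodegron). It is a starting point, not a curated compendium: larger
#' tables are supplied through [load_motifs()].
#'
#' @return A `motif_set` tibble.
#' @export
builtin_motifs <- function() {
  path <- system.file("extdata", "degron_motifs.tsv", package = "degronkit")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "degron_motifs.tsv")
  out <- load_motifs(path, format = "tsv")
  attr(out, "provenance") <- "degronkit builtin starter set"
  out
}
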