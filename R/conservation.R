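#' Read a multiple sequence alignment
#'
#' Reads aligned FASTA, Clustal or Stockholm through Biostrings. Row order is
#' preserved; all rows must have equal aligned length.
#'
#' @param path Alignment file path.
#' @param format `"auto"` (by extension: `.aln`/`.clustal` -> clustal,
#'   `.sto`/`.stk`/`.stockholm` -> stockholm, else fasta), or one of
#'   `"fasta"`, `"clustal"`, `"stockholm"`.
#' @return Tibble with columns `id`, `aligned`.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "clustal", "stockholm")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext,
      aln = , clustal = "clustal",
      sto = , stk = , stockholm = "stockholm",
      "fasta"
    )
  }
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- as.character(aln)
  tibble::tibble(id = names(seqs), aligned = toupper(unname(seqs)))
}

#' Map a query protein into an MSA
#'
#' Builds the query-position to alignment-column map and validates that the
#' ungapped query row reproduces the protein sequence exactly.
#'
#' @param protein One-row protein tibble.
#' @param msa MSA tibble from [read_msa()] (or a path to an alignment file).
#' @param query_row_id Row id of the query within the alignment.
#' @return An object of class `degron_msa`: list with `rows` (the MSA
#'   tibble), `query_row_id`, and `col_map` (integer vector: query position
#'   -> alignment column).
#' @export
map_to_msa <- function(protein, msa, query_row_id) {
  stopifnot(is.data.frame(protein), nrow(protein) == 1L)
  if (is.character(msa) && length(msa) == 1L) msa <- read_msa(msa)
  if (!query_row_id %in% msa$id) {
    stop("query row '", query_row_id, "' absent from the alignment")
  }
  widths <- nchar(msa$aligned)
  if (length(unique(widths)) != 1L) stop("alignment rows have unequal lengths")
  qrow <- msa$aligned[match(query_row_id, msa$id)]
  qchars <- strsplit(qrow, "")[[1]]
  col_map <- which(qchars != "-")
  ungapped <- paste(qchars[col_map], collapse = "")
  if (ungapped != protein$sequence) {
    diff <- which(strsplit(ungapped, "")[[1]] != strsplit(protein$sequence, "")[[1]])
    first <- if (length(diff) > 0L) diff[1] else min(nchar(ungapped), nchar(protein$sequence)) + 1L
    stop(
      "sequence_mismatch: ungapped query row differs from protein ", protein$id,
      " (first difference at position ", first, ")"
    )
  }
  structure(
    list(rows = msa, query_row_id = query_row_id, col_map = col_map),
    class = "degron_msa"
  )
}

#' @export
print.degron_msa <- function(x, ...) {
  cat("<degron_msa>", nrow(x$rows), "rows x", nchar(x$rows$aligned[1]),
    "columns; query:", x$query_row_id, "\n")
  invisible(x)
}

# anchored match of a motif against an alignment slice; gaps never match
anchored_hit <- function(matcher, slice) {
  n <- nchar(slice)
  if (n < matcher$min_len || n > matcher$max_len) return(FALSE)
  grepl(paste0("^(?:", matcher$regex, ")$"), slice, perl = TRUE)
}

#' Degron conservation scores over an MSA
#'
#' Four complementary scores per degron match, each in `[0, 1]`, covering
#' strict preservation through to column-level variability (score definitions
#' are versioned in the output's `score_version` attribute):
#'
#' * `s1_presence` — fraction of non-query rows where the motif matches,
#'   anchored exactly at the aligned motif column span.
#' * `s2_window_presence` — fraction of non-query rows with a motif hit
#'   anywhere within the motif span widened by `flank` columns on each side
#'   (always >= `s1_presence`).
#' * `s3_column_identity` — mean, over the motif's query-residue columns, of
#'   the fraction of non-query rows whose residue equals the query residue.
#' * `s4_column_conservation` — mean over those columns of
#'   `1 - H/log(20)`, where `H` is the Shannon entropy of the column's
#'   residue distribution (gaps excluded).
#'
#' Alignment gaps never satisfy a motif character class, and rows that are
#' entirely gaps across the motif span are excluded from the denominators.
#' With no usable non-query rows all scores are `NA`.
#'
#' @param matches Degron match tibble from [scan_degrons()].
#' @param msa A `degron_msa` from [map_to_msa()].
#' @param motifs The `motif_set` the matches came from.
#' @param flank Window flank for `s2`, in alignment columns (default 5).
#' @return Tibble: `protein_id`, `motif_id`, `start`, `end`, `s1_presence`,
#'   `s2_window_presence`, `s3_column_identity`, `s4_column_conservation`,
#'   `n_rows_used`.
#' @export
score_conservation <- function(matches, msa, motifs, flank = 5L) {
  stopifnot(inherits(msa, "degron_msa"), is.data.frame(matches))
  other <- msa$rows[msa$rows$id != msa$query_row_id, , drop = FALSE]
  ncol_aln <- nchar(msa$rows$aligned[1])
  matchers <- stats::setNames(purrr::map(motifs$pattern, compile_pattern), motifs$motif_id)

  out <- purrr::map_dfr(seq_len(nrow(matches)), function(i) {
    m <- matches[i, ]
    if (m$start < 1L || m$end > length(msa$col_map)) {
      stop("match columns out of range for motif ", m$motif_id)
    }
    matcher <- matchers[[m$motif_id]]
    span <- msa$col_map[m$start]:msa$col_map[m$end] # full alignment span
    cols <- msa$col_map[m$start:m$end] # query-residue columns
    wlo <- max(1L, span[1] - flank)
    whi <- min(ncol_aln, span[length(span)] + flank)

    row_span <- substring(other$aligned, span[1], span[length(span)])
    usable <- gsub("-", "", row_span) != ""
    n_used <- sum(usable)
    if (n_used == 0L) {
      return(tibble::tibble(
        protein_id = m$protein_id, motif_id = m$motif_id, start = m$start, end = m$end,
        s1_presence = NA_real_, s2_window_presence = NA_real_,
        s3_column_identity = NA_real_, s4_column_conservation = NA_real_,
        n_rows_used = 0L
      ))
    }
    rows_u <- other$aligned[usable]

    s1 <- mean(vapply(row_span[usable], function(sl) anchored_hit(matcher, sl), logical(1)))
    s2 <- mean(vapply(substring(rows_u, wlo, whi), function(win) {
      nrow(match_pattern(matcher, win)) > 0L
    }, logical(1)))

    qaa <- strsplit(m$matched_seq, "")[[1]]
    col_chars <- purrr::map(cols, function(cc) substring(rows_u, cc, cc))
    s3 <- mean(vapply(seq_along(cols), function(k) {
      mean(col_chars[[k]] == qaa[k])
    }, numeric(1)))
    ent <- vapply(col_chars, function(ch) {
      ch <- ch[ch != "-"]
      if (length(ch) == 0L) return(NA_real_)
      p <- table(ch) / length(ch)
      -sum(p * log(p)) / log(20)
    }, numeric(1))
    s4 <- if (all(is.na(ent))) NA_real_ else 1 - mean(ent, na.rm = TRUE)

    tibble::tibble(
      protein_id = m$protein_id, motif_id = m$motif_id, start = m$start, end = m$end,
      s1_presence = s1, s2_window_presence = s2,
      s3_column_identity = s3, s4_column_conservation = s4,
      n_rows_used = n_used
    )
  })
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      protein_id = character(), motif_id = character(), start = integer(), end = integer(),
      s1_presence = numeric(), s2_window_presence = numeric(),
      s3_column_identity = numeric(), s4_column_conservation = numeric(),
      n_rows_used = integer()
    )
  }
  attr(out, "score_version") <- "degronkit-conservation-1"
  out
}
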