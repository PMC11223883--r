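mk_msa <- function(rows, query_id, protein_seq = NULL) {
  msa <- tibble::tibble(id = names(rows), aligned = unname(unlist(rows)))
  seq <- protein_seq %||% gsub("-", "", rows[[query_id]])
  map_to_msa(tibble::tibble(id = "q", sequence = seq), msa, query_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("query-to-column maps account for gaps and validate the sequence", {
  m <- mk_msa(list(q = "MAK", a = "MAK"), "q")
  expect_equal(m$col_map, 1:3)

  m2 <- mk_msa(list(q = "M-AK", a = "MKAK"), "q")
  expect_equal(m2$col_map, c(1L, 3L, 4L))

  msa <- tibble::tibble(id = c("q", "a"), aligned = c("M-AK", "MKAK"))
  expect_error(
    map_to_msa(tibble::tibble(id = "q", sequence = "MGK"), msa, "q"),
    "sequence_mismatch.*position 2"
  )
  expect_error(
    map_to_msa(tibble::tibble(id = "q", sequence = "MAK"), msa, "zz"),
    "absent"
  )
})

test_that("alignment files round-trip through the FASTA reader", {
  f <- withr::local_tempfile(fileext = ".fasta")
  write_toy_msa_fasta(f, list(q = "KEN-AA", orth1 = "KENQAA", orth2 = "KDN-AA"))
  msa <- read_msa(f)
  expect_equal(msa$id, c("q", "orth1", "orth2"))
  expect_equal(nchar(msa$aligned), rep(6L, 3))
})

toy_match <- function(start, end, seq, motif_id = "m1") {
  tibble::tibble(
    protein_id = "q", motif_id = motif_id, start = start, end = end,
    matched_seq = substr(seq, start, end), location_class = "INTERNAL",
    pathway = "toy", met_variant = "as_given", terminus = "none"
  )
}

test_that("perfectly conserved alignments score 1 on all four scores", {
  rows <- list(q = "AKENAA", a = "AKENAA", b = "AKENAA", c = "AKENAA")
  m <- mk_msa(rows, "q")
  motifs <- toy_motif_set("KEN", "INTERNAL")
  sc <- score_conservation(toy_match(2, 4, "AKENAA", "m1"), m, motifs)
  expect_equal(sc$s1_presence, 1)
  expect_equal(sc$s2_window_presence, 1)
  expect_equal(sc$s3_column_identity, 1)
  expect_equal(sc$s4_column_conservation, 1)
  expect_equal(sc$n_rows_used, 3L)
})

test_that("anchored presence counts exactly the rows with the motif in place", {
  # motif KEN at columns 2-4 present verbatim in 5 of 10 non-query rows
  present <- replicate(5, "AKENAA")
  absent <- replicate(5, "AQQNAA")
  rows <- c(list(q = "AKENAA"), stats::setNames(
    as.list(c(present, absent)), paste0("r", 1:10)))
  m <- mk_msa(rows, "q")
  motifs <- toy_motif_set("KEN", "INTERNAL")
  sc <- score_conservation(toy_match(2, 4, "AKENAA"), m, motifs)
  expect_equal(sc$s1_presence, 0.5)
  expect_true(sc$s2_window_presence >= sc$s1_presence)
  expect_equal(sc$n_rows_used, 10L)

  # a row with the motif shifted out of the span counts for s2, not s1
  rows2 <- list(q = "AKENAAAA", r1 = "AAAKENAA")
  m2 <- mk_msa(rows2, "q")
  sc2 <- score_conservation(toy_match(2, 4, "AKENAAAA"), m2, motifs, flank = 5)
  expect_equal(sc2$s1_presence, 0)
  expect_equal(sc2$s2_window_presence, 1)
})

test_that("degenerate alignments give NA scores, not zeros", {
  m <- mk_msa(list(q = "AKENAA"), "q")
  motifs <- toy_motif_set("KEN", "INTERNAL")
  sc <- score_conservation(toy_match(2, 4, "AKENAA"), m, motifs)
  expect_true(is.na(sc$s1_presence))
  expect_true(is.na(sc$s4_column_conservation))
  expect_equal(sc$n_rows_used, 0L)

  # all-gap rows across the motif are excluded from denominators
  m2 <- mk_msa(list(q = "AKENAA", g = "A---AA", r = "AKENAA"), "q")
  sc2 <- score_conservation(toy_match(2, 4, "AKENAA"), m2, motifs)
  expect_equal(sc2$n_rows_used, 1L)
  expect_equal(sc2$s1_presence, 1)
})

test_that("scores are permutation-invariant, bounded, and monotone under relaxation", {
  set.seed(91)
  motifs <- toy_motif_set("KEN", "INTERNAL")
  for (i in 1:25) {
    n_rows <- sample(3:12, 1)
    width <- 12L
    qseq <- paste0("AA", "KEN", random_sequence(width - 5))
    others <- vapply(seq_len(n_rows), function(j) {
      s <- strsplit(random_sequence(width), "")[[1]]
      if (stats::runif(1) < 0.4) s[3:5] <- c("K", "E", "N")
      if (stats::runif(1) < 0.3) s[sample(width, 2)] <- "-"
      paste(s, collapse = "")
    }, character(1))
    rows <- c(list(q = qseq), stats::setNames(as.list(others), paste0("r", seq_len(n_rows))))
    m <- mk_msa(rows, "q")
    match <- toy_match(3, 5, qseq)
    sc <- score_conservation(match, m, motifs)
    vals <- unlist(sc[, c("s1_presence", "s2_window_presence",
      "s3_column_identity", "s4_column_conservation")])
    vals <- vals[!is.na(vals)]
    expect_true(all(vals >= 0 & vals <= 1))
    if (!is.na(sc$s1_presence)) {
      expect_gte(sc$s2_window_presence, sc$s1_presence)
    }

    # permuting non-query rows changes nothing
    perm <- c(list(q = qseq), stats::setNames(
      as.list(sample(others)), paste0("p", seq_len(n_rows))))
    sc_perm <- score_conservation(match, mk_msa(perm, "q"), motifs)
    expect_equal(sc_perm[, 5:9], sc[, 5:9])

    # adding a query-identical row never decreases any score
    plus <- c(rows, list(extra = qseq))
    sc_plus <- score_conservation(match, mk_msa(plus, "q"), motifs)
    for (col in c("s1_presence", "s2_window_presence", "s3_column_identity")) {
      if (!is.na(sc[[col]])) expect_gte(sc_plus[[col]], sc[[col]])
    }
  }
})
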