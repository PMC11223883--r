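mk_context <- function(sequence, disorder = NULL, rsa = NULL) {
  L <- nchar(sequence)
  tibble::tibble(
    position = seq_len(L),
    aa = strsplit(sequence, "")[[1]],
    ss = "-",
    asa = NA_real_,
    rsa = rsa %||% rep(NA_real_, L),
    disorder_score = disorder %||% rep(0.3, L),
    disordered = (disorder %||% rep(0.3, L)) > 0.5
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("secondary degrons are every K/C/S/T in the motif and flanks", {
  #            123456789012345678901
  seq <- paste0("AAAKACASATAAA", "KEN", "AAAAACA") # K4 C6 S8 T10 inside left flank
  p <- tibble::tibble(id = "p", sequence = seq)
  match <- tibble::tibble(
    protein_id = "p", motif_id = "ken", start = 14L, end = 16L,
    matched_seq = "KEN", location_class = "INTERNAL", pathway = "APC/C",
    met_variant = "as_given", terminus = "none"
  )
  ctx <- mk_context(seq)
  sec <- find_secondary_degrons(match, p, ctx, flank = 15L)
  expect_setequal(sec$residue, c("K", "C", "S", "T"))
  expect_setequal(sec$position, c(4L, 6L, 8L, 10L, 14L, 22L))
  expect_true(sec$within_primary[sec$position == 14L]) # the KEN lysine itself
  expect_false(any(sec$within_primary[sec$position != 14L]))

  # flank devoid of K/C/S/T -> empty
  seq2 <- "AAAAAKENAAAAA"
  m2 <- match
  m2$start <- 6L
  m2$end <- 8L
  sec2 <- find_secondary_degrons(m2, tibble::tibble(id = "p", sequence = seq2),
    mk_context(seq2), flank = 4L)
  expect_equal(sum(!sec2$within_primary), 0L)
})

test_that("secondary-degron sets equal exhaustive window enumeration on random proteins", {
  set.seed(51)
  for (i in 1:40) {
    seq <- random_sequence(sample(20:80, 1))
    L <- nchar(seq)
    s <- sample(seq_len(L - 2), 1)
    e <- min(L, s + sample(0:5, 1))
    flank <- sample(0:15, 1)
    match <- tibble::tibble(
      protein_id = "r", motif_id = "m", start = s, end = e,
      matched_seq = substr(seq, s, e), location_class = "INTERNAL",
      pathway = "toy", met_variant = "as_given", terminus = "none"
    )
    sec <- find_secondary_degrons(match, tibble::tibble(id = "r", sequence = seq),
      mk_context(seq), flank = flank)
    aa <- strsplit(seq, "")[[1]]
    want <- intersect(max(1, s - flank):min(L, e + flank), which(aa %in% c("K", "C", "S", "T")))
    expect_setequal(sec$position, want)
    expect_true(all(sec$position >= s - flank & sec$position <= e + flank))
  }
})

test_that("tertiary assignment picks the nearest IDR with N-terminal tie-break", {
  idrs <- tibble::tibble(start = c(10L, 30L), end = c(15L, 40L),
    length = c(6L, 11L), mean_disorder = c(0.8, 0.9))
  sec <- tibble::tibble(position = c(12L, 21L, 5L))
  out <- assign_tertiary(sec, idrs)
  expect_equal(out$idr_distance, c(0L, 6L, 5L))
  expect_equal(out$idr_start, c(10L, 10L, 10L))
  # position 21 is 6 from [10,15] and 9 from [30,40]; 23 is equidistant (8,7)?
  tie <- assign_tertiary(tibble::tibble(position = 19L), idrs) # d=4 to both? 19-15=4; 30-19=11
  expect_equal(tie$idr_start, 10L)
  # exact tie: place site so distances are equal
  tie2 <- assign_tertiary(tibble::tibble(position = 22L),
    tibble::tibble(start = c(10L, 26L), end = c(18L, 30L)))
  expect_equal(tie2$idr_distance, 4L)
  expect_equal(tie2$idr_start, 10L) # N-terminal IDR wins the d=4 tie

  none <- assign_tertiary(sec, tibble::tibble(start = integer(), end = integer()))
  expect_true(all(is.na(none$idr_start)))

  # oracle: distance equals the exhaustive minimum over IDRs
  set.seed(61)
  for (i in 1:30) {
    k <- sample(1:4, 1)
    starts <- sort(sample(1:80, k))
    ends <- pmin(100L, starts + sample(3:10, k, replace = TRUE))
    idr <- tibble::tibble(start = starts, end = ends)
    pos <- sample(1:100, 5)
    got <- assign_tertiary(tibble::tibble(position = pos), idr)
    want <- vapply(pos, function(p) {
      min(ifelse(idr$start <= p & p <= idr$end, 0L, pmin(abs(p - idr$start), abs(p - idr$end))))
    }, numeric(1))
    expect_equal(got$idr_distance, as.integer(want))
  }
})

test_that("annotation overlay decorates without altering upstream results", {
  seq <- paste0(strrep("A", 10), "KEN", strrep("A", 10), "S", strrep("A", 6))
  p <- tibble::tibble(id = "p", sequence = seq)
  match <- tibble::tibble(
    protein_id = "p", motif_id = "ken", start = 11L, end = 13L,
    matched_seq = "KEN", location_class = "INTERNAL", pathway = "APC/C",
    met_variant = "as_given", terminus = "none"
  )
  rep0 <- tripartite_report(match, p, mk_context(seq), idrs = NULL, flank = 15L)

  ptms <- tibble::tibble(protein_id = "p",
    position = c(11L, 24L, 30L), # in motif; in flank; beyond flank+motif? 13+15=28 -> 30 out
    ptm_type = c("ubiquitination", "phosphorylation", "phosphorylation"),
    source = "toy")
  muts <- tibble::tibble(protein_id = "p",
    position = c(12L, 24L, 2L), ref = c("E", "S", "A"), alt = c("K", "F", "V"),
    source = "toy")
  rep1 <- overlay_annotations(rep0, ptms, muts, flank = 15L)

  # PTMs attach within motif + flanks only
  expect_setequal(rep1$ptms$position, c(11L, 24L))
  expect_true(rep1$ptms$within_primary[rep1$ptms$position == 11L])
  # mutations attach inside the motif, and at PTM-bearing flank positions
  expect_setequal(rep1$mutations$position, c(12L, 24L))
  expect_equal(rep1$mutations$ref[rep1$mutations$position == 12L], "E")
  expect_true(rep1$mutations$at_flank_ptm[rep1$mutations$position == 24L])
  # pure decoration: primary and secondaries unchanged
  expect_identical(rep1$primary, rep0$primary)
  expect_identical(rep1$secondaries, rep0$secondaries)
})

test_that("annotation loaders reject malformed rows with a warning", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "protein_id\tposition\tptm_type\tsource",
    "p\t3\tphosphorylation\ttoy",
    "p\t999\tubiquitination\ttoy",
    "p\tNA\tubiquitination\ttoy"
  ), f)
  p <- tibble::tibble(id = "p", sequence = strrep("A", 50))
  expect_warning(tab <- load_ptms(f, p), "rejected")
  expect_equal(tab$position, 3L)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tposition", "p\t3"), f2)
  expect_error(load_ptms(f2), "lacks column")
})
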