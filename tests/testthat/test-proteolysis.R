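test_that("the built-in registry holds 35 enzymes and resolves lookups", {
  reg <- builtin_rules()
  expect_equal(nrow(reg), 35L)
  expect_equal(anyDuplicated(reg$enzyme), 0L)

  tr <- cleavage_rule("Trypsin")
  expect_s3_class(tr, "cleavage_rule")
  # K/R site with downstream-proline veto, plus the classical exception table
  expect_equal(tr$sites[[1]][["P1"]], "[KR]")
  expect_equal(tr$sites[[1]][["P1p"]], "[^P]")
  expect_equal(length(tr$exceptions), 4L)

  expect_error(cleavage_rule("NoSuchEnzyme"), "unknown_enzyme")
})

test_that("trypsin digests the toy substrate cutting after K2 and K6 only", {
  p <- tibble::tibble(id = "toy", sequence = "AKRPGKA")
  ev <- find_cleavage_sites(p, enzyme = "Trypsin")
  expect_equal(ev$position, c(2L, 6L)) # R3 blocked by P4 proline
  expect_equal(unique(ev$source), "rule")

  # hand-applied oracle on the same substrate
  expect_equal(oracle_cleave("AKRPGKA", cleavage_rule("Trypsin")), c(2L, 6L))

  fr <- digest(p, ev, mode = "full")
  expect_equal(fr$sequence, c("AK", "RPGK", "A"))
})

test_that("rule engine equals the naive per-bond oracle on random substrates", {
  set.seed(71)
  enzymes <- builtin_rules()$enzyme
  for (i in 1:120) {
    enz <- sample(enzymes, 1)
    seq <- random_sequence(sample(5:50, 1))
    rule <- cleavage_rule(enz)
    got <- find_cleavage_sites(tibble::tibble(id = "r", sequence = seq),
      enzyme = rule)$position
    expect_equal(got, oracle_cleave(seq, rule), info = paste(enz, "on", seq))
  }
})

test_that("full digests partition the parent and single-site mode pairs fragments", {
  p <- tibble::tibble(id = "p", sequence = "MKAYLDE")
  fr <- digest(p, c(2L, 6L), mode = "full")
  expect_equal(fr$start, c(1L, 3L, 7L))
  expect_equal(fr$end, c(2L, 6L, 7L))
  expect_equal(paste(fr$sequence, collapse = ""), p$sequence)
  expect_equal(fr$neo_n, c(FALSE, TRUE, TRUE))
  expect_equal(fr$neo_c, c(TRUE, TRUE, FALSE))

  # empty event set: identity fragmentation
  id_fr <- digest(p, integer(), mode = "full")
  expect_equal(nrow(id_fr), 1L)
  expect_equal(id_fr$sequence, p$sequence)
  expect_false(id_fr$neo_n || id_fr$neo_c)

  ss <- digest(p, c(2L, 6L), mode = "single_site")
  expect_equal(nrow(ss), 4L)
  expect_equal(ss$event_position, c(2L, 2L, 6L, 6L))
  expect_equal(ss$sequence[1:2], c("MK", "AYLDE"))

  expect_error(digest(p, 7L), "out of range")
})

test_that("fragment conservation holds on fuzzed digests", {
  set.seed(81)
  for (i in 1:120) {
    seq <- random_sequence(sample(2:120, 1))
    L <- nchar(seq)
    k <- sample(0:min(6, L - 1), 1)
    events <- if (k == 0) integer() else sort(sample(seq_len(L - 1), k))
    fr <- digest(tibble::tibble(id = "z", sequence = seq), events, mode = "full")
    expect_equal(nrow(fr), k + 1L)
    expect_equal(fr$start[1], 1L)
    expect_equal(fr$end[nrow(fr)], L)
    if (nrow(fr) > 1) expect_equal(fr$start[-1], fr$end[-nrow(fr)] + 1L)
    expect_equal(paste(fr$sequence, collapse = ""), seq)
  }
})

test_that("neo-termini are screened and original termini are not", {
  motifs <- toy_motif_set(c("GG", "[RKH]"), c("C_TERMINAL", "N_TERMINAL"))
  p <- tibble::tibble(id = "p", sequence = "KAAGGKLLAA") # starts K, internal GG
  fr <- digest(p, 5L, mode = "full") # fragments 1-5 (KAAGG), 6-10 (KLLAA)
  neo <- neo_degron_screen(fr, motifs)

  # fragment 1: original N-terminus (K) must NOT be screened; neo-C "GG" must hit
  f1 <- neo[neo$fragment_id == "p_1-5", ]
  expect_false(f1$neo_n)
  m1 <- f1$matches[[1]]
  expect_true(all(m1$terminus == "C"))
  expect_equal(m1$parent_start, 4L)
  expect_equal(m1$parent_end, 5L)

  # fragment 2: neo-N lysine -> type1_primary and the N-terminal class motif fires
  f2 <- neo[neo$fragment_id == "p_6-10", ]
  expect_equal(f2$neo_n_residue, "K")
  expect_equal(f2$neo_n_class, "type1_primary")
  expect_equal(f2$neo_n_parent_pos, 6L)
  m2 <- f2$matches[[1]]
  expect_true(any(m2$terminus == "N" & m2$parent_start == 6L))
  expect_false(any(m2$terminus == "C")) # original C-terminus not screened
})

test_that("cleavage sources: user motif, explicit sites, and site tables", {
  p <- tibble::tibble(id = "p", sequence = "AAGGKAAGGKA")
  ev <- find_cleavage_sites(p, motif = "GG")
  expect_equal(ev$position, c(4L, 9L))
  expect_equal(unique(ev$source), "user_motif")
  expect_error(find_cleavage_sites(p, motif = "W"), "no bond")

  ev2 <- find_cleavage_sites(p, positions = c(3L, 7L))
  expect_equal(ev2$position, c(3L, 7L))
  expect_error(find_cleavage_sites(p, positions = 11L), "out of range")
  expect_error(find_cleavage_sites(p, enzyme = "Trypsin", motif = "GG"),
    "exactly one")

  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "protein_id\tposition\tenzyme\tphysiological\tsource",
    "p\t4\tDUB\tTRUE\ttoy",
    "p\t9\tDUB\tFALSE\ttoy"
  ), f)
  st <- load_cleavage_sites(f)
  expect_equal(nrow(st), 1L) # non-physiological rows skipped by default
  ev3 <- find_cleavage_sites(p, sites_table = st)
  expect_equal(ev3$position, 4L)
  st_all <- load_cleavage_sites(f, physiological_only = FALSE)
  expect_equal(nrow(st_all), 2L)
})
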