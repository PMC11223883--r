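test_that("RSA normalization divides by residue maxima and clamps at 1", {
  for (aa in c("A", "W", "G", "R")) {
    mx <- degronkit:::SANDER_MAX_ASA[aa]
    expect_equal(residue_rsa(aa, mx), unname(1))
    expect_equal(residue_rsa(aa, 0), unname(0))
    expect_equal(residue_rsa(aa, 1.2 * mx), unname(1)) # clamped
    expect_equal(residue_rsa(aa, 0.37 * mx), unname(0.37))
  }
  # monotone non-decreasing in asa and equal to independent recomputation
  asa <- seq(0, 300, by = 7.5)
  r <- residue_rsa("L", asa)
  expect_true(all(diff(r) >= 0))
  expect_equal(r, pmin(1, asa / 164))
  expect_error(residue_rsa("J", 10), "non-canonical")
  expect_error(residue_rsa("A", -1), "non-negative")
})

test_that("structure-mode disorder thresholds pLDDT below 70 by default", {
  f <- withr::local_tempfile(fileext = ".pdb")
  b <- rep(90, 30)
  write_toy_pdb(f, rep(c("A", "K", "L"), 10), b = b)
  m <- read_structure(f)
  prof <- disorder_profile(m, mode = "structure_plddt")
  expect_equal(attr(prof, "threshold"), 70)
  expect_false(any(prof$disordered))

  b[10:21] <- 50
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(f2, rep(c("A", "K", "L"), 10), b = b)
  prof2 <- disorder_profile(read_structure(f2), mode = "structure_plddt")
  expect_equal(which(prof2$disordered), 10:21)

  # structure mode without a structure is an error; zero B-factors warn
  expect_error(disorder_profile("MAK", mode = "structure_plddt"), "structure_model")
  f3 <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(f3, c("A", "K", "L"), b = rep(0, 3))
  expect_warning(disorder_profile(read_structure(f3), mode = "structure_plddt"),
    "not pLDDT")
})

test_that("sequence-mode disorder flags above threshold and accepts adapters", {
  prof <- disorder_profile("MAKLVILFAAKDDE", mode = "sequence",
    predictor = function(s) rep(0.4, nchar(s)))
  expect_false(any(prof$disordered))
  expect_equal(attr(prof, "threshold"), 0.5)

  prof2 <- disorder_profile("MAKL", mode = "sequence",
    predictor = function(s) c(0.9, 0.9, 0.2, 0.6))
  expect_equal(prof2$disordered, c(TRUE, TRUE, FALSE, TRUE))

  expect_error(
    disorder_profile("MAKL", mode = "sequence", predictor = function(s) c(0.9)),
    "length_mismatch"
  )

  # built-in heuristic: charged low-hydropathy tracts score disordered,
  # hydrophobic tracts ordered; deterministic
  seq <- paste0(strrep("E", 25), strrep("I", 25))
  p <- disorder_profile(seq, mode = "sequence")
  expect_true(mean(p$score[1:15]) > 0.5)
  expect_true(mean(p$score[36:50]) < 0.5)
  expect_identical(p, disorder_profile(seq, mode = "sequence"))
})

test_that("IDR segmentation returns maximal runs meeting the length floor", {
  mk_prof <- function(flags) {
    tibble::tibble(position = seq_along(flags), score = as.numeric(flags),
      disordered = flags)
  }
  one_run <- mk_prof(c(rep(FALSE, 5), rep(TRUE, 12), rep(FALSE, 3)))
  idr <- segment_idrs(one_run, min_len = 10)
  expect_equal(nrow(idr), 1L)
  expect_equal(c(idr$start, idr$end, idr$length), c(6L, 17L, 12L))

  expect_equal(nrow(segment_idrs(mk_prof(c(rep(FALSE, 3), rep(TRUE, 5))), 10)), 0L)

  full <- segment_idrs(mk_prof(rep(TRUE, 40)), 10)
  expect_equal(c(full$start, full$end), c(1L, 40L))

  # property: runs are disjoint, sorted, and cover exactly the qualifying positions
  set.seed(41)
  for (i in 1:40) {
    flags <- stats::runif(sample(20:80, 1)) < 0.5
    min_len <- sample(2:6, 1)
    idrs <- segment_idrs(mk_prof(flags), min_len)
    if (nrow(idrs) > 1) expect_true(all(diff(idrs$start) > 0))
    covered <- as.integer(unlist(purrr::map2(idrs$start, idrs$end, seq)))
    expect_equal(anyDuplicated(covered), 0L)
    r <- rle(flags)
    ends <- cumsum(r$lengths)
    want <- as.integer(unlist(purrr::map(which(r$values & r$lengths >= min_len), function(k) {
      (ends[k] - r$lengths[k] + 1L):ends[k]
    })))
    expect_equal(sort(covered), sort(want))
  }
})

test_that("secondary structure comes from the adapter or degrades to unknown", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(f, c("A", "K", "L", "W"))
  m <- read_structure(f)

  expect_warning(ss0 <- secondary_structure(m), "no secondary-structure adapter")
  expect_equal(ss0$ss, rep("-", 4))
  expect_true(all(is.na(ss0$rsa)))

  mock <- function(model) list(ss = c("H", "H", "E", "C"), asa = c(53, 205, 82, 227))
  ss1 <- secondary_structure(m, adapter = mock)
  expect_equal(ss1$ss, c("H", "H", "E", "C"))
  expect_equal(ss1$rsa, c(53 / 106, 205 / 205, 82 / 164, 227 / 227))

  bad <- function(model) list(ss = c("H", "H"), asa = c(1, 2))
  expect_error(secondary_structure(m, adapter = bad), "length_mismatch")

  failing <- function(model) stop("tool crashed")
  expect_warning(ss2 <- secondary_structure(m, adapter = failing), "adapter failed")
  expect_equal(ss2$ss, rep("-", 4))
})
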