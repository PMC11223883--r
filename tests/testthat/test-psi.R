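test_that("terminal featurization covers the window set with exact descriptors", {
  pep <- strrep("A", 23)
  f <- featurize_terminus(pep, "C")
  tags <- c("full", "w10", "w8", "w6", "w4", "w2")
  for (tag in tags) {
    expect_equal(unname(f[1, paste0(tag, "_comp_A")]), 1.0)
    expect_equal(unname(f[1, paste0(tag, "_gravy")]), 1.8)
  }
  expect_equal(unname(f[1, "full_eff_len"]), 23)
  expect_equal(unname(f[1, "w10_eff_len"]), 10)
  # aromaticity/aliphatic sanity on a poly-A peptide
  expect_equal(unname(f[1, "full_aromaticity"]), 0)
  expect_equal(unname(f[1, "full_aliphatic_index"]), 100)

  # windows shorter than requested use the available residues
  short <- featurize_terminus("KAVL", "C")
  expect_equal(unname(short[1, "w10_eff_len"]), 4)

  expect_error(featurize_terminus("KAJL", "C"), "non-canonical")
  expect_error(featurize_terminus("K", "C"), "length >= 2")
})

test_that("retained initiator methionine is excluded from windowed descriptors", {
  pep <- paste0("M", strrep("A", 22))
  f <- featurize_terminus(pep, "N_met_retained")
  # w2 window is "AA", not "MA"
  expect_equal(unname(f[1, "w2_comp_A"]), 1.0)
  expect_equal(unname(f[1, "w2_comp_M"]), 0.0)
  # the full-peptide block still sees the Met
  expect_gt(f[1, "full_comp_M"], 0)

  # cleaved-N windows start at residue 1 as given
  f2 <- featurize_terminus(strrep("K", 23), "N_met_cleaved")
  expect_equal(unname(f2[1, "w2_comp_K"]), 1.0)

  # purity / column-order stability
  expect_identical(featurize_terminus(pep, "N_met_retained"), f)
})

test_that("net charge and isoelectric point behave physically", {
  acid <- featurize_terminus(strrep("E", 10), "C")
  base <- featurize_terminus(strrep("K", 10), "C")
  expect_lt(acid[1, "full_net_charge"], 0)
  expect_gt(base[1, "full_net_charge"], 0)
  expect_lt(acid[1, "full_isoelectric_point"], 5)
  expect_gt(base[1, "full_isoelectric_point"], 9)
  # molecular weight of AA dipeptide: 2 * 71.0788 + water
  di <- featurize_terminus("AA", "C")
  expect_equal(unname(di[1, "full_mol_weight"]), 2 * 71.0788 + 18.0153, tolerance = 1e-6)
})

test_that("stability categories partition the line with right-closed bins", {
  q <- c(-2, -1, 0, 1)
  expect_equal(categorize_psi(-3, q), "most_unstable")
  expect_equal(categorize_psi(-2, q), "most_unstable") # exactly at the cut: lower bin
  expect_equal(categorize_psi(-0.5, q), "medium")
  expect_equal(categorize_psi(1, q), "stable") # at the top cut -> stable, not most_stable
  expect_equal(categorize_psi(1.5, q), "most_stable")

  # every psi maps to exactly one category
  psi <- seq(-4, 4, by = 0.01)
  cats <- categorize_psi(psi, q)
  expect_false(anyNA(cats))
  expect_true(all(cats %in% c("most_unstable", "unstable", "medium", "stable", "most_stable")))

  expect_warning(deg <- categorize_psi(c(-1, 5), c(0, 0, 0, 0)), "degenerate")
  expect_equal(deg, c("medium", "medium"))
  expect_error(categorize_psi(0, c(1, 0, 2, 3)), "monotone")
})

test_that("the synthetic PSI generator is seed-reproducible", {
  d1 <- synthesize_psi_dataset(100, terminus = "C", seed = 7)
  d2 <- synthesize_psi_dataset(100, terminus = "C", seed = 7)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 100L)
  expect_true(all(nchar(d1$peptide) == 23L))
  d3 <- synthesize_psi_dataset(50, terminus = "N_met_retained", seed = 7)
  expect_true(all(startsWith(d3$peptide, "M")))
  expect_false(identical(d1$peptide[1:50], d3$peptide))
})

test_that("training reports the configured split and CV defaults", {
  d <- synthesize_psi_dataset(300, terminus = "C", seed = 3)
  m <- train_psi(d, cv_folds = 2L, nrounds = 40L)
  expect_equal(m$metrics$n_train, 270L)
  expect_equal(m$metrics$n_test, 30L)
  expect_equal(unname(m$metrics$split), c(0.9, 0.1))
  expect_equal(nrow(m$metrics$cv), 2L)
  expect_length(m$training_quantiles, 4L)
  expect_false(is.unsorted(m$training_quantiles))

  g <- glance(m)
  expect_equal(g$n_train, 270L)
  td <- tidy(m)
  expect_true(all(c("term", "gain") %in% names(td)))
  expect_gt(nrow(td), 0L)

  expect_error(train_psi(d[1:30, ]), "insufficient rows")
  mixed <- d
  mixed$terminus[1] <- "N_met_cleaved"
  expect_error(train_psi(mixed), "mixed termini")
})

test_that("constant targets give a constant model with near-zero test error", {
  d <- synthesize_psi_dataset(120, terminus = "C", seed = 5)
  d$psi <- 3.25
  m <- train_psi(d, cv_folds = 0L)
  expect_lt(m$metrics$rmse_test, 1e-6)
  pred <- suppressWarnings(predict_psi(m, peptides = tibble::tibble(protein_id = "x",
    peptide = strrep("A", 23)))) # degenerate quantile cuts warn by design
  expect_equal(pred$psi, 3.25)
})

test_that("a noiseless linear Gravy signal is recovered almost perfectly", {
  d <- synthesize_psi_dataset(1200, terminus = "C", sigma = 0, seed = 9)
  m <- train_psi(d, cv_folds = 0L, nrounds = 400L)
  expect_gte(m$metrics$r2_test, 0.99)
  # the planted feature dominates importance
  expect_equal(tidy(m)$term[1], "full_gravy")
})

test_that("prediction slices termini, categorizes, and respects the median", {
  d <- synthesize_psi_dataset(400, terminus = "C", seed = 13)
  m <- train_psi(d, cv_folds = 0L, nrounds = 60L)

  # psi equal to the training median -> medium; below q20 -> most_unstable
  q <- m$training_quantiles
  med <- (q[2] + q[3]) / 2
  expect_equal(categorize_psi(med, q), "medium")
  expect_equal(categorize_psi(q[1] - 1, q), "most_unstable")

  prot <- tibble::tibble(id = "long", sequence = random_sequence(60))
  pred <- predict_psi(m, proteins = prot)
  expect_equal(nchar(pred$peptide), 23L)
  expect_equal(pred$peptide, substring(prot$sequence, 38, 60))
  expect_true(pred$category %in% c("most_unstable", "unstable", "medium",
    "stable", "most_stable"))

  shortp <- tibble::tibble(id = "short", sequence = random_sequence(10))
  expect_message(pred2 <- predict_psi(m, proteins = shortp), "shorter than 23")
  expect_equal(nchar(pred2$peptide), 10L)

  nmod <- train_psi(synthesize_psi_dataset(200, terminus = "N_met_cleaved", seed = 17),
    cv_folds = 0L, nrounds = 40L)
  predn <- predict_psi(nmod, proteins = prot)
  expect_equal(predn$peptide, substr(prot$sequence, 1, 23))
})
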