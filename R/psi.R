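PSI_TERMINI <- c("N_met_cleaved", "N_met_retained", "C")
PSI_CATEGORIES <- c("most_unstable", "unstable", "medium", "stable", "most_stable")
PSI_WINDOWS <- c(10L, 8L, 6L, 4L, 2L)

# ---- vectorized physicochemical descriptors over peptide strings ----

aa_count_matrix <- function(peptides) {
  mats <- lapply(strsplit(peptides, ""), function(a) {
    tabulate(match(a, AA_CANONICAL), nbins = 20L)
  })
  m <- do.call(rbind, mats)
  colnames(m) <- AA_CANONICAL
  m
}

# net charge at a given pH from residue counts (Henderson-Hasselbalch,
# EMBOSS pKa set, free N- and C-termini)
charge_from_counts <- function(counts, pH) {
  pos <- 1 / (1 + 10^(pH - PKA_NTERM))
  for (aa in AA_BASIC) {
    pos <- pos + counts[, aa] / (1 + 10^(pH - PKA_SIDECHAIN[aa]))
  }
  neg <- 1 / (1 + 10^(PKA_CTERM - pH))
  for (aa in AA_ACIDIC) {
    neg <- neg + counts[, aa] / (1 + 10^(PKA_SIDECHAIN[aa] - pH))
  }
  pos - neg
}

isoelectric_from_counts <- function(counts) {
  lo <- rep(0, nrow(counts))
  hi <- rep(14, nrow(counts))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    q <- charge_from_counts(counts, mid)
    lo <- ifelse(q > 0, mid, lo)
    hi <- ifelse(q > 0, hi, mid)
  }
  (lo + hi) / 2
}

window_features <- function(peptides, tag) {
  len <- nchar(peptides)
  if (any(len == 0L)) stop("empty window peptide")
  counts <- aa_count_matrix(peptides)
  if (any(rowSums(counts) != len)) stop("non-canonical residue in peptide(s)")
  frac <- counts / len
  feats <- cbind(
    frac,
    gravy = as.numeric(counts %*% KD_HYDROPATHY[AA_CANONICAL]) / len,
    net_charge = charge_from_counts(counts, 7.0),
    mol_weight = as.numeric(counts %*% AA_RESIDUE_MASS[AA_CANONICAL]) + WATER_MASS,
    aromaticity = rowSums(frac[, AA_AROMATIC, drop = FALSE]),
    isoelectric_point = isoelectric_from_counts(counts),
    aliphatic_index = 100 * (frac[, "A"] + 2.9 * frac[, "V"] + 3.9 * (frac[, "I"] + frac[, "L"])),
    eff_len = len
  )
  colnames(feats)[1:20] <- paste0("comp_", AA_CANONICAL)
  colnames(feats) <- paste0(tag, "_", colnames(feats))
  feats
}

#' Featurize terminal peptides for PSI modelling
#'
#' Computes sequence-derived physicochemical descriptors — amino-acid
#' composition (20), Gravy, net charge at pH 7.0, molecular weight,
#' aromaticity fraction, isoelectric point and aliphatic index — over the
#' whole peptide and over the terminal 10, 8, 6, 4 and 2 residues. For
#' N-terminal peptides the windows are taken from the front (excluding the
#' initiator methionine when `terminus = "N_met_retained"`); for C-terminal
#' peptides from the back. Windows shorter than requested use the available
#' residues and record the effective length as a feature.
#'
#' @param peptides Character vector of canonical peptides (length >= 2),
#'   or a tibble with a `peptide` column.
#' @param terminus One of `"N_met_cleaved"`, `"N_met_retained"`, `"C"`.
#' @return A numeric matrix, one row per peptide, with a stable column
#'   schema (attribute `terminus` records the terminus used).
#' @export
featurize_terminus <- function(peptides, terminus = c("C", "N_met_cleaved", "N_met_retained")) {
  terminus <- match.arg(terminus)
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  peptides <- toupper(peptides)
  if (any(nchar(peptides) < 2L)) stop("peptides must have length >= 2")
  # windowed descriptors exclude the initiator Met when it is retained
  core <- if (terminus == "N_met_retained") {
    ifelse(startsWith(peptides, "M") & nchar(peptides) >= 2L, substring(peptides, 2L), peptides)
  } else {
    peptides
  }
  from_n <- terminus != "C"
  blocks <- c(
    list(window_features(peptides, "full")),
    lapply(PSI_WINDOWS, function(w) {
      len <- nchar(core)
      wl <- pmin(w, len)
      slice <- if (from_n) substr(core, 1L, wl) else substring(core, len - wl + 1L, len)
      window_features(slice, paste0("w", w))
    })
  )
  out <- do.call(cbind, blocks)
  attr(out, "terminus") <- terminus
  out
}

#' Generate a synthetic terminal-peptide stability dataset
#'
#' Draws random canonical 23-mers (with a fixed leading methionine for
#' `N_met_retained`) and assigns each a PSI value
#' `psi = effect(features) + N(0, sigma)`. The default effect is linear in
#' the full-window Gravy (`psi = 2 * gravy`), a clean planted signal for
#' parameter-recovery testing of the training pipeline. Reproducible under
#' `seed`.
#'
#' @param n Number of peptides.
#' @param terminus Terminus label for the dataset.
#' @param effect Function of the feature matrix returning the noiseless PSI;
#'   default `2 * full_gravy`.
#' @param sigma Gaussian noise standard deviation (default 0.1).
#' @param seed RNG seed.
#' @param peptide_length Peptide length (default 23).
#' @return Tibble with columns `protein_id`, `terminus`, `peptide`, `psi`.
#' @export
synthesize_psi_dataset <- function(n, terminus = "C", effect = NULL, sigma = 0.1,
                                   seed = 1L, peptide_length = 23L) {
  stopifnot(n >= 1L, terminus %in% PSI_TERMINI)
  if (is.null(effect)) effect <- function(features) 2 * features[, "full_gravy"]
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  body_len <- if (terminus == "N_met_retained") peptide_length - 1L else peptide_length
  peptides <- vapply(seq_len(n), function(i) {
    paste(sample(AA_CANONICAL, body_len, replace = TRUE), collapse = "")
  }, character(1))
  if (terminus == "N_met_retained") peptides <- paste0("M", peptides)
  feats <- featurize_terminus(peptides, terminus)
  psi <- as.numeric(effect(feats)) + stats::rnorm(n, 0, sigma)
  tibble::tibble(
    protein_id = sprintf("syn%05d", seq_len(n)),
    terminus = terminus,
    peptide = peptides,
    psi = psi
  )
}

#' Load a terminal-peptide stability (GPS-style) table
#'
#' TSV schema: `protein_id`, `terminus` (one of `N_met_cleaved`,
#' `N_met_retained`, `C`), `peptide` (canonical, length 2-23), `psi`
#' (numeric). Nothing is bundled: users populate this table from published
#' stability studies.
#'
#' @param path TSV path.
#' @return Tibble of validated rows.
#' @export
load_gps_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, quote = "")
  required <- c("protein_id", "terminus", "peptide", "psi")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("stability table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!all(df$terminus %in% PSI_TERMINI)) {
    stop("terminus values must be one of: ", paste(PSI_TERMINI, collapse = ", "))
  }
  df$peptide <- toupper(df$peptide)
  bad <- !grepl(paste0("^[", paste(AA_CANONICAL, collapse = ""), "]{2,23}$"), df$peptide)
  if (any(bad)) {
    stop("non-canonical or out-of-length peptide(s) in row(s): ",
      paste(which(bad), collapse = ", "))
  }
  df$psi <- as.numeric(df$psi)
  tibble::as_tibble(df)
}

#' Train a terminal-peptide stability (PSI) regressor
#'
#' Trains a gradient-boosted tree regressor of PSI from terminal-peptide
#' descriptors for a single terminus. The data are split into training and
#' held-out test sets (default 90:10); performance (R-squared and RMSE) is
#' reported on the held-out split, and additionally by repeated
#' random-permutation cross-validation on the training set (default 5 folds,
#' 20% validation each). Stability-category quantile cuts are computed from
#' the training PSI distribution. Degenerate constant-target data yield a
#' constant model.
#'
#' @param data Tibble with columns `terminus`, `peptide`, `psi` (>= 50 rows,
#'   a single terminus).
#' @param split Training fraction (default 0.9).
#' @param cv_folds Number of random-permutation CV folds (default 5; 0
#'   disables CV).
#' @param cv_validation Validation fraction per CV fold (default 0.2).
#' @param category_quantiles Quantile cuts for stability categories
#'   (default 20/40/60/80th percentiles).
#' @param seed RNG seed for the split, CV and booster (default 42).
#' @param nrounds,max_depth,eta Booster hyperparameters (modest defaults;
#'   no hyperparameter search is performed).
#' @return An object of class `psi_model`.
#' @export
train_psi <- function(data, split = 0.9, cv_folds = 5L, cv_validation = 0.2,
                      category_quantiles = c(0.2, 0.4, 0.6, 0.8),
                      seed = 42L, nrounds = 300L, max_depth = 5L, eta = 0.1) {
  stopifnot(is.data.frame(data), all(c("terminus", "peptide", "psi") %in% names(data)))
  termini <- unique(data$terminus)
  if (length(termini) != 1L) {
    stop("mixed termini in training data: ", paste(termini, collapse = ", "),
      "; train one model per terminus")
  }
  if (nrow(data) < 50L) stop("insufficient rows: need >= 50, got ", nrow(data))
  terminus <- termini[1]
  feats <- featurize_terminus(data$peptide, terminus)
  y <- as.numeric(data$psi)

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- nrow(data)
  idx <- sample.int(n)
  n_train <- floor(split * n)
  train_idx <- idx[seq_len(n_train)]
  test_idx <- idx[-seq_len(n_train)]

  quantiles <- stats::quantile(y[train_idx], probs = category_quantiles, names = FALSE)

  fit_booster <- function(rows) {
    xgboost::xgb.train(
      params = list(
        objective = "reg:squarederror", max_depth = max_depth, eta = eta,
        subsample = 0.9, colsample_bytree = 0.9, nthread = 1, seed = seed
      ),
      data = xgboost::xgb.DMatrix(feats[rows, , drop = FALSE], label = y[rows]),
      nrounds = nrounds, verbose = 0
    )
  }
  eval_on <- function(booster, rows) {
    pred <- stats::predict(booster, xgboost::xgb.DMatrix(feats[rows, , drop = FALSE]))
    rmse <- sqrt(mean((pred - y[rows])^2))
    denom <- sum((y[rows] - mean(y[rows]))^2)
    r2 <- if (denom == 0) NA_real_ else 1 - sum((pred - y[rows])^2) / denom
    list(r2 = r2, rmse = rmse, pred = pred)
  }

  constant <- NULL
  if (stats::sd(y[train_idx]) == 0) {
    constant <- y[train_idx][1]
    booster <- NULL
    test_pred <- rep(constant, length(test_idx))
    rmse_test <- sqrt(mean((test_pred - y[test_idx])^2))
    r2_test <- NA_real_
    cv <- tibble::tibble(fold = integer(), r2 = numeric(), rmse = numeric())
  } else {
    booster <- fit_booster(train_idx)
    ev <- eval_on(booster, test_idx)
    r2_test <- ev$r2
    rmse_test <- ev$rmse
    test_pred <- ev$pred
    cv <- if (cv_folds > 0L) {
      purrr::map_dfr(seq_len(cv_folds), function(f) {
        perm <- sample(train_idx)
        n_val <- max(1L, floor(cv_validation * length(perm)))
        val <- perm[seq_len(n_val)]
        tr <- perm[-seq_len(n_val)]
        b <- xgboost::xgb.train(
          params = list(
            objective = "reg:squarederror", max_depth = max_depth, eta = eta,
            subsample = 0.9, colsample_bytree = 0.9, nthread = 1, seed = seed + f
          ),
          data = xgboost::xgb.DMatrix(feats[tr, , drop = FALSE], label = y[tr]),
          nrounds = nrounds, verbose = 0
        )
        ev <- eval_on(b, val)
        tibble::tibble(fold = f, r2 = ev$r2, rmse = ev$rmse)
      })
    } else {
      tibble::tibble(fold = integer(), r2 = numeric(), rmse = numeric())
    }
  }

  structure(
    list(
      terminus = terminus,
      booster = booster,
      constant = constant,
      feature_names = colnames(feats),
      training_quantiles = quantiles,
      category_quantiles = category_quantiles,
      seed = seed,
      metrics = list(
        r2_test = r2_test, rmse_test = rmse_test,
        n_train = length(train_idx), n_test = length(test_idx),
        cv_folds = cv_folds, split = c(train = split, test = 1 - split),
        cv = cv
      ),
      test = tibble::tibble(observed = y[test_idx], predicted = test_pred),
      config = list(nrounds = nrounds, max_depth = max_depth, eta = eta)
    ),
    class = "psi_model"
  )
}

#' @export
print.psi_model <- function(x, ...) {
  cat("<psi_model> terminus:", x$terminus,
    " n_train:", x$metrics$n_train, " n_test:", x$metrics$n_test, "\n")
  cat("  r2_test:", signif(x$metrics$r2_test, 3),
    " rmse_test:", signif(x$metrics$rmse_test, 3), "\n")
  cat("  category cuts:", paste(signif(x$training_quantiles, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Assign a stability category from quantile cuts
#'
#' Bins a PSI value against the training-distribution quantile cuts
#' (default 20/40/60/80th percentiles) into five categories from
#' `most_unstable` (lowest PSI) to `most_stable`. Bins are right-closed: a
#' value exactly at a cut falls in the lower bin. Degenerate (all-equal)
#' cuts yield `medium` with a warning.
#'
#' @param psi Numeric vector of PSI values.
#' @param quantiles Monotone non-decreasing numeric vector of 4 cuts.
#' @return Character vector of categories.
#' @export
categorize_psi <- function(psi, quantiles) {
  stopifnot(length(quantiles) == 4L)
  if (is.unsorted(quantiles)) stop("quantile cuts must be monotone non-decreasing")
  if (length(unique(quantiles)) == 1L) {
    warning("degenerate quantile cuts (all equal): category set to 'medium'")
    return(rep("medium", length(psi)))
  }
  idx <- findInterval(psi, quantiles, left.open = TRUE)
  PSI_CATEGORIES[idx + 1L]
}

#' Predict terminal-peptide stability
#'
#' Applies a trained PSI model to proteins (sliced automatically to their
#' terminal 23-mer on the model's terminus) or to explicit peptides, and
#' assigns each prediction a stability category from the model's training
#' quantiles.
#'
#' @param model A `psi_model` from [train_psi()].
#' @param proteins Protein tibble (`id`, `sequence`); termini are sliced per
#'   the model's terminus (`N_*`: first 23 residues, `C`: last 23). Proteins
#'   shorter than 23 residues are featurized on the available residues, with
#'   a note.
#' @param peptides Alternatively, a tibble with `protein_id` and `peptide`.
#' @return Tibble: `protein_id`, `peptide`, `terminus`, `psi`, `category`.
#' @export
predict_psi <- function(model, proteins = NULL, peptides = NULL) {
  stopifnot(inherits(model, "psi_model"))
  if (is.null(peptides) == is.null(proteins)) {
    stop("supply exactly one of proteins or peptides")
  }
  if (!is.null(proteins)) {
    lens <- nchar(proteins$sequence)
    if (any(lens < 23L)) {
      message("protein(s) shorter than 23 residues featurized on the available residues: ",
        paste(proteins$id[lens < 23L], collapse = ", "))
    }
    pep <- ifelse(
      rep(model$terminus != "C", nrow(proteins)),
      substr(proteins$sequence, 1L, pmin(23L, lens)),
      substring(proteins$sequence, pmax(1L, lens - 22L), lens)
    )
    peptides <- tibble::tibble(protein_id = proteins$id, peptide = pep)
  }
  if (any(nchar(peptides$peptide) < 2L)) stop("peptide shorter than 2 residues")
  feats <- featurize_terminus(peptides$peptide, model$terminus)
  feats <- feats[, model$feature_names, drop = FALSE]
  psi <- if (!is.null(model$constant)) {
    rep(model$constant, nrow(feats))
  } else {
    stats::predict(model$booster, xgboost::xgb.DMatrix(feats))
  }
  tibble::tibble(
    protein_id = peptides$protein_id,
    peptide = peptides$peptide,
    terminus = model$terminus,
    psi = as.numeric(psi),
    category = categorize_psi(as.numeric(psi), model$training_quantiles)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PSI model: feature importance
#'
#' @param x A `psi_model`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `gain`, `cover`, `frequency` (empty
#'   for a degenerate constant model).
#' @method tidy psi_model
#' @export
tidy.psi_model <- function(x, ...) {
  if (is.null(x$booster)) {
    return(tibble::tibble(term = character(), gain = numeric(),
      cover = numeric(), frequency = numeric()))
  }
  imp <- xgboost::xgb.importance(model = x$booster)
  tibble::tibble(
    term = imp$Feature, gain = imp$Gain, cover = imp$Cover, frequency = imp$Frequency
  )
}

#' Glance at a PSI model: one-row fit summary
#'
#' @param x A `psi_model`.
#' @param ... Unused.
#' @return One-row tibble: `terminus`, `r2_test`, `rmse_test`, `n_train`,
#'   `n_test`, `cv_folds`, `cv_r2_mean`, `cv_rmse_mean`.
#' @method glance psi_model
#' @export
glance.psi_model <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    terminus = x$terminus,
    r2_test = m$r2_test,
    rmse_test = m$rmse_test,
    n_train = m$n_train,
    n_test = m$n_test,
    cv_folds = m$cv_folds,
    cv_r2_mean = if (nrow(m$cv) > 0) mean(m$cv$r2) else NA_real_,
    cv_rmse_mean = if (nrow(m$cv) > 0) mean(m$cv$rmse) else NA_real_
  )
}
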