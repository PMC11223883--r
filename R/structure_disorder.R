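#' Relative solvent accessibility by residue-type maxima
#'
#' Normalizes an absolute accessible surface area (ASA, in square Angstrom)
#' to relative solvent accessibility by dividing by the residue-type maximum
#' of Rost & Sander (1994) and clamping at 1.
#'
#' @param aa Character vector of one-letter residue codes.
#' @param asa Numeric vector of absolute ASA values (>= 0), recycled against
#'   `aa`.
#' @return Numeric vector of RSA values in `[0, 1]`.
#' @examples
#' residue_rsa("A", c(0, 53, 106, 130))
#' @export
residue_rsa <- function(aa, asa) {
  aa <- toupper(aa)
  bad <- !aa %in% AA_CANONICAL
  if (any(bad)) stop("non-canonical residue(s): ", paste(unique(aa[bad]), collapse = ", "))
  if (any(asa < 0, na.rm = TRUE)) stop("asa must be non-negative")
  pmin(1, asa / SANDER_MAX_ASA[aa])
}

# FoldIndex-style sequence disorder heuristic: windowed mean hydropathy
# (Kyte-Doolittle rescaled to [0,1]) against windowed mean absolute net
# charge; FI < 0 indicates disorder. Mapped to [0,1] through a logistic so
# that score > 0.5 <=> FI < 0, matching the sequence-mode threshold.
sequence_disorder_score <- function(sequence, window = 21L) {
  aa <- strsplit(sequence, "")[[1]]
  L <- length(aa)
  h <- (KD_HYDROPATHY[aa] + 4.5) / 9
  q <- ifelse(aa %in% c("K", "R"), 1, ifelse(aa %in% c("D", "E"), -1, 0))
  half <- (window - 1L) %/% 2L
  fi <- vapply(seq_len(L), function(i) {
    lo <- max(1L, i - half)
    hi <- min(L, i + half)
    2.785 * mean(h[lo:hi]) - abs(mean(q[lo:hi])) - 1.151
  }, numeric(1))
  stats::plogis(-5 * fi)
}

#' Per-residue disorder profile
#'
#' Two modes mirror the two standard inputs for disorder calling:
#'
#' * `structure_plddt` — requires a [read_structure()] model whose B-factor
#'   column carries pLDDT/LDDT values; a residue is disordered when its score
#'   is *below* the threshold (default 70).
#' * `sequence` — scores come from `predictor` if supplied (an adapter
#'   function `function(sequence) -> numeric in [0,1]`, e.g. wrapping an
#'   external disorder predictor), otherwise from the built-in windowed
#'   hydropathy/net-charge heuristic; a residue is disordered when its score
#'   is *above* the threshold (default 0.5).
#'
#' @param x A `structure_model` (structure mode) or a protein tibble / single
#'   sequence string (sequence mode).
#' @param mode `"structure_plddt"` or `"sequence"`.
#' @param threshold Disorder cutoff; defaults to 70 (structure) or 0.5
#'   (sequence).
#' @param predictor Optional adapter function for sequence mode.
#' @return A tibble of class `disorder_profile` with columns `position`,
#'   `aa`, `score`, `disordered`, and attributes `mode` and `threshold`.
#' @export
disorder_profile <- function(x, mode = c("structure_plddt", "sequence"),
                             threshold = NULL, predictor = NULL) {
  mode <- match.arg(mode)
  if (mode == "structure_plddt") {
    if (!inherits(x, "structure_model")) {
      stop("structure_plddt mode requires a structure_model (see read_structure())")
    }
    if (is.null(threshold)) threshold <- 70
    scores <- x$residues$b_factor
    if (all(scores == 0)) {
      warning("all B-factor values are zero: the column is likely not pLDDT/LDDT")
    }
    out <- tibble::tibble(
      position = x$residues$position,
      aa = x$residues$aa,
      score = scores,
      disordered = scores < threshold
    )
  } else {
    seq <- if (inherits(x, "structure_model")) {
      x$record$sequence
    } else if (is.data.frame(x)) {
      if (nrow(x) != 1L) stop("sequence mode expects a single protein row or string")
      x$sequence
    } else {
      as.character(x)
    }
    if (is.null(threshold)) threshold <- 0.5
    scores <- if (is.null(predictor)) {
      sequence_disorder_score(seq)
    } else {
      s <- predictor(seq)
      if (length(s) != nchar(seq)) {
        stop("length_mismatch: disorder predictor returned ", length(s),
          " scores for ", nchar(seq), " residues")
      }
      as.numeric(s)
    }
    out <- tibble::tibble(
      position = seq_len(nchar(seq)),
      aa = strsplit(seq, "")[[1]],
      score = scores,
      disordered = scores > threshold
    )
  }
  attr(out, "mode") <- mode
  attr(out, "threshold") <- threshold
  class(out) <- c("disorder_profile", class(out))
  out
}

#' Segment a disorder profile into intrinsically disordered regions
#'
#' IDRs are maximal runs of consecutively disordered residues whose length
#' meets the configured minimum.
#'
#' @param profile A `disorder_profile` tibble (or any tibble with `position`
#'   and `disordered` plus `score` columns).
#' @param min_len Minimum run length (default 10 residues).
#' @return Tibble with columns `start`, `end`, `length`, `mean_disorder`,
#'   sorted by `start`.
#' @export
segment_idrs <- function(profile, min_len = 10L) {
  stopifnot(min_len >= 1L)
  empty <- tibble::tibble(
    start = integer(), end = integer(), length = integer(), mean_disorder = numeric()
  )
  flags <- profile$disordered
  if (length(flags) == 0L || !any(flags)) return(empty)
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  out <- purrr::map_dfr(which(keep), function(k) {
    idx <- starts[k]:ends[k]
    tibble::tibble(
      start = profile$position[starts[k]],
      end = profile$position[ends[k]],
      length = r$lengths[k],
      mean_disorder = mean(profile$score[idx])
    )
  })
  dplyr::bind_rows(empty, out)
}

#' Secondary structure and accessibility through an external adapter
#'
#' Secondary-structure assignment and absolute ASA are delegated to an
#' external tool (typically a DSSP wrapper) through an adapter function; the
#' package never re-implements hydrogen-bond assignment. When no adapter is
#' configured, every residue gets `ss = "-"` and ASA/RSA are `NA`, and the
#' analysis degrades gracefully rather than failing.
#'
#' The adapter contract: `adapter(model)` returns a list (or data frame) with
#' elements `ss` (character vector, DSSP 8-class alphabet) and `asa`
#' (numeric, square Angstrom), both of length equal to the number of
#' residues.
#'
#' @param model A `structure_model`.
#' @param adapter Optional adapter function; `NULL` (default) means none is
#'   configured.
#' @return Tibble with columns `position`, `aa`, `ss`, `asa`, `rsa`.
#' @export
secondary_structure <- function(model, adapter = NULL) {
  stopifnot(inherits(model, "structure_model"))
  n <- nrow(model$residues)
  if (is.null(adapter)) {
    warning("no secondary-structure adapter configured: ss set to '-' and ASA unavailable")
    return(tibble::tibble(
      position = model$residues$position, aa = model$residues$aa,
      ss = "-", asa = NA_real_, rsa = NA_real_
    ))
  }
  res <- tryCatch(adapter(model), error = function(e) e)
  if (inherits(res, "error")) {
    warning("secondary-structure adapter failed (", conditionMessage(res),
      "): falling back to unknown ss")
    return(tibble::tibble(
      position = model$residues$position, aa = model$residues$aa,
      ss = "-", asa = NA_real_, rsa = NA_real_
    ))
  }
  if (length(res$ss) != n || length(res$asa) != n) {
    stop("length_mismatch: adapter returned ", length(res$ss), "/", length(res$asa),
      " values for ", n, " residues")
  }
  tibble::tibble(
    position = model$residues$position,
    aa = model$residues$aa,
    ss = as.character(res$ss),
    asa = as.numeric(res$asa),
    rsa = residue_rsa(model$residues$aa, as.numeric(res$asa))
  )
}

#' Assemble the per-residue context table
#'
#' Joins secondary structure/accessibility (structure queries with an adapter)
#' with the disorder profile into the per-residue context consumed by the
#' tripartite analysis. Sequence-only queries get `ss = "-"` and `NA`
#' ASA/RSA.
#'
#' @param x A `structure_model` or protein tibble row.
#' @param mode,threshold,predictor Passed to [disorder_profile()]; `mode`
#'   defaults to `"structure_plddt"` for structures and `"sequence"`
#'   otherwise.
#' @param adapter Optional secondary-structure adapter (structures only).
#' @return Tibble with columns `position`, `aa`, `ss`, `asa`, `rsa`,
#'   `disorder_score`, `disordered`.
#' @export
residue_context <- function(x, mode = NULL, threshold = NULL, predictor = NULL,
                            adapter = NULL) {
  is_struct <- inherits(x, "structure_model")
  if (is.null(mode)) mode <- if (is_struct) "structure_plddt" else "sequence"
  prof <- disorder_profile(x, mode = mode, threshold = threshold, predictor = predictor)
  if (is_struct) {
    ss <- if (is.null(adapter)) {
      tibble::tibble(
        position = x$residues$position, aa = x$residues$aa,
        ss = "-", asa = NA_real_, rsa = NA_real_
      )
    } else {
      secondary_structure(x, adapter = adapter)
    }
  } else {
    ss <- tibble::tibble(
      position = prof$position, aa = prof$aa,
      ss = "-", asa = NA_real_, rsa = NA_real_
    )
  }
  dplyr::left_join(ss, tibble::tibble(
    position = prof$position, disorder_score = prof$score, disordered = prof$disordered
  ), by = "position")
}
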