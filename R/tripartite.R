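#' Find secondary degrons around primary matches
#'
#' Under the tripartite degron model a primary motif is accompanied by
#' secondary degrons — candidate ubiquitination sites: not only lysines (K)
#' but also cysteines (C), serines (S) and threonines (T) — in the motif and
#' its flanking regions. This collects every K/C/S/T within
#' `[start - flank, end + flank]` (clipped to the protein) for each primary
#' match, annotating each site with its structural context.
#'
#' @param matches Degron match tibble from [scan_degrons()].
#' @param proteins Protein tibble containing the matched proteins.
#' @param context Per-residue context from [residue_context()] for the
#'   protein(s); must cover all positions. May be `NULL`, in which case
#'   structural columns are `NA`.
#' @param idrs IDR tibble from [segment_idrs()] (used for `in_idr`); may be
#'   empty or `NULL`.
#' @param flank Flank size in residues on each side of the primary match
#'   (default 15).
#' @param site_window Half-window for `mean_flank_disorder` around each site
#'   (default 5, i.e. a site-centred window of +-5 residues).
#' @return Tibble with one row per secondary degron: `protein_id`,
#'   `motif_id`, `primary_start`, `primary_end`, `met_variant`, `position`,
#'   `residue`, `rsa`, `ss`, `in_idr`, `mean_flank_disorder`,
#'   `within_primary`.
#' @export
find_secondary_degrons <- function(matches, proteins, context = NULL, idrs = NULL,
                                   flank = 15L, site_window = 5L) {
  stopifnot(is.data.frame(matches), is.data.frame(proteins))
  empty <- tibble::tibble(
    protein_id = character(), motif_id = character(), primary_start = integer(),
    primary_end = integer(), met_variant = character(), position = integer(),
    residue = character(), rsa = numeric(), ss = character(), in_idr = logical(),
    mean_flank_disorder = numeric(), within_primary = logical()
  )
  if (nrow(matches) == 0L) return(empty)
  out <- purrr::map_dfr(seq_len(nrow(matches)), function(i) {
    m <- matches[i, ]
    seq <- proteins$sequence[match(m$protein_id, proteins$id)]
    L <- nchar(seq)
    lo <- max(1L, m$start - flank)
    hi <- min(L, m$end + flank)
    pos <- lo:hi
    aa <- substring(seq, pos, pos)
    keep <- aa %in% c("K", "C", "S", "T")
    if (!any(keep)) return(NULL)
    pos <- pos[keep]
    aa <- aa[keep]
    site_ctx <- function(p) {
      if (is.null(context)) {
        return(list(rsa = NA_real_, ss = "-", score = NA_real_, flankmean = NA_real_))
      }
      j <- match(p, context$position)
      wlo <- max(1L, p - site_window)
      whi <- min(L, p + site_window)
      widx <- which(context$position >= wlo & context$position <= whi)
      list(
        rsa = context$rsa[j],
        ss = context$ss[j],
        score = context$disorder_score[j],
        flankmean = mean(context$disorder_score[widx])
      )
    }
    ctxs <- purrr::map(pos, site_ctx)
    in_idr <- if (is.null(idrs) || nrow(idrs) == 0L) {
      rep(FALSE, length(pos))
    } else {
      vapply(pos, function(p) any(idrs$start <= p & p <= idrs$end), logical(1))
    }
    tibble::tibble(
      protein_id = m$protein_id,
      motif_id = m$motif_id,
      primary_start = m$start,
      primary_end = m$end,
      met_variant = m$met_variant,
      position = pos,
      residue = aa,
      rsa = vapply(ctxs, `[[`, numeric(1), "rsa"),
      ss = vapply(ctxs, `[[`, character(1), "ss"),
      in_idr = in_idr,
      mean_flank_disorder = vapply(ctxs, `[[`, numeric(1), "flankmean"),
      within_primary = pos >= m$start & pos <= m$end
    )
  })
  dplyr::bind_rows(empty, out)
}

# residue-interval distance: 0 inside, else distance to the nearer boundary
interval_distance <- function(p, s, e) {
  ifelse(s <= p & p <= e, 0L, pmin(abs(p - s), abs(p - e)))
}

#' Assign the nearest IDR (tertiary degron) to each secondary degron
#'
#' For each secondary site, reports the IDR minimizing residue distance
#' (0 when the site lies inside one); ties are broken toward the
#' N-terminal-most IDR. With no IDRs the assignment columns are `NA`.
#'
#' @param secondaries Tibble from [find_secondary_degrons()].
#' @param idrs IDR tibble from [segment_idrs()], sorted by `start`.
#' @return `secondaries` with added columns `idr_start`, `idr_end`,
#'   `idr_distance` — exactly one assignment per secondary row.
#' @export
assign_tertiary <- function(secondaries, idrs) {
  stopifnot(is.data.frame(secondaries))
  if (nrow(secondaries) == 0L) {
    secondaries$idr_start <- integer()
    secondaries$idr_end <- integer()
    secondaries$idr_distance <- integer()
    return(secondaries)
  }
  if (is.null(idrs) || nrow(idrs) == 0L) {
    secondaries$idr_start <- NA_integer_
    secondaries$idr_end <- NA_integer_
    secondaries$idr_distance <- NA_integer_
    return(secondaries)
  }
  idrs <- dplyr::arrange(idrs, .data$start)
  assign_one <- function(p) {
    d <- interval_distance(p, idrs$start, idrs$end)
    k <- which.min(d) # ties resolve to the first (N-terminal) IDR
    c(idrs$start[k], idrs$end[k], d[k])
  }
  res <- t(vapply(secondaries$position, assign_one, numeric(3)))
  secondaries$idr_start <- as.integer(res[, 1])
  secondaries$idr_end <- as.integer(res[, 2])
  secondaries$idr_distance <- as.integer(res[, 3])
  secondaries
}

validate_annotation_table <- function(df, required, what, proteins = NULL) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(what, " table lacks column(s): ", paste(missing, collapse = ", "))
  }
  df <- tibble::as_tibble(df)
  df$position <- suppressWarnings(as.integer(df$position))
  bad <- is.na(df$position) | df$position < 1L
  if (!is.null(proteins)) {
    len <- nchar(proteins$sequence)[match(df$protein_id, proteins$id)]
    bad <- bad | (!is.na(len) & df$position > len)
  }
  if (any(bad)) {
    warning(what, " row(s) ", paste(which(bad), collapse = ", "),
      " rejected: position missing or out of range")
    df <- df[!bad, , drop = FALSE]
  }
  df
}

#' Load PTM, mutation and E3-interactor annotation tables
#'
#' Schema-compatible TSV loaders for user-supplied annotation tables
#' (tab-separated, header row):
#'
#' * PTMs: `protein_id`, `position`, `ptm_type`, `source`
#' * missense mutations: `protein_id`, `position`, `ref`, `alt`, `source`
#' * E3 interactors: `protein_id`, `e3_id`, `source`
#'
#' Malformed rows (missing or out-of-range positions, checked against
#' `proteins` when given) are rejected with a warning naming the rows.
#'
#' @param path TSV file path.
#' @param proteins Optional protein tibble for length validation.
#' @return A tibble with the validated rows.
#' @export
load_ptms <- function(path, proteins = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, quote = "")
  validate_annotation_table(df, c("protein_id", "position", "ptm_type", "source"),
    "PTM", proteins)
}

#' @rdname load_ptms
#' @export
load_mutations <- function(path, proteins = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, quote = "")
  validate_annotation_table(df, c("protein_id", "position", "ref", "alt", "source"),
    "mutation", proteins)
}

#' @rdname load_ptms
#' @export
load_e3_interactors <- function(path, proteins = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, quote = "")
  missing <- setdiff(c("protein_id", "e3_id", "source"), names(df))
  if (length(missing) > 0L) {
    stop("E3 interactor table lacks column(s): ", paste(missing, collapse = ", "))
  }
  tibble::as_tibble(df)
}

#' Assemble tripartite degron reports
#'
#' For every primary degron match, assembles the full tripartite report:
#' motif-level structural summary (mean RSA, mean disorder, fraction of motif
#' residues inside an IDR), secondary degrons with their context, and the
#' nearest-IDR tertiary assignment per secondary site.
#'
#' @inheritParams find_secondary_degrons
#' @return An object of class `tripartite_report`: list with `primary`
#'   (matches plus summary columns `mean_rsa`, `mean_disorder`,
#'   `frac_in_idr`), `secondaries` (tibble including tertiary columns) and
#'   `params`.
#' @export
tripartite_report <- function(matches, proteins, context = NULL, idrs = NULL,
                              flank = 15L, site_window = 5L) {
  primary <- matches
  if (nrow(primary) > 0L) {
    summarise_match <- function(i) {
      m <- primary[i, ]
      if (is.null(context)) {
        return(c(NA_real_, NA_real_, NA_real_))
      }
      idx <- which(context$position >= m$start & context$position <= m$end)
      fin <- if (is.null(idrs) || nrow(idrs) == 0L) 0 else {
        mean(vapply(context$position[idx],
          function(p) any(idrs$start <= p & p <= idrs$end), logical(1)))
      }
      c(mean(context$rsa[idx]), mean(context$disorder_score[idx]), fin)
    }
    s <- t(vapply(seq_len(nrow(primary)), summarise_match, numeric(3)))
    primary$mean_rsa <- s[, 1]
    primary$mean_disorder <- s[, 2]
    primary$frac_in_idr <- s[, 3]
  } else {
    primary$mean_rsa <- numeric()
    primary$mean_disorder <- numeric()
    primary$frac_in_idr <- numeric()
  }
  secondaries <- find_secondary_degrons(matches, proteins, context, idrs,
    flank = flank, site_window = site_window)
  secondaries <- assign_tertiary(secondaries, idrs)
  structure(
    list(
      primary = primary,
      secondaries = secondaries,
      params = list(flank = flank, site_window = site_window)
    ),
    class = "tripartite_report"
  )
}

#' @export
print.tripartite_report <- function(x, ...) {
  cat("<tripartite_report>", nrow(x$primary), "primary match(es),",
    nrow(x$secondaries), "secondary degron site(s)\n")
  invisible(x)
}

#' Overlay PTM and mutation annotations on a tripartite report
#'
#' Pure decoration: attaches experimentally validated PTMs to any position
#' within each primary motif or its flanks, and missense mutations within the
#' motif itself plus at PTM-bearing flank positions. Nothing computed
#' upstream is altered.
#'
#' @param report A `tripartite_report`.
#' @param ptms PTM tibble ([load_ptms()] schema); may be `NULL`.
#' @param mutations Mutation tibble ([load_mutations()] schema); may be
#'   `NULL`.
#' @param flank Flank size (use the same value as the report).
#' @return The report with added tibbles `ptms` and `mutations`, each row
#'   linked to a primary match by `motif_id`/`primary_start`.
#' @export
overlay_annotations <- function(report, ptms = NULL, mutations = NULL, flank = 15L) {
  stopifnot(inherits(report, "tripartite_report"))
  empty_ptm <- tibble::tibble(
    protein_id = character(), motif_id = character(), primary_start = integer(),
    position = integer(), ptm_type = character(), source = character(),
    within_primary = logical()
  )
  empty_mut <- tibble::tibble(
    protein_id = character(), motif_id = character(), primary_start = integer(),
    position = integer(), ref = character(), alt = character(), source = character(),
    at_flank_ptm = logical()
  )
  prim <- report$primary
  ptm_rows <- empty_ptm
  mut_rows <- empty_mut
  if (nrow(prim) > 0L && !is.null(ptms) && nrow(ptms) > 0L) {
    ptm_rows <- purrr::map_dfr(seq_len(nrow(prim)), function(i) {
      m <- prim[i, ]
      hit <- ptms$protein_id == m$protein_id &
        ptms$position >= m$start - flank & ptms$position <= m$end + flank
      if (!any(hit)) return(NULL)
      tibble::tibble(
        protein_id = m$protein_id, motif_id = m$motif_id, primary_start = m$start,
        position = ptms$position[hit], ptm_type = ptms$ptm_type[hit],
        source = ptms$source[hit],
        within_primary = ptms$position[hit] >= m$start & ptms$position[hit] <= m$end
      )
    })
    if (nrow(ptm_rows) == 0L) ptm_rows <- empty_ptm
  }
  if (nrow(prim) > 0L && !is.null(mutations) && nrow(mutations) > 0L) {
    mut_rows <- purrr::map_dfr(seq_len(nrow(prim)), function(i) {
      m <- prim[i, ]
      in_motif <- mutations$protein_id == m$protein_id &
        mutations$position >= m$start & mutations$position <= m$end
      flank_ptm_pos <- ptm_rows$position[
        ptm_rows$motif_id == m$motif_id & ptm_rows$primary_start == m$start &
          !ptm_rows$within_primary
      ]
      at_ptm <- mutations$protein_id == m$protein_id &
        mutations$position %in% flank_ptm_pos
      hit <- in_motif | at_ptm
      if (!any(hit)) return(NULL)
      tibble::tibble(
        protein_id = m$protein_id, motif_id = m$motif_id, primary_start = m$start,
        position = mutations$position[hit], ref = mutations$ref[hit],
        alt = mutations$alt[hit], source = mutations$source[hit],
        at_flank_ptm = at_ptm[hit] & !in_motif[hit]
      )
    })
    if (nrow(mut_rows) == 0L) mut_rows <- empty_mut
  }
  report$ptms <- ptm_rows
  report$mutations <- mut_rows
  report
}
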