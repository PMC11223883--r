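#' Protease cleavage rules
#'
#' Rule-based cleavage prediction follows the PeptideCutter (Expasy)
#' specificity model: each enzyme's specificity is expressed as one or more
#' context patterns over the subsite window P4-P3-P2-P1 | P1'-P2' (the
#' scissile bond sits between P1 and P1'), plus optional exception patterns
#' that veto a cut. Positions beyond the sequence termini are padded with a
#' neutral out-of-sequence symbol that satisfies wildcards and negated
#' classes (the forbidden residue is certainly absent) but never a positive
#' requirement.
#'
#' Each subsite constraint uses the motif dialect's single-token forms:
#' `"x"` (no constraint), a literal letter, `"[KR]"`, `"[^P]"`.
#'
#' @name cleavage_rules
NULL

SUBSITES <- c("P4", "P3", "P2", "P1", "P1p", "P2p")

# clause helper: named subsite constraints, unnamed positions default to "x"
cl <- function(...) {
  spec <- c(...)
  out <- stats::setNames(rep("x", 6L), SUBSITES)
  out[names(spec)] <- spec
  out
}

# The 35-enzyme registry. Specificities follow the PeptideCutter
# documentation; the trypsin exception table is attached to trypsin as veto
# patterns.
BUILTIN_RULES <- list(
  list(enzyme = "Arg-C proteinase", sites = list(cl(P1 = "R"))),
  list(enzyme = "Asp-N endopeptidase", sites = list(cl(P1p = "D"))),
  list(enzyme = "BNPS-Skatole", sites = list(cl(P1 = "W"))),
  list(enzyme = "Caspase 1", sites = list(cl(P4 = "[FWYL]", P2 = "[HAT]", P1 = "D", P1p = "[^PEDQKR]"))),
  list(enzyme = "Caspase 2", sites = list(cl(P4 = "D", P3 = "V", P2 = "A", P1 = "D", P1p = "[^PEDQKR]"))),
  list(enzyme = "Caspase 3", sites = list(cl(P4 = "D", P3 = "M", P2 = "Q", P1 = "D", P1p = "[^PEDQKR]"))),
  list(enzyme = "Caspase 4", sites = list(cl(P4 = "L", P3 = "E", P2 = "V", P1 = "D", P1p = "[^PEDQKR]"))),
  list(enzyme = "Caspase 5", sites = list(cl(P4 = "[LW]", P3 = "E", P2 = "H", P1 = "D"))),
  list(enzyme = "Caspase 6", sites = list(cl(P4 = "V", P3 = "E", P2 = "[HI]", P1 = "D", P1p = "[^PEDQKR]"))),
  list(enzyme = "Caspase 7", sites = list(cl(P4 = "D", P3 = "E", P2 = "V", P1 = "D", P1p = "[^PEDQKR]"))),
  list(enzyme = "Caspase 8", sites = list(cl(P4 = "[IL]", P3 = "E", P2 = "T", P1 = "D", P1p = "[^PEDQKR]"))),
  list(enzyme = "Caspase 9", sites = list(cl(P4 = "L", P3 = "E", P2 = "H", P1 = "D"))),
  list(enzyme = "Caspase 10", sites = list(cl(P4 = "I", P3 = "E", P2 = "A", P1 = "D"))),
  list(enzyme = "Chymotrypsin (high specificity)", sites = list(
    cl(P1 = "[FY]", P1p = "[^P]"), cl(P1 = "W", P1p = "[^MP]")
  )),
  list(enzyme = "Chymotrypsin (low specificity)", sites = list(
    cl(P1 = "[FLY]", P1p = "[^P]"), cl(P1 = "W", P1p = "[^MP]"),
    cl(P1 = "M", P1p = "[^PY]"), cl(P1 = "H", P1p = "[^DMPW]")
  )),
  list(enzyme = "Clostripain", sites = list(cl(P1 = "R"))),
  list(enzyme = "CNBr", sites = list(cl(P1 = "M"))),
  list(enzyme = "Enterokinase", sites = list(cl(P4 = "[DE]", P3 = "[DE]", P2 = "[DE]", P1 = "K"))),
  list(enzyme = "Factor Xa", sites = list(cl(P4 = "[AFGILTVM]", P3 = "[DE]", P2 = "G", P1 = "R"))),
  list(enzyme = "Formic acid", sites = list(cl(P1 = "D"))),
  list(enzyme = "Glutamyl endopeptidase", sites = list(cl(P1 = "E"))),
  list(enzyme = "Granzyme B", sites = list(cl(P4 = "I", P3 = "E", P2 = "P", P1 = "D"))),
  list(enzyme = "Hydroxylamine", sites = list(cl(P1 = "N", P1p = "G"))),
  list(enzyme = "Iodosobenzoic acid", sites = list(cl(P1 = "W"))),
  list(enzyme = "LysC", sites = list(cl(P1 = "K"))),
  list(enzyme = "Neutrophil elastase", sites = list(cl(P1 = "[AV]"))),
  list(enzyme = "NTCB", sites = list(cl(P1p = "C"))),
  list(enzyme = "Pepsin (pH 1.3)", sites = list(
    cl(P3 = "[^HKR]", P2 = "[^P]", P1 = "[^R]", P1p = "[FL]", P2p = "[^P]"),
    cl(P3 = "[^HKR]", P2 = "[^P]", P1 = "[FL]", P2p = "[^P]")
  )),
  list(enzyme = "Pepsin (pH > 2)", sites = list(
    cl(P3 = "[^HKR]", P2 = "[^P]", P1 = "[^R]", P1p = "[FLWY]", P2p = "[^P]"),
    cl(P3 = "[^HKR]", P2 = "[^P]", P1 = "[FLWY]", P2p = "[^P]")
  )),
  list(enzyme = "Proline endopeptidase", sites = list(cl(P2 = "[HKR]", P1 = "P", P1p = "[^P]"))),
  list(enzyme = "Proteinase K", sites = list(cl(P1 = "[AEFILTVWY]"))),
  list(enzyme = "Staphylococcal peptidase I", sites = list(cl(P2 = "[^E]", P1 = "E"))),
  list(enzyme = "Thermolysin", sites = list(cl(P1 = "[^DE]", P1p = "[AFILMV]", P2p = "[^P]"))),
  list(enzyme = "Thrombin", sites = list(
    cl(P2 = "G", P1 = "R", P1p = "G"),
    cl(P4 = "[AFGILTVM]", P3 = "[AFGILTVW]", P2 = "P", P1 = "R", P1p = "[^DE]", P2p = "[^DE]")
  )),
  list(enzyme = "Trypsin",
    sites = list(
      cl(P1 = "[KR]", P1p = "[^P]"),
      cl(P2 = "W", P1 = "K", P1p = "P"),
      cl(P2 = "M", P1 = "R", P1p = "P")
    ),
    exceptions = list(
      cl(P2 = "[CD]", P1 = "K", P1p = "D"),
      cl(P2 = "C", P1 = "K", P1p = "[HY]"),
      cl(P2 = "C", P1 = "R", P1p = "K"),
      cl(P2 = "R", P1 = "R", P1p = "[HR]")
    )
  )
)

new_cleavage_rule <- function(spec) {
  structure(
    list(
      enzyme = spec$enzyme,
      sites = spec$sites,
      exceptions = spec$exceptions %||% list()
    ),
    class = "cleavage_rule"
  )
}

#' @export
print.cleavage_rule <- function(x, ...) {
  cat("<cleavage_rule>", x$enzyme, "-", length(x$sites), "site pattern(s),",
    length(x$exceptions), "exception(s)\n")
  invisible(x)
}

#' Built-in protease rule registry
#'
#' Returns the registry of the 35 built-in proteolytic enzymes with
#' PeptideCutter-compatible specificities (see [cleavage_rules]).
#'
#' @return Tibble with columns `enzyme`, `n_site_patterns`, `n_exceptions`.
#' @seealso [cleavage_rule()] to fetch one enzyme's rule object.
#' @export
builtin_rules <- function() {
  tibble::tibble(
    enzyme = vapply(BUILTIN_RULES, `[[`, character(1), "enzyme"),
    n_site_patterns = vapply(BUILTIN_RULES, function(r) length(r$sites), integer(1)),
    n_exceptions = vapply(BUILTIN_RULES, function(r) length(r$exceptions %||% list()), integer(1))
  )
}

#' Fetch one protease rule by name
#'
#' @param enzyme Enzyme name (case-insensitive exact match against
#'   [builtin_rules()]).
#' @return A `cleavage_rule` object.
#' @export
cleavage_rule <- function(enzyme) {
  idx <- match(tolower(enzyme), tolower(vapply(BUILTIN_RULES, `[[`, character(1), "enzyme")))
  if (is.na(idx)) {
    stop("unknown_enzyme: '", enzyme, "' is not in the built-in registry; see builtin_rules()")
  }
  new_cleavage_rule(BUILTIN_RULES[[idx]])
}

# translate one subsite constraint into a PCRE fragment over the padded
# sequence; '#' is the neutral pad symbol
subsite_regex <- function(constraint) {
  if (constraint == "x") return("[A-Z#]")
  if (grepl("^\\[\\^", constraint)) {
    inner <- sub("^\\[\\^(.*)\\]$", "\\1", constraint)
    return(paste0("[^", inner, "]")) # pad '#' passes: forbidden residue absent
  }
  constraint # literal or positive class: pad can never satisfy it
}

clause_regex <- function(clause) {
  paste(vapply(unname(clause), subsite_regex, character(1)), collapse = "")
}

# all bond positions where a clause list matches; bond p cuts between p and p+1
match_clauses <- function(sequence, clauses) {
  L <- nchar(sequence)
  if (L < 2L) return(integer())
  padded <- paste0("###", sequence, "##")
  hits <- integer()
  for (clause in clauses) {
    regex <- paste0("(?=", clause_regex(clause), ")")
    m <- gregexpr(regex, padded, perl = TRUE)[[1]]
    if (m[1] != -1L) hits <- c(hits, as.integer(m) + 3L - 3L) # padded P4 index == bond
  }
  hits <- sort(unique(hits))
  hits[hits >= 1L & hits <= L - 1L]
}

apply_rule <- function(sequence, rule) {
  cut <- match_clauses(sequence, rule$sites)
  veto <- match_clauses(sequence, rule$exceptions)
  setdiff(cut, veto)
}

#' Find proteolytic cleavage sites
#'
#' Identifies cleavage events on a protein from exactly one of four sources:
#'
#' * `enzyme` — a built-in protease rule name (or a `cleavage_rule` object),
#'   applied at every bond with exception patterns removed;
#' * `motif` — a user cleavage motif in the pattern dialect; the bond
#'   C-terminal to each motif occurrence is cut (shift with `cut_offset`,
#'   relative to the motif end);
#' * `positions` — explicit bond positions (an event at `p` cuts between
#'   residues `p` and `p + 1`);
#' * `sites_table` — rows from a site table ([load_cleavage_sites()]).
#'
#' @param protein One-row protein tibble.
#' @param enzyme,motif,positions,sites_table Exactly one must be supplied.
#' @param cut_offset For motif mode: offset of the cut bond from the motif's
#'   last residue (0 = cut immediately after the motif).
#' @return Tibble of sorted unique events: `protein_id`, `position`,
#'   `source` (`"rule"`, `"user_motif"`, `"user_site"`, `"site_table"`),
#'   `enzyme`.
#' @examples
#' p <- tibble::tibble(id = "toy", sequence = "AKRPGKA")
#' find_cleavage_sites(p, enzyme = "Trypsin")
#' @export
find_cleavage_sites <- function(protein, enzyme = NULL, motif = NULL,
                                positions = NULL, sites_table = NULL,
                                cut_offset = 0L) {
  stopifnot(is.data.frame(protein), nrow(protein) == 1L)
  supplied <- !c(is.null(enzyme), is.null(motif), is.null(positions), is.null(sites_table))
  if (sum(supplied) != 1L) {
    stop("supply exactly one of enzyme, motif, positions, sites_table")
  }
  seq <- protein$sequence
  L <- nchar(seq)
  if (!is.null(enzyme)) {
    rule <- if (inherits(enzyme, "cleavage_rule")) enzyme else cleavage_rule(enzyme)
    pos <- apply_rule(seq, rule)
    out <- tibble::tibble(position = pos, source = "rule", enzyme = rule$enzyme)
  } else if (!is.null(motif)) {
    matcher <- if (inherits(motif, "degron_matcher")) motif else compile_pattern(motif)
    hits <- match_pattern(matcher, seq)
    pos <- unique(hits$end + cut_offset)
    pos <- pos[pos >= 1L & pos <= L - 1L]
    if (length(pos) == 0L) {
      stop("cleavage motif '", matcher$pattern, "' marks no bond on protein ", protein$id)
    }
    out <- tibble::tibble(position = sort(pos), source = "user_motif", enzyme = NA_character_)
  } else if (!is.null(positions)) {
    positions <- as.integer(positions)
    if (any(positions < 1L | positions > L - 1L)) {
      stop("cleavage position(s) out of range 1..", L - 1L, ": ",
        paste(positions[positions < 1L | positions > L - 1L], collapse = ", "))
    }
    out <- tibble::tibble(position = sort(unique(positions)), source = "user_site",
      enzyme = NA_character_)
  } else {
    st <- sites_table[sites_table$protein_id == protein$id, , drop = FALSE]
    pos <- as.integer(st$position)
    keep <- !is.na(pos) & pos >= 1L & pos <= L - 1L
    if (any(!keep)) {
      warning("site-table row(s) with out-of-range position dropped for ", protein$id)
    }
    out <- tibble::tibble(
      position = pos[keep],
      source = "site_table",
      enzyme = if ("enzyme" %in% names(st)) as.character(st$enzyme)[keep] else NA_character_
    )
    out <- dplyr::arrange(dplyr::distinct(out), .data$position)
  }
  dplyr::bind_cols(tibble::tibble(protein_id = protein$id), out)
}

#' Load an experimental cleavage-site table
#'
#' TSV schema: `protein_id`, `position`, `enzyme`, `physiological` (logical),
#' `source`. Rows with `physiological = FALSE` are skipped by default so only
#' physiologically relevant sites enter the simulation.
#'
#' @param path TSV path.
#' @param physiological_only Keep only physiologically relevant rows
#'   (default `TRUE`).
#' @return Tibble of site rows.
#' @export
load_cleavage_sites <- function(path, physiological_only = TRUE) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, quote = "")
  required <- c("protein_id", "position", "enzyme", "physiological", "source")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("cleavage-site table lacks column(s): ", paste(missing, collapse = ", "))
  }
  df$physiological <- as.logical(df$physiological)
  if (physiological_only) df <- df[df$physiological %in% TRUE, , drop = FALSE]
  tibble::as_tibble(df)
}

#' Digest a protein at given cleavage events
#'
#' `full` mode cuts all bonds simultaneously, yielding `k + 1` fragments that
#' partition the parent; `single_site` mode treats each event independently
#' and returns the two fragments it would produce. An event at position `p`
#' cuts the bond between residues `p` and `p + 1`.
#'
#' @param protein One-row protein tibble.
#' @param events Cleavage event tibble from [find_cleavage_sites()] (or a
#'   bare integer vector of bond positions).
#' @param mode `"full"` or `"single_site"`.
#' @return Tibble of fragments: `parent_id`, `fragment_id`, `start`, `end`
#'   (1-based inclusive, parent coordinates), `sequence`, `neo_n`, `neo_c`,
#'   and (single-site mode) `event_position`.
#' @export
digest <- function(protein, events, mode = c("full", "single_site")) {
  stopifnot(is.data.frame(protein), nrow(protein) == 1L)
  mode <- match.arg(mode)
  pos <- if (is.data.frame(events)) events$position else as.integer(events)
  pos <- sort(unique(pos))
  seq <- protein$sequence
  L <- nchar(seq)
  if (any(pos < 1L | pos > L - 1L)) stop("event position out of range 1..", L - 1L)
  frag_tbl <- function(starts, ends, event = NA_integer_) {
    tibble::tibble(
      parent_id = protein$id,
      start = starts,
      end = ends,
      sequence = substring(seq, starts, ends),
      neo_n = starts > 1L,
      neo_c = ends < L,
      event_position = event
    )
  }
  out <- if (mode == "full") {
    starts <- c(1L, pos + 1L)
    ends <- c(pos, L)
    frag_tbl(starts, ends)
  } else {
    purrr::map_dfr(pos, function(p) frag_tbl(c(1L, p + 1L), c(p, L), event = p))
  }
  out$fragment_id <- paste0(protein$id, "_", out$start, "-", out$end)
  dplyr::relocate(out, "parent_id", "fragment_id")
}

#' Screen fragment neo-termini for degrons
#'
#' For each digestion fragment, screens only the *newly created* termini: a
#' neo-N terminus gets its Arg/N-end-rule class and an N-terminal motif scan
#' anchored at the fragment's first residue; a neo-C terminus gets a
#' C-terminal motif scan anchored at its last residue. Terminal Gravy is
#' computed for every fragment. Optionally, trained PSI models predict the
#' stability of the new terminal 23-mers.
#'
#' @param fragments Fragment tibble from [digest()].
#' @param motifs A `motif_set`.
#' @param gravy_window Terminal Gravy window (default 15; short fragments use
#'   all residues).
#' @param psi_models Optional named list of `psi_model` objects with elements
#'   `n` (applied to neo-N 23-mers) and/or `c` (neo-C 23-mers).
#' @return Tibble with one row per fragment: fragment coordinates, neo flags,
#'   `neo_n_residue`, `neo_n_parent_pos`, `neo_n_class`, `n_gravy`,
#'   `c_gravy`, optional `psi_neo_n`/`psi_neo_c` (+ categories), and a
#'   list-column `matches` of degron hits at neo termini in fragment and
#'   parent coordinates.
#' @export
neo_degron_screen <- function(fragments, motifs, gravy_window = 15L, psi_models = NULL) {
  stopifnot(is.data.frame(fragments))
  purrr::map_dfr(seq_len(nrow(fragments)), function(i) {
    f <- fragments[i, ]
    fl <- nchar(f$sequence)
    frec <- tibble::tibble(id = f$fragment_id, sequence = f$sequence)
    # fragments are screened as-is: no initiator-Met maturation on a cut product
    hits <- scan_degrons(frec, motifs, met_variants = FALSE)
    keep <- rep(FALSE, nrow(hits))
    if (f$neo_n) keep <- keep | hits$terminus == "N"
    if (f$neo_c) keep <- keep | hits$terminus == "C"
    hits <- hits[keep, , drop = FALSE]
    if (nrow(hits) > 0L) {
      hits$parent_start <- hits$start + f$start - 1L
      hits$parent_end <- hits$end + f$start - 1L
    } else {
      hits$parent_start <- integer()
      hits$parent_end <- integer()
    }
    w <- min(gravy_window, fl)
    row <- tibble::tibble(
      parent_id = f$parent_id,
      fragment_id = f$fragment_id,
      start = f$start, end = f$end,
      neo_n = f$neo_n, neo_c = f$neo_c,
      neo_n_residue = ifelse(f$neo_n, substr(f$sequence, 1L, 1L), NA_character_),
      neo_n_parent_pos = ifelse(f$neo_n, f$start, NA_integer_),
      neo_n_class = ifelse(f$neo_n, n_end_rule_class(substr(f$sequence, 1L, 1L)), NA_character_),
      n_gravy = gravy(substr(f$sequence, 1L, w)),
      c_gravy = gravy(substr(f$sequence, fl - w + 1L, fl)),
      matches = list(hits)
    )
    if (!is.null(psi_models)) {
      if (f$neo_n && !is.null(psi_models$n) && fl >= 2L) {
        pep <- substr(f$sequence, 1L, min(23L, fl))
        pred <- predict_psi(psi_models$n, peptides = tibble::tibble(
          protein_id = f$fragment_id, peptide = pep
        ))
        row$psi_neo_n <- pred$psi
        row$psi_neo_n_category <- pred$category
      }
      if (f$neo_c && !is.null(psi_models$c) && fl >= 2L) {
        pep <- substr(f$sequence, max(1L, fl - 22L), fl)
        pred <- predict_psi(psi_models$c, peptides = tibble::tibble(
          protein_id = f$fragment_id, peptide = pep
        ))
        row$psi_neo_c <- pred$psi
        row$psi_neo_c_category <- pred$category
      }
    }
    row
  })
}
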