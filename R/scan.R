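#' Scan proteins for degron motifs
#'
#' Screens each protein — optionally both initiator-Met variants — for every
#' motif in a motif set, respecting location classes: N-terminal motifs are
#' tested only anchored at the active variant's first residue (widened with
#' `n_anchor_window`), C-terminal motifs only anchored at the last residue,
#' internal motifs at all positions. Overlapping and nested matches are all
#' reported; nothing is greedily suppressed, because downstream tripartite
#' analysis is per-match.
#'
#' All coordinates are reported in the full-length (as-given) frame; matches
#' found on the Met-cleaved variant carry `met_variant = "met_cleaved"` and
#' have variant positions shifted by +1.
#'
#' @param proteins Protein tibble (columns `id`, `sequence`; rows are scanned
#'   independently).
#' @param motifs A `motif_set` tibble ([load_motifs()], [builtin_motifs()]).
#' @param met_variants If `TRUE` (default) scan both the as-given and the
#'   Met-cleaved variant of each Met-initiated protein.
#' @param n_anchor_window Number of leading variant positions at which an
#'   N-terminal motif may be anchored (default 1).
#' @return Tibble with columns `protein_id`, `motif_id`, `start`, `end`,
#'   `matched_seq`, `location_class`, `pathway`, `met_variant`, `terminus`
#'   (`"N"`, `"C"` or `"none"`), deduplicated on
#'   (`protein_id`, `motif_id`, `start`, `end`, `met_variant`) and ordered by
#'   protein, start, then motif_id.
#' @examples
#' prot <- tibble::tibble(id = "p", sequence = "MKENAAPGG")
#' scan_degrons(prot, builtin_motifs())
#' @export
scan_degrons <- function(proteins, motifs, met_variants = TRUE, n_anchor_window = 1L) {
  stopifnot(is.data.frame(proteins), is.data.frame(motifs))
  variants <- if (met_variants) met_variants(proteins) else {
    v <- proteins
    v$met_variant <- "as_given"
    v$offset <- 0L
    v
  }
  matchers <- purrr::map(motifs$pattern, compile_pattern)

  out <- purrr::map_dfr(seq_len(nrow(variants)), function(vi) {
    vseq <- variants$sequence[vi]
    off <- variants$offset[vi]
    L <- nchar(vseq)
    purrr::map_dfr(seq_len(nrow(motifs)), function(mi) {
      loc <- motifs$location_class[mi]
      hits <- if (loc == "N_TERMINAL") {
        purrr::map_dfr(seq_len(min(n_anchor_window, L)), function(a) {
          h <- match_pattern(matchers[[mi]], substring(vseq, a), anchor = "start")
          if (nrow(h) > 0L) {
            h$start <- h$start + a - 1L
            h$end <- h$end + a - 1L
          }
          h
        })
      } else if (loc == "C_TERMINAL") {
        match_pattern(matchers[[mi]], vseq, anchor = "end")
      } else {
        match_pattern(matchers[[mi]], vseq, anchor = "none")
      }
      if (nrow(hits) == 0L) return(NULL)
      tibble::tibble(
        protein_id = variants$id[vi],
        motif_id = motifs$motif_id[mi],
        start = hits$start + off,
        end = hits$end + off,
        matched_seq = hits$matched_seq,
        location_class = loc,
        pathway = motifs$pathway[mi],
        met_variant = variants$met_variant[vi],
        terminus = switch(loc, N_TERMINAL = "N", C_TERMINAL = "C", "none")
      )
    })
  })
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      protein_id = character(), motif_id = character(), start = integer(),
      end = integer(), matched_seq = character(), location_class = character(),
      pathway = character(), met_variant = character(), terminus = character()
    ))
  }
  out |>
    dplyr::distinct(
      .data$protein_id, .data$motif_id, .data$start, .data$end, .data$met_variant,
      .keep_all = TRUE
    ) |>
    dplyr::arrange(.data$protein_id, .data$start, .data$motif_id)
}

#' Terminal hydropathy and N-end-rule summary
#'
#' Computes the Gravy hydropathy index of each protein's terminal residues
#' (default window 15; sequences shorter than the window use the whole
#' sequence) and the Arg/N-end-rule class of the N-terminal residue of each
#' initiator-Met variant. Terminal hydrophobicity matters because several
#' N-/C-degron E3 ligases recognize bulky hydrophobic termini.
#'
#' @param proteins Protein tibble.
#' @param window Terminal window length in residues (default 15).
#' @param met_variants If `TRUE`, summarise both Met variants.
#' @return Tibble with columns `protein_id`, `met_variant`, `n_gravy`,
#'   `c_gravy`, `window_used_n`, `window_used_c`, `n_terminal_residue`,
#'   `n_end_class`.
#' @export
terminal_gravy <- function(proteins, window = 15L, met_variants = TRUE) {
  stopifnot(is.data.frame(proteins), window >= 1L)
  variants <- if (met_variants) met_variants(proteins) else {
    v <- proteins
    v$met_variant <- "as_given"
    v$offset <- 0L
    v
  }
  purrr::map_dfr(seq_len(nrow(variants)), function(i) {
    seq <- variants$sequence[i]
    L <- nchar(seq)
    w <- min(window, L)
    tibble::tibble(
      protein_id = variants$id[i],
      met_variant = variants$met_variant[i],
      n_gravy = gravy(substr(seq, 1L, w)),
      c_gravy = gravy(substr(seq, L - w + 1L, L)),
      window_used_n = w,
      window_used_c = w,
      n_terminal_residue = substr(seq, 1L, 1L),
      n_end_class = n_end_rule_class(substr(seq, 1L, 1L))
    )
  })
}
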