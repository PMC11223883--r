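#' Synthetic SDE2-like ubiquitin-fold precursor
#'
#' A synthetic stand-in for a DUB-matured ubiquitin-fold precursor protein,
#' built for worked examples and tests: an N-terminal ubiquitin-like (UBL)
#' domain based on the human ubiquitin sequence, closed by a diglycine motif
#' at positions 76-77, followed by a destabilizing lysine at position 78 and
#' a synthetic C-domain. Deubiquitinase cleavage after the diglycine (bond
#' 77|78) releases a C-fragment whose neo-N-terminal lysine is an Arg/N
#' type-1 primary destabilizing residue — the architecture of precursor
#' proteins such as SDE2 that are matured by proteolysis and then cleared by
#' the N-degron pathway.
#'
#' The sequence is synthetic: only its UBL core is the real ubiquitin
#' sequence; the C-domain is designed (no internal diglycine, mixed
#' charge/hydropathy) and matches no natural protein.
#'
#' @return One-row protein tibble (`id = "SDE2_SYNTHETIC"`).
#' @export
synthetic_sde2_precursor <- function() {
  ubiquitin <- paste0(
    "MQIFVKTLTGKTITLEVEPSDTIENVKAKIQDKEGIPPDQQRLIFAGKQLEDGRTLSDYNIQKESTLHLVLRLRGG"
  )
  # UBL: ubiquitin 1-74 + "AGG" puts the domain-closing diglycine at 76-77
  ubl <- paste0(substr(ubiquitin, 1, 74), "AGG")
  # synthetic C-domain: neo-N lysine (parent position 78), then a designed
  # mixed segment with no glycine (hence no stray diglycine)
  cdom <- paste0(
    "KSPEMRALQESPTKRSLEDDEDSMSFRSPSKKQPLSEDEAMRVATEALQSME",
    "RPSSRAEDLVKSMDNPFVSRALEWAAKHQDES"
  )
  tibble::tibble(
    id = "SDE2_SYNTHETIC",
    description = "synthetic ubiquitin-fold precursor (UBL diglycine 76-77, K78)",
    sequence = paste0(ubl, cdom),
    origin = "fasta",
    met_variant = "as_given"
  )
}

#' Generate random synthetic proteins
#'
#' Uniform-random canonical sequences for property-based testing and
#' benchmarking. Reproducible under `seed`.
#'
#' @param n Number of proteins.
#' @param length_range Two-element integer range of sequence lengths.
#' @param seed RNG seed.
#' @param prefix Id prefix.
#' @return Protein tibble.
#' @export
synthesize_proteins <- function(n, length_range = c(30L, 120L), seed = 1L,
                                prefix = "synprot") {
  stopifnot(n >= 1L, length(length_range) == 2L)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
  tibble::tibble(
    id = sprintf("%s%04d", prefix, seq_len(n)),
    description = "synthetic random protein",
    sequence = vapply(lens, function(L) {
      paste(sample(AA_CANONICAL, L, replace = TRUE), collapse = "")
    }, character(1)),
    origin = "fasta",
    met_variant = "as_given"
  )
}
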