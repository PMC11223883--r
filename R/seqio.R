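#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly multi-record, wrapped or unwrapped) FASTA file into a
#' protein table. Sequences are upper-cased but not validated; run
#' [validate_query()] before analysis.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per entry, in file order, and columns
#'   `id` (first whitespace-delimited token of the header), `description`
#'   (remainder of the header), `sequence`, `origin` (`"fasta"`) and
#'   `met_variant` (`"as_given"`).
#' @seealso [write_fasta()], [met_variants()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aas <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("could not parse FASTA file '", path, "': ", conditionMessage(e))
  )
  if (length(aas) == 0L) stop("zero records in FASTA file: ", path)
  headers <- names(aas)
  seqs <- toupper(as.character(aas))
  if (any(nchar(seqs) == 0L)) {
    stop(
      "zero-length entry in FASTA file: ",
      paste(headers[nchar(seqs) == 0L], collapse = ", ")
    )
  }
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  tibble::tibble(
    id = unname(ids),
    description = unname(desc),
    sequence = unname(seqs),
    origin = "fasta",
    met_variant = "as_given"
  )
}

#' Write a protein table to FASTA
#'
#' @param proteins Protein tibble as returned by [read_fasta()] (columns `id`,
#'   `sequence`, optionally `description`).
#' @param path Output file path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  stopifnot(is.data.frame(proteins), all(c("id", "sequence") %in% names(proteins)))
  desc <- if ("description" %in% names(proteins)) proteins$description else rep("", nrow(proteins))
  lines <- unlist(purrr::map2(seq_len(nrow(proteins)), desc, function(i, d) {
    header <- paste0(">", proteins$id[i], if (nzchar(d)) paste0(" ", d) else "")
    seq <- proteins$sequence[i]
    starts <- seq(1L, nchar(seq), by = width)
    c(header, substring(seq, starts, pmin(starts + width - 1L, nchar(seq))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein monomer structure from a PDB file
#'
#' Loads a single-model, single-chain PDB file into a structure model whose
#' per-residue table carries the B-factor column verbatim (interpretable as
#' pLDDT/LDDT when the file is a predicted model). The first conformer of any
#' alternate location is kept; HETATM records are ignored. Residue numbering
#' must be continuous starting from 1, the file must not exceed `max_bytes`,
#' and all residues must be standard amino acids.
#'
#' @param path Path to a PDB file.
#' @param max_bytes Maximum permitted file size (default 5 MB).
#' @return An object of class `structure_model`: a list with `record` (a
#'   one-row protein tibble with `origin = "pdb"`), `residues` (tibble with
#'   `position`, `aa`, `b_factor`) and `atoms` (tibble with `position`,
#'   `name`, `x`, `y`, `z`).
#' @export
read_structure <- function(path, max_bytes = 5e6) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) > max_bytes) {
    stop("file_too_large: PDB file exceeds ", max_bytes, " bytes")
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("empty: no ATOM records in ", path)
  # bio3d returns only MODEL 1 coordinates in $atom but records extra models in xyz
  n_models <- tryCatch(nrow(pdb$xyz), error = function(e) 1L)
  if (!is.null(n_models) && !is.na(n_models) && n_models > 1L) {
    stop("multi_model: PDB file contains more than one model")
  }
  chains <- unique(atoms$chain)
  chains <- chains[!is.na(chains)]
  if (length(chains) > 1L) {
    stop("multi_chain: PDB file contains chains ", paste(chains, collapse = ", "))
  }
  # first conformer of any altloc
  keep_alt <- is.na(atoms$alt) | atoms$alt %in% c("", "A")
  atoms <- atoms[keep_alt, , drop = FALSE]
  res_no <- atoms$resno
  res_starts <- !duplicated(res_no)
  resno_seq <- res_no[res_starts]
  if (resno_seq[1] != 1L || any(diff(resno_seq) != 1L)) {
    stop("discontinuous_numbering: residue numbering must be continuous from 1")
  }
  aa3 <- atoms$resid[res_starts]
  aa1 <- suppressWarnings(bio3d::aa321(aa3))
  if (any(is.na(aa1) | aa1 == "X" | !aa1 %in% AA_CANONICAL)) {
    stop(
      "non_protein: non-standard residue(s): ",
      paste(unique(aa3[is.na(aa1) | !aa1 %in% AA_CANONICAL]), collapse = ", ")
    )
  }
  residues <- tibble::tibble(
    position = as.integer(resno_seq),
    aa = unname(aa1),
    b_factor = as.numeric(atoms$b[res_starts])
  )
  id <- sub("\\.pdb$", "", basename(path), ignore.case = TRUE)
  record <- tibble::tibble(
    id = id,
    description = "",
    sequence = paste(residues$aa, collapse = ""),
    origin = "pdb",
    met_variant = "as_given"
  )
  structure(
    list(
      record = record,
      residues = residues,
      atoms = tibble::tibble(
        position = as.integer(atoms$resno),
        name = atoms$elety,
        x = atoms$x, y = atoms$y, z = atoms$z
      )
    ),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat(
    "<structure_model> ", x$record$id, ": ", nrow(x$residues), " residues, ",
    nrow(x$atoms), " atoms\n",
    sep = ""
  )
  invisible(x)
}

#' Validate a query protein or structure
#'
#' Collects all applicable failures (not fail-fast): sequences must be
#' non-empty, consist of the 20 canonical residues, and be shorter than
#' `max_length` residues (strictly below the limit). Structure models are
#' additionally checked for residue/sequence consistency. The default limit
#' mirrors the 40 000-residue query cap.
#'
#' @param x A protein tibble (one or more rows) or a `structure_model`.
#' @param max_length Exclusive residue-count limit (default 40000).
#' @param allow_x If `TRUE`, the placeholder residue `X` is admitted (it never
#'   satisfies any motif character class downstream).
#' @return An object of class `degron_validation`: list with `ok` (logical)
#'   and `failures` (tibble with `id`, `code`, `message`).
#' @export
validate_query <- function(x, max_length = 40000L, allow_x = FALSE) {
  if (inherits(x, "structure_model")) {
    res <- validate_query(x$record, max_length = max_length, allow_x = allow_x)
    if (paste(x$residues$aa, collapse = "") != x$record$sequence) {
      res$failures <- dplyr::bind_rows(res$failures, tibble::tibble(
        id = x$record$id, code = "non_canonical",
        message = "residue letters disagree with record sequence"
      ))
      res$ok <- FALSE
    }
    return(res)
  }
  stopifnot(is.data.frame(x), all(c("id", "sequence") %in% names(x)))
  alphabet <- if (allow_x) c(AA_CANONICAL, "X") else AA_CANONICAL
  failures <- purrr::map_dfr(seq_len(nrow(x)), function(i) {
    seq <- x$sequence[i]
    id <- x$id[i]
    out <- list()
    if (nchar(seq) == 0L) {
      out <- c(out, list(tibble::tibble(id = id, code = "empty", message = "empty sequence")))
    }
    if (nchar(seq) >= max_length) {
      out <- c(out, list(tibble::tibble(
        id = id, code = "too_long",
        message = sprintf("length %d is not below the %d-residue limit", nchar(seq), max_length)
      )))
    }
    letters_seen <- unique(strsplit(seq, "")[[1]])
    bad <- setdiff(letters_seen, alphabet)
    if (length(bad) > 0L) {
      out <- c(out, list(tibble::tibble(
        id = id, code = "non_canonical",
        message = paste0("non-canonical residue(s): ", paste(bad, collapse = ", "))
      )))
    }
    dplyr::bind_rows(out)
  })
  if (nrow(failures) == 0L) {
    failures <- tibble::tibble(id = character(), code = character(), message = character())
  }
  structure(list(ok = nrow(failures) == 0L, failures = failures), class = "degron_validation")
}

#' @export
print.degron_validation <- function(x, ...) {
  if (x$ok) {
    cat("<degron_validation> ok\n")
  } else {
    cat("<degron_validation>", nrow(x$failures), "failure(s):\n")
    print(x$failures)
  }
  invisible(x)
}

#' Expand a protein table into initiator-methionine variants
#'
#' Proteins whose sequence starts with methionine are commonly matured by
#' Met-aminopeptidase cleavage, which changes the exposed N-terminus. For each
#' input row this returns the protein as given plus, when the sequence starts
#' with M and has at least two residues, a `met_cleaved` variant with the
#' initiator Met removed. The `offset` column maps variant-local positions to
#' full-length coordinates (`full = local + offset`).
#'
#' @param proteins Protein tibble (columns `id`, `sequence`, ...).
#' @return Tibble with one or two rows per input protein and columns of the
#'   input plus `met_variant` (`"as_given"` or `"met_cleaved"`) and `offset`
#'   (0 or 1).
#' @export
met_variants <- function(proteins) {
  stopifnot(is.data.frame(proteins), all(c("id", "sequence") %in% names(proteins)))
  purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    row <- proteins[i, , drop = FALSE]
    row$met_variant <- "as_given"
    row$offset <- 0L
    seq <- row$sequence
    if (startsWith(seq, "M") && nchar(seq) >= 2L) {
      cleaved <- row
      cleaved$sequence <- substring(seq, 2L)
      cleaved$met_variant <- "met_cleaved"
      cleaved$offset <- 1L
      dplyr::bind_rows(row, cleaved)
    } else {
      row
    }
  })
}

#' Fetch a protein sequence by UniProt accession
#'
#' Network access is off by default: the package is offline-first and all
#' analyses run from user-supplied files. Set `online = TRUE` to perform a
#' single HTTPS fetch of the canonical sequence.
#'
#' @param accession UniProt accession (e.g. `"Q6IQ49"`).
#' @param online Must be `TRUE` to allow the network fetch.
#' @return Protein tibble with `origin = "accession"`.
#' @export
fetch_uniprot <- function(accession, online = FALSE) {
  if (!isTRUE(online)) {
    stop(
      "fetch_uniprot() requires online = TRUE; in offline use supply the ",
      "sequence as FASTA instead"
    )
  }
  url <- paste0("https://rest.uniprot.org/uniprotkb/", accession, ".fasta")
  tmp <- tempfile(fileext = ".fasta")
  utils::download.file(url, tmp, quiet = TRUE)
  on.exit(unlink(tmp))
  out <- read_fasta(tmp)
  out$origin <- "accession"
  out$id <- accession
  out
}
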