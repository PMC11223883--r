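#' Default run configuration
#'
#' All customizable parameters with their defaults: query length limit 40000
#' residues (exclusive), pLDDT disorder threshold 70 (disordered below),
#' sequence-mode disorder threshold 0.5 (disordered above), minimum IDR
#' length 10, terminal Gravy window 15, tripartite flank 15 with site window
#' 5, conservation flank 5 columns, terminal peptide length 23, PSI training
#' split 90:10 with 5-fold cross-validation and 20/40/60/80th-percentile
#' stability categories.
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    max_length = 40000L,
    allow_x = FALSE,
    plddt_threshold = 70,
    sequence_disorder_threshold = 0.5,
    idr_min_len = 10L,
    gravy_window = 15L,
    n_anchor_window = 1L,
    met_variants = TRUE,
    tripartite_flank = 15L,
    site_window = 5L,
    conservation_flank = 5L,
    terminal_peptide_length = 23L,
    psi_split = 0.9,
    psi_cv_folds = 5L,
    psi_category_quantiles = c(0.2, 0.4, 0.6, 0.8),
    seed = 42L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "run_config")
}

#' Run the full degron analysis workflow
#'
#' Orchestrates the per-protein workflow: motif scan on both Met variants,
#' terminal Gravy and N-end-rule summary, optional PSI prediction, optional
#' MSA conservation scoring, disorder/IDR calling (structure pLDDT mode for
#' PDB queries, sequence mode otherwise), tripartite assembly with optional
#' PTM/mutation overlay, and optional proteolysis simulation with neo-degron
#' screening. Stage failures are reported as warnings and independent stages
#' continue. The result is deterministic for fixed inputs and config.
#'
#' Structure-bearing queries include structural context (RSA/ss through the
#' adapter, pLDDT disorder); sequence-only queries use sequence-mode disorder
#' and omit ss/RSA.
#'
#' @param proteins Protein tibble (FASTA queries), or `NULL` when `structure`
#'   is given.
#' @param structure Optional `structure_model` (PDB query).
#' @param motifs Motif set (default [builtin_motifs()]).
#' @param config A [default_config()] list.
#' @param msa Optional `degron_msa` (see [map_to_msa()]) for conservation.
#' @param ptms,mutations,e3 Optional annotation tibbles.
#' @param cleavage Optional list passed to [find_cleavage_sites()] (e.g.
#'   `list(enzyme = "Trypsin")` or `list(positions = 77)`).
#' @param psi_models Optional named list of `psi_model`s (`n` and/or `c`)
#'   used for terminus PSI prediction and neo-termini screening.
#' @param ss_adapter Optional secondary-structure adapter function.
#' @return An object of class `report_bundle`: named list of tibbles
#'   (`proteins`, `matches`, `terminal`, `psi`, `conservation`, `context`,
#'   `idrs`, `tripartite_primary`, `tripartite_secondary`, `ptms`,
#'   `mutations`, `e3`, `fragments`, `neo_degrons`) plus `metadata`.
#' @export
run_pipeline <- function(proteins = NULL, structure = NULL, motifs = builtin_motifs(),
                         config = default_config(), msa = NULL, ptms = NULL,
                         mutations = NULL, e3 = NULL, cleavage = NULL,
                         psi_models = NULL, ss_adapter = NULL) {
  if (is.null(proteins) && is.null(structure)) stop("supply proteins and/or structure")
  if (is.null(proteins)) proteins <- structure$record
  val <- validate_query(proteins, max_length = config$max_length, allow_x = config$allow_x)
  if (!val$ok) {
    stop("query validation failed:\n", paste(
      paste0("  [", val$failures$code, "] ", val$failures$id, ": ", val$failures$message),
      collapse = "\n"
    ))
  }
  has_structure <- !is.null(structure)
  stage <- function(name, expr, empty) {
    tryCatch(expr, error = function(e) {
      warning("stage '", name, "' failed: ", conditionMessage(e))
      empty
    })
  }

  matches <- stage("scan",
    scan_degrons(proteins, motifs, met_variants = config$met_variants,
      n_anchor_window = config$n_anchor_window),
    tibble::tibble())
  terminal <- stage("terminal",
    terminal_gravy(proteins, window = config$gravy_window,
      met_variants = config$met_variants),
    tibble::tibble())

  empty_psi <- tibble::tibble(protein_id = character(), peptide = character(),
    terminus = character(), psi = numeric(), category = character())
  psi <- empty_psi
  if (!is.null(psi_models)) {
    psi <- stage("psi", {
      preds <- list()
      if (!is.null(psi_models$n)) preds$n <- predict_psi(psi_models$n, proteins = proteins)
      if (!is.null(psi_models$c)) preds$c <- predict_psi(psi_models$c, proteins = proteins)
      dplyr::bind_rows(preds)
    }, empty_psi)
  }

  empty_cons <- tibble::tibble(
    protein_id = character(), motif_id = character(), start = integer(),
    end = integer(), s1_presence = numeric(), s2_window_presence = numeric(),
    s3_column_identity = numeric(), s4_column_conservation = numeric(),
    n_rows_used = integer()
  )
  conservation <- empty_cons
  if (!is.null(msa)) {
    conservation <- stage("conservation", {
      prot_matches <- matches[matches$protein_id %in% proteins$id &
        matches$met_variant == "as_given", , drop = FALSE]
      score_conservation(prot_matches, msa, motifs, flank = config$conservation_flank)
    }, empty_cons)
  }

  context <- stage("context", {
    if (has_structure) {
      residue_context(structure, mode = "structure_plddt",
        threshold = config$plddt_threshold, adapter = ss_adapter)
    } else {
      purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
        ctx <- residue_context(proteins[i, ], mode = "sequence",
          threshold = config$sequence_disorder_threshold)
        dplyr::bind_cols(tibble::tibble(protein_id = proteins$id[i]), ctx)
      })
    }
  }, tibble::tibble())
  if (has_structure && nrow(context) > 0L && !"protein_id" %in% names(context)) {
    context <- dplyr::bind_cols(tibble::tibble(protein_id = proteins$id[1]), context)
  }

  idrs <- stage("idrs", {
    purrr::map_dfr(unique(context$protein_id), function(pid) {
      ctx <- context[context$protein_id == pid, , drop = FALSE]
      prof <- tibble::tibble(position = ctx$position, score = ctx$disorder_score,
        disordered = ctx$disordered)
      seg <- segment_idrs(prof, min_len = config$idr_min_len)
      if (nrow(seg) > 0L) dplyr::bind_cols(tibble::tibble(protein_id = pid), seg) else seg
    })
  }, tibble::tibble())

  trip <- stage("tripartite", {
    purrr::map(unique(proteins$id), function(pid) {
      m <- matches[matches$protein_id == pid, , drop = FALSE]
      ctx <- context[context$protein_id == pid, , drop = FALSE]
      pidr <- if (nrow(idrs) > 0L) idrs[idrs$protein_id == pid, , drop = FALSE] else idrs
      rep <- tripartite_report(m, proteins, context = if (nrow(ctx) > 0L) ctx else NULL,
        idrs = pidr, flank = config$tripartite_flank, site_window = config$site_window)
      overlay_annotations(rep, ptms = ptms, mutations = mutations,
        flank = config$tripartite_flank)
    })
  }, list())
  tri_primary <- dplyr::bind_rows(purrr::map(trip, "primary"))
  tri_secondary <- dplyr::bind_rows(purrr::map(trip, "secondaries"))
  tri_ptms <- dplyr::bind_rows(purrr::map(trip, "ptms"))
  tri_muts <- dplyr::bind_rows(purrr::map(trip, "mutations"))

  fragments <- tibble::tibble(
    parent_id = character(), fragment_id = character(), start = integer(),
    end = integer(), sequence = character(), neo_n = logical(), neo_c = logical(),
    event_position = integer()
  )
  neo <- tibble::tibble(
    parent_id = character(), fragment_id = character(), start = integer(),
    end = integer(), neo_n = logical(), neo_c = logical(),
    neo_n_residue = character(), neo_n_parent_pos = integer(),
    neo_n_class = character(), n_gravy = numeric(), c_gravy = numeric()
  )
  if (!is.null(cleavage)) {
    fragments <- stage("proteolysis", {
      purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
        args <- c(list(protein = proteins[i, ]), cleavage)
        events <- do.call(find_cleavage_sites, args)
        digest(proteins[i, ], events, mode = "full")
      })
    }, fragments)
    if (nrow(fragments) > 0L) {
      neo <- stage("neo_degrons",
        neo_degron_screen(fragments, motifs, gravy_window = config$gravy_window,
          psi_models = psi_models),
        neo)
    }
  }

  structure(
    list(
      proteins = proteins,
      matches = matches,
      terminal = terminal,
      psi = psi,
      conservation = conservation,
      context = context,
      idrs = idrs,
      tripartite_primary = tri_primary,
      tripartite_secondary = tri_secondary,
      ptms = tri_ptms,
      mutations = tri_muts,
      e3 = if (is.null(e3)) {
        tibble::tibble(protein_id = character(), e3_id = character(), source = character())
      } else {
        tibble::as_tibble(e3)
      },
      fragments = fragments,
      neo_degrons = neo,
      metadata = list(
        package_version = as.character(utils::packageVersion("degronkit")),
        config = unclass(config),
        query_type = if (has_structure) "pdb" else "fasta",
        n_motifs = nrow(motifs),
        motif_provenance = attr(motifs, "provenance") %||% "user",
        timestamp = NULL # kept NULL so identical inputs give identical bundles
      )
    ),
    class = "report_bundle"
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>", nrow(x$proteins), "protein(s)\n")
  for (nm in setdiff(names(x), c("metadata", "proteins"))) {
    if (is.data.frame(x[[nm]])) cat(sprintf("  %-22s %d row(s)\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

bundle_sections <- function(bundle) {
  names(bundle)[vapply(bundle, is.data.frame, logical(1))]
}

#' Export a report bundle
#'
#' `tsv_bundle` writes one TSV per section plus a `manifest.json` with the
#' run metadata; `json` writes a single JSON document. Empty sections are
#' written with a header row only. List-columns (nested match tables) are
#' serialized as JSON strings in TSV output.
#'
#' @param bundle A `report_bundle`.
#' @param out_dir Output directory (created if needed).
#' @param format `"tsv_bundle"` or `"json"`.
#' @return Character vector of files written, invisibly.
#' @export
export_report <- function(bundle, out_dir, format = c("tsv_bundle", "json")) {
  stopifnot(inherits(bundle, "report_bundle"))
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  flatten_listcols <- function(df) {
    for (nm in names(df)) {
      if (is.list(df[[nm]])) {
        df[[nm]] <- vapply(df[[nm]], function(el) {
          as.character(jsonlite::toJSON(el, digits = NA))
        }, character(1))
      }
    }
    df
  }
  if (format == "json") {
    path <- file.path(out_dir, "report.json")
    payload <- c(
      purrr::map(bundle[bundle_sections(bundle)], flatten_listcols),
      list(metadata = bundle$metadata)
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
      null = "null")
    return(invisible(path))
  }
  files <- character()
  for (nm in bundle_sections(bundle)) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(flatten_listcols(bundle[[nm]]), path, sep = "\t",
      quote = FALSE, row.names = FALSE, na = "NA")
    files <- c(files, path)
  }
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(sections = bundle_sections(bundle), metadata = bundle$metadata),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(c(files, manifest))
}

#' Re-read an exported TSV bundle
#'
#' @param dir Directory written by [export_report()] with
#'   `format = "tsv_bundle"`.
#' @return Named list of tibbles plus `metadata`.
#' @export
read_report_bundle <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  out <- purrr::map(manifest$sections, function(nm) {
    tibble::as_tibble(utils::read.delim(file.path(dir, paste0(nm, ".tsv")),
      sep = "\t", stringsAsFactors = FALSE, quote = ""))
  })
  names(out) <- manifest$sections
  out$metadata <- manifest$metadata
  out
}
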