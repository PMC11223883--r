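# Independent brute-force oracles and fixture builders for the test suite.
# The oracles deliberately avoid the package's matching machinery: patterns
# are interpreted token-by-token with plain set logic so agreement with the
# implementation is a real cross-check.

# ---- independent motif-dialect interpreter ----

# parse a dialect pattern into a list of (allowed-set | negated-set, min, max)
oracle_parse <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  toks <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- which(chars[-seq_len(i)] == "]")[1] + i
      body <- chars[(i + 1):(j - 1)]
      neg <- body[1] == "^"
      if (neg) body <- body[-1]
      toks[[length(toks) + 1]] <- list(set = body, neg = neg, min = 1L, max = 1L)
      i <- j + 1L
    } else if (ch == "x") {
      toks[[length(toks) + 1]] <- list(set = NULL, neg = FALSE, min = 1L, max = 1L)
      i <- i + 1L
    } else if (ch == "{") {
      j <- which(chars[-seq_len(i)] == "}")[1] + i
      body <- paste(chars[(i + 1):(j - 1)], collapse = "")
      parts <- as.integer(strsplit(body, ",")[[1]])
      k <- length(toks)
      toks[[k]]$min <- parts[1]
      toks[[k]]$max <- parts[length(parts)]
      i <- j + 1L
    } else {
      toks[[length(toks) + 1]] <- list(set = ch, neg = FALSE, min = 1L, max = 1L)
      i <- i + 1L
    }
  }
  toks
}

oracle_token_ok <- function(tok, ch) {
  if (!ch %in% LETTERS || ch == "X") return(FALSE) # gaps/X never match
  if (is.null(tok$set)) return(TRUE)
  if (tok$neg) !(ch %in% tok$set) else ch %in% tok$set
}

# recursively test whether tokens consume exactly the residue vector
oracle_consume <- function(toks, aa) {
  if (length(toks) == 0L) return(length(aa) == 0L)
  tok <- toks[[1]]
  for (reps in tok$min:tok$max) {
    if (reps > length(aa)) break
    if (reps == 0L || all(vapply(seq_len(reps), function(k) {
      oracle_token_ok(tok, aa[k])
    }, logical(1)))) {
      if (oracle_consume(toks[-1], aa[-seq_len(reps)])) return(TRUE)
    }
  }
  FALSE
}

# all (start, end) occurrences by testing every start and every length
oracle_match <- function(pattern, sequence) {
  toks <- oracle_parse(pattern)
  aa <- strsplit(sequence, "")[[1]]
  L <- length(aa)
  min_len <- sum(vapply(toks, `[[`, integer(1), "min"))
  max_len <- sum(vapply(toks, `[[`, integer(1), "max"))
  out <- NULL
  for (s in seq_len(L)) {
    for (len in min_len:min(max_len, L - s + 1L)) {
      if (len >= 1L && oracle_consume(toks, aa[s:(s + len - 1L)])) {
        out <- rbind(out, c(s, s + len - 1L))
      }
    }
  }
  if (is.null(out)) {
    tibble::tibble(start = integer(), end = integer())
  } else {
    tibble::tibble(start = as.integer(out[, 1]), end = as.integer(out[, 2]))
  }
}

# brute-force degron scan honouring location-class anchoring on one variant
oracle_scan_variant <- function(sequence, pattern, location_class) {
  hits <- oracle_match(pattern, sequence)
  L <- nchar(sequence)
  if (location_class == "N_TERMINAL") hits <- hits[hits$start == 1L, , drop = FALSE]
  if (location_class == "C_TERMINAL") hits <- hits[hits$end == L, , drop = FALSE]
  hits
}

# ---- independent protease-rule oracle: naive per-bond subsite check ----

oracle_subsite_ok <- function(constraint, ch) {
  # ch is NA beyond the termini: satisfies wildcards and negated classes only
  if (constraint == "x") return(TRUE)
  if (grepl("^\\[\\^", constraint)) {
    members <- strsplit(gsub("^\\[\\^|\\]$", "", constraint), "")[[1]]
    return(is.na(ch) || !(ch %in% members))
  }
  if (grepl("^\\[", constraint)) {
    members <- strsplit(gsub("^\\[|\\]$", "", constraint), "")[[1]]
    return(!is.na(ch) && ch %in% members)
  }
  !is.na(ch) && ch == constraint
}

oracle_clause_at <- function(clause, aa, p) {
  offsets <- c(-3L, -2L, -1L, 0L, 1L, 2L) # P4..P1, P1', P2' relative to bond residue p
  all(vapply(seq_along(offsets), function(k) {
    pos <- p + offsets[k]
    ch <- if (pos >= 1L && pos <= length(aa)) aa[pos] else NA_character_
    oracle_subsite_ok(clause[[k]], ch)
  }, logical(1)))
}

oracle_cleave <- function(sequence, rule) {
  aa <- strsplit(sequence, "")[[1]]
  L <- length(aa)
  if (L < 2L) return(integer())
  bonds <- seq_len(L - 1L)
  cut <- bonds[vapply(bonds, function(p) {
    any(vapply(rule$sites, oracle_clause_at, logical(1), aa = aa, p = p))
  }, logical(1))]
  veto <- bonds[vapply(bonds, function(p) {
    length(rule$exceptions) > 0L &&
      any(vapply(rule$exceptions, oracle_clause_at, logical(1), aa = aa, p = p))
  }, logical(1))]
  setdiff(cut, veto)
}

# ---- fixture builders ----

random_sequence <- function(L, alphabet = degronkit:::AA_CANONICAL) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

random_dialect_pattern <- function() {
  n_tok <- sample(1:4, 1)
  toks <- vapply(seq_len(n_tok), function(i) {
    kind <- sample(c("lit", "class", "nclass", "any"), 1,
      prob = c(0.4, 0.25, 0.15, 0.2))
    tok <- switch(kind,
      lit = sample(degronkit:::AA_CANONICAL, 1),
      class = paste0("[", paste(sample(degronkit:::AA_CANONICAL, sample(2:4, 1)),
        collapse = ""), "]"),
      nclass = paste0("[^", paste(sample(degronkit:::AA_CANONICAL, sample(1:3, 1)),
        collapse = ""), "]"),
      any = "x"
    )
    if (stats::runif(1) < 0.15) {
      m <- sample(1:2, 1)
      tok <- paste0(tok, "{", m, ",", m + sample(0:1, 1), "}")
    }
    tok
  }, character(1))
  paste(toks, collapse = "")
}

toy_motif_set <- function(patterns, classes) {
  degronkit:::validate_motif_table(tibble::tibble(
    motif_id = paste0("m", seq_along(patterns)),
    name = paste0("toy ", seq_along(patterns)),
    pattern = patterns,
    location_class = classes,
    pathway = "toy",
    source = "test fixture"
  ))
}

# minimal single-chain PDB text: one CA atom per residue
write_toy_pdb <- function(path, aa1, chain = "A", start = 1L, b = NULL,
                          extra_chain = NULL, n_models = 1L) {
  aa123 <- c(
    A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY", H = "HIS",
    I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN", P = "PRO", Q = "GLN",
    R = "ARG", S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR"
  )
  if (is.null(b)) b <- rep(90, length(aa1))
  atom_lines <- function(aa1, chain, start, b, serial0 = 0L) {
    vapply(seq_along(aa1), function(i) {
      sprintf(
        "ATOM  %5d  CA  %s %s%4d    %8.3f%8.3f%8.3f  1.00%6.2f           C",
        serial0 + i, aa123[aa1[i]], chain, start + i - 1L,
        i * 3.8, 0, 0, b[i]
      )
    }, character(1))
  }
  lines <- character()
  for (m in seq_len(n_models)) {
    if (n_models > 1L) lines <- c(lines, sprintf("MODEL     %4d", m))
    lines <- c(lines, atom_lines(aa1, chain, start, b))
    if (!is.null(extra_chain)) {
      lines <- c(lines, atom_lines(extra_chain$aa1, extra_chain$chain,
        extra_chain$start, rep(90, length(extra_chain$aa1)),
        serial0 = length(aa1)))
    }
    if (n_models > 1L) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

write_toy_msa_fasta <- function(path, rows) {
  writeLines(unlist(purrr::imap(rows, function(seq, id) c(paste0(">", id), seq))), path)
  path
}
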