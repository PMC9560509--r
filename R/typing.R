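AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

check_protein <- function(seq, what = "sequence") {
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% AA_LETTERS)
  if (length(bad) > 0) {
    abort(paste0("non-amino-acid character '", chars[bad[1]], "' at position ",
                 bad[1], " in ", what))
  }
  invisible(seq)
}

# Scoring for the global alignment: match +1, mismatch -1, affine gaps
# costing 5 for the first gapped residue and 1 per further residue
# (documented fixed scoring; adequate for >70%-identity inputs).
# Biostrings charges gapOpening + gapExtension * length, hence opening 4.
aa_identity_matrix <- function() {
  m <- matrix(-1, length(AA_LETTERS), length(AA_LETTERS),
              dimnames = list(AA_LETTERS, AA_LETTERS))
  diag(m) <- 1
  m
}

#' Map a query OmpA sequence onto the mature reference coordinates
#'
#' Performs a global pairwise alignment of the query against the mature
#' 325-residue reference (match +1, mismatch -1, affine gap cost 5 for a single-residue gap, +1 per further residue)
#' and returns, for every reference position, the corresponding query
#' position (or `NA` at deletions).  Precursor inputs (length >= 340 whose
#' first 21 residues resemble the signal peptide) are trimmed first and
#' flagged.  Sequences below the identity floor are rejected as not
#' OmpA-like, which is how inputs from genera outside the classification
#' system (e.g. Klebsiella, Yersinia) are kept out rather than force-binned.
#'
#' @param query Amino-acid string.
#' @param scheme An `ompa_scheme` (supplies the reference).
#' @param min_identity Identity floor in `[0, 1]`; queries below it error.
#' @return A tibble of class `position_map` with columns `ref_pos`,
#'   `query_pos` (NA at gaps) and attributes `trimmed` (logical),
#'   `identity` (percent).
#' @examples
#' sch <- load_scheme()
#' pm <- align_to_reference(sch$reference$mature, sch)
#' all(pm$ref_pos == pm$query_pos)
#' @export
align_to_reference <- function(query, scheme, min_identity = 0.70) {
  check_protein(query, "query")
  ref <- scheme$reference$mature
  trimmed <- FALSE
  signal <- scheme$reference$signal_peptide
  if (nchar(signal) > 0 && nchar(query) >= 340) {
    lead <- substr(query, 1, nchar(signal))
    ident <- mean(strsplit(lead, "")[[1]] == strsplit(signal, "")[[1]])
    if (ident >= 0.6) {
      query <- substr(query, nchar(signal) + 1, nchar(query))
      trimmed <- TRUE
    }
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query),
    subject = Biostrings::AAString(ref),
    type = "global",
    substitutionMatrix = aa_identity_matrix(),
    gapOpening = 4, gapExtension = 1
  )
  identity <- Biostrings::pid(aln)
  if (identity < 100 * min_identity) {
    abort(paste0("query is not OmpA-like: ", round(identity, 1),
                 "% identity to the reference (floor ",
                 100 * min_identity, "%)"))
  }
  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ref_pos <- cumsum(ra != "-")
  query_pos <- cumsum(qa != "-")
  keep <- ra != "-"
  map <- tibble::tibble(
    ref_pos = ref_pos[keep],
    query_pos = ifelse(qa[keep] == "-", NA_integer_, query_pos[keep])
  )
  structure(map, class = c("position_map", class(map)),
            trimmed = trimmed, identity = identity, query = query)
}

site_run_from_map <- function(query, map, start, end) {
  qp <- map$query_pos[map$ref_pos >= start & map$ref_pos <= end]
  qp <- qp[!is.na(qp)]
  if (length(qp) == 0) {
    return("gap")
  }
  # Span between the outermost mapped query positions, so insertions and
  # deletions inside the run are captured as a length change.
  substr(query, min(qp), max(qp))
}

#' Extract the residues observed at every classification site
#'
#' @param query Amino-acid string (mature or precursor).
#' @param scheme An `ompa_scheme`.
#' @param map Optional precomputed [align_to_reference()] result.
#' @param id Sequence identifier carried into the profile.
#' @return A tibble of class `variant_profile` with one row per scheme site:
#'   `site`, `kind`, `classifying`, `residues` (`"gap"` when the site is
#'   deleted in the query) and attribute `trimmed`.
#' @export
extract_variant_profile <- function(query, scheme, map = NULL, id = NA_character_) {
  if (is.null(map)) map <- align_to_reference(query, scheme)
  qseq <- attr(map, "query")
  sites <- scheme$sites
  prof <- tibble::tibble(
    id = id,
    site = sites$name,
    kind = sites$kind,
    classifying = sites$classifying,
    residues = vapply(seq_len(nrow(sites)), function(i) {
      site_run_from_map(qseq, map, sites$start[i], sites$end[i])
    }, character(1))
  )
  structure(prof, class = c("variant_profile", class(prof)),
            trimmed = attr(map, "trimmed"))
}

match_domain <- function(profile, patterns, site_names) {
  obs <- setNames(profile$residues, profile$site)[site_names]
  mism <- vapply(patterns, function(pat) {
    sum(vapply(site_names, function(s) {
      !identical(unname(obs[[s]]), pat[[s]])
    }, logical(1)))
  }, numeric(1))
  best <- min(mism)
  nearest <- names(mism)[mism == best]
  if (best == 0) {
    list(call = nearest[1], mismatches = 0L, nearest = nearest[1],
         ambiguous = FALSE)
  } else {
    list(call = "novel", mismatches = as.integer(best),
         nearest = nearest, ambiguous = length(nearest) >= 2)
  }
}

#' Assign (N-terminal, C-terminal) allele bins from a variant profile
#'
#' Each domain is called independently by exact match of the observed site
#' residues against the pattern definitions; loop runs of unequal length
#' count as one mismatch.  Without an exact match the domain is `"novel"`
#' and all nearest patterns (by site-mismatch count) are reported; ties set
#' the `ambiguous_tie` flag rather than silently picking one.
#'
#' @param profile A `variant_profile` from [extract_variant_profile()].
#' @param scheme An `ompa_scheme`.
#' @return A one-row tibble of class `allele_call`: `id`, `nterm`, `cterm`,
#'   `nterm_mismatches`, `cterm_mismatches`, `nterm_nearest`,
#'   `cterm_nearest` (comma-separated when tied) and `flags`.
#' @export
call_allele <- function(profile, scheme) {
  loop_sites <- scheme$sites$name[scheme$sites$kind == "loop" &
                                    scheme$sites$classifying]
  c_sites <- c("p175", "p203", "p251")
  missing <- setdiff(c(loop_sites, c_sites), profile$site)
  if (length(missing) > 0) {
    abort(paste0("profile is missing site(s): ", paste(missing, collapse = ", ")))
  }
  nt <- match_domain(profile, scheme$nterm_patterns, loop_sites)
  ct <- match_domain(profile, scheme$cterm_patterns, c_sites)
  flags <- c(
    if (isTRUE(attr(profile, "trimmed"))) "signal-peptide-trimmed",
    if (nt$ambiguous || ct$ambiguous) "ambiguous-tie"
  )
  out <- tibble::tibble(
    id = profile$id[1],
    nterm = nt$call, cterm = ct$call,
    nterm_mismatches = nt$mismatches, cterm_mismatches = ct$mismatches,
    nterm_nearest = paste(nt$nearest, collapse = ","),
    cterm_nearest = paste(ct$nearest, collapse = ","),
    flags = paste(flags, collapse = ";")
  )
  structure(out, class = c("allele_call", class(out)))
}

#' Type one protein sequence end to end
#'
#' Convenience wrapper: align, extract the variant profile, call the allele.
#'
#' @inheritParams align_to_reference
#' @param id Sequence identifier.
#' @return An `allele_call` tibble (one row).
#' @export
type_sequence <- function(query, scheme, id = NA_character_,
                          min_identity = 0.70) {
  map <- align_to_reference(query, scheme, min_identity = min_identity)
  prof <- extract_variant_profile(query, scheme, map = map, id = id)
  call_allele(prof, scheme)
}

#' Collapse N-terminal patterns onto the two-allele ompA1/ompA2 system
#'
#' The coarser historical system: `ompA1` covers outer-loop patterns I, IV
#' and VII; `ompA2` covers II and III.  Patterns V, VI and novel calls fall
#' outside both and return `"unmapped"`.
#'
#' @param nterm Character vector of N-terminal pattern ids (or an
#'   `allele_call`/typing tibble with an `nterm` column).
#' @return Character vector (or the input tibble with a `power_allele`
#'   column appended).
#' @examples
#' map_to_power_alleles(c("I", "III", "V"))
#' @export
map_to_power_alleles <- function(nterm) {
  if (is.data.frame(nterm)) {
    nterm$power_allele <- map_to_power_alleles(nterm$nterm)
    return(nterm)
  }
  dplyr::case_when(
    nterm %in% c("I", "IV", "VII") ~ "ompA1",
    nterm %in% c("II", "III") ~ "ompA2",
    TRUE ~ "unmapped"
  )
}

#' Type every record of a protein FASTA
#'
#' @param fasta Path to a multi-record protein FASTA file, or a named
#'   character vector of sequences.
#' @param scheme An `ompa_scheme`.
#' @param min_identity Identity floor passed to [align_to_reference()].
#' @return A tibble with one row per record, in input order: `id`, `nterm`,
#'   `cterm`, mismatch counts, nearest patterns and `flags`.  A record that
#'   fails (non-amino-acid characters, below the identity floor) yields a
#'   row with `NA` calls and the error message in `flags`; the run
#'   continues.  An empty input returns an empty tibble with a warning.
#' @export
batch_type <- function(fasta, scheme, min_identity = 0.70) {
  seqs <- if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta)) {
    ss <- Biostrings::readAAStringSet(fasta)
    setNames(as.character(ss), names(ss))
  } else {
    fasta
  }
  if (length(seqs) == 0) {
    warn("no sequences in input; returning empty typing table")
    return(tibble::tibble(
      id = character(0), nterm = character(0), cterm = character(0),
      nterm_mismatches = integer(0), cterm_mismatches = integer(0),
      nterm_nearest = character(0), cterm_nearest = character(0),
      flags = character(0)
    ))
  }
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    tryCatch(
      type_sequence(seqs[[i]], scheme, id = ids[i], min_identity = min_identity),
      error = function(e) {
        tibble::tibble(
          id = ids[i], nterm = NA_character_, cterm = NA_character_,
          nterm_mismatches = NA_integer_, cterm_mismatches = NA_integer_,
          nterm_nearest = NA_character_, cterm_nearest = NA_character_,
          flags = paste0("error:", conditionMessage(e))
        )
      }
    )
  })
  dplyr::bind_rows(rows)
}

#' Write allele calls as CSV
#'
#' Columns: `id,nterm,cterm,nterm_mismatches,cterm_mismatches,flags`.
#'
#' @param calls Typing tibble from [batch_type()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_allele_calls <- function(calls, path) {
  readr::write_csv(
    calls[, c("id", "nterm", "cterm", "nterm_mismatches",
              "cterm_mismatches", "flags")],
    path
  )
  invisible(path)
}
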