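#' Default side-chain pKa set
#'
#' A Protein-Calculator-style set stored as data and swappable: the tool the
#' published table was produced with is named but its constants are not, so
#' the set is a documented configuration, not a claim about that tool.
#'
#' @return A tibble with columns `group` (residue one-letter code, or
#'   `"Nterm"`/`"Cterm"`), `pka`, `polarity` (`"acidic"`/`"basic"`).
#' @export
default_pka_table <- function() {
  tibble::tibble(
    group    = c("D", "E", "C", "Y", "H", "K", "R", "Nterm", "Cterm"),
    pka      = c(4.05, 4.45, 9.0, 10.0, 5.98, 10.0, 12.0, 8.0, 3.1),
    polarity = c("acidic", "acidic", "acidic", "acidic",
                 "basic", "basic", "basic", "basic", "acidic")
  )
}

#' Kyte-Doolittle hydrophobicity scale
#'
#' @param mode Aggregation mode: `"mean"` (GRAVY-style, default) or `"sum"`.
#' @return A `hydro_scale` object: list with `values` (named numeric over
#'   the 20 residues), `mode`, `name`.
#' @export
kyte_doolittle_scale <- function(mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  vals <- c(
    A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
  )
  hydro_scale(vals, mode = mode, name = "Kyte-Doolittle")
}

#' Build a hydrophobicity scale
#'
#' @param values Named numeric vector covering all 20 residues.
#' @param mode `"mean"` or `"sum"`.
#' @param name Scale name for provenance.
#' @return A `hydro_scale` object.
#' @export
hydro_scale <- function(values, mode = c("mean", "sum"), name = "custom") {
  mode <- match.arg(mode)
  missing <- setdiff(AA_LETTERS, names(values))
  if (length(missing) > 0) {
    abort(paste0("scale is missing residue(s): ", paste(missing, collapse = ", ")))
  }
  structure(list(values = values, mode = mode, name = name),
            class = "hydro_scale")
}

#' Net charge of a peptide segment at a given pH
#'
#' Henderson-Hasselbalch partial charges:
#' `charge = sum_basic 1/(1+10^(pH-pKa)) - sum_acidic 1/(1+10^(pKa-pH))`.
#' Termini contribute only when `include_termini = TRUE`; internal segments
#' such as barrel loops carry no free termini, so the default is off.
#'
#' @param seq Amino-acid string (vectorized).
#' @param pH pH in (0, 14); default 8.0, the buffer condition of the
#'   zeta-potential measurements.
#' @param pka A pKa tibble as from [default_pka_table()].
#' @param include_termini Add the N-/C-terminal ionizable groups.
#' @return Net charge in elementary-charge units (numeric, one per `seq`).
#' @examples
#' segment_charge("DE", pH = 8)    # ~ -2
#' segment_charge("K", pH = 8)     # ~ +0.99
#' @export
segment_charge <- function(seq, pH = 8.0, pka = default_pka_table(),
                           include_termini = FALSE) {
  stopifnot(pH > 0, pH < 14)
  vapply(seq, function(s) {
    if (nchar(s) == 0) abort("empty sequence")
    check_protein(s, "segment")
    chars <- strsplit(s, "")[[1]]
    total <- 0
    for (i in seq_len(nrow(pka))) {
      g <- pka$group[i]
      n <- if (g %in% c("Nterm", "Cterm")) {
        if (include_termini) 1 else 0
      } else {
        sum(chars == g)
      }
      if (n == 0) next
      total <- total + n * if (pka$polarity[i] == "basic") {
        1 / (1 + 10^(pH - pka$pka[i]))
      } else {
        -1 / (1 + 10^(pka$pka[i] - pH))
      }
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' Hydrophobicity index of a peptide segment
#'
#' Aggregates per-residue scale values under the scale's mode (`mean` gives
#' the GRAVY-style index; `sum` is additive over concatenation).
#'
#' @param seq Amino-acid string (vectorized).
#' @param scale A `hydro_scale`; default Kyte-Doolittle, mean mode.
#' @return Numeric index, one per `seq`.
#' @export
segment_hydrophobicity <- function(seq, scale = kyte_doolittle_scale()) {
  vapply(seq, function(s) {
    if (nchar(s) == 0) abort("empty sequence")
    check_protein(s, "segment")
    v <- scale$values[strsplit(s, "")[[1]]]
    if (scale$mode == "mean") mean(v) else sum(v)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Per-allele, per-segment property table
#'
#' Reconstructs each allele's full sequence from the scheme, slices the
#' surface-exposed loop segments (coordinates shifted where loop-3 length
#' differs) and tabulates net charge at `pH` and hydrophobicity index, with
#' subtotal rows for the N-terminal loops (1-4), the C-terminal loops (5-8)
#' and all exposed loops.  Because the C-terminal classification sites lie
#' between, not inside, loops 5-8, the C-terminal loop rows are identical
#' across alleles.
#'
#' @param scheme An `ompa_scheme`.
#' @param alleles Tibble with `nterm`, `cterm` columns; defaults to the
#'   seven exemplar alleles.
#' @param pH pH for the charge calculation.
#' @param pka pKa set.
#' @param scale Hydrophobicity scale.
#' @return A tidy tibble: `allele`, `nterm`, `cterm`, `segment`, `charge`,
#'   `hydrophobicity`.  Subtotals appear as segments `sum_nterm_loops`,
#'   `sum_cterm_loops`, `sum_all_loops` (charges add; hydrophobicity
#'   subtotals add the per-loop indices, mirroring the published layout).
#' @export
tabulate_allele_properties <- function(scheme, alleles = exemplar_alleles(),
                                       pH = 8.0, pka = default_pka_table(),
                                       scale = kyte_doolittle_scale()) {
  loops <- scheme$segments[grepl("^loop", scheme$segments$name), ]
  nloops <- paste0("loop", 1:4)
  cloops <- paste0("loop", 5:8)
  rows <- purrr::pmap(alleles[, c("nterm", "cterm")], function(nterm, cterm) {
    rec <- reconstruct_allele_sequence(scheme, nterm, cterm)
    if (max(rec$coord(loops$end)) > nchar(rec$sequence)) {
      abort("segment outside sequence bounds")
    }
    per_loop <- tibble::tibble(
      allele = paste0("(", nterm, ",", cterm, ")"),
      nterm = nterm, cterm = cterm,
      segment = loops$name,
      seq = substr(rep(rec$sequence, nrow(loops)),
                   rec$coord(loops$start), rec$coord(loops$end))
    )
    per_loop$charge <- segment_charge(per_loop$seq, pH = pH, pka = pka)
    per_loop$hydrophobicity <- segment_hydrophobicity(per_loop$seq, scale = scale)
    subtot <- function(which_loops, label) {
      sel <- per_loop[per_loop$segment %in% which_loops, ]
      tibble::tibble(
        allele = per_loop$allele[1], nterm = nterm, cterm = cterm,
        segment = label, seq = NA_character_,
        charge = sum(sel$charge), hydrophobicity = sum(sel$hydrophobicity)
      )
    }
    dplyr::bind_rows(
      per_loop,
      subtot(nloops, "sum_nterm_loops"),
      subtot(cloops, "sum_cterm_loops"),
      subtot(loops$name, "sum_all_loops")
    )
  })
  dplyr::bind_rows(rows) %>% dplyr::select(-"seq")
}

#' Correlate predicted segment properties with measured phenotypes
#'
#' The published comparison: per-allele predicted loop-property sums against
#' per-allele measured means, judged by whether the 95% confidence interval
#' of the regression slope excludes zero.  Delegates to
#' [slope_ci_association()].
#'
#' @param predicted,measured Numeric vectors, one value per allele
#'   (>= 3 alleles).
#' @param conf Confidence level.
#' @return A one-row tibble: `slope`, `ci_lower`, `ci_upper`, `p_value`,
#'   `significant`.
#' @export
correlate_predictions_with_measurements <- function(predicted, measured,
                                                    conf = 0.95) {
  slope_ci_association(predicted, measured, conf = conf)
}

#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`
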