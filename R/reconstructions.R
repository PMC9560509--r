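#' Published cohort sizes
#'
#' The isolate-group sizes printed in the study: 78 environmental isolates,
#' 412 ExPEC sequences (APEC 171, UPEC 148, NMEC 80, plus 13 AIEC), 30
#' non-AIEC mucosal isolates, and the phylotype-restricted pool A 45,
#' B1 83, B2 229, F 43 (n = 400, of which 47 are environmental).
#'
#' @return A named list of named integer vectors: `source`, `expec_types`,
#'   `phylotypes`, plus `trimmed_pool_environmental` (scalar).
#' @export
published_cohorts <- function() {
  list(
    source = c(environmental = 78L, ExPEC = 412L),
    expec_types = c(APEC = 171L, UPEC = 148L, NMEC = 80L, AIEC = 13L),
    phylotypes = c(A = 45L, B1 = 83L, B2 = 229L, F = 43L),
    trimmed_pool_environmental = 47L
  )
}

#' Published allele totals in the trimmed phylotype pool
#'
#' Alleles kept after the lump-below-10 rule, with their printed n.  (The
#' printed table elsewhere lists `(III, alpha)` with n = 14 while the text
#' gives n = 36; the text value is used here and the discrepancy is
#' documented rather than hidden.)
#'
#' @return Named integer vector of per-allele totals.
#' @export
published_allele_totals <- function() {
  c("(I,alpha)" = 57L, "(I,delta)" = 96L, "(II,alpha)" = 53L,
    "(III,alpha)" = 36L, "(III,gamma)" = 36L, "(III,delta)" = 41L,
    "(IV,beta)" = 23L, "(IV,delta)" = 40L, other = 40L)
}

#' Reconstruct the published enrichment 2x2 tables from printed percentages
#'
#' Rebuilds the carrier/non-carrier tables behind three headline
#' enrichments, from the printed percentages and cohort sizes only:
#'
#' * `(I, delta)` in ExPEC (22% of 412) vs environmental (3% of 78) --
#'   percentages are fractions of the cohort;
#' * `(II, alpha)` in phylotype B1 (91% of its n = 53 carriers) vs B2 (4%)
#'   -- percentages are fractions of the allele's n, against phylotype
#'   cohort sizes 83 and 229;
#' * `(I, delta)` in NMEC (53% of its n = 96) vs APEC (6%), against cohort
#'   sizes 80 and 171.
#'
#' Counts use half-away-from-zero rounding (22% of 412 -> 91; 3% of 78 -> 2).
#'
#' @return A tibble: `comparison`, `allele`, `group1`, `group2`,
#'   `a`, `b`, `c`, `d` (the 2x2 cells: carriers/non-carriers of group1 then
#'   group2).
#' @export
reconstructed_enrichment_tables <- function() {
  coh <- published_cohorts()
  tot <- published_allele_totals()
  cell <- function(pct, base) round_half_away(pct / 100 * base)

  a1 <- cell(22, coh$source[["ExPEC"]])
  c1 <- cell(3, coh$source[["environmental"]])
  a2 <- cell(91, tot[["(II,alpha)"]])
  c2 <- cell(4, tot[["(II,alpha)"]])
  a3 <- cell(53, tot[["(I,delta)"]])
  c3 <- cell(6, tot[["(I,delta)"]])

  tibble::tibble(
    comparison = c("I_delta_ExPEC_vs_environmental",
                   "II_alpha_B1_vs_B2",
                   "I_delta_NMEC_vs_APEC"),
    allele = c("(I,delta)", "(II,alpha)", "(I,delta)"),
    group1 = c("ExPEC", "B1", "NMEC"),
    group2 = c("environmental", "B2", "APEC"),
    a = c(a1, a2, a3),
    b = c(coh$source[["ExPEC"]] - a1, coh$phylotypes[["B1"]] - a2,
          coh$expec_types[["NMEC"]] - a3),
    c = c(c1, c2, c3),
    d = c(coh$source[["environmental"]] - c1,
          coh$phylotypes[["B2"]] - c2, coh$expec_types[["APEC"]] - c3)
  )
}

#' Run the reconstructed enrichment tests
#'
#' Applies [fisher_2x2()] to each table from
#' [reconstructed_enrichment_tables()].
#'
#' @param alpha Significance cutoff (default the published 1e-5).
#' @return The table tibble with `odds_ratio`, `p_value`, `significant`
#'   appended.
#' @export
reconstructed_enrichments <- function(alpha = 1e-5) {
  tabs <- reconstructed_enrichment_tables()
  res <- purrr::pmap_dfr(tabs[, c("a", "b", "c", "d")], function(a, b, c, d) {
    ft <- fisher_2x2(matrix(c(a, b, c, d), 2, byrow = TRUE))
    tibble::tibble(odds_ratio = ft$odds_ratio, p_value = ft$p_value)
  })
  out <- dplyr::bind_cols(tabs, res)
  out$significant <- out$p_value < alpha
  out
}

#' Environmental share of the trimmed phylotype pool
#'
#' The phylotype-restricted pool is rebuilt from the printed per-phylotype
#' counts (A 45 + B1 83 + B2 229 + F 43 = 400) and the environmental share
#' computed from the 47 environmental isolates it retains.
#'
#' @return A one-row tibble: `pool_n`, `environmental_n`, `percent`.
#' @export
trimmed_pool_environmental_share <- function() {
  coh <- published_cohorts()
  pool <- sum(coh$phylotypes)
  env <- coh$trimmed_pool_environmental
  tibble::tibble(pool_n = pool, environmental_n = env,
                 percent = 100 * env / pool)
}

#' Reconstruct the environmental vs ExPEC allele distribution
#'
#' The two alleles whose source percentages are printed -- `(I, alpha)`
#' (environmental 29%, ExPEC 9%) and `(I, delta)` (environmental 3%,
#' ExPEC 22%) -- reconstructed as a `count_table` against the cohort sizes,
#' suitable for [enrichment_scan()].
#'
#' @param lump_threshold Passed to [build_count_table()]; default 0 (the
#'   printed rows are already above the published lumping rule).
#' @return A `count_table`.
#' @export
reconstructed_source_distribution <- function(lump_threshold = 0) {
  coh <- published_cohorts()
  build_count_table(
    tibble::tibble(
      group = c("environmental", "ExPEC", "environmental", "ExPEC"),
      allele = c("(I,alpha)", "(I,alpha)", "(I,delta)", "(I,delta)"),
      percent = c(29, 9, 3, 22)
    ),
    group_sizes = coh$source,
    percent_of = "group",
    lump_threshold = lump_threshold
  )
}
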