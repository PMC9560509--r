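#' MATH-assay cell surface hydrophobicity
#'
#' Microbial adhesion to hydrocarbons: cells are contacted with dodecane and
#' the optical-density drop of the aqueous phase measures partitioning into
#' the organic phase.  The published formula is
#' `100 * (OD_initial - OD_aqueous) / OD_aqueous`, which this function
#' implements as printed.  The conventional MATH statistic instead divides
#' by the initial OD; set `conventional = TRUE` for that variant when
#' comparing against other studies.
#'
#' @param od_initial,od_aqueous OD546 readings (vectorized).
#' @param conventional Use the initial-OD denominator instead of the printed
#'   aqueous-OD denominator.
#' @return Hydrophobicity in percent.  Inputs with `od_aqueous > od_initial`
#'   are physically anomalous: the negative value is returned with a warning.
#' @examples
#' math_hydrophobicity(0.5, 0.4)  # 25
#' @export
math_hydrophobicity <- function(od_initial, od_aqueous, conventional = FALSE) {
  if (any(od_aqueous <= 0)) abort("od_aqueous must be > 0")
  if (any(od_initial < 0)) abort("od_initial must be >= 0")
  if (any(od_aqueous > od_initial)) {
    warn("aqueous OD exceeds initial OD; returning negative hydrophobicity")
  }
  denom <- if (conventional) od_initial else od_aqueous
  100 * (od_initial - od_aqueous) / denom
}

#' Crystal-violet biofilm formation index
#'
#' Stain absorbance normalized by planktonic culture density:
#' `OD570 / OD620`.  When replicate standard deviations are supplied the
#' index SD is propagated to first order (quadrature of relative errors):
#' `sd = index * sqrt((sd570/od570)^2 + (sd620/od620)^2)`.
#'
#' @param od570,od620 Mean channel readings (vectorized); `od620` must be
#'   positive.
#' @param sd570,sd620 Optional replicate SDs for error propagation.
#' @return The numeric index, or (when SDs are given) a tibble with
#'   `index` and `index_sd`.
#' @examples
#' biofilm_index(0.6, 0.3)  # 2
#' @export
biofilm_index <- function(od570, od620, sd570 = NULL, sd620 = NULL) {
  if (any(od620 <= 0)) abort("od620 must be > 0")
  if (any(od570 < 0)) abort("od570 must be >= 0")
  index <- od570 / od620
  if (is.null(sd570) && is.null(sd620)) {
    return(index)
  }
  sd570 <- sd570 %||% 0
  sd620 <- sd620 %||% 0
  rel <- sqrt(ifelse(od570 > 0, (sd570 / od570)^2, 0) + (sd620 / od620)^2)
  tibble::tibble(index = index, index_sd = abs(index) * rel)
}

#' Survival after neutrophil-elastase treatment
#'
#' Survival is the ratio of mean treated to mean control colony-forming
#' units after incubation with the protease; a kill is declared only when a
#' two-tailed t-test on the replicate CFU counts falls below `alpha` AND the
#' treated mean is lower -- mirroring the study's severe fixed cutoff
#' (p < 0.005) instead of a multiplicity correction.
#'
#' @param cfu_treated,cfu_control Replicate CFU counts (>= 2 each).
#' @param alpha Significance cutoff for the kill flag.
#' @param var_equal Pooled-variance t-test (the study's "student's t-test");
#'   set `FALSE` for Welch.
#' @return A one-row tibble: `survival`, `p_value`, `significant_kill`,
#'   `n_treated`, `n_control`.
#' @export
ne_survival <- function(cfu_treated, cfu_control, alpha = 0.005,
                        var_equal = TRUE) {
  if (length(cfu_treated) < 2 || length(cfu_control) < 2) {
    abort("need >= 2 replicates per arm")
  }
  if (any(cfu_treated < 0) || any(cfu_control < 0)) {
    abort("CFU counts must be >= 0")
  }
  if (mean(cfu_control) == 0) abort("zero control mean")
  p <- pooled_t_p(cfu_treated, cfu_control, var_equal = var_equal)
  survival <- mean(cfu_treated) / mean(cfu_control)
  tibble::tibble(
    survival = survival,
    p_value = p,
    significant_kill = is.finite(p) && p < alpha && survival < 1,
    n_treated = length(cfu_treated),
    n_control = length(cfu_control)
  )
}

# Two-tailed two-sample t-test p-value robust to zero-variance degeneracy:
# equal constant samples -> p = 1, unequal constants -> p = 0.
pooled_t_p <- function(x, y, var_equal = TRUE) {
  if (sd(x) == 0 && sd(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  stats::t.test(x, y, var.equal = var_equal)$p.value
}
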