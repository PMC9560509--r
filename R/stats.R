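#' One-way fixed-effects ANOVA on replicate phenotype values
#'
#' Classical single-factor ANOVA, the study's first gate for "does this
#' phenotype vary by allele at all".
#'
#' @param data A data frame of replicate measurements.
#' @param value,group Column names (strings) of the measurement and the
#'   grouping variable (allele).
#' @return A one-row tibble: `f_statistic`, `df_between`, `df_within`,
#'   `p_value`.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 1, 5, 6, 5))
#' one_way_anova(d, "y", "g")
#' @export
one_way_anova <- function(data, value = "value", group = "allele") {
  g <- factor(data[[group]])
  y <- data[[value]]
  tab <- table(g)
  if (length(tab) < 2) abort("need >= 2 groups")
  if (any(tab < 2)) {
    abort(paste0("group with < 2 replicates: ",
                 names(tab)[which(tab < 2)[1]]))
  }
  if (sd(y) == 0) {
    # All observations identical: no variance to partition.
    return(tibble::tibble(f_statistic = 0,
                          df_between = length(tab) - 1L,
                          df_within = length(y) - length(tab),
                          p_value = 1))
  }
  a <- stats::anova(stats::lm(y ~ g))
  tibble::tibble(
    f_statistic = a$`F value`[1],
    df_between = a$Df[1],
    df_within = a$Df[2],
    p_value = a$`Pr(>F)`[1]
  )
}

#' Pairwise t-tests with a compact letter display
#'
#' All pairwise two-tailed pooled-variance t-tests at a severe fixed cutoff
#' (default p < 0.005, no multiplicity correction -- the study's convention),
#' followed by insert-and-absorb letter assignment so that two groups share
#' at least one letter if and only if their pairwise test is
#' non-significant.  Zero-variance pairs with equal means count as
#' non-significant (p = 1).
#'
#' @param data Replicate data frame.
#' @param value,group Column names of measurement and grouping variable.
#' @param alpha Pairwise significance cutoff.
#' @param var_equal Pooled-variance t-test (`TRUE`, the default) or Welch.
#' @return A tibble of class `letter_grouping`: `group`, `letters`, `mean`;
#'   attributes `alpha`, `p_matrix` (symmetric matrix of pairwise p-values).
#' @export
pairwise_letter_groups <- function(data, value = "value", group = "allele",
                                   alpha = 0.005, var_equal = TRUE) {
  g <- factor(data[[group]], levels = unique(data[[group]]))
  y <- data[[value]]
  lev <- levels(g)
  k <- length(lev)
  if (k < 2) abort("need >= 2 groups")
  pmat <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      p <- pooled_t_p(y[g == lev[i]], y[g == lev[j]], var_equal = var_equal)
      pmat[i, j] <- pmat[j, i] <- p
    }
  }
  sig <- pmat < alpha
  letters_sets <- assign_letters(sig)
  means <- vapply(lev, function(l) mean(y[g == l]), numeric(1))
  out <- tibble::tibble(
    group = lev,
    letters = vapply(seq_len(k), function(i) {
      paste(sort(letters_sets[[i]]), collapse = "")
    }, character(1)),
    mean = unname(means)
  )
  structure(out, class = c("letter_grouping", class(out)),
            alpha = alpha, p_matrix = pmat)
}

# Insert-and-absorb compact letter display.  `sig` is a k x k logical matrix
# (TRUE = significantly different).  Returns a list of letter vectors per
# group index.  Invariant: groups i and j share a letter iff !sig[i, j].
assign_letters <- function(sig) {
  k <- nrow(sig)
  cols <- list(seq_len(k))          # start: one column holding every group
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!isTRUE(sig[i, j])) next
      offending <- which(vapply(cols, function(cc) i %in% cc && j %in% cc,
                                logical(1)))
      for (ci in offending) {
        cc <- cols[[ci]]
        cols[[ci]] <- setdiff(cc, i)
        cols[[length(cols) + 1]] <- setdiff(cc, j)
      }
      # Absorb columns that are subsets of another column.
      drop <- rep(FALSE, length(cols))
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (a != b && !drop[b] && !drop[a] &&
              all(cols[[a]] %in% cols[[b]]) &&
              !(length(cols[[a]]) == length(cols[[b]]) && a < b)) {
            drop[a] <- TRUE
          }
        }
      }
      cols <- cols[!drop]
    }
  }
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  lab <- letters[seq_along(cols)]
  lapply(seq_len(k), function(i) {
    lab[vapply(cols, function(cc) i %in% cc, logical(1))]
  })
}

#' Slope confidence-interval association test
#'
#' The study's correlation criterion: ordinary least-squares slope of `y`
#' on `x` with its `conf`-level confidence interval
#' (`slope +/- t(1-(1-conf)/2, n-2) * SE`); the association is called
#' significant iff the interval excludes zero.
#'
#' @param x,y Paired numeric vectors (>= 3 points).
#' @param conf Confidence level (default 0.95).
#' @return A one-row tibble of class `slope_ci`: `slope`, `se`, `ci_lower`,
#'   `ci_upper`, `p_value`, `significant`, `n`; attribute `fit` holds the lm.
#' @examples
#' slope_ci_association(1:5, 2 * (1:5))
#' @export
slope_ci_association <- function(x, y, conf = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need >= 3 paired points")
  if (sd(x) == 0) abort("constant x: slope undefined")
  fit <- stats::lm(y ~ x)
  su <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(coef(fit)[2])
  se <- su[2, 2]
  n <- length(x)
  tcrit <- stats::qt(1 - (1 - conf) / 2, df = n - 2)
  lo <- slope - tcrit * se
  hi <- slope + tcrit * se
  p <- su[2, 4]
  significant <- (lo > 0 || hi < 0) ||
    (se == 0 && slope != 0)   # exact fit with nonzero slope
  out <- tibble::tibble(
    slope = slope, se = se, ci_lower = lo, ci_upper = hi,
    p_value = p, significant = significant, n = n
  )
  structure(out, class = c("slope_ci", class(out)), fit = fit, conf = conf)
}

#' Scan classification sites for association with a phenotype
#'
#' For each classification site, alleles are partitioned by the residue they
#' present there; replicate phenotype values (default) or allele means are
#' then compared across residue classes with a two-tailed pooled t-test
#' (two classes) or one-way ANOVA (more).  Sites where every allele shows
#' the same residue are reported untestable rather than dropped.
#'
#' @param site_residues Tibble with columns `allele`, `site`, `residues`
#'   (one row per allele x site), e.g. built from the scheme patterns.
#' @param phenotypes Tibble with columns `allele`, `value` (replicate
#'   level).
#' @param mode `"replicates"` (pool replicate values by residue class,
#'   default) or `"means"` (collapse each allele to its mean first).
#' @return A tibble: `site`, `n_classes`, `test`, `p_value`, `testable`.
#' @export
position_phenotype_scan <- function(site_residues, phenotypes,
                                    mode = c("replicates", "means")) {
  mode <- match.arg(mode)
  pheno <- if (mode == "means") {
    phenotypes %>% dplyr::group_by(allele) %>%
      dplyr::summarise(value = mean(value), .groups = "drop")
  } else {
    phenotypes
  }
  sites <- unique(site_residues$site)
  rows <- lapply(sites, function(s) {
    sr <- site_residues[site_residues$site == s, ]
    d <- dplyr::inner_join(pheno, sr[, c("allele", "residues")], by = "allele")
    classes <- unique(d$residues)
    if (length(classes) < 2 || nrow(d) < 3) {
      return(tibble::tibble(site = s, n_classes = length(classes),
                            test = NA_character_, p_value = NA_real_,
                            testable = FALSE))
    }
    if (length(classes) == 2) {
      p <- pooled_t_p(d$value[d$residues == classes[1]],
                      d$value[d$residues == classes[2]])
      tibble::tibble(site = s, n_classes = 2L, test = "t-test",
                     p_value = p, testable = TRUE)
    } else {
      a <- one_way_anova(data.frame(value = d$value, allele = d$residues))
      tibble::tibble(site = s, n_classes = length(classes), test = "anova",
                     p_value = a$p_value, testable = TRUE)
    }
  })
  dplyr::bind_rows(rows)
}

#' Site residues of the scheme patterns for the exemplar alleles
#'
#' Helper feeding [position_phenotype_scan()]: one row per allele and
#' classification site with the defining residue run.
#'
#' @param scheme An `ompa_scheme`.
#' @param alleles Tibble with `nterm`, `cterm`, `label` columns.
#' @return Tibble: `allele` (label), `site`, `residues`.
#' @export
allele_site_residues <- function(scheme, alleles = exemplar_alleles()) {
  purrr::pmap_dfr(alleles, function(nterm, cterm, label) {
    runs <- c(scheme$nterm_patterns[[nterm]], scheme$cterm_patterns[[cterm]])
    tibble::tibble(allele = label, site = names(runs),
                   residues = unlist(runs))
  })
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-tailed p-value under the hypergeometric null, using the
#' "sum the probabilities of all tables at most as probable as the observed
#' one" two-sided convention (the common implementation convention; others
#' exist).  The odds ratio is the conditional maximum-likelihood estimate
#' under the noncentral hypergeometric model.
#'
#' @param tab A 2x2 matrix of non-negative integer counts
#'   (rows = groups, columns = carrier/non-carrier), or four counts
#'   `c(a, b, c, d)` filling the table by row.
#' @return A one-row tibble: `p_value`, `odds_ratio`, `a`,`b`,`c`,`d`,
#'   `degenerate` (TRUE when a margin is zero; p = 1 by convention).
#' @examples
#' fisher_2x2(matrix(c(91, 2, 321, 76), 2))
#' @export
fisher_2x2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, 2, byrow = TRUE)
  if (!all(dim(tab) == 2)) abort("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("counts must be non-negative integers")
  }
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- cc + d; k <- a + cc
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    return(tibble::tibble(p_value = 1, odds_ratio = NA_real_,
                          a = a, b = b, c = cc, d = d, degenerate = TRUE))
  }
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  tibble::tibble(
    p_value = min(p, 1), odds_ratio = conditional_or(a, m, n, k),
    a = a, b = b, c = cc, d = d, degenerate = FALSE
  )
}

# Conditional MLE of the odds ratio: solves E_psi[X] = a under the
# noncentral hypergeometric distribution on the table's support.
conditional_or <- function(a, m, n, k) {
  support <- max(0, k - n):min(k, m)
  if (a == min(support)) return(0)
  if (a == max(support)) return(Inf)
  logw <- lchoose(m, support) + lchoose(n, k - support)
  emean <- function(logpsi) {
    lp <- logw + support * logpsi
    lp <- lp - max(lp)
    w <- exp(lp)
    sum(support * w) / sum(w)
  }
  f <- function(logpsi) emean(logpsi) - a
  lo <- -1; hi <- 1
  while (f(lo) > 0) lo <- lo * 2
  while (f(hi) < 0) hi <- hi * 2
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root)
}

#' Chi-square test of homogeneity for an r x c count table
#'
#' Classical Pearson chi-square (no continuity correction) with
#' df = (r-1)(c-1), plus an adequacy flag that goes `FALSE` when more than
#' 20% of expected counts fall below 5 (the usual validity rule).
#'
#' @param tab Matrix of non-negative counts.
#' @return A one-row tibble: `chi_sq`, `df`, `p_value`, `adequate`.
#' @export
chi_square_homogeneity <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) abort("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("zero row or column margin")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(
    chi_sq = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value,
    adequate = mean(ct$expected < 5) <= 0.2
  )
}

round_half_away <- function(x) trunc(x + 0.5 * sign(x))

#' Build an isolate-count table by group and allele
#'
#' Two input modes.  With per-isolate calls (`data` has `group` and
#' `allele` columns, one row per isolate) counts are tallied directly.
#' With printed percentage summaries (`data` has `group`, `allele`,
#' `percent`) counts are reconstructed as `round(percent/100 * base)` with
#' half-away-from-zero rounding, where the base per row is either the group
#' cohort size (`percent_of = "group"`) or the allele's total carrier count
#' (`percent_of = "allele"`, requires `allele_totals`).  Alleles whose total
#' count falls below `lump_threshold` are lumped into `"other"`.
#' Reconstructed tables are labelled as reconstructions.
#'
#' @param data Tibble as above.
#' @param group_sizes Named integer vector of cohort sizes per group
#'   (required: supplies the non-carrier complement for exact tests).
#' @param percent_of `"group"` or `"allele"` (see above); ignored for
#'   per-isolate input.
#' @param allele_totals Named vector of per-allele total n (for
#'   `percent_of = "allele"`).
#' @param lump_threshold Alleles with total count below this are pooled as
#'   `"other"` (default 10, the published rule).
#' @return A tibble of class `count_table`: `group`, `allele`, `count`;
#'   attributes `group_sizes`, `reconstructed`.
#' @examples
#' build_count_table(
#'   tibble::tibble(group = c("ExPEC", "environmental"),
#'                  allele = "(I,delta)", percent = c(22, 3)),
#'   group_sizes = c(ExPEC = 412, environmental = 78),
#'   lump_threshold = 0
#' )
#' @export
build_count_table <- function(data, group_sizes,
                              percent_of = c("group", "allele"),
                              allele_totals = NULL, lump_threshold = 10) {
  percent_of <- match.arg(percent_of)
  if (is.null(names(group_sizes))) abort("group_sizes must be named")
  reconstructed <- "percent" %in% names(data)
  if (reconstructed) {
    if (percent_of == "group") {
      bad <- data %>% dplyr::group_by(group) %>%
        dplyr::summarise(tot = sum(percent), .groups = "drop") %>%
        dplyr::filter(tot > 100 + 1e-9)
      if (nrow(bad) > 0) {
        abort(paste0("percentages sum above 100% in group ", bad$group[1]))
      }
      base <- group_sizes[data$group]
    } else {
      if (is.null(allele_totals)) {
        abort("percent_of = 'allele' requires allele_totals")
      }
      base <- allele_totals[data$allele]
    }
    counts <- data %>%
      dplyr::mutate(count = unname(round_half_away(percent / 100 * base))) %>%
      dplyr::select(group, allele, count)
  } else {
    counts <- data %>% dplyr::count(group, allele, name = "count")
  }
  tot <- counts %>% dplyr::group_by(allele) %>%
    dplyr::summarise(total = sum(count), .groups = "drop")
  lumped <- tot$allele[tot$total < lump_threshold]
  if (length(lumped) > 0) {
    counts <- counts %>%
      dplyr::mutate(allele = ifelse(allele %in% lumped, "other", allele)) %>%
      dplyr::group_by(group, allele) %>%
      dplyr::summarise(count = sum(count), .groups = "drop")
  }
  over <- counts %>% dplyr::group_by(group) %>%
    dplyr::summarise(tot = sum(count), .groups = "drop")
  for (i in seq_len(nrow(over))) {
    gs <- group_sizes[[over$group[i]]]
    if (!is.null(gs) && !is.na(gs) && over$tot[i] > gs) {
      warn(paste0("reconstructed counts in group ", over$group[i],
                  " exceed the stated cohort size (", over$tot[i], " > ",
                  gs, "); kept as-is so the inconsistency stays visible"))
    }
  }
  structure(dplyr::arrange(counts, group, allele),
            class = c("count_table", class(counts)),
            group_sizes = group_sizes, reconstructed = reconstructed)
}

#' Exact-test enrichment scan over a count table
#'
#' For every allele and every unordered pair of groups, forms the 2x2
#' carrier/non-carrier table (non-carriers from the stated cohort sizes)
#' and applies [fisher_2x2()]; results are flagged at the severe fixed
#' cutoff `alpha` (default 1e-5, no multiplicity correction) and sorted by
#' p-value.
#'
#' @param counts A `count_table` from [build_count_table()].
#' @param alpha Significance cutoff.
#' @return A tibble: `allele`, `group1`, `group2`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p_value`, `significant`.
#' @export
enrichment_scan <- function(counts, alpha = 1e-5) {
  sizes <- attr(counts, "group_sizes")
  groups <- names(sizes)
  groups <- groups[groups %in% unique(counts$group)]
  if (length(groups) < 2) abort("need >= 2 groups")
  alleles <- unique(counts$allele)
  get_count <- function(g, al) {
    v <- counts$count[counts$group == g & counts$allele == al]
    if (length(v) == 0) 0L else v[1]
  }
  rows <- list()
  for (al in alleles) {
    for (i in seq_len(length(groups) - 1)) {
      for (j in (i + 1):length(groups)) {
        g1 <- groups[i]; g2 <- groups[j]
        a <- get_count(g1, al); cc <- get_count(g2, al)
        b <- sizes[[g1]] - a; d <- sizes[[g2]] - cc
        ft <- fisher_2x2(matrix(c(a, b, cc, d), 2, byrow = TRUE))
        rows[[length(rows) + 1]] <- tibble::tibble(
          allele = al, group1 = g1, group2 = g2,
          a = a, b = b, c = cc, d = d,
          odds_ratio = ft$odds_ratio, p_value = ft$p_value,
          significant = ft$p_value < alpha
        )
      }
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), p_value)
}
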