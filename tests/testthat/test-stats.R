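test_that("one-way ANOVA handles degenerate and two-group cases exactly", {
  d0 <- data.frame(allele = rep(c("a", "b", "c"), each = 3), value = 5)
  res0 <- one_way_anova(d0)
  expect_identical(res0$f_statistic, 0)
  expect_identical(res0$p_value, 1)

  # two groups: F = t^2 and identical p (pooled-variance identity)
  set.seed(8)
  d <- data.frame(allele = rep(c("a", "b"), each = 6),
                  value = c(rnorm(6), rnorm(6, 1)))
  res <- one_way_anova(d)
  tt <- stats::t.test(value ~ allele, data = d, var.equal = TRUE)
  expect_equal(res$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)

  expect_error(one_way_anova(data.frame(allele = c("a", "a", "b"),
                                        value = 1:3)), "< 2 replicates")
  expect_error(one_way_anova(data.frame(allele = "a", value = 1)), "2 groups")
})

test_that("letter groups satisfy the share-a-letter iff non-significant
           biconditional on random inputs", {
  set.seed(17)
  for (rep in 1:20) {
    k <- sample(3:7, 1)
    means <- rnorm(k, sd = sample(c(0.2, 2, 10), 1))
    d <- data.frame(
      allele = rep(letters[1:k], each = 4),
      value = rnorm(4 * k, rep(means, each = 4), 0.8)
    )
    lg <- pairwise_letter_groups(d, alpha = 0.05)
    pm <- attr(lg, "p_matrix")
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      shared <- length(intersect(strsplit(lg$letters[i], "")[[1]],
                                 strsplit(lg$letters[j], "")[[1]])) > 0
      expect_identical(shared, pm[i, j] >= 0.05,
                       info = sprintf("rep %d pair %d-%d", rep, i, j))
    }
    expect_true(all(nchar(lg$letters) >= 1))
  }
})

test_that("letter groups collapse, separate and tolerate zero variance as
           specified", {
  # identical draws: a single letter
  d0 <- data.frame(allele = rep(c("x", "y", "z"), each = 3), value = 2)
  lg0 <- pairwise_letter_groups(d0)
  expect_identical(unique(lg0$letters), "a")

  # three well-separated groups: three disjoint letters
  d3 <- data.frame(allele = rep(c("x", "y", "z"), each = 4),
                   value = c(rnorm(4, 0, 0.01), rnorm(4, 5, 0.01),
                             rnorm(4, 10, 0.01)))
  set.seed(23)
  lg3 <- pairwise_letter_groups(d3)
  expect_identical(sort(unique(lg3$letters)), c("a", "b", "c"))

  # zero-variance pair with equal means is non-significant (p = 1)
  dz <- data.frame(allele = rep(c("x", "y"), each = 3), value = c(1, 1, 1, 1, 1, 1))
  lgz <- pairwise_letter_groups(dz)
  expect_identical(attr(lgz, "p_matrix")[1, 2], 1)
  expect_identical(lgz$letters, c("a", "a"))
})

test_that("synthetic biofilm data with the published 10-fold split yields
           exactly the alpha vs beta/gamma letter partition", {
  ph <- gen_phenotypes(fig2_biofilm_means(), n_reps = 3, seed = 11)
  lg <- pairwise_letter_groups(ph, "value", "allele", alpha = 0.005)
  ex <- exemplar_alleles()
  high <- lg$letters[lg$group %in% ex$label[ex$cterm == "alpha"]]
  low <- lg$letters[lg$group %in% ex$label[ex$cterm != "alpha"]]
  expect_identical(unique(high), "a")
  expect_identical(unique(low), "b")
})

test_that("slope-CI association matches its closed form and edge cases", {
  res <- slope_ci_association(1:5, 2 * (1:5))
  expect_equal(res$slope, 2)
  expect_equal(res$ci_lower, 2)
  expect_equal(res$ci_upper, 2)
  expect_true(res$significant)

  flat <- slope_ci_association(1:5, rep(3, 5))
  expect_equal(flat$slope, 0)
  expect_false(flat$significant)

  # CI matches confint() on a noisy fit
  set.seed(5)
  x <- rnorm(10); y <- 1.5 * x + rnorm(10)
  res2 <- slope_ci_association(x, y)
  ci <- confint(stats::lm(y ~ x))[2, ]
  expect_equal(unname(c(res2$ci_lower, res2$ci_upper)), unname(ci),
               tolerance = 1e-10)

  expect_error(slope_ci_association(rep(1, 5), 1:5), "constant x")
  expect_error(slope_ci_association(1:2, 1:2), ">= 3")
})

test_that("the slope-CI criterion attains its nominal type-I error on null
           simulations", {
  set.seed(29)
  n_sim <- 1000
  hits <- 0
  for (i in seq_len(n_sim)) {
    x <- rnorm(7); y <- rnorm(7)
    if (slope_ci_association(x, y)$significant) hits <- hits + 1
  }
  rate <- hits / n_sim
  mc_se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(rate - 0.05), 3 * mc_se)
})

test_that("the position-phenotype scan recovers a planted effect at site 203
           and reports untestable sites", {
  sr <- allele_site_residues(SCHEME)
  # planted: phenotype depends only on the residue at 203 (N vs T)
  n203 <- sr[sr$site == "p203", ]
  means <- setNames(ifelse(n203$residues == "N", 2, 0.2), n203$allele)
  ph <- gen_phenotypes(means, n_reps = 3, seed = 3)
  scan <- position_phenotype_scan(sr, ph[, c("allele", "value")])
  testable <- scan[scan$testable, ]
  expect_identical(testable$site[which.min(testable$p_value)], "p203")
  # constant phenotype: every testable site gets p = 1
  ph0 <- ph; ph0$value <- 1
  scan0 <- position_phenotype_scan(sr, ph0[, c("allele", "value")])
  expect_true(all(scan0$p_value[scan0$testable] == 1))
  # a site with one residue class across alleles is untestable
  sr1 <- dplyr::bind_rows(sr, tibble::tibble(
    allele = unique(sr$allele), site = "const", residues = "Q"))
  scan1 <- position_phenotype_scan(sr1, ph[, c("allele", "value")])
  expect_false(scan1$testable[scan1$site == "const"])
})

test_that("fisher_2x2 handles the trivial, degenerate and published tables", {
  even <- fisher_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(even$p_value, 1)
  expect_equal(even$odds_ratio, 1, tolerance = 1e-6)

  degen <- fisher_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_identical(degen$p_value, 1)
  expect_true(degen$degenerate)

  # reconstructed (I, delta) ExPEC vs environmental table
  res <- fisher_2x2(matrix(c(91, 321, 2, 76), 2, byrow = TRUE))
  expect_lt(res$p_value, 1e-5)
  expect_error(fisher_2x2(matrix(c(1, -1, 2, 3), 2)), "non-negative")
})

test_that("fisher_2x2 agrees with enumeration, stats::fisher.test and is
           symmetric, on random tables", {
  set.seed(37)
  for (i in 1:60) {
    tab <- matrix(rpois(4, sample(c(2, 8, 25), 1)), 2)
    res <- fisher_2x2(tab)
    ft <- stats::fisher.test(tab)
    expect_equal(res$p_value, ft$p.value, tolerance = 1e-9)
    if (is.finite(res$odds_ratio) && res$odds_ratio > 0) {
      expect_equal(res$odds_ratio, unname(ft$estimate), tolerance = 1e-4)
    }
    # transposing, or swapping both rows and columns, leaves p unchanged
    expect_equal(fisher_2x2(t(tab))$p_value, res$p_value, tolerance = 1e-12)
    expect_equal(fisher_2x2(tab[2:1, 2:1])$p_value, res$p_value,
                 tolerance = 1e-12)
  }
})

test_that("chi-square homogeneity matches its classical identities", {
  # proportional rows: chi-square 0, p 1
  hom <- chi_square_homogeneity(matrix(c(10, 20, 30, 60), 2, byrow = TRUE))
  expect_equal(hom$chi_sq, 0, tolerance = 1e-12)
  expect_equal(hom$p_value, 1)

  # 2x2: chi-square equals the squared two-proportion z statistic
  tab <- matrix(c(30, 70, 45, 55), 2, byrow = TRUE)
  res <- chi_square_homogeneity(tab)
  p1 <- 30 / 100; p2 <- 45 / 100; pp <- 75 / 200
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 100 + 1 / 100))
  expect_equal(res$chi_sq, z^2, tolerance = 1e-10)
  expect_identical(res$df, 1L)

  sparse <- chi_square_homogeneity(matrix(c(1, 2, 2, 1, 1, 2), 2, byrow = TRUE))
  expect_false(sparse$adequate)
  expect_error(chi_square_homogeneity(matrix(c(0, 0, 1, 2), 2, byrow = TRUE)),
               "zero row")
})

test_that("count tables reconstruct from percentages with the published
           rounding and lumping rules", {
  ct <- build_count_table(
    tibble::tibble(group = c("ExPEC", "environmental"),
                   allele = "(I,delta)", percent = c(22, 3)),
    group_sizes = c(ExPEC = 412, environmental = 78), lump_threshold = 0
  )
  expect_identical(ct$count[ct$group == "ExPEC"], 91)
  expect_identical(ct$count[ct$group == "environmental"], 2)
  expect_true(attr(ct, "reconstructed"))

  # one allele at 100%: the cell equals the group size
  full <- build_count_table(
    tibble::tibble(group = "g", allele = "x", percent = 100),
    group_sizes = c(g = 57), lump_threshold = 0
  )
  expect_identical(full$count, 57)

  # a 9-count allele is absorbed into "other" at the default threshold
  d <- tibble::tibble(group = rep("g", 18), allele = rep(c("x", "y"), c(9, 9)))
  lumped <- build_count_table(d, group_sizes = c(g = 30), lump_threshold = 10)
  expect_identical(unique(lumped$allele), "other")
  expect_identical(lumped$count, 18L)

  expect_error(
    build_count_table(
      tibble::tibble(group = "g", allele = c("x", "y"), percent = c(70, 40)),
      group_sizes = c(g = 10)
    ), "above 100"
  )
})

test_that("the enrichment scan flags planted enrichments and stays silent on
           uniform tables", {
  freqs <- c("(I,alpha)" = 0.3, "(I,delta)" = 0.1, "(II,alpha)" = 0.2,
             "(III,gamma)" = 0.2, "(IV,beta)" = 0.2)
  uni <- gen_count_table(c(environmental = 400, ExPEC = 400), freqs, seed = 2)
  scan_u <- enrichment_scan(uni$counts)
  expect_false(any(scan_u$significant))

  planted <- gen_count_table(
    c(environmental = 78, ExPEC = 400), freqs,
    planted = tibble::tibble(group = "ExPEC", allele = "(I,delta)", odds = 10),
    seed = 3
  )
  scan_p <- enrichment_scan(planted$counts)
  expect_identical(scan_p$allele[1], "(I,delta)")
  expect_true(scan_p$significant[1])
})

test_that("a permuted-label table almost never triggers the severe cutoff", {
  set.seed(41)
  freqs <- c(a = 0.4, b = 0.3, c = 0.2, d = 0.1)
  n_flag <- 0
  for (i in 1:300) {
    tab <- gen_count_table(c(g1 = 200, g2 = 200), freqs, seed = 1000 + i)
    if (any(enrichment_scan(tab$counts)$significant)) n_flag <- n_flag + 1
  }
  expect_lte(n_flag, 1)
})
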