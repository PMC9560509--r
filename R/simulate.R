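# Hierarchical seed stream: each generator derives its own sub-seed from
# (seed, label), so adding one generator call never perturbs another's draws.
sub_seed <- function(seed, label) {
  as.integer((as.numeric(seed) * 1000003 + sum(utf8ToInt(label)) * 7919) %%
               2147483629)
}

#' Generate synthetic OmpA sequences with known allele ground truth
#'
#' Builds each record by editing the reference to a target allele's site
#' residues, then (optionally) applying a loop-3 indel just outside the
#' variant run, site noise at the classification sites, and background
#' mutations away from all classification sites.  Site noise substitutes a
#' designated novel residue (`W`, absent from every pattern definition at
#' the variant sites), so a noised site can never coincide with another
#' pattern and the expected novel-call fraction has the closed form
#' `1 - (1 - rate)^S` with `S = 7` classification sites.
#'
#' @param scheme An `ompa_scheme`.
#' @param n_per_allele Sequences per allele.
#' @param alleles Tibble of `nterm`, `cterm` targets (default the seven
#'   exemplars).
#' @param background_rate Per-site substitution probability outside
#'   classification sites.
#' @param site_noise_rate Per-classification-site probability of a novel
#'   residue.
#' @param loop3_indel_prob Probability of deleting or inserting 1-2
#'   residues inside loop 3 but outside the variant run.
#' @param seed Integer seed.
#' @return A list: `sequences` (named character vector) and `truth`
#'   (tibble: `id`, `nterm`, `cterm`, `site_noised`, `indel`,
#'   `n_background`).
#' @export
gen_sequences <- function(scheme, n_per_allele = 10,
                          alleles = exemplar_alleles(),
                          background_rate = 0, site_noise_rate = 0,
                          loop3_indel_prob = 0, seed = 1) {
  set.seed(sub_seed(seed, "sequences"))
  sites <- scheme$sites[scheme$sites$classifying, ]
  seqs <- character(0)
  truth <- list()
  for (r in seq_len(nrow(alleles))) {
    nt <- alleles$nterm[r]; ct <- alleles$cterm[r]
    rec <- reconstruct_allele_sequence(scheme, nt, ct)
    for (i in seq_len(n_per_allele)) {
      s <- rec$sequence
      site_pos <- unlist(lapply(seq_len(nrow(sites)), function(k) {
        rec$coord(sites$start[k]):rec$coord(sites$end[k])
      }))
      # Loop-3 indel outside the variant run: edit within the loop segment.
      # Insertions go upstream of the run and deletions downstream, so the
      # alignment cannot trade the indel against the run's own length
      # difference (patterns VI/VII carry a shorter run than the reference).
      indel <- 0L
      if (stats::runif(1) < loop3_indel_prob) {
        kdel <- sample(1:2, 1)
        site3 <- sites[sites$name == "loop3", ]
        if (stats::runif(1) < 0.5) {
          at <- rec$coord(site3$end) + 1   # first position after the run
          s <- paste0(substr(s, 1, at - 1), substr(s, at + kdel, nchar(s)))
          indel <- -kdel
          site_pos <- ifelse(site_pos >= at, site_pos + indel, site_pos)
        } else {
          at <- rec$coord(site3$start) - 1 # just before the run
          s <- paste0(substr(s, 1, at - 1), strrep("G", kdel),
                      substr(s, at, nchar(s)))
          indel <- kdel
          site_pos <- ifelse(site_pos >= at, site_pos + indel, site_pos)
        }
      }
      # Site noise: novel residue at each classification site w.p. rate.
      noised <- FALSE
      for (k in seq_len(nrow(sites))) {
        if (stats::runif(1) < site_noise_rate) {
          noised <- TRUE
          pos <- rec$coord(sites$start[k])
          if (sites$kind[k] == "loop" && sites$name[k] == "loop3") {
            pos <- pos + 1   # loop-3 runs begin with W; noise the 2nd residue
          }
          if (indel != 0 && pos > rec$coord(sites$end[k])) pos <- pos  # no-op
          substr(s, pos, pos) <- "W"
        }
      }
      # Background substitutions away from all classification sites.
      nbg <- 0L
      if (background_rate > 0) {
        eligible <- setdiff(seq_len(nchar(s)), site_pos)
        hit <- eligible[stats::runif(length(eligible)) < background_rate]
        for (p in hit) {
          cur <- substr(s, p, p)
          repl <- sample(setdiff(AA_LETTERS, cur), 1)
          substr(s, p, p) <- repl
        }
        nbg <- length(hit)
      }
      id <- sprintf("%s_%s_%03d", nt, ct, i)
      seqs[[id]] <- s
      truth[[length(truth) + 1]] <- tibble::tibble(
        id = id, nterm = nt, cterm = ct,
        site_noised = noised, indel = indel, n_background = nbg
      )
    }
  }
  list(sequences = seqs, truth = dplyr::bind_rows(truth))
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector of amino-acid strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Generate replicate phenotype measurements with allele-level means
#'
#' Gaussian replicates around configured per-allele means, emulating the
#' study's replicate structure (three biological replicates by default).
#'
#' @param means Named numeric vector: mean per allele label.
#' @param sd Replicate SD; either one value or a named vector per allele.
#'   Default is 5% of each allele's mean (tight replicates).
#' @param n_reps Replicates per allele.
#' @param phenotype Phenotype name carried in the output.
#' @param seed Integer seed.
#' @return A tibble: `allele`, `phenotype`, `replicate`, `value`.
#' @export
gen_phenotypes <- function(means, sd = NULL, n_reps = 3,
                           phenotype = "phenotype", seed = 1) {
  set.seed(sub_seed(seed, "phenotypes"))
  if (is.null(names(means))) abort("means must be named by allele")
  if (is.null(sd)) sd <- abs(means) * 0.05
  sd <- rep_len(sd, length(means))
  if (any(sd < 0)) abort("sd must be >= 0")
  purrr::imap_dfr(means, function(m, al) {
    s <- sd[[match(al, names(means))]]
    tibble::tibble(
      allele = al, phenotype = phenotype,
      replicate = seq_len(n_reps),
      value = stats::rnorm(n_reps, m, s)
    )
  })
}

#' Per-allele biofilm means emulating the published two-group pattern
#'
#' The alpha C-terminal alleles form roughly tenfold more biofilm than the
#' beta/gamma alleles; these preset means encode that planted partition for
#' power and letter-grouping checks.
#'
#' @return Named numeric vector of biofilm-index means for the seven
#'   exemplar allele labels.
#' @export
fig2_biofilm_means <- function() {
  ex <- exemplar_alleles()
  m <- ifelse(ex$cterm == "alpha", 2.0, 0.2)
  setNames(m, ex$label)
}

#' Generate synthetic growth curves with known kinetics
#'
#' Piecewise lag / exponential / plateau curves sampled on the study's grid
#' (15 h at 10-minute spacing, 91 points) with multiplicative Gaussian
#' noise: `OD(t) = od0 * exp(mu * clamp(t - lag, 0, plateau - lag)) * eps`.
#'
#' @param n_curves Number of curves.
#' @param mu Specific growth rate (1/h).
#' @param lag_h Lag duration (h).
#' @param plateau_h Time growth stops (h).
#' @param od0 Initial OD550.
#' @param noise_sd SD of multiplicative (log-scale) noise.
#' @param duration_h,dt_h Sampling extent and interval.
#' @param seed Integer seed.
#' @return A list: `curves` (tibble: `curve_id`, `time_h`, `od550`) and
#'   `truth` (tibble: `curve_id`, `mu`, `lag_h`, `plateau_h`,
#'   `breakpoint_index` -- the sample index where growth stops).
#' @export
gen_growth_curves <- function(n_curves = 1, mu = 0.6, lag_h = 1,
                              plateau_h = 6, od0 = 0.05, noise_sd = 0.01,
                              duration_h = 15, dt_h = 1 / 6, seed = 1) {
  set.seed(sub_seed(seed, "growth"))
  times <- seq(0, duration_h, by = dt_h)
  curves <- purrr::map_dfr(seq_len(n_curves), function(i) {
    expo <- pmin(pmax(times - lag_h, 0), plateau_h - lag_h)
    od <- od0 * exp(mu * expo) * exp(stats::rnorm(length(times), 0, noise_sd))
    tibble::tibble(curve_id = sprintf("curve%03d", i),
                   time_h = times, od550 = od)
  })
  bp <- which.min(abs(times - plateau_h))
  truth <- tibble::tibble(
    curve_id = sprintf("curve%03d", seq_len(n_curves)),
    mu = mu, lag_h = lag_h, plateau_h = plateau_h,
    breakpoint_index = bp
  )
  list(curves = curves, truth = truth)
}

#' Generate a multinomial isolate-count table with planted enrichments
#'
#' Draws each group's allele counts from a multinomial over the configured
#' frequency vector, optionally reweighted by planted odds multipliers on
#' designated (group, allele) cells.
#'
#' @param group_sizes Named integer vector of isolates per group.
#' @param freqs Either one named frequency vector (shared by all groups) or
#'   a named list of per-group vectors; each must sum to 1.
#' @param planted Optional tibble `group`, `allele`, `odds` of planted
#'   multipliers.
#' @param seed Integer seed.
#' @param lump_threshold Passed through to [build_count_table()].
#' @return A list: `counts` (a `count_table`) and `truth` (the planted
#'   tibble, possibly empty).
#' @export
gen_count_table <- function(group_sizes, freqs, planted = NULL, seed = 1,
                            lump_threshold = 0) {
  set.seed(sub_seed(seed, "counts"))
  groups <- names(group_sizes)
  if (is.null(groups)) abort("group_sizes must be named")
  per_group <- if (is.list(freqs)) freqs else {
    setNames(rep(list(freqs), length(groups)), groups)
  }
  rows <- purrr::map_dfr(groups, function(g) {
    f <- per_group[[g]]
    if (abs(sum(f) - 1) > 1e-8) abort("frequency vector must sum to 1")
    if (!is.null(planted)) {
      pg <- planted[planted$group == g, ]
      for (i in seq_len(nrow(pg))) {
        f[pg$allele[i]] <- f[pg$allele[i]] * pg$odds[i]
      }
      f <- f / sum(f)
    }
    draw <- stats::rmultinom(1, group_sizes[[g]], f)[, 1]
    tibble::tibble(group = g, allele = names(f), count = as.integer(draw))
  })
  per_isolate <- rows[rep(seq_len(nrow(rows)), rows$count),
                      c("group", "allele")]
  counts <- build_count_table(per_isolate, group_sizes = group_sizes,
                              lump_threshold = lump_threshold)
  list(counts = counts,
       truth = planted %||% tibble::tibble(group = character(0),
                                           allele = character(0),
                                           odds = numeric(0)))
}
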