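test_that("self-alignment yields the identity map", {
  pm <- align_to_reference(REF, SCHEME)
  expect_identical(pm$ref_pos, 1:325)
  expect_identical(pm$query_pos, 1:325)
  expect_false(attr(pm, "trimmed"))
})

test_that("a loop-3 deletion shifts all downstream positions by one,
           matching an independent Needleman-Wunsch oracle", {
  del <- 105  # inside the loop-3 variant run
  query <- paste0(substr(REF, 1, del - 1), substr(REF, del + 1, 325))
  pm <- align_to_reference(query, SCHEME)
  oracle <- nw_map_oracle(query, REF)
  expect_equal(pm$query_pos, oracle$query_pos)
  # positions before the deletion map 1:1; one reference position is gapped;
  # everything after shifts by exactly 1
  expect_identical(pm$query_pos[1:(del - 1)], 1:(del - 1))
  expect_identical(sum(is.na(pm$query_pos)), 1L)
  expect_identical(pm$query_pos[325], 324L)
})

test_that("precursor input is signal-trimmed to an identity map", {
  prec <- paste0(SCHEME$reference$signal_peptide, REF)
  pm <- align_to_reference(prec, SCHEME)
  expect_true(attr(pm, "trimmed"))
  expect_identical(pm$query_pos, 1:325)
})

test_that("non-OmpA-like input fails the identity floor and bad characters error", {
  expect_error(align_to_reference("ACDB", SCHEME), "non-amino-acid")
  set.seed(4)
  scrambled <- paste(sample(strsplit(REF, "")[[1]]), collapse = "")
  expect_error(align_to_reference(scrambled, SCHEME), "not OmpA-like")
})

test_that("K-12 reference profiles to the alpha residues and types as (I, alpha)", {
  prof <- extract_variant_profile(REF, SCHEME, id = "K12")
  cres <- setNames(prof$residues, prof$site)
  expect_identical(cres[["p175"]], SCHEME$cterm_patterns$alpha$p175)
  expect_identical(cres[["p203"]], SCHEME$cterm_patterns$alpha$p203)
  expect_identical(cres[["p251"]], SCHEME$cterm_patterns$alpha$p251)
  # the excluded trio is recorded but flagged non-classifying
  expect_identical(prof$classifying[prof$site %in% c("p93", "p129", "p161")],
                   rep(FALSE, 3))

  call <- call_allele(prof, SCHEME)
  expect_identical(call$nterm, "I")
  expect_identical(call$cterm, "alpha")
  expect_identical(call$nterm_mismatches + call$cterm_mismatches, 0L)
})

test_that("a single substitution changes the profile only at that site", {
  q <- mutate_at(REF, 203, "T")
  p0 <- extract_variant_profile(REF, SCHEME)
  p1 <- extract_variant_profile(q, SCHEME)
  differs <- p0$residues != p1$residues
  expect_identical(p0$site[differs], "p203")
})

test_that("loop-2 residues constrain the N-terminal call as published", {
  sve <- c("I", "IV", "V", "VII")
  dni <- c("II", "III", "VI")
  for (pid in names(SCHEME$nterm_patterns)) {
    run <- SCHEME$nterm_patterns[[pid]]$loop2
    expect_identical(run, if (pid %in% sve) "SVE" else "DNI")
  }
  # typing honours it: every generated sequence with SVE at loop 2 gets an
  # SVE-group call
  gs <- gen_sequences(SCHEME, n_per_allele = 1, seed = 5)
  calls <- batch_type(gs$sequences, SCHEME)
  profs <- purrr::map_chr(gs$sequences, function(s) {
    p <- extract_variant_profile(s, SCHEME)
    p$residues[p$site == "loop2"]
  })
  expect_true(all(calls$nterm[profs == "SVE"] %in% sve))
  expect_true(all(calls$nterm[profs == "DNI"] %in% dni))
})

test_that("novel profiles report nearest patterns at the right distance", {
  # poison one loop-1 residue with a residue no pattern uses
  q <- mutate_at(REF, 25, "W")
  call <- type_sequence(q, SCHEME)
  expect_identical(call$nterm, "novel")
  expect_identical(call$nterm_mismatches, 1L)
  expect_identical(call$nterm_nearest, "I")
  expect_identical(call$cterm, "alpha")

  # missing site errors by name
  prof <- extract_variant_profile(REF, SCHEME)
  expect_error(call_allele(prof[prof$site != "p203", ], SCHEME), "p203")
})

test_that("novel calls agree with exhaustive pattern comparison on random
           few-site mutants", {
  set.seed(71)
  loop_sites <- SCHEME$sites[SCHEME$sites$kind == "loop" & SCHEME$sites$classifying, ]
  exhaustive_nterm <- function(obs) {
    mism <- vapply(SCHEME$nterm_patterns, function(pat) {
      sum(vapply(loop_sites$name, function(s) !identical(obs[[s]], pat[[s]]),
                 logical(1)))
    }, numeric(1))
    list(best = min(mism), ids = names(mism)[mism == min(mism)])
  }
  for (rep in 1:25) {
    q <- REF
    npos <- sample(1:3, 1)
    pos <- sample(c(25:27, 66:68, 144:146, 175, 203, 251), npos)
    for (p in pos) q <- mutate_at(q, p, sample(setdiff(AA <- strsplit(
      "ACDEFGHIKLMNPQRSTVWY", "")[[1]], substr(q, p, p)), 1))
    prof <- extract_variant_profile(q, SCHEME)
    obs <- setNames(as.list(prof$residues), prof$site)
    ex <- exhaustive_nterm(obs)
    call <- call_allele(prof, SCHEME)
    if (ex$best == 0) {
      expect_identical(call$nterm, ex$ids[1])
    } else {
      expect_identical(call$nterm, "novel")
      expect_identical(call$nterm_mismatches, as.integer(ex$best))
      expect_identical(call$nterm_nearest, paste(ex$ids, collapse = ","))
      if (length(ex$ids) >= 2) expect_match(call$flags, "ambiguous-tie")
    }
  }
})

test_that("domain calls are independent and robust to loop-3 indels", {
  # mutating only 203/251 never changes the nterm call
  q <- mutate_at(REF, c(203, 251), c("T", "A"))   # alpha -> delta
  call <- type_sequence(q, SCHEME)
  expect_identical(call$nterm, "I")
  expect_identical(call$cterm, "delta")

  # mutating only loop residues never changes the cterm call
  q2 <- mutate_at(REF, c(25, 66), c("S", "D"))
  call2 <- type_sequence(q2, SCHEME)
  expect_identical(call2$cterm, "alpha")

  # inserting/deleting k <= 2 residues inside loop 3 (outside the run)
  # leaves the calls at 175/203/251 unchanged
  for (k in 1:2) {
    ins <- paste0(substr(REF, 1, 100), strrep("G", k), substr(REF, 101, 325))
    del <- paste0(substr(REF, 1, 110), substr(REF, 111 + k, 325))
    for (q3 in c(ins, del)) {
      call3 <- type_sequence(q3, SCHEME)
      expect_identical(call3$cterm, "alpha")
      expect_identical(call3$cterm_mismatches, 0L)
    }
  }
})

test_that("the ompA1/ompA2 mapping follows the published grouping", {
  expect_identical(map_to_power_alleles(c("I", "IV", "VII")),
                   rep("ompA1", 3))
  expect_identical(map_to_power_alleles(c("II", "III")), rep("ompA2", 2))
  expect_identical(map_to_power_alleles(c("V", "VI", "novel")),
                   rep("unmapped", 3))
  calls <- tibble::tibble(nterm = c("I", "III", "V"))
  expect_identical(map_to_power_alleles(calls)$power_allele,
                   c("ompA1", "ompA2", "unmapped"))
})

test_that("batch typing handles files, duplicates, errors and empty input", {
  gs <- gen_sequences(SCHEME, n_per_allele = 1, seed = 2)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(gs$sequences, fa)
  calls <- batch_type(fa, SCHEME)
  expect_identical(nrow(calls), 7L)
  expect_identical(calls$nterm, gs$truth$nterm)
  expect_identical(calls$cterm, gs$truth$cterm)

  # repeated sequence gives identical calls
  dup <- batch_type(c(a = REF, b = REF), SCHEME)
  expect_identical(dup$nterm, c("I", "I"))
  expect_identical(dup$cterm, c("alpha", "alpha"))

  # malformed record yields a row-level error, run continues
  mixed <- batch_type(c(good = REF, bad = "NOTPROTEIN1"), SCHEME)
  expect_identical(mixed$nterm, c("I", NA_character_))
  expect_match(mixed$flags[2], "^error:")

  # empty input warns and returns an empty table
  expect_warning(empty <- batch_type(character(0), SCHEME), "no sequences")
  expect_identical(nrow(empty), 0L)

  # CSV writer emits the documented column set
  csv <- withr::local_tempfile(fileext = ".csv")
  write_allele_calls(calls, csv)
  expect_identical(
    names(readr::read_csv(csv, show_col_types = FALSE)),
    c("id", "nterm", "cterm", "nterm_mismatches", "cterm_mismatches", "flags")
  )
})
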