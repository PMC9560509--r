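# Tiny FNV-1a hash over a deparsed object, for manifest config hashes.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

default_analysis_config <- function() {
  list(
    alpha = 0.005,          # pairwise / ANOVA significance cutoff
    enrich_alpha = 1e-5,    # exact-test enrichment cutoff
    conf = 0.95,            # slope CI level
    lump_threshold = 10,    # lump alleles below this total into "other"
    min_identity = 0.70,    # typing identity floor
    pH = 8.0                # charge prediction pH
  )
}

#' Run the full analysis chain
#'
#' Orchestrates typing, segment-property prediction, phenotype statistics
#' (ANOVA + compact letter displays + property correlations), growth-rate
#' fitting and enrichment analysis over whichever inputs are supplied, and
#' writes one CSV per result plus a JSON run manifest sufficient to
#' re-execute the run.  Any stage failure aborts with the stage name.
#'
#' @param out_dir Output directory (created if needed).
#' @param sequences Optional FASTA path (or named character vector) of OmpA
#'   protein sequences to type.
#' @param phenotypes Optional tibble `allele`, `phenotype`, `replicate`,
#'   `value` of replicate measurements.
#' @param curves Optional tibble `curve_id` (or `strain`), `time_h`, `od550`.
#' @param counts Optional `count_table` for enrichment analysis.
#' @param scheme Classification scheme (default bundled).
#' @param config Named list of thresholds; see defaults in the manifest.
#' @param seed Integer seed recorded in the manifest (the stages themselves
#'   are deterministic).
#' @return Invisibly, a list of the result tibbles plus `manifest`.
#' @export
run_full_analysis <- function(out_dir,
                              sequences = NULL, phenotypes = NULL,
                              curves = NULL, counts = NULL,
                              scheme = load_scheme(),
                              config = list(), seed = 1) {
  if (is.null(sequences) && is.null(phenotypes) &&
      is.null(curves) && is.null(counts)) {
    abort("at least one input (sequences/phenotypes/curves/counts) required")
  }
  cfg <- utils::modifyList(default_analysis_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  outputs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  emit <- function(tbl, file) {
    path <- file.path(out_dir, file)
    readr::write_csv(tbl, path)
    outputs <<- c(outputs, path)
    tbl
  }

  if (!is.null(sequences)) {
    results$calls <- stage("typing", {
      calls <- batch_type(sequences, scheme, min_identity = cfg$min_identity)
      emit(map_to_power_alleles(calls), "allele_calls.csv")
    })
  }

  results$properties <- stage("properties", {
    emit(tabulate_allele_properties(scheme, pH = cfg$pH),
         "segment_properties.csv")
  })

  if (!is.null(phenotypes)) {
    results$anova <- stage("phenotype-anova", {
      phenotypes %>%
        dplyr::group_by(phenotype) %>%
        dplyr::group_modify(~ one_way_anova(.x, "value", "allele")) %>%
        dplyr::ungroup() %>%
        emit("phenotype_anova.csv")
    })
    results$letters <- stage("letter-groups", {
      phenotypes %>%
        dplyr::group_by(phenotype) %>%
        dplyr::group_modify(function(d, key) {
          lg <- pairwise_letter_groups(d, "value", "allele",
                                       alpha = cfg$alpha)
          tibble::as_tibble(lg)
        }) %>%
        dplyr::ungroup() %>%
        emit("letter_groups.csv")
    })
  }

  if (!is.null(curves)) {
    results$growth <- stage("growth", {
      idcol <- intersect(c("curve_id", "strain"), names(curves))[1]
      fits <- fit_growth_curves(curves, !!rlang::sym(idcol))
      emit(fits, "growth_fits.csv")
    })
  }

  if (!is.null(counts)) {
    results$enrichment <- stage("enrichment", {
      emit(enrichment_scan(counts, alpha = cfg$enrich_alpha),
           "enrichment.csv")
    })
  }

  manifest <- list(
    subcommand = "run-all",
    inputs = list(
      sequences = if (is.character(sequences) && length(sequences) == 1)
        sequences else if (!is.null(sequences)) "<in-memory>" else NULL,
      phenotypes = if (!is.null(phenotypes)) "<in-memory>" else NULL,
      curves = if (!is.null(curves)) "<in-memory>" else NULL,
      counts = if (!is.null(counts)) "<in-memory>" else NULL
    ),
    config = cfg,
    config_hash = config_hash(cfg),
    seed = seed,
    package_version = as.character(utils::packageVersion("ompalleles")),
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = basename(outputs)
  )
  manifest_path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  results$manifest <- manifest
  invisible(results)
}
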