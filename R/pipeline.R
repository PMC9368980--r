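#' Pipeline configuration
#'
#' Collects input locations and the analysis thresholds. Defaults are the
#' framework's standard operating point: relatedness cut `pi_hat > 0.35`,
#' drop of the 5% lowest-AN variants, population-bias and MFV percentile
#' 0.90, PS4 injection at `log2fc >= 1.5`, CADD_PHRED deleteriousness at
#' 30, gene-level FDR 0.05, and carrier-frequency support of at least 3
#' solved cases.
#'
#' @param vcf,coverage,metadata,annotations,vus Input file paths (ignored
#'   when `run_pipeline()` is given an in-memory bundle).
#' @param panels Named character vector of panel TSV paths.
#' @param exclusions Path to the actionable-gene list (optional).
#' @param out_dir Directory for stage reports and the run manifest.
#' @param pi_hat_threshold,an_drop_fraction,popbias_quantile,mfv_quantile,
#'   vus_fc_threshold,cadd_cutoff,fdr_alpha,cf_min_solved,min_depth
#'   Analysis thresholds; see Details above.
#' @param seed Integer seed recorded in the manifest (the pipeline itself
#'   is deterministic; the seed governs upstream simulation).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(vcf = NULL, coverage = NULL, metadata = NULL,
                            panels = NULL, exclusions = NULL,
                            annotations = NULL, vus = NULL,
                            out_dir = "cohortAF-results",
                            pi_hat_threshold = 0.35,
                            an_drop_fraction = 0.05,
                            popbias_quantile = 0.90,
                            mfv_quantile = 0.90,
                            vus_fc_threshold = 1.5,
                            cadd_cutoff = 30,
                            fdr_alpha = 0.05,
                            cf_min_solved = 3,
                            min_depth = 10,
                            seed = 1L) {
  check_unit <- function(x, nm, lo = 0, hi = 1, open = TRUE) {
    ok <- if (open) x > lo && x < hi else x >= lo && x <= hi
    if (!ok) abort(paste0(nm, " = ", x, " outside valid range"))
  }
  check_unit(pi_hat_threshold, "pi_hat_threshold", open = FALSE)
  check_unit(an_drop_fraction, "an_drop_fraction", hi = 1)
  check_unit(popbias_quantile, "popbias_quantile")
  check_unit(mfv_quantile, "mfv_quantile")
  check_unit(fdr_alpha, "fdr_alpha")
  stopifnot(cadd_cutoff >= 0, cf_min_solved >= 0, min_depth >= 0)
  structure(as.list(environment())[setdiff(names(formals()), "")],
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose keys are `pipeline_config()` arguments.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

write_stage <- function(tbl, path) {
  tmp <- paste0(path, ".partial")
  readr::write_tsv(tbl, tmp, progress = FALSE)
  file.rename(tmp, path)
  path
}

#' Run the full prioritization pipeline
#'
#' Executes the framework's workflow in order: relatedness QC (SNP
#' pruning, IBD, removal) -> per-subcohort frequency database -> quality
#' and population-bias variant filters -> case-versus-pseudocontrol MFV
#' prioritization with deleterious-enrichment tests -> PS4 VUS
#' reclassification -> gene prioritization -> carrier frequencies. Every
#' stage writes a TSV under `config$out_dir` and a JSON run manifest
#' records thresholds, stage counts and input checksums. A stage failure
#' aborts with the stage name; completed stage outputs are kept and the
#' failing stage's partial file keeps a `.partial` suffix.
#'
#' @param config A [pipeline_config()].
#' @param bundle Optional in-memory `cohort_bundle` (from
#'   [simulate_cohort()]); when supplied, file inputs in `config` are
#'   ignored.
#' @param solved_case_counts Optional tibble (`gene`, `n_solved`) of
#'   per-gene solved-case support for the carrier-frequency gate. When
#'   absent it is derived as the number of solved cases carrying a
#'   deleterious allele of the gene.
#' @return Invisibly, a list of the main stage results.
#' @export
run_pipeline <- function(config, bundle = NULL, solved_case_counts = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("cohortAF")),
    thresholds = config[!vapply(config, is.null, logical(1))][
      c("pi_hat_threshold", "an_drop_fraction", "popbias_quantile",
        "mfv_quantile", "vus_fc_threshold", "cadd_cutoff", "fdr_alpha",
        "cf_min_solved", "min_depth")],
    seed = config$seed)

  inputs <- stage("load", {
    if (!is.null(bundle)) {
      stopifnot(inherits(bundle, "cohort_bundle"))
      bundle
    } else {
      input_files <- c(vcf = config$vcf, coverage = config$coverage,
                       metadata = config$metadata,
                       annotations = config$annotations)
      list(calls = load_cohort(config$vcf, config$coverage,
                               min_depth = config$min_depth),
           meta = read_sample_metadata(config$metadata),
           panels = read_gene_panels(config$panels, config$exclusions),
           annotations = read_variant_annotations(config$annotations),
           vus = if (!is.null(config$vus)) read_vus_profiles(config$vus),
           checksums = as.list(tools::md5sum(unlist(input_files))))
    }
  })
  if (!is.null(inputs$checksums)) manifest$input_checksums <- inputs$checksums
  calls <- inputs$calls; meta <- inputs$meta

  ## relatedness QC
  qc <- stage("relatedness_qc", {
    snps <- prune_snps(calls)
    ibd <- estimate_ibd(calls, snps)
    removed <- drop_related(ibd, threshold = config$pi_hat_threshold)
    write_stage(ibd, file.path(config$out_dir, "ibd_pairs.tsv"))
    writeLines(removed, file.path(config$out_dir, "removed_samples.txt"))
    list(ibd = ibd, removed = removed)
  })
  if (length(qc$removed)) {
    calls <- subset_calls(calls,
                          sample_ids = setdiff(calls$samples, qc$removed))
    meta <- meta %>% filter(!(.data$sample_id %in% qc$removed))
  }
  manifest$n_samples_removed_related <- length(qc$removed)

  ## frequency database + variant-level filters
  freqs <- stage("frequency_db", {
    specs <- default_subcohorts()
    db <- build_frequency_db(calls, meta, specs)
    whole <- compute_frequencies(calls, meta, calls$samples) %>%
      mutate(subcohort = "all")
    qcf <- qc_filter_lowest_an(whole, fraction = config$an_drop_fraction)
    pop <- population_bias_filter(
      db %>% filter(.data$subcohort == "ird_solved") %>%
        semi_join(qcf$kept, by = "variant_id"),
      db %>% filter(.data$subcohort == "ird_non_solved") %>%
        semi_join(qcf$kept, by = "variant_id"),
      quantile = config$popbias_quantile)
    kept_ids <- pop$kept$variant_id
    db <- db %>% filter(.data$variant_id %in% kept_ids)
    write_stage(bind_rows(db, whole %>%
                            filter(.data$variant_id %in% kept_ids)) %>%
                  select(-"variant_id"),
                file.path(config$out_dir, "frequency_db.tsv"))
    list(db = db, n_qc_removed = nrow(qcf$removed),
         n_pop_removed = nrow(pop$removed))
  })
  manifest$n_variants_qc_removed <- freqs$n_qc_removed
  manifest$n_variants_popbias_removed <- freqs$n_pop_removed
  db <- freqs$db
  pc_freqs <- db %>% filter(.data$subcohort == "pc")
  ann <- classify_relevance(inputs$annotations,
                            cadd_cutoff = config$cadd_cutoff)
  panel_map <- inputs$panels$panels %>% select("gene", "panel")

  ## variant prioritization (MFVs + enrichment), solved and non-solved
  prior <- stage("variant_prioritization", {
    purrr::map(c(solved = "ird_solved", non_solved = "ird_non_solved"),
               function(sc) {
      fc <- fold_changes(db %>% filter(.data$subcohort == sc), pc_freqs) %>%
        select_mfv(quantile = config$mfv_quantile) %>%
        left_join(ann %>% select("variant_id", "gene", "relevance"),
                  by = "variant_id") %>%
        left_join(panel_map, by = "gene") %>%
        mutate(panel = dplyr::coalesce(.data$panel, "none"))
      enr <- enrichment_test(fc)
      write_stage(fc %>% select(-"pc_af_adj"),
                  file.path(config$out_dir,
                            paste0("variant_prioritization_", sc, ".tsv")))
      list(fc = fc, enrichment = enr, threshold = mfv_threshold(fc))
    })
  })
  manifest$mfv_thresholds <- purrr::map(prior, "threshold")

  ## VUS reclassification with PS4 (general case cohort vs pseudocontrols)
  vus_res <- stage("acmg_reclassification", {
    if (is.null(inputs$vus) || nrow(inputs$vus) == 0) NULL else {
      vus <- inputs$vus
      if ("variant_id" %in% names(vus)) {
        fc_all <- fold_changes(db %>% filter(.data$subcohort == "ird_all"),
                               pc_freqs)
        vus <- vus %>%
          select(-"log2fc") %>%
          left_join(fc_all %>% select("variant_id", "log2fc"),
                    by = "variant_id") %>%
          filter(!is.na(.data$log2fc))
      }
      res <- batch_reclassify(vus, fc_threshold = config$vus_fc_threshold)
      write_stage(tidy(res),
                  file.path(config$out_dir, "vus_reclassification.tsv"))
      res
    }
  })
  if (!is.null(vus_res)) manifest$vus_summary <- as.list(glance(vus_res))

  ## gene prioritization on the non-solved comparison
  genes_res <- stage("gene_prioritization", {
    gp <- prioritize_genes(prior$non_solved$fc, ann, inputs$panels,
                           alpha = config$fdr_alpha)
    write_stage(as_tibble(gp),
                file.path(config$out_dir, "gene_prioritization.tsv"))
    gp
  })
  manifest$n_genes_significant <- sum(genes_res$significant)

  ## carrier frequencies
  cf_res <- stage("carrier_frequency", {
    if (is.null(solved_case_counts)) {
      solved_ids <- subcohort_samples(meta, default_subcohorts()$ird_solved)
      del_ids <- ann$variant_id[ann$relevance == "deleterious"]
      carriers <- calls$genotype[
        intersect(del_ids, calls$variants$variant_id),
        intersect(solved_ids, calls$samples), drop = FALSE]
      per_var <- rowSums(carriers > 0, na.rm = TRUE)
      solved_case_counts <- tibble(variant_id = names(per_var),
                                   n = per_var) %>%
        inner_join(ann %>% select("variant_id", "gene"), by = "variant_id") %>%
        group_by(.data$gene) %>%
        summarise(n_solved = sum(.data$n), .groups = "drop")
    }
    male_ids <- meta$sample_id[!is.na(meta$sex) & meta$sex == "male" &
                                 meta$disease_group == "NRD"]
    pc_male <- if (length(male_ids)) {
      compute_frequencies(calls, meta, male_ids)
    }
    cf <- carrier_frequency_report(ann, inputs$panels, pc_freqs,
                                   solved_case_counts,
                                   pc_freqs_male = pc_male,
                                   min_solved = config$cf_min_solved,
                                   cadd_cutoff = config$cadd_cutoff)
    write_stage(cf %>%
                  mutate(included_variants = purrr::map_chr(
                    .data$included_variants, paste, collapse = ",")),
                file.path(config$out_dir, "carrier_frequency.tsv"))
    cf
  })

  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(qc = qc, frequency_db = db, prioritization = prior,
                 vus = vus_res, genes = genes_res, carrier = cf_res,
                 manifest = manifest))
}
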