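#' Configuration for the synthetic cohort generator
#'
#' Captures the statistical structure the pipeline assumes: subcohort
#' sample counts (defaults follow the heterogeneous clinical-exome cohort
#' the framework targets: 955 solved + 811 non-solved disease cases, 386
#' other eye-related and 3531 non-related disease samples), gene panels
#' with inheritance modes, per-variant base allele frequencies drawn from
#' a scaled beta (low-frequency) distribution, a block of common SNPs for
#' relatedness estimation, planted case-enriched variants, planted
#' duplicate/parent-child samples, coverage dropout and an annotation
#' label mix.
#'
#' @param n_ird_solved,n_ird_nonsolved,n_oerd,n_nrd Subcohort sample
#'   counts.
#' @param n_genes Named integer vector: genes per panel.
#' @param variants_per_gene Rare variants simulated per gene.
#' @param base_af_shape1,base_af_shape2,base_af_scale Parameters of the
#'   scaled beta base-AF distribution (`rbeta(shape1, shape2) * scale`).
#' @param n_common_snps Common biallelic SNVs (AF uniform on
#'   `[0.1, 0.5]`) spread over the genes, the substrate for IBD pruning.
#' @param ld_block_size,ld_r With `ld_block_size > 1`, consecutive common
#'   SNPs form copula blocks: each non-leading SNP copies the leading
#'   SNP's genotype per sample with probability `ld_r`.
#' @param planted_enrichments Tibble with columns `gene`, `n_variants`,
#'   `multiplier` (>= 1, case AF multiplier), `relevance`
#'   (deleterious/benign).
#' @param coverage_dropout Per-site, per-sample probability of a
#'   non-callable cell.
#' @param n_duplicates,n_parent_child Planted related sample pairs.
#' @param clinvar_mix Named proportions over the ClinVar vocabulary for
#'   unplanted variants (must sum to 1).
#' @param p_cadd_high Probability an unplanted variant draws a CADD_PHRED
#'   in `[30, 50]` rather than `[0, 30)`.
#' @param consequence_mix Named proportions over consequence classes.
#' @param subphenotype_mix Named proportions over disease sub-phenotypes
#'   for case samples.
#' @param n_x_genes Number of IRD-panel genes placed on chromosome X.
#' @param n_vus Curated-VUS rows generated for the reclassification stage.
#' @param seed Integer seed; the whole bundle is a pure function of the
#'   config.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_ird_solved = 955, n_ird_nonsolved = 811,
                       n_oerd = 386, n_nrd = 3531,
                       n_genes = c(IRD = 20, OERD = 30, NRD = 50),
                       variants_per_gene = 10,
                       base_af_shape1 = 0.6, base_af_shape2 = 12,
                       base_af_scale = 0.3,
                       n_common_snps = 2000,
                       ld_block_size = 1, ld_r = 0.9,
                       planted_enrichments = NULL,
                       coverage_dropout = 0.02,
                       n_duplicates = 0, n_parent_child = 0,
                       clinvar_mix = c(pathogenic = 0.01,
                                       likely_pathogenic = 0.01,
                                       benign = 0.04, likely_benign = 0.06,
                                       vus = 0.04, conflicting = 0.04,
                                       missing = 0.80),
                       p_cadd_high = 0.02,
                       consequence_mix = c(intronic = 0.63, missense = 0.13,
                                           synonymous = 0.09, splice = 0.03,
                                           frameshift = 0.02,
                                           stop_gain = 0.02, other = 0.08),
                       subphenotype_mix = c(syndromic = 0.30,
                                            non_syndromic = 0.55,
                                            macular_dystrophy = 0.15),
                       n_x_genes = 1, n_vus = 10, seed = 1L) {
  stopifnot(all(c(n_ird_solved, n_ird_nonsolved, n_oerd, n_nrd) >= 0),
            all(n_genes >= 0), variants_per_gene >= 0,
            coverage_dropout >= 0, coverage_dropout < 1,
            abs(sum(clinvar_mix) - 1) < 1e-8,
            abs(sum(consequence_mix) - 1) < 1e-8,
            abs(sum(subphenotype_mix) - 1) < 1e-8)
  if (!is.null(planted_enrichments)) {
    planted_enrichments <- as_tibble(planted_enrichments)
    stopifnot(all(c("gene", "n_variants", "multiplier", "relevance") %in%
                    names(planted_enrichments)),
              all(planted_enrichments$multiplier >= 1))
  }
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

sample_levels <- function(n, mix) {
  sample(names(mix), n, replace = TRUE, prob = mix)
}

#' Simulate a complete synthetic cohort bundle
#'
#' Draws genotypes per variant under Hardy-Weinberg equilibrium at the
#' variant's subcohort-specific allele frequency: every variant has a base
#' AF shared by all samples except that planted case-enriched variants use
#' `base AF * multiplier` (clipped at 0.95 with a warning) in the disease
#' subcohort. Duplicate samples copy genotypes exactly; parent-child pairs
#' transmit one allele. Coverage dropout marks cells non-callable
#' (genotype missing). Companion tables — sample metadata, gene panels
#' with inheritance, per-variant annotations (ClinVar/CADD/consequence/
#' LOVD), and a curated-VUS table — are generated alongside. Fully
#' reproducible given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `cohort_bundle` list: `calls` ([cohort_calls()]), `meta`,
#'   `panels` ([gene_panels()]), `annotations`, `vus`, `truth` (see
#'   [truth_table()]), `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  ## ---- samples and metadata
  n_ird <- cfg$n_ird_solved + cfg$n_ird_nonsolved
  n_all <- n_ird + cfg$n_oerd + cfg$n_nrd
  ids <- sprintf("S%05d", seq_len(n_all))
  meta <- tibble(
    sample_id = ids,
    disease_group = rep(c("IRD", "OERD", "NRD"),
                        times = c(n_ird, cfg$n_oerd, cfg$n_nrd)),
    diag_status = c(rep("solved", cfg$n_ird_solved),
                    rep("non_solved", cfg$n_ird_nonsolved),
                    rep("not_applicable", cfg$n_oerd + cfg$n_nrd)),
    subphenotype = c(sample_levels(n_ird, cfg$subphenotype_mix),
                     rep(NA_character_, cfg$n_oerd + cfg$n_nrd)),
    sex = sample(c("male", "female"), n_all, replace = TRUE)
  )
  is_case <- meta$disease_group == "IRD"

  ## ---- gene panels
  panel_tabs <- purrr::imap(as.list(cfg$n_genes), function(ng, pnl) {
    if (ng == 0) return(NULL)
    tibble(gene = sprintf("%sG%03d", pnl, seq_len(ng)), panel = pnl,
           inheritance = sample(c("recessive", "dominant", "r_or_d",
                                  "x_linked", "undetermined"),
                                ng, replace = TRUE,
                                prob = c(0.5, 0.3, 0.08, 0.04, 0.08)),
           subpanel = if (pnl == "IRD") {
             sample(c("syndromic", "non_syndromic", "both"), ng,
                    replace = TRUE, prob = c(0.45, 0.45, 0.1))
           } else NA_character_)
  })
  panel_df <- bind_rows(panel_tabs)
  # chromosome assignment; optionally put leading IRD genes on X
  panel_df$chrom <- paste0("chr", rep_len(1:22, nrow(panel_df)))
  if (cfg$n_x_genes > 0 && any(panel_df$panel == "IRD")) {
    xi <- which(panel_df$panel == "IRD")[seq_len(min(cfg$n_x_genes,
                                                     sum(panel_df$panel == "IRD")))]
    panel_df$chrom[xi] <- "X"
    panel_df$inheritance[xi] <- "x_linked"
  }
  panels <- gene_panels(panel_df[, c("gene", "panel", "inheritance",
                                     "subpanel")])

  ## ---- variant table: rare variants per gene + common SNPs
  bases <- c("A", "C", "G", "T")
  mk_alleles <- function(n) {
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    list(ref = ref, alt = alt)
  }
  rare <- purrr::map_dfr(seq_len(nrow(panel_df)), function(gi) {
    nv <- cfg$variants_per_gene
    if (nv == 0) return(NULL)
    al <- mk_alleles(nv)
    tibble(gene = panel_df$gene[gi], chrom = panel_df$chrom[gi],
           pos = sort(sample.int(1e6, nv)) + gi * 2e6,
           ref = al$ref, alt = al$alt,
           base_af = rbeta(nv, cfg$base_af_shape1, cfg$base_af_shape2) *
             cfg$base_af_scale,
           common = FALSE)
  })
  common <- NULL
  if (cfg$n_common_snps > 0) {
    gidx <- rep_len(seq_len(nrow(panel_df)), cfg$n_common_snps)
    al <- mk_alleles(cfg$n_common_snps)
    common <- tibble(gene = panel_df$gene[gidx], chrom = panel_df$chrom[gidx],
                     pos = sample.int(1e6, cfg$n_common_snps) + gidx * 2e6 + 1e6,
                     ref = al$ref, alt = al$alt,
                     base_af = runif(cfg$n_common_snps, 0.1, 0.5),
                     common = TRUE)
  }
  variants <- bind_rows(rare, common) %>%
    arrange(.data$chrom, .data$pos) %>%
    mutate(variant_id = variant_id(.data$chrom, .data$pos, .data$ref,
                                   .data$alt))
  nv <- nrow(variants)

  ## ---- planted enrichments
  variants$case_af <- variants$base_af
  variants$planted <- FALSE
  variants$relevance_truth <- NA_character_
  variants$multiplier <- 1
  if (!is.null(cfg$planted_enrichments)) {
    for (r in seq_len(nrow(cfg$planted_enrichments))) {
      pe <- cfg$planted_enrichments[r, ]
      cand <- which(variants$gene == pe$gene & !variants$common &
                      !variants$planted)
      if (length(cand) < pe$n_variants) {
        abort(paste0("gene '", pe$gene, "' has too few free variants to plant"))
      }
      pick <- cand[seq_len(pe$n_variants)]
      target <- variants$base_af[pick] * pe$multiplier
      if (any(target > 0.95)) {
        warn("planted case AF clipped at 0.95")
        target <- pmin(target, 0.95)
      }
      variants$case_af[pick] <- target
      variants$planted[pick] <- TRUE
      variants$relevance_truth[pick] <- pe$relevance
      variants$multiplier[pick] <- pe$multiplier
    }
  }

  ## ---- genotypes under HWE, per subcohort AF
  male <- meta$sex == "male"
  on_x <- variants$chrom %in% .x_chroms
  geno <- matrix(0L, nv, n_all)
  for (i in seq_len(nv)) {
    p_case <- variants$case_af[i]; p_ctrl <- variants$base_af[i]
    p_vec <- ifelse(is_case, p_case, p_ctrl)
    ploidy <- if (on_x[i]) ifelse(male, 1L, 2L) else rep(2L, n_all)
    geno[i, ] <- rbinom(n_all, ploidy, p_vec)
  }
  # LD copula blocks over common SNPs (genome order within chromosome)
  if (cfg$ld_block_size > 1 && !is.null(common)) {
    ci <- which(variants$common)
    blocks <- split(ci, ceiling(seq_along(ci) / cfg$ld_block_size))
    for (b in blocks) {
      if (length(b) < 2) next
      lead <- b[1]
      for (f in b[-1]) {
        copy <- runif(n_all) < cfg$ld_r
        geno[f, copy] <- geno[lead, copy]
      }
    }
  }

  ## ---- planted relatives appended as extra samples
  truth_rel <- NULL
  extra_ids <- character(); extra_geno <- NULL; extra_meta <- NULL
  add_sample <- function(g, m) {
    extra_geno <<- cbind(extra_geno, g)
    extra_meta <<- bind_rows(extra_meta, m)
    extra_ids <<- c(extra_ids, m$sample_id)
  }
  if (cfg$n_duplicates > 0) {
    src <- sample(ids, cfg$n_duplicates)
    for (k in seq_len(cfg$n_duplicates)) {
      sid <- paste0(src[k], "_dup")
      add_sample(geno[, match(src[k], ids)],
                 meta[match(src[k], ids), ] %>% mutate(sample_id = sid))
      truth_rel <- bind_rows(truth_rel,
                             tibble(relationship = "duplicate",
                                    sample1 = src[k], sample2 = sid,
                                    expected_pi_hat = 1))
    }
  }
  if (cfg$n_parent_child > 0) {
    src <- sample(setdiff(ids, sub("_dup$", "", extra_ids)),
                  cfg$n_parent_child)
    for (k in seq_len(cfg$n_parent_child)) {
      pidx <- match(src[k], ids)
      parent <- geno[, pidx]
      p_vec <- ifelse(is_case[pidx], variants$case_af, variants$base_af)
      transmitted <- rbinom(nv, 1, parent / 2)
      other <- rbinom(nv, 1, p_vec)
      child <- transmitted + other
      if (any(on_x)) child[on_x] <- pmin(child[on_x], 2L)
      sid <- paste0(src[k], "_kid")
      add_sample(as.integer(child),
                 meta[pidx, ] %>% mutate(sample_id = sid,
                                         sex = sample(c("male", "female"), 1)))
      truth_rel <- bind_rows(truth_rel,
                             tibble(relationship = "parent_child",
                                    sample1 = src[k], sample2 = sid,
                                    expected_pi_hat = 0.5))
    }
  }
  if (length(extra_ids)) {
    geno <- cbind(geno, extra_geno)
    meta <- bind_rows(meta, extra_meta)
  }

  ## ---- coverage dropout
  covered <- matrix(runif(length(geno)) >= cfg$coverage_dropout,
                    nrow(geno), ncol(geno))
  calls <- cohort_calls(variants[, c("chrom", "pos", "ref", "alt")],
                        meta$sample_id, geno, covered)

  ## ---- annotations
  n_rare <- sum(!variants$common)
  ann <- variants %>%
    select("chrom", "pos", "ref", "alt", "gene", "variant_id", "common",
           "planted", "relevance_truth") %>%
    mutate(clinvar = ifelse(.data$common, "missing",
                            sample_levels(nv, cfg$clinvar_mix)),
           cadd_phred = ifelse(
             !.data$common & runif(nv) < cfg$p_cadd_high,
             runif(nv, 30, 50), runif(nv, 0, 29.9)),
           consequence = ifelse(.data$common,
                                sample(c("intronic", "synonymous"), nv,
                                       replace = TRUE),
                                sample_levels(nv, cfg$consequence_mix)),
           lovd = "missing")
  # planted labels override the mix so truth matches the classifier
  del <- which(ann$planted & ann$relevance_truth == "deleterious")
  if (length(del)) {
    via_clinvar <- runif(length(del)) < 0.5
    ann$clinvar[del[via_clinvar]] <- sample(c("pathogenic",
                                              "likely_pathogenic"),
                                            sum(via_clinvar), replace = TRUE)
    ann$clinvar[del[!via_clinvar]] <- "missing"
    ann$cadd_phred[del[!via_clinvar]] <- runif(sum(!via_clinvar), 30, 50)
    ann$cadd_phred[del[via_clinvar]] <- runif(sum(via_clinvar), 0, 29.9)
  }
  ben <- which(ann$planted & ann$relevance_truth == "benign")
  if (length(ben)) {
    ann$clinvar[ben] <- sample(c("benign", "likely_benign"), length(ben),
                               replace = TRUE)
    ann$cadd_phred[ben] <- runif(length(ben), 0, 29.9)
  }
  annotations <- validate_annotations(
    ann %>% select("chrom", "pos", "ref", "alt", "gene", "clinvar",
                   "cadd_phred", "consequence", "lovd"))

  ## ---- curated-VUS table for the reclassification stage
  vus_pool <- which(ann$clinvar == "vus" & !ann$common)
  n_vus <- min(cfg$n_vus, length(vus_pool))
  vus <- if (n_vus > 0) {
    pick <- sample(vus_pool, n_vus)
    tibble(gene = ann$gene[pick],
           hgvs = ann$variant_id[pick],
           variant_id = ann$variant_id[pick],
           inheritance = sample(c("AR", "AD", "AR_AD", "XL"), n_vus,
                                replace = TRUE, prob = c(.55, .3, .1, .05)),
           log2fc = NA_real_,
           criteria = purrr::map(seq_len(n_vus), function(i) {
             sample(list(c("PM2"), c("PM2", "PP3"), c("PM2", "BP4"),
                         c("PM1", "PM2")), 1)[[1]]
           }))
  } else {
    tibble(gene = character(), hgvs = character(), variant_id = character(),
           inheritance = character(), log2fc = numeric(),
           criteria = list())
  }

  truth <- list(
    planted_variants = variants %>%
      filter(.data$planted) %>%
      select("variant_id", "gene", "base_af", "case_af", "multiplier",
             relevance = "relevance_truth") %>%
      mutate(expected_log2fc = log2(.data$case_af / .data$base_af)),
    related_pairs = truth_rel %||%
      tibble(relationship = character(), sample1 = character(),
             sample2 = character(), expected_pi_hat = numeric()),
    planted_genes = if (is.null(cfg$planted_enrichments)) {
      character()
    } else {
      unique(cfg$planted_enrichments$gene[
        cfg$planted_enrichments$relevance == "deleterious"])
    }
  )

  structure(list(calls = calls, meta = meta, panels = panels,
                 annotations = annotations, vus = vus, truth = truth,
                 config = cfg),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle>\n")
  print(x$calls)
  print(count(x$meta, .data$disease_group, .data$diag_status))
  invisible(x)
}

#' Planted-truth table of a simulated bundle
#'
#' Machine-readable record of everything the generator planted — enriched
#' variants with their expected log2 fold change, related sample pairs
#' with their expected genome-sharing `pi_hat`, and the planted genes —
#' for recovery scoring of the pipeline.
#'
#' @param bundle A `cohort_bundle` from [simulate_cohort()].
#' @return A list of tibbles `planted_variants`, `related_pairs`, and the
#'   `planted_genes` character vector.
#' @export
truth_table <- function(bundle) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  bundle$truth
}

#' Write a simulated bundle to disk in the pipeline's input formats
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             coverage = file.path(dir, "coverage.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             vus = file.path(dir, "curated_vus.tsv"),
             truth = file.path(dir, "truth_planted_variants.tsv"))
  write_cohort(bundle$calls, paths["vcf"], paths["coverage"])
  readr::write_tsv(bundle$meta, paths["metadata"], progress = FALSE)
  readr::write_tsv(bundle$annotations %>% select(-"variant_id"),
                   paths["annotations"], progress = FALSE)
  readr::write_tsv(bundle$vus %>%
                     mutate(criteria = purrr::map_chr(.data$criteria, paste,
                                                      collapse = ",")),
                   paths["vus"], progress = FALSE)
  readr::write_tsv(bundle$truth$planted_variants, paths["truth"],
                   progress = FALSE)
  for (p in unique(bundle$panels$panels$panel)) {
    fp <- file.path(dir, paste0("panel_", p, ".tsv"))
    readr::write_tsv(bundle$panels$panels %>% filter(.data$panel == p) %>%
                       select(-"panel"),
                     fp, progress = FALSE)
    paths[paste0("panel_", p)] <- fp
  }
  invisible(paths)
}
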