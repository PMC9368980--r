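#' Load a merged multi-sample cohort from VCF plus coverage
#'
#' Reads a multi-sample VCF (v4.2, GT field required) and a per-sample
#' coverage source, splits multiallelic records into one biallelic key per
#' alternate allele, and returns the genotype/callability matrices.
#' Input is assumed normalized; no left-realignment is performed.
#'
#' Dosage is the per-sample count of the record's alternate allele in the GT
#' field (unphased or phased); a GT containing `.` is missing. Haploid GT
#' values (e.g. male X) yield dosage 0/1. Sites with depth below `min_depth`
#' (or outside a sample's callable intervals) are marked `covered = FALSE`
#' and their genotypes set to missing.
#'
#' @param vcf_path Path to a VCF file (may be bgzipped).
#' @param coverage_path Path to a coverage table: either a wide per-site
#'   depth TSV (`chrom`, `pos`, then one integer column per sample) or a
#'   callable-intervals TSV (`sample_id`, `chrom`, `start`, `end`, 1-based
#'   inclusive).
#' @param min_depth Depth at or above which a site counts as callable
#'   (default 10); only used with the per-site depth format.
#' @return A [cohort_calls()] object.
#' @export
load_cohort <- function(vcf_path, coverage_path, min_depth = 10) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("VCF contains no variant records")
  gt_raw <- vcf@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2) {
    abort("VCF has no sample genotype columns")
  }
  fmt <- gt_raw[, 1]
  samples <- colnames(gt_raw)[-1]
  gt_idx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(x) match("GT", x), integer(1))
  if (anyNA(gt_idx)) {
    abort(paste0("malformed VCF: record ", which(is.na(gt_idx))[1],
                 " has no GT in FORMAT"))
  }
  gt <- matrix(NA_character_, nrow(gt_raw), length(samples))
  for (j in seq_along(samples)) {
    cells <- strsplit(gt_raw[, j + 1], ":", fixed = TRUE)
    gt[, j] <- vapply(seq_along(cells), function(i) {
      v <- cells[[i]]
      if (gt_idx[i] > length(v)) "." else v[gt_idx[i]]
    }, character(1))
  }

  # split multiallelic records: one key per alt, per-alt dosage
  out_var <- list(); out_geno <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    toks <- strsplit(gt[i, ], "[/|]")
    for (k in seq_along(alts)) {
      dos <- vapply(toks, function(tt) {
        if (length(tt) == 0 || anyNA(tt) || any(tt == "."))
          return(NA_integer_)
        a <- suppressWarnings(as.integer(tt))
        if (anyNA(a)) return(NA_integer_)
        sum(a == k)
      }, integer(1))
      out_var[[length(out_var) + 1L]] <-
        tibble(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
               ref = fix$REF[i], alt = alts[k])
      out_geno[[length(out_geno) + 1L]] <- dos
    }
  }
  variants <- bind_rows(out_var)
  genotype <- do.call(rbind, out_geno)

  covered <- read_coverage_matrix(coverage_path, variants, samples, min_depth)
  cohort_calls(variants, samples, genotype, covered)
}

read_coverage_matrix <- function(path, variants, samples, min_depth) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (all(c("sample_id", "chrom", "start", "end") %in% names(tab))) {
    covered <- matrix(FALSE, nrow(variants), length(samples))
    missing_s <- setdiff(samples, unique(tab$sample_id))
    if (length(missing_s)) {
      abort(paste("coverage file lacks samples present in VCF:",
                  paste(missing_s, collapse = ", ")))
    }
    for (j in seq_along(samples)) {
      iv <- tab[tab$sample_id == samples[j], , drop = FALSE]
      for (cc in unique(variants$chrom)) {
        vi <- which(variants$chrom == cc)
        ivc <- iv[iv$chrom == cc, , drop = FALSE]
        if (nrow(ivc) == 0) next
        hit <- vapply(variants$pos[vi], function(p) {
          any(ivc$start <= p & p <= ivc$end)
        }, logical(1))
        covered[vi, j] <- hit
      }
    }
    return(covered)
  }
  if (!all(c("chrom", "pos") %in% names(tab))) {
    abort("coverage table must be per-site depth (chrom, pos, <samples>) or intervals (sample_id, chrom, start, end)")
  }
  depth_samples <- setdiff(names(tab), c("chrom", "pos"))
  if (!setequal(depth_samples, samples)) {
    abort(paste0("sample sets of VCF and coverage disagree: VCF-only {",
                 paste(setdiff(samples, depth_samples), collapse = ","),
                 "}, coverage-only {",
                 paste(setdiff(depth_samples, samples), collapse = ","), "}"))
  }
  key <- paste(tab$chrom, tab$pos)
  idx <- match(paste(variants$chrom, variants$pos), key)
  if (anyNA(idx)) {
    abort(paste("coverage table lacks", sum(is.na(idx)), "variant site(s)"))
  }
  depth <- as.matrix(tab[idx, samples, drop = FALSE])
  storage.mode(depth) <- "double"
  depth >= min_depth
}

#' Write a cohort call set to VCF plus a per-site depth table
#'
#' The inverse of [load_cohort()]: variants are written one biallelic record
#' per row (GT-only FORMAT) together with a wide depth TSV in which callable
#' cells receive `depth` and non-callable cells 0, so a round trip through
#' [load_cohort()] reproduces the matrices.
#'
#' @param calls A [cohort_calls()] object.
#' @param vcf_path,coverage_path Output paths.
#' @param depth Depth written for callable cells (default 30).
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(calls, vcf_path, coverage_path, depth = 30) {
  stopifnot(inherits(calls, "cohort_calls"))
  gt_str <- matrix("./.", nrow(calls$genotype), ncol(calls$genotype))
  gt_str[calls$genotype == 0L] <- "0/0"
  gt_str[calls$genotype == 1L] <- "0/1"
  gt_str[calls$genotype == 2L] <- "1/1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", calls$samples), collapse = "\t")
  )
  body <- paste(calls$variants$chrom, calls$variants$pos, ".",
                calls$variants$ref, calls$variants$alt, ".", "PASS", ".",
                "GT", apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), vcf_path)
  dp <- matrix(0L, nrow(calls$covered), ncol(calls$covered))
  dp[calls$covered] <- as.integer(depth)
  cov <- cbind(calls$variants[, c("chrom", "pos")],
               as.data.frame(dp) %>% setNames(calls$samples)) %>%
    distinct(.data$chrom, .data$pos, .keep_all = TRUE)
  readr::write_tsv(cov, coverage_path, progress = FALSE)
  invisible(c(vcf_path, coverage_path))
}

#' Read and validate the sample metadata table
#'
#' @param path TSV with header; required columns `sample_id`,
#'   `disease_group` (IRD/OERD/NRD), `diag_status`; optional `subphenotype`
#'   and `sex`.
#' @return A tibble of validated sample metadata.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_metadata(meta)
}

#' @rdname read_sample_metadata
#' @param meta A data frame of sample metadata to validate in place.
#' @export
validate_sample_metadata <- function(meta) {
  meta <- as_tibble(meta)
  req <- c("sample_id", "disease_group", "diag_status")
  if (nrow(meta) == 0) {
    warn("empty sample metadata table")
    missing_cols <- setdiff(c(req, "subphenotype", "sex"), names(meta))
    for (mc in missing_cols) meta[[mc]] <- character(0)
    return(meta)
  }
  if (!all(req %in% names(meta))) {
    abort(paste("metadata must have columns:", paste(req, collapse = ", ")))
  }
  if (!"subphenotype" %in% names(meta)) meta$subphenotype <- NA_character_
  if (!"sex" %in% names(meta)) meta$sex <- NA_character_
  if (anyDuplicated(meta$sample_id)) {
    abort(paste("duplicate sample_id:",
                paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
                      collapse = ", ")))
  }
  bad <- setdiff(unique(meta$disease_group), .disease_groups)
  if (length(bad)) abort(paste("unknown disease_group value(s):",
                               paste(bad, collapse = ", ")))
  bad <- setdiff(unique(meta$diag_status), .diag_statuses)
  if (length(bad)) abort(paste("unknown diag_status value(s):",
                               paste(bad, collapse = ", ")))
  bad <- setdiff(unique(meta$subphenotype[!is.na(meta$subphenotype)]),
                 .subphenotypes)
  if (length(bad)) abort(paste("unknown subphenotype value(s):",
                               paste(bad, collapse = ", ")))
  off <- meta$disease_group != "IRD" & meta$diag_status != "not_applicable"
  if (any(off)) {
    abort(paste("diag_status other than not_applicable outside IRD for:",
                paste(meta$sample_id[off], collapse = ", ")))
  }
  meta
}

#' Assemble gene panels with actionable-gene exclusions
#'
#' Panels are disjoint gene sets for the disease subcohort (IRD), other
#' related phenotypes (OERD) and unrelated diseases (NRD). Genes on the
#' actionable (secondary-findings) exclusion list are removed from every
#' panel unless they appear in `exceptions` (e.g. RPE65, an actionable gene
#' that is itself a retinal-dystrophy gene).
#'
#' @param panels A data frame with columns `gene`, `panel` (IRD/OERD/NRD),
#'   and optionally `inheritance` (recessive/dominant/r_or_d/x_linked/
#'   undetermined) and `subpanel` (`syndromic`/`non_syndromic`/`both`, IRD
#'   panel only).
#' @param exclusions Character vector of actionable genes to drop.
#' @param exceptions Character vector of genes retained despite exclusion.
#' @return A `gene_panels` object.
#' @export
gene_panels <- function(panels, exclusions = character(),
                        exceptions = character()) {
  panels <- as_tibble(panels)
  if (!all(c("gene", "panel") %in% names(panels))) {
    abort("panels need columns gene, panel")
  }
  if (!"inheritance" %in% names(panels)) panels$inheritance <- "undetermined"
  if (!"subpanel" %in% names(panels)) panels$subpanel <- NA_character_
  bad <- setdiff(unique(panels$panel), .disease_groups)
  if (length(bad)) abort(paste("unknown panel:", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(panels$inheritance), .inheritances)
  if (length(bad)) abort(paste("unknown inheritance:",
                               paste(bad, collapse = ", ")))
  dup <- panels %>% distinct(.data$gene, .data$panel) %>% count(.data$gene) %>%
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste("gene(s) in more than one panel:",
                paste(dup$gene, collapse = ", ")))
  }
  drop <- setdiff(exclusions, exceptions)
  panels <- panels %>% filter(!(.data$gene %in% drop))
  structure(list(panels = panels,
                 exclusions = unique(exclusions),
                 exceptions = unique(exceptions)),
            class = "gene_panels")
}

#' @export
print.gene_panels <- function(x, ...) {
  cat("<gene_panels>\n")
  print(count(x$panels, .data$panel))
  cat("excluded actionable genes:", length(x$exclusions),
      "(exceptions:", paste(x$exceptions, collapse = ", "), ")\n")
  invisible(x)
}

#' Read gene panels from TSV files
#'
#' @param panel_paths Named character vector/list of TSV paths; names are
#'   panel labels (IRD/OERD/NRD). Each file needs a `gene` column and may
#'   carry `inheritance` and `subpanel` columns.
#' @param exclusions_path Optional path to the actionable-gene list (one
#'   symbol per line, or TSV with a `gene` column).
#' @param exceptions Genes kept in their panel despite being on the
#'   exclusion list. Default `"RPE65"`.
#' @return A `gene_panels` object.
#' @export
read_gene_panels <- function(panel_paths, exclusions_path = NULL,
                             exceptions = "RPE65") {
  stopifnot(length(names(panel_paths)) == length(panel_paths))
  tabs <- purrr::imap(as.list(panel_paths), function(p, nm) {
    tab <- readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
    tab$panel <- nm
    tab
  })
  panels <- bind_rows(tabs)
  exclusions <- character()
  if (!is.null(exclusions_path)) {
    first <- readLines(exclusions_path, n = 1)
    if (identical(first, "gene") || grepl("\t", first)) {
      exclusions <- readr::read_tsv(exclusions_path, show_col_types = FALSE,
                                    progress = FALSE)$gene
    } else {
      exclusions <- readLines(exclusions_path)
    }
    exclusions <- exclusions[nzchar(exclusions)]
  }
  gene_panels(panels, exclusions, exceptions)
}

#' Read the per-variant annotation table
#'
#' One record per variant: gene symbol, ClinVar assertion, CADD_PHRED score,
#' consequence class and an optional LOVD assertion. Absent ClinVar/LOVD
#' values are normalized to `"missing"`.
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `clinvar`, `cadd_phred`, `consequence`, and optionally `lovd`.
#' @return A tibble keyed by `variant_id`.
#' @export
read_variant_annotations <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_annotations(ann)
}

#' @rdname read_variant_annotations
#' @param ann A data frame of annotations to validate in place.
#' @export
validate_annotations <- function(ann) {
  ann <- as_tibble(ann)
  req <- c("chrom", "pos", "ref", "alt", "gene", "clinvar", "cadd_phred",
           "consequence")
  if (!all(req %in% names(ann))) {
    abort(paste("annotations must have columns:", paste(req, collapse = ", ")))
  }
  if (!"lovd" %in% names(ann)) ann$lovd <- "missing"
  ann <- ann %>%
    mutate(clinvar = dplyr::coalesce(as.character(.data$clinvar), "missing"),
           lovd = dplyr::coalesce(as.character(.data$lovd), "missing"),
           variant_id = variant_id(.data$chrom, .data$pos, .data$ref, .data$alt))
  for (col in c("clinvar", "lovd")) {
    bad <- setdiff(unique(ann[[col]]), .clinvar_levels)
    if (length(bad)) abort(paste0("unknown ", col, " value(s): ",
                                  paste(bad, collapse = ", ")))
  }
  bad <- setdiff(unique(ann$consequence), .consequences)
  if (length(bad)) abort(paste("unknown consequence value(s):",
                               paste(bad, collapse = ", ")))
  if (any(!is.na(ann$cadd_phred) & ann$cadd_phred < 0)) {
    abort("cadd_phred must be non-negative")
  }
  if (anyDuplicated(ann$variant_id)) {
    abort("more than one annotation record for a variant")
  }
  ann
}

#' Read a curated VUS evidence table
#'
#' Each row is a variant of uncertain significance with its previously
#' asserted ACMG evidence codes and its case-versus-pseudocontrol log2 fold
#' change, ready for PS4 injection via [batch_reclassify()].
#'
#' @param path TSV with columns `gene`, `inheritance` (AR/AD/AR_AD/XL),
#'   `log2fc`, `criteria` (comma-separated ACMG codes; empty for none), and
#'   optionally `hgvs`.
#' @return A tibble with `criteria` parsed into a list-column of code vectors.
#' @export
read_vus_profiles <- function(path) {
  vus <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("gene", "inheritance", "log2fc", "criteria")
  if (!all(req %in% names(vus))) {
    abort(paste("VUS table must have columns:", paste(req, collapse = ", ")))
  }
  bad <- setdiff(unique(vus$inheritance), c("AR", "AD", "AR_AD", "XL"))
  if (length(bad)) abort(paste("unknown inheritance:",
                               paste(bad, collapse = ", ")))
  vus %>%
    mutate(criteria = purrr::map(.data$criteria, function(x) {
      if (is.na(x) || !nzchar(x)) return(character())
      toks <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
      toks[nzchar(toks)]
    }))
}
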