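write_vcf_text <- function(records, samples) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}

write_depth_text <- function(tbl) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(tbl, path, progress = FALSE)
  path
}

test_that("GT decoding, coverage masking and haploid GT work", {
  vcf <- write_vcf_text(c(
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t1/1",
    "chr1\t200\t.\tG\tC\t.\tPASS\t.\tGT\t0/0\t./.",
    "chrX\t50\t.\tT\tG\t.\tPASS\t.\tGT\t1\t0/1"),
    c("S1", "S2"))
  cov <- write_depth_text(tibble(chrom = c("chr1", "chr1", "chrX"),
                                 pos = c(100, 200, 50),
                                 S1 = c(30, 30, 30), S2 = c(30, 0, 30)))
  calls <- load_cohort(vcf, cov, min_depth = 10)
  expect_equal(unname(calls$genotype[1, ]), c(1L, 2L))
  # depth 0 -> covered FALSE and genotype missing
  expect_false(calls$covered[2, "S2"])
  expect_true(is.na(calls$genotype[2, "S2"]))
  expect_equal(unname(calls$genotype[2, "S1"]), 0L)
  # haploid GT gives dosage in {0,1}
  expect_equal(unname(calls$genotype[3, ]), c(1L, 1L))
})

test_that("multiallelic records split into per-alt keys conserving dosage", {
  vcf <- write_vcf_text(
    "chr2\t500\t.\tG\tA,C\t.\tPASS\t.\tGT\t1/2\t0/1\t2/2",
    c("S1", "S2", "S3"))
  cov <- write_depth_text(tibble(chrom = "chr2", pos = 500,
                                 S1 = 30, S2 = 30, S3 = 30))
  calls <- load_cohort(vcf, cov)
  expect_equal(nrow(calls$variants), 2)
  expect_equal(calls$variants$alt, c("A", "C"))
  expect_equal(unname(calls$genotype["chr2:500:G:A", ]), c(1L, 1L, 0L))
  expect_equal(unname(calls$genotype["chr2:500:G:C", ]), c(1L, 0L, 2L))
  # split conserves the per-sample total alt dosage of the source record
  expect_equal(unname(colSums(calls$genotype)), c(2L, 1L, 2L))
})

test_that("sample-set mismatch between VCF and coverage is an error", {
  vcf <- write_vcf_text("chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t1/1",
                        c("S1", "S2"))
  cov <- write_depth_text(tibble(chrom = "chr1", pos = 100,
                                 S1 = 30, SX = 30))
  expect_error(load_cohort(vcf, cov), "disagree")
})

test_that("callable-interval coverage marks sites outside intervals", {
  vcf <- write_vcf_text(c(
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t1/1",
    "chr1\t900\t.\tG\tC\t.\tPASS\t.\tGT\t0/1\t0/0"),
    c("S1", "S2"))
  iv <- write_depth_text(tibble(sample_id = c("S1", "S1", "S2"),
                                chrom = "chr1",
                                start = c(1, 800, 1),
                                end = c(200, 1000, 200)))
  calls <- load_cohort(vcf, iv)
  expect_true(all(calls$covered[, "S1"]))
  expect_equal(unname(calls$covered[, "S2"]), c(TRUE, FALSE))
  expect_true(is.na(calls$genotype[2, "S2"]))
})

test_that("writing and re-loading a cohort reproduces the matrices", {
  withr::with_seed(11, {
    calls <- hwe_calls(runif(30, 0.05, 0.5), 12)
    # punch some holes in coverage
    calls$covered[sample.int(length(calls$covered), 40)] <- FALSE
    calls <- cohort_calls(calls$variants[, 1:4], calls$samples,
                          calls$genotype, calls$covered)
  })
  vcf <- withr::local_tempfile(fileext = ".vcf")
  cov <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(calls, vcf, cov)
  back <- load_cohort(vcf, cov)
  expect_equal(back$genotype, calls$genotype)
  expect_equal(back$covered, calls$covered)
  expect_equal(back$variants, calls$variants)
})

test_that("cohort_calls enforces its invariants", {
  v <- tibble(chrom = "chr1", pos = 1L, ref = "A", alt = "T")
  expect_error(cohort_calls(v, c("S1", "S1"), matrix(0L, 1, 2),
                            matrix(TRUE, 1, 2)), "duplicate sample")
  expect_error(cohort_calls(mutate(v, alt = "A"), "S1", matrix(0L, 1, 1),
                            matrix(TRUE, 1, 1)), "differ")
  expect_error(cohort_calls(v, "S1", matrix(3L, 1, 1), matrix(TRUE, 1, 1)),
               "dosage")
  # uncovered cells are forced missing
  cc <- cohort_calls(v, "S1", matrix(2L, 1, 1), matrix(FALSE, 1, 1))
  expect_true(is.na(cc$genotype[1, 1]))
})

test_that("metadata validation enforces the vocabulary", {
  good <- tiny_meta()
  expect_silent(validate_sample_metadata(good))
  expect_error(validate_sample_metadata(mutate(good, disease_group =
    replace(disease_group, 1, "EYE"))), "disease_group")
  expect_error(validate_sample_metadata(bind_rows(good, good[1, ])),
               "duplicate sample_id")
  # diag status outside IRD must be not_applicable
  expect_error(validate_sample_metadata(mutate(good, diag_status =
    replace(diag_status, 3, "solved"))), "not_applicable")
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(good[0, ], path, progress = FALSE)
  expect_warning(out <- read_sample_metadata(path), "empty")
  expect_equal(nrow(out), 0)
})

test_that("panel assembly applies exclusions with exceptions", {
  panels <- tibble(gene = c("MYO7A", "RPE65", "BRCA2", "PAH"),
                   panel = c("IRD", "IRD", "NRD", "OERD"),
                   inheritance = "recessive")
  gp <- gene_panels(panels, exclusions = c("RPE65", "BRCA2"),
                    exceptions = "RPE65")
  expect_false("BRCA2" %in% gp$panels$gene)
  expect_true("RPE65" %in% gp$panels$gene)
  expect_equal(gp$panels$panel[gp$panels$gene == "MYO7A"], "IRD")
  # collisions across panels are rejected
  expect_error(gene_panels(bind_rows(panels,
                                     tibble(gene = "MYO7A", panel = "NRD",
                                            inheritance = "recessive"))),
               "MYO7A")
  # idempotent: re-assembling the result changes nothing
  gp2 <- gene_panels(gp$panels, gp$exclusions, gp$exceptions)
  expect_equal(gp2$panels, gp$panels)
})

test_that("annotation validation normalizes and rejects bad values", {
  ann <- tibble(chrom = "chr1", pos = 1:2, ref = "A", alt = "T",
                gene = "G1", clinvar = c("pathogenic", NA),
                cadd_phred = c(10, NA), consequence = "missense")
  out <- validate_annotations(ann)
  expect_equal(out$clinvar[2], "missing")
  expect_equal(out$lovd, c("missing", "missing"))
  expect_error(validate_annotations(mutate(ann, clinvar = "bogus")), "clinvar")
  expect_error(validate_annotations(mutate(ann, cadd_phred = -1)),
               "non-negative")
  expect_error(validate_annotations(bind_rows(ann, ann[1, ])),
               "more than one")
})
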