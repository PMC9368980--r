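mk_freq <- function(ac, an, subcohort = "x") {
  n <- length(ac)
  tibble(chrom = "chr1", pos = seq_len(n), ref = "A", alt = "T",
         variant_id = sprintf("chr1:%d:A:T", seq_len(n)),
         subcohort = subcohort, ac = as.integer(ac), an = as.integer(an),
         af = ifelse(an > 0, ac / an, NA_real_),
         hom = 0L)
}

test_that("log2 fold change follows the AF ratio with half-count surrogate", {
  case <- mk_freq(c(20, 40, 10), 1000)
  pc <- mk_freq(c(20, 10, 0), 1000)
  fc <- fold_changes(case, pc)
  expect_equal(fc$log2fc[1], 0)
  expect_equal(fc$log2fc[2], 2)
  # pc absent: af surrogate 0.5/1000 -> log2(0.01 / 0.0005)
  expect_equal(fc$log2fc[3], log2(0.01 / 0.0005))
  expect_equal(fc$log2fc[3], 4.3219, tolerance = 1e-4)
})

test_that("records without a defined fold change are skipped with a message", {
  case <- mk_freq(c(0, 10, 5), c(1000, 0, 1000))
  pc <- mk_freq(c(1, 1, 1), 1000)
  expect_message(fc <- fold_changes(case, pc), "skipped")
  expect_equal(fc$variant_id, "chr1:3:A:T")
})

test_that("MFV threshold is the type-7 quantile and flags strictly above", {
  fc <- mk_freq(rep(1, 20), 100) %>%
    mutate(log2fc = as.numeric(1:20))
  out <- select_mfv(fc)
  expect_equal(mfv_threshold(out), 18.1)
  expect_equal(mfv_threshold(out), quantile7_oracle(1:20, 0.9))
  expect_setequal(out$log2fc[out$is_mfv], c(19, 20))
  expect_equal(out$group[out$log2fc == 18], "non_prioritized")
  # all-identical fold changes: nothing strictly above, warning
  fce <- fc %>% mutate(log2fc = 1)
  expect_warning(oute <- select_mfv(fce), "no variant")
  expect_false(any(oute$is_mfv))
  # MFV count never exceeds a tenth (rounded up) of the records
  withr::with_seed(41, {
    for (n in c(10, 37, 100)) {
      fcr <- mk_freq(rep(1, n), 100) %>% mutate(log2fc = rnorm(n))
      outr <- select_mfv(fcr)
      expect_lte(sum(outr$is_mfv), ceiling(0.10 * n))
    }
  })
})

test_that("relevance: curated ClinVar outranks CADD, CADD rescues missing", {
  ann <- tibble(clinvar = c("pathogenic", "missing", "conflicting",
                            "benign", "likely_benign", "vus"),
                cadd_phred = c(12, 35, 10, 45, NA, 31))
  out <- classify_relevance(ann)
  expect_equal(out$relevance,
               c("deleterious", "deleterious", "not_informative",
                 "benign", "benign", "deleterious"))
})

test_that("enrichment p equals exact hypergeometric enumeration", {
  mk_fc <- function(m) {
    tibble(relevance = rep(rep(c("deleterious", "benign"), 2),
                           times = c(m[1, 1], m[2, 1], m[1, 2], m[2, 2])),
           group = rep(c("mfv", "non_prioritized"),
                       times = c(sum(m[, 1]), sum(m[, 2]))))
  }
  m1 <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  r1 <- enrichment_test(mk_fc(m1))
  expect_equal(r1$p_value, 17 / 70, tolerance = 1e-12)
  expect_equal(r1$p_value, fisher_oracle_greater(m1), tolerance = 1e-12)
  m2 <- matrix(c(10, 0, 0, 10), 2, byrow = TRUE)
  r2 <- enrichment_test(mk_fc(m2))
  expect_equal(r2$p_value, 1 / choose(20, 10), tolerance = 1e-12)
  # degenerate margin: no deleterious anywhere
  m3 <- matrix(c(0, 0, 4, 6), 2, byrow = TRUE)
  r3 <- enrichment_test(mk_fc(m3))
  expect_equal(r3$p_value, 1)
  expect_true(r3$degenerate)
  expect_true(is.na(r3$odds_ratio))
  # random tables with margins <= 30 against the oracle
  withr::with_seed(42, {
    for (i in 1:25) {
      m <- matrix(rpois(4, 5), 2)
      if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
      r <- enrichment_test(mk_fc(m))
      expect_equal(r$p_value, fisher_oracle_greater(m), tolerance = 1e-12)
    }
  })
})

test_that("tidy and glance expose the enrichment result", {
  fc <- tibble(relevance = c("deleterious", "deleterious", "benign",
                             "benign", "not_informative"),
               group = c("mfv", "non_prioritized", "mfv",
                         "non_prioritized", "mfv"))
  r <- enrichment_test(fc)
  td <- tidy(r)
  expect_equal(td$del_mfv + td$del_non_prioritized +
                 td$ben_mfv + td$ben_non_prioritized, 4)
  expect_equal(glance(r)$n, 4)
})

test_that("stratified analysis localizes a planted syndromic signal", {
  ps <- withr::with_seed(43, {
    purrr::map_dfr(1:6, function(r) {
      cfg <- sim_config(
        n_ird_solved = 0, n_ird_nonsolved = 160, n_oerd = 0, n_nrd = 400,
        n_genes = c(IRD = 6, OERD = 2, NRD = 4), variants_per_gene = 15,
        n_common_snps = 0, coverage_dropout = 0,
        subphenotype_mix = c(syndromic = 0.5, non_syndromic = 0.5,
                             macular_dystrophy = 0),
        seed = 430 + r)
      b <- simulate_cohort(cfg)
      # plant enrichment only in syndromic cases for deleterious variants
      syn <- b$meta$sample_id[!is.na(b$meta$subphenotype) &
                                b$meta$subphenotype == "syndromic"]
      ann <- classify_relevance(b$annotations)
      del_ids <- ann$variant_id[ann$relevance == "deleterious"]
      del_ids <- intersect(del_ids, b$calls$variants$variant_id)[1:10]
      del_ids <- del_ids[!is.na(del_ids)]
      idx <- match(del_ids, b$calls$variants$variant_id)
      b$calls$genotype[idx, syn] <-
        matrix(rbinom(length(idx) * length(syn), 2, 0.08),
               length(idx), length(syn))
      res <- suppressMessages(stratified_analysis(
        b$calls, b$meta, ann,
        strata = list(
          syndromic = subcohort_spec("syn", disease_group = "IRD",
                                     subphenotype = "syndromic"),
          non_syndromic = subcohort_spec("nonsyn", disease_group = "IRD",
                                         subphenotype = "non_syndromic"))))
      tibble(rep = r,
             p_syn = res$p_value[res$stratum == "syndromic"],
             p_non = res$p_value[res$stratum == "non_syndromic"])
    })
  })
  expect_lt(median(ps$p_syn), median(ps$p_non))
})

test_that("a stratum equal to the full case set reproduces the plain run", {
  b <- withr::with_seed(44, simulate_cohort(sim_config(
    n_ird_solved = 0, n_ird_nonsolved = 80, n_oerd = 0, n_nrd = 200,
    n_genes = c(IRD = 4, OERD = 2, NRD = 4), variants_per_gene = 10,
    n_common_snps = 0, seed = 44)))
  ann <- classify_relevance(b$annotations)
  res <- suppressMessages(stratified_analysis(
    b$calls, b$meta, ann,
    strata = list(all_cases = subcohort_spec("all", disease_group = "IRD"))))
  pc <- compute_frequencies(b$calls, b$meta, default_subcohorts()$pc)
  cs <- compute_frequencies(b$calls, b$meta, default_subcohorts()$ird_all)
  fc <- suppressMessages(fold_changes(cs, pc)) %>%
    select_mfv() %>%
    left_join(ann %>% select(variant_id, relevance), by = "variant_id")
  direct <- enrichment_test(fc)
  expect_equal(res$p_value, direct$p_value)
  expect_equal(res$mfv_threshold, mfv_threshold(fc))
})
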