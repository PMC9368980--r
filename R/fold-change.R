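#' Case-versus-pseudocontrol log2 fold changes
#'
#' Joins a case subcohort frequency table with the pseudocontrol table and
#' computes `log2(case_af / pc_af)` per variant. A variant absent from the
#' cases (AC = 0) or uncovered in either subcohort (AN = 0) has no defined
#' fold change and is dropped with a message; a variant absent from the
#' pseudocontrols uses the half-count surrogate `pc_af = 0.5 / pc_an`,
#' keeping the ratio finite.
#'
#' @param case_freqs,pc_freqs Frequency tibbles from
#'   [compute_frequencies()].
#' @return A tibble with the variant key, `case_ac/an/af`, `pc_ac/an/af`
#'   (surrogate-adjusted AF in `pc_af_adj`) and `log2fc`.
#' @export
fold_changes <- function(case_freqs, pc_freqs) {
  joined <- inner_join(
    case_freqs %>% select("chrom", "pos", "ref", "alt", "variant_id",
                          case_ac = "ac", case_an = "an", case_af = "af"),
    pc_freqs %>% select("variant_id", pc_ac = "ac", pc_an = "an",
                        pc_af = "af"),
    by = "variant_id")
  defined <- joined$case_an > 0 & joined$case_ac > 0 & joined$pc_an > 0
  n_drop <- sum(!defined)
  if (n_drop > 0) {
    inform(paste(n_drop, "variant(s) without a defined fold change skipped"))
  }
  joined %>%
    filter(defined) %>%
    mutate(pc_af_adj = adjusted_af(.data$pc_ac, .data$pc_an),
           log2fc = log2(.data$case_af / .data$pc_af_adj))
}

#' Flag the most frequent variants (MFVs)
#'
#' The "most frequent variants" of a case subcohort are those in the top
#' `1 - quantile` of the log2 fold-change distribution against
#' pseudocontrols: the threshold is the type-7 quantile of `log2fc` over
#' all records and a variant is an MFV when strictly above it.
#' Non-prioritized variants are those more frequent in cases
#' (`log2fc > 0`) but at or below the threshold; the remainder are labelled
#' `other`.
#'
#' @param fc_tbl Fold-change tibble from [fold_changes()].
#' @param quantile Quantile defining the MFV threshold (default 0.90).
#' @return `fc_tbl` with columns `is_mfv` and `group` (`mfv` /
#'   `non_prioritized` / `other`); the threshold is stored in attribute
#'   `mfv_threshold` (see [mfv_threshold()]).
#' @export
select_mfv <- function(fc_tbl, quantile = 0.90) {
  stopifnot(quantile > 0, quantile < 1)
  if (nrow(fc_tbl) < 10) {
    warn("fewer than 10 fold-change records; MFV threshold is unstable")
  }
  thr <- stats::quantile(fc_tbl$log2fc, probs = quantile, type = 7,
                         names = FALSE)
  out <- fc_tbl %>%
    mutate(is_mfv = .data$log2fc > thr,
           group = case_when(.data$is_mfv ~ "mfv",
                             .data$log2fc > 0 ~ "non_prioritized",
                             TRUE ~ "other"))
  if (!any(out$is_mfv)) {
    warn("no variant strictly above the MFV threshold")
  }
  attr(out, "mfv_threshold") <- thr
  out
}

#' @rdname select_mfv
#' @param x A tibble returned by `select_mfv()`.
#' @export
mfv_threshold <- function(x) attr(x, "mfv_threshold")

#' Clinical-relevance classification of variants
#'
#' A variant is `deleterious` when asserted pathogenic or likely pathogenic
#' in ClinVar, or (failing a ClinVar benign/likely-benign assertion, which
#' as curated evidence outranks the in-silico score) when its CADD_PHRED is
#' at least `cadd_cutoff`; `benign` when asserted benign or likely benign;
#' otherwise `not_informative`.
#'
#' @param ann Annotation tibble with columns `clinvar` and `cadd_phred`
#'   (see [read_variant_annotations()]).
#' @param cadd_cutoff CADD_PHRED deleteriousness cutoff (default 30, the
#'   top 0.1% most deleterious substitutions).
#' @return `ann` with an added `relevance` column.
#' @export
classify_relevance <- function(ann, cadd_cutoff = 30) {
  ann %>%
    mutate(relevance = case_when(
      .data$clinvar %in% c("pathogenic", "likely_pathogenic") ~ "deleterious",
      .data$clinvar %in% c("benign", "likely_benign") ~ "benign",
      !is.na(.data$cadd_phred) & .data$cadd_phred >= cadd_cutoff ~ "deleterious",
      TRUE ~ "not_informative"))
}

#' Deleterious-variant enrichment among MFVs
#'
#' Tests whether deleterious variants are over-represented among the MFVs
#' relative to the non-prioritized variants (one-sided Fisher's exact
#' test), after removing not-informative variants. Optionally restricted to
#' the variants of one gene panel.
#'
#' @param fc_tbl Output of [select_mfv()] carrying `relevance` (join with
#'   [classify_relevance()] output first) and, if panel filtering is used,
#'   a `panel` column.
#' @param panel_filter Optional panel label (IRD/OERD/NRD).
#' @return An object of class `mfv_enrichment`: the 2x2 counts, odds ratio
#'   and one-sided p-value; see [tidy()] and [glance()].
#' @export
enrichment_test <- function(fc_tbl, panel_filter = NULL) {
  if (!"relevance" %in% names(fc_tbl)) {
    abort("fc_tbl needs a relevance column; join with classify_relevance()")
  }
  dat <- fc_tbl %>%
    filter(.data$relevance %in% c("deleterious", "benign"),
           .data$group %in% c("mfv", "non_prioritized"))
  if (!is.null(panel_filter)) {
    dat <- dat %>% filter(.data$panel %in% panel_filter)
  }
  m <- matrix(c(
    sum(dat$group == "mfv" & dat$relevance == "deleterious"),
    sum(dat$group == "non_prioritized" & dat$relevance == "deleterious"),
    sum(dat$group == "mfv" & dat$relevance == "benign"),
    sum(dat$group == "non_prioritized" & dat$relevance == "benign")),
    nrow = 2, byrow = TRUE,
    dimnames = list(relevance = c("deleterious", "benign"),
                    group = c("mfv", "non_prioritized")))
  degenerate <- any(rowSums(m) == 0) || any(colSums(m) == 0)
  if (degenerate) {
    p <- 1; or <- NA_real_
  } else {
    ft <- fisher.test(m, alternative = "greater")
    p <- ft$p.value; or <- unname(ft$estimate)
  }
  structure(list(table = m, odds_ratio = or, p_value = p,
                 degenerate = degenerate,
                 panel = panel_filter %||% "all"),
            class = "mfv_enrichment")
}

#' @export
print.mfv_enrichment <- function(x, ...) {
  cat("<mfv_enrichment> panel:", x$panel, "\n")
  print(x$table)
  cat(sprintf("odds ratio %.3g, one-sided p = %.3g%s\n", x$odds_ratio,
              x$p_value, if (x$degenerate) " (degenerate margin)" else ""))
  invisible(x)
}

#' @rdname enrichment_test
#' @param x An `mfv_enrichment` object.
#' @param ... Unused.
#' @export
tidy.mfv_enrichment <- function(x, ...) {
  tibble(panel = x$panel,
         del_mfv = x$table[1, 1], del_non_prioritized = x$table[1, 2],
         ben_mfv = x$table[2, 1], ben_non_prioritized = x$table[2, 2],
         odds_ratio = x$odds_ratio, p_value = x$p_value,
         degenerate = x$degenerate)
}

#' @rdname enrichment_test
#' @export
glance.mfv_enrichment <- function(x, ...) {
  tibble(n = sum(x$table), odds_ratio = x$odds_ratio, p_value = x$p_value)
}

#' Sub-phenotype stratified enrichment analysis
#'
#' Reruns the frequency -> fold change -> MFV -> enrichment chain for one
#' or more case strata (e.g. syndromic, non-syndromic, macular dystrophy
#' forms) against the same pseudocontrol subcohort.
#'
#' @param calls A [cohort_calls()] object.
#' @param meta Sample metadata.
#' @param annotations Annotation tibble (with or without `relevance`).
#' @param strata Named list of [subcohort_spec()]s for the case strata.
#' @param pc_spec Pseudocontrol spec (default the NRD subcohort).
#' @param panels Optional [gene_panels()] used to attach a `panel` column.
#' @param quantile MFV quantile (default 0.90).
#' @param cadd_cutoff Passed to [classify_relevance()].
#' @return A tibble with one row per stratum: threshold, counts and the
#'   enrichment test results.
#' @export
stratified_analysis <- function(calls, meta, annotations, strata,
                                pc_spec = default_subcohorts()$pc,
                                panels = NULL, quantile = 0.90,
                                cadd_cutoff = 30) {
  if (!"relevance" %in% names(annotations)) {
    annotations <- classify_relevance(annotations, cadd_cutoff = cadd_cutoff)
  }
  pc_freqs <- compute_frequencies(calls, meta, pc_spec)
  purrr::imap(strata, function(spec, nm) {
    ids <- subcohort_samples(meta, spec)
    if (length(ids) == 0) abort(paste0("stratum '", nm, "' is empty"))
    if (length(ids) == 1) {
      warn(paste0("stratum '", nm,
                  "' has a single case; fold changes will be unstable"))
    }
    fc <- fold_changes(compute_frequencies(calls, meta, spec), pc_freqs) %>%
      select_mfv(quantile = quantile) %>%
      left_join(annotations %>% select("variant_id", "gene", "relevance"),
                by = "variant_id")
    if (!is.null(panels)) {
      fc <- fc %>% left_join(panels$panels %>% select("gene", "panel"),
                             by = "gene") %>%
        mutate(panel = dplyr::coalesce(.data$panel, "none"))
    }
    enr <- enrichment_test(fc)
    tidy(enr) %>%
      mutate(stratum = nm, n_cases = length(ids),
             mfv_threshold = mfv_threshold(fc), n_mfv = sum(fc$is_mfv),
             .before = 1)
  }) %>% bind_rows()
}
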