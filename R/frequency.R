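#' Define a subcohort by metadata predicate
#'
#' A subcohort is the set of samples whose metadata match all supplied
#' field filters (`NULL` means "any value"). The standard subcohorts of the
#' framework — the disease subcohort and its diagnostic/phenotype slices,
#' plus the pseudocontrols (samples with non-related diseases) — are
#' available from [default_subcohorts()].
#'
#' @param name Subcohort label used in frequency records.
#' @param disease_group,diag_status,subphenotype,sex Optional character
#'   vectors of admitted values for each metadata field.
#' @return A `subcohort_spec` object.
#' @export
subcohort_spec <- function(name, disease_group = NULL, diag_status = NULL,
                           subphenotype = NULL, sex = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  structure(list(name = name, disease_group = disease_group,
                 diag_status = diag_status, subphenotype = subphenotype,
                 sex = sex),
            class = "subcohort_spec")
}

#' @rdname subcohort_spec
#' @details `default_subcohorts()` returns the six disease-side subcohorts
#'   (all cases; non-solved cases, i.e. free of candidate variants; solved
#'   cases; syndromic; non-syndromic; macular dystrophy) and the
#'   pseudocontrol subcohort (`pc`, the NRD group).
#' @export
default_subcohorts <- function() {
  list(
    ird_all = subcohort_spec("ird_all", disease_group = "IRD"),
    ird_non_solved = subcohort_spec("ird_non_solved", disease_group = "IRD",
                                    diag_status = "non_solved"),
    ird_solved = subcohort_spec("ird_solved", disease_group = "IRD",
                                diag_status = "solved"),
    ird_syndromic = subcohort_spec("ird_syndromic", disease_group = "IRD",
                                   subphenotype = "syndromic"),
    ird_non_syndromic = subcohort_spec("ird_non_syndromic",
                                       disease_group = "IRD",
                                       subphenotype = "non_syndromic"),
    ird_macular = subcohort_spec("ird_macular", disease_group = "IRD",
                                 subphenotype = "macular_dystrophy"),
    pc = subcohort_spec("pc", disease_group = "NRD")
  )
}

#' @rdname subcohort_spec
#' @param meta Sample metadata tibble (see [read_sample_metadata()]).
#' @param spec A `subcohort_spec`.
#' @return `subcohort_samples()`: character vector of matching sample ids.
#' @export
subcohort_samples <- function(meta, spec) {
  stopifnot(inherits(spec, "subcohort_spec"))
  keep <- rep(TRUE, nrow(meta))
  for (field in c("disease_group", "diag_status", "subphenotype", "sex")) {
    vals <- spec[[field]]
    if (!is.null(vals)) keep <- keep & !is.na(meta[[field]]) &
        meta[[field]] %in% vals
  }
  meta$sample_id[keep]
}

#' Per-subcohort allele frequencies
#'
#' Computes, per variant, the allele number AN (total called alleles over
#' the subcohort's covered samples), allele count AC (alternate alleles
#' observed), allele frequency AF = AC/AN, and the homozygote count. Only
#' covered, genotyped samples contribute, so non-covered sites are
#' distinguished from non-mutated ones. With `sex_aware = TRUE`, males
#' contribute one allele at variants on the X chromosome (dosage capped at
#' 1); hemizygous males are not counted as homozygotes.
#'
#' @param calls A [cohort_calls()] object.
#' @param meta Sample metadata covering the selected samples.
#' @param spec A [subcohort_spec()] (or a character vector of sample ids).
#' @param sex_aware Cap male X-chromosome ploidy at 1 when sex is known
#'   (default `TRUE`).
#' @return A tibble: variant key columns, `subcohort`, `ac`, `an`, `af`
#'   (`NA` when `an = 0`), `hom`.
#' @export
compute_frequencies <- function(calls, meta, spec, sex_aware = TRUE) {
  stopifnot(inherits(calls, "cohort_calls"))
  if (inherits(spec, "subcohort_spec")) {
    ids <- subcohort_samples(meta, spec)
    nm <- spec$name
  } else {
    ids <- as.character(spec)
    nm <- "custom"
  }
  if (length(ids) == 0) {
    abort(paste0("subcohort '", nm, "' selects zero samples"))
  }
  missing_s <- setdiff(ids, calls$samples)
  if (length(missing_s)) {
    abort(paste("selected samples absent from calls:",
                paste(missing_s, collapse = ", ")))
  }
  g <- calls$genotype[, ids, drop = FALSE]
  ploidy <- matrix(2L, nrow(g), ncol(g))
  if (sex_aware && "sex" %in% names(meta)) {
    males <- ids %in% meta$sample_id[!is.na(meta$sex) & meta$sex == "male"]
    on_x <- calls$variants$chrom %in% .x_chroms
    if (any(males) && any(on_x)) {
      ploidy[on_x, males] <- 1L
      g[on_x, males] <- pmin(g[on_x, males], 1L)
    }
  }
  called <- !is.na(g)
  an <- as.integer(rowSums(ploidy * called))
  gz <- g; gz[!called] <- 0L
  ac <- as.integer(rowSums(gz))
  hom <- as.integer(rowSums(called & gz == 2L & ploidy == 2L))
  calls$variants %>%
    mutate(subcohort = nm, ac = ac, an = an,
           af = ifelse(an > 0, ac / an, NA_real_), hom = hom)
}

#' @rdname compute_frequencies
#' @param specs A named list of subcohort specs (default
#'   [default_subcohorts()]).
#' @return `build_frequency_db()`: one long tibble over all subcohorts.
#' @export
build_frequency_db <- function(calls, meta, specs = default_subcohorts(),
                               sex_aware = TRUE) {
  bind_rows(purrr::map(specs, ~compute_frequencies(calls, meta, .x,
                                                   sex_aware = sex_aware)))
}

#' Drop the lowest-AN fraction of variants (quality filter)
#'
#' Removes exactly `floor(fraction * V)` variants ranked by whole-cohort AN
#' ascending, breaking ties deterministically on the lexicographic variant
#' key. A warning is emitted when the cut falls inside a tie run, since the
#' choice among equal-AN variants is then the tie-break's, not the data's.
#'
#' @param freqs Whole-cohort frequency tibble (one row per variant).
#' @param fraction Fraction of variants to drop (default 0.05).
#' @return A list with tibbles `kept` and `removed`.
#' @export
qc_filter_lowest_an <- function(freqs, fraction = 0.05) {
  stopifnot(fraction >= 0, fraction < 1)
  if (anyDuplicated(freqs$variant_id)) {
    abort("qc filter expects one whole-cohort row per variant")
  }
  n_remove <- floor(fraction * nrow(freqs))
  ord <- order(freqs$an, freqs$variant_id)
  if (n_remove > 0 && n_remove < nrow(freqs) &&
      freqs$an[ord[n_remove]] == freqs$an[ord[n_remove + 1]]) {
    warn("AN tie at the quality-filter boundary; resolved by variant key order")
  }
  removed_idx <- ord[seq_len(n_remove)]
  list(kept = freqs[sort(setdiff(seq_len(nrow(freqs)), removed_idx)), ],
       removed = freqs[removed_idx, ])
}

# half-count surrogate keeps fold changes finite and monotone when AC = 0
adjusted_af <- function(ac, an) {
  ifelse(an > 0, ifelse(ac == 0, 0.5 / an, ac / an), NA_real_)
}

#' Remove variants with a population-origin bias (population filter)
#'
#' Assuming no population-origin difference between solved and non-solved
#' cases of the disease subcohort, a variant whose frequency differs
#' strongly between the two is suspect. Over variants present (AC > 0) in
#' either subcohort, the absolute log2 fold change between the two AFs is
#' computed (zero-AC side replaced by the half-count surrogate `0.5/AN`);
#' variants above its `quantile` (type-7) are removed unless both raw AFs
#' are below `rescue_af`, in which case they are rescued. Variants absent
#' from both subcohorts, or uncovered in one, pass through untouched.
#'
#' @param solved_freqs,nonsolved_freqs Frequency tibbles for the solved and
#'   non-solved case subcohorts (same variant universe).
#' @param quantile Percentile of the |log2 FC| distribution above which a
#'   variant is suspect (default 0.90).
#' @param rescue_af Both-sides AF bound below which suspect variants are
#'   rescued (default 0.1).
#' @return A list: `kept` and `removed` variant-id tibbles with the
#'   computed `abs_log2fc` and flags.
#' @export
population_bias_filter <- function(solved_freqs, nonsolved_freqs,
                                   quantile = 0.90, rescue_af = 0.1) {
  joined <- inner_join(
    solved_freqs %>% select("variant_id", s_ac = "ac", s_an = "an", s_af = "af"),
    nonsolved_freqs %>% select("variant_id", n_ac = "ac", n_an = "an",
                               n_af = "af"),
    by = "variant_id")
  if (nrow(joined) != nrow(solved_freqs)) {
    abort("solved and non-solved tables must share the variant universe")
  }
  joined <- joined %>%
    mutate(present = (.data$s_ac > 0 | .data$n_ac > 0),
           computable = .data$present & .data$s_an > 0 & .data$n_an > 0,
           abs_log2fc = ifelse(
             .data$computable,
             abs(log2(adjusted_af(.data$n_ac, .data$n_an) /
                        adjusted_af(.data$s_ac, .data$s_an))),
             NA_real_))
  thr <- stats::quantile(joined$abs_log2fc[joined$computable],
                         probs = quantile, type = 7, names = FALSE,
                         na.rm = TRUE)
  joined <- joined %>%
    mutate(suspect = .data$computable & .data$abs_log2fc > thr,
           rescued = .data$suspect & .data$s_af < rescue_af &
             .data$n_af < rescue_af,
           removed = .data$suspect & !.data$rescued)
  list(kept = joined %>% filter(!.data$removed),
       removed = joined %>% filter(.data$removed),
       threshold = thr)
}

#' Write a frequency database to TSV
#'
#' @param freqs Long frequency tibble from [build_frequency_db()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_frequency_db <- function(freqs, path) {
  freqs %>%
    select("chrom", "pos", "ref", "alt", "subcohort",
           AC = "ac", AN = "an", AF = "af", hom = "hom") %>%
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}
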