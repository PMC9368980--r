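#' Select the pathogenic variant set for carrier-frequency estimation
#'
#' For one gene, the union of four rules over its variants observed in the
#' pseudocontrols (AC > 0): asserted pathogenic/likely pathogenic in
#' ClinVar; asserted pathogenic/likely pathogenic in LOVD; CADD_PHRED at
#' least `cadd_cutoff`; or a frameshift/stop-gain consequence. Known
#' hypomorphic alleles may be excluded by variant key.
#'
#' @param gene Gene symbol.
#' @param annotations Annotation tibble (see [read_variant_annotations()]).
#' @param pc_freqs Pseudocontrol frequency tibble.
#' @param hypomorphic_exclusions Optional character vector of `variant_id`s
#'   to drop (hypomorphic alleles).
#' @param cadd_cutoff CADD_PHRED inclusion cutoff (default 30).
#' @return Tibble of selected variants with their pseudocontrol `ac`/`an`.
#' @export
select_cf_variants <- function(gene, annotations, pc_freqs,
                               hypomorphic_exclusions = NULL,
                               cadd_cutoff = 30) {
  plp <- c("pathogenic", "likely_pathogenic")
  ann <- annotations %>%
    filter(.data$gene == !!gene,
           .data$clinvar %in% plp |
             .data$lovd %in% plp |
             (!is.na(.data$cadd_phred) & .data$cadd_phred >= cadd_cutoff) |
             .data$consequence %in% c("frameshift", "stop_gain"))
  sel <- ann %>%
    inner_join(pc_freqs %>% select("variant_id", "ac", "an", "af"),
               by = "variant_id") %>%
    filter(.data$ac > 0)
  if (!is.null(hypomorphic_exclusions)) {
    sel <- sel %>% filter(!(.data$variant_id %in% hypomorphic_exclusions))
  }
  sel
}

#' Carrier frequency of a recessive gene
#'
#' Aggregates the selected pathogenic variants of a recessive gene into a
#' carrier frequency: `CF% = 200 * sum(AC) / maxAN`, where `maxAN` is the
#' largest per-variant allele number among the selected variants in the
#' pseudocontrols (AN varies by coverage). Counting is allele-wise, so a
#' homozygote contributes twice.
#'
#' @param variants Selected-variant tibble from [select_cf_variants()]
#'   (needs `ac`, `an`, `variant_id`).
#' @param gene Gene symbol carried into the result.
#' @return A one-row tibble: `gene`, `mode`, `n_variants`, `cf_percent`,
#'   `included_variants` (list-column).
#' @export
carrier_frequency <- function(variants, gene = variants$gene[1]) {
  if (nrow(variants) == 0) {
    return(tibble(gene = gene %||% NA_character_, mode = "recessive",
                  n_variants = 0L, cf_percent = 0,
                  included_variants = list(character())))
  }
  max_an <- max(variants$an)
  if (max_an == 0) abort("no covered pseudocontrols among selected variants")
  tibble(gene = gene, mode = "recessive", n_variants = nrow(variants),
         cf_percent = 200 * sum(variants$ac) / max_an,
         included_variants = list(variants$variant_id))
}

#' Carrier frequency for dominant and X-linked genes
#'
#' The dominant/X-linked analogue of [carrier_frequency()]: deleterious
#' heterozygous carriers for autosomal dominant genes keep the x2 allele
#' factor (`200 * sum(AC) / maxAN`); hemizygous counting for X-linked
#' genes drops it (`100 * sum(AC) / maxAN`), with `pc_freqs` expected to
#' be computed over male pseudocontrols only. If no sex information is
#' available for an X-linked gene the diploid convention is used with a
#' warning.
#'
#' @param gene Gene symbol.
#' @param annotations Annotation tibble.
#' @param pc_freqs Pseudocontrol frequencies (male-only for hemizygous
#'   counting).
#' @param inheritance `"dominant"` or `"x_linked"`.
#' @param have_sex_info Whether `pc_freqs` could be restricted by sex
#'   (default `TRUE`); ignored for dominant genes.
#' @param hypomorphic_exclusions,cadd_cutoff Passed to
#'   [select_cf_variants()].
#' @return A one-row tibble as [carrier_frequency()], `mode =
#'   "dominant_xl"`.
#' @export
dominant_xl_frequency <- function(gene, annotations, pc_freqs, inheritance,
                                  have_sex_info = TRUE,
                                  hypomorphic_exclusions = NULL,
                                  cadd_cutoff = 30) {
  stopifnot(inheritance %in% c("dominant", "x_linked"))
  sel <- select_cf_variants(gene, annotations, pc_freqs,
                            hypomorphic_exclusions, cadd_cutoff)
  if (nrow(sel) == 0) {
    return(tibble(gene = gene, mode = "dominant_xl", n_variants = 0L,
                  cf_percent = 0, included_variants = list(character())))
  }
  hemizygous <- inheritance == "x_linked"
  if (hemizygous && !have_sex_info) {
    warn(paste0("X-linked gene '", gene,
                "' computed diploid: no sex information"))
    hemizygous <- FALSE
  }
  factor <- if (hemizygous) 100 else 200
  max_an <- max(sel$an)
  if (max_an == 0) abort("no covered pseudocontrols among selected variants")
  tibble(gene = gene, mode = "dominant_xl", n_variants = nrow(sel),
         cf_percent = factor * sum(sel$ac) / max_an,
         included_variants = list(sel$variant_id))
}

#' Gate genes for carrier-frequency reporting
#'
#' Carrier frequencies are reported for genes of the non-syndromic disease
#' panel supported by at least `min_solved` solved cases in the cohort.
#'
#' @param gene Gene symbol.
#' @param solved_case_counts Named integer vector or tibble
#'   (`gene`, `n_solved`) of solved-case counts per gene.
#' @param panels A [gene_panels()] object whose IRD panel carries a
#'   `subpanel` column.
#' @param min_solved Minimum solved-case support (default 3).
#' @return `TRUE` when the gene qualifies.
#' @export
cf_gene_gate <- function(gene, solved_case_counts, panels, min_solved = 3) {
  if (is.data.frame(solved_case_counts)) {
    counts <- setNames(solved_case_counts$n_solved, solved_case_counts$gene)
  } else {
    counts <- solved_case_counts
  }
  row <- panels$panels %>% filter(.data$gene == !!gene)
  in_panel <- nrow(row) == 1 && row$panel == "IRD" &&
    !is.na(row$subpanel) && row$subpanel %in% c("non_syndromic", "both")
  n <- counts[gene]
  in_panel && !is.na(n) && n >= min_solved
}

#' Cohort-wide carrier-frequency report
#'
#' Applies [cf_gene_gate()] across the panel genes and computes the
#' carrier frequency for each qualifying gene with the mode implied by its
#' inheritance annotation (recessive genes via [carrier_frequency()];
#' dominant and X-linked genes via [dominant_xl_frequency()]).
#'
#' @param annotations,panels,solved_case_counts See the underlying
#'   functions.
#' @param pc_freqs Pseudocontrol frequencies (all samples).
#' @param pc_freqs_male Optional male-only pseudocontrol frequencies for
#'   hemizygous counting of X-linked genes.
#' @param hypomorphic_exclusions Named list: gene -> variant ids to drop.
#' @param min_solved,cadd_cutoff Thresholds (defaults 3 and 30).
#' @return A tibble with one row per reported gene.
#' @export
carrier_frequency_report <- function(annotations, panels, pc_freqs,
                                     solved_case_counts,
                                     pc_freqs_male = NULL,
                                     hypomorphic_exclusions = list(),
                                     min_solved = 3, cadd_cutoff = 30) {
  genes <- panels$panels %>%
    filter(.data$panel == "IRD",
           !is.na(.data$subpanel),
           .data$subpanel %in% c("non_syndromic", "both"))
  rows <- purrr::pmap(list(genes$gene, genes$inheritance), function(g, inh) {
    if (!cf_gene_gate(g, solved_case_counts, panels, min_solved)) {
      return(NULL)
    }
    excl <- hypomorphic_exclusions[[g]]
    if (inh %in% c("recessive", "r_or_d", "undetermined")) {
      sel <- select_cf_variants(g, annotations, pc_freqs, excl, cadd_cutoff)
      cf <- carrier_frequency(sel, gene = g)
    } else if (inh == "x_linked") {
      freqs <- pc_freqs_male %||% pc_freqs
      cf <- dominant_xl_frequency(g, annotations, freqs, "x_linked",
                                  have_sex_info = !is.null(pc_freqs_male),
                                  hypomorphic_exclusions = excl,
                                  cadd_cutoff = cadd_cutoff)
    } else {
      cf <- dominant_xl_frequency(g, annotations, pc_freqs, "dominant",
                                  hypomorphic_exclusions = excl,
                                  cadd_cutoff = cadd_cutoff)
    }
    cf %>% mutate(inheritance = inh)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    warn("no gene passes the carrier-frequency gate")
    return(tibble(gene = character(), mode = character(),
                  n_variants = integer(), cf_percent = numeric(),
                  included_variants = list(), inheritance = character()))
  }
  out %>% arrange(desc(.data$cf_percent))
}
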