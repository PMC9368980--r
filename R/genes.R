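#' Per-gene deleterious and benign fold-change sets
#'
#' Partitions a gene's variants (by their clinical-relevance label) into
#' deleterious and benign log2 fold-change sets; not-informative variants
#' appear in neither. Genes need at least `min_del` deleterious and
#' `min_ben` benign variants to be testable.
#'
#' @param gene Gene symbol (exact match).
#' @param fc_tbl Fold-change tibble (from [fold_changes()]).
#' @param annotations Annotation tibble carrying `relevance` (see
#'   [classify_relevance()]).
#' @param min_del,min_ben Eligibility gate (defaults 5 and 5).
#' @return A list `(del_fcs, ben_fcs)` or `NULL` (with an attribute-free
#'   message) when the gene is ineligible.
#' @export
gene_fc_sets <- function(gene, fc_tbl, annotations, min_del = 5,
                         min_ben = 5) {
  ann <- annotations %>% filter(.data$gene == !!gene)
  if (nrow(ann) == 0) {
    inform(paste0("gene '", gene, "' absent from annotations; excluded"))
    return(NULL)
  }
  dat <- fc_tbl %>%
    inner_join(ann %>% select("variant_id", "relevance"), by = "variant_id")
  del <- dat$log2fc[dat$relevance == "deleterious"]
  ben <- dat$log2fc[dat$relevance == "benign"]
  if (length(del) < min_del || length(ben) < min_ben) return(NULL)
  list(del_fcs = del, ben_fcs = ben)
}

#' One-sided Wilcoxon rank-sum test on fold-change sets
#'
#' Tests whether the deleterious fold changes are stochastically greater
#' than the benign ones. The p-value is exact (full enumeration) when the
#' combined sample size is at most 12 and there are no ties; otherwise the
#' normal approximation with midrank tie correction and continuity
#' correction is used.
#'
#' @param del_fcs,ben_fcs Numeric vectors (each non-empty).
#' @return The one-sided p-value.
#' @export
rank_sum_test <- function(del_fcs, ben_fcs) {
  if (length(del_fcs) == 0 || length(ben_fcs) == 0) {
    abort("both fold-change sets must be non-empty")
  }
  ties <- anyDuplicated(c(del_fcs, ben_fcs)) > 0
  use_exact <- (length(del_fcs) + length(ben_fcs) <= 12) && !ties
  suppressWarnings(
    wilcox.test(del_fcs, ben_fcs, alternative = "greater",
                exact = use_exact, correct = TRUE)$p.value
  )
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment (or Benjamini-Yekutieli under arbitrary
#' dependence), order-preserving and capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` (default) or `"BY"`.
#' @return Adjusted p-values, aligned with the input.
#' @export
bh_fdr <- function(p_values, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = method)
}

#' Gene prioritization by deleterious-versus-benign burden
#'
#' Sweeps the genes of the loaded panels (actionable exclusions already
#' applied by [gene_panels()]): for each gene with at least `min_del`
#' deleterious and `min_ben` benign variants, compares the two log2
#' fold-change distributions with the one-sided Wilcoxon rank-sum test and
#' adjusts p-values across tested genes by FDR. Genes with adjusted
#' p-value below `alpha` are flagged significant. Results are sorted by
#' panel and then by number of deleterious variants, descending.
#'
#' @param fc_tbl Fold-change tibble for the case subcohort of interest
#'   (typically non-solved cases) versus pseudocontrols.
#' @param annotations Annotation tibble with `gene` and `relevance`.
#' @param panels A [gene_panels()] object.
#' @param min_del,min_ben Per-gene eligibility gate (defaults 5/5).
#' @param alpha FDR significance level (default 0.05).
#' @param fdr_method `"BH"` (default) or `"BY"`.
#' @param min_del_display Optional report filter keeping significant genes
#'   with at least this many deleterious variants (display only).
#' @return A `gene_prior_result` tibble: `gene`, `n_del`, `n_ben`,
#'   `mean_fc_del`, `mean_fc_ben`, `p_value`, `fdr`, `significant`,
#'   `panel`, `inheritance`.
#' @export
prioritize_genes <- function(fc_tbl, annotations, panels, min_del = 5,
                             min_ben = 5, alpha = 0.05,
                             fdr_method = c("BH", "BY"),
                             min_del_display = NULL) {
  fdr_method <- match.arg(fdr_method)
  if (!"relevance" %in% names(annotations)) {
    annotations <- classify_relevance(annotations)
  }
  genes <- unique(panels$panels$gene)
  dat <- fc_tbl %>%
    select(-dplyr::any_of(c("gene", "relevance", "panel"))) %>%
    inner_join(annotations %>%
                 select("variant_id", "gene", "relevance"),
               by = "variant_id") %>%
    filter(.data$gene %in% genes,
           .data$relevance %in% c("deleterious", "benign"))
  per_gene <- dat %>%
    group_by(.data$gene) %>%
    summarise(n_del = sum(.data$relevance == "deleterious"),
              n_ben = sum(.data$relevance == "benign"),
              mean_fc_del = mean(.data$log2fc[.data$relevance == "deleterious"]),
              mean_fc_ben = mean(.data$log2fc[.data$relevance == "benign"]),
              p_value = if (n_del >= min_del && n_ben >= min_ben) {
                rank_sum_test(.data$log2fc[.data$relevance == "deleterious"],
                              .data$log2fc[.data$relevance == "benign"])
              } else NA_real_,
              .groups = "drop") %>%
    filter(.data$n_del >= min_del, .data$n_ben >= min_ben)
  if (nrow(per_gene) == 0) {
    warn("no gene passes the deleterious/benign eligibility gate")
    out <- per_gene %>% mutate(fdr = numeric(), significant = logical(),
                               panel = character(), inheritance = character())
    return(structure(out, class = c("gene_prior_result", class(out))))
  }
  out <- per_gene %>%
    mutate(fdr = bh_fdr(.data$p_value, method = fdr_method),
           significant = .data$fdr < alpha) %>%
    left_join(panels$panels %>% select("gene", "panel", "inheritance"),
              by = "gene") %>%
    mutate(panel = factor(.data$panel, levels = .disease_groups)) %>%
    arrange(.data$panel, desc(.data$n_del)) %>%
    mutate(panel = as.character(.data$panel))
  if (!is.null(min_del_display)) {
    out <- out %>% filter(!.data$significant | .data$n_del >= min_del_display)
  }
  structure(out, class = c("gene_prior_result", class(out)),
            alpha = alpha, fdr_method = fdr_method)
}

#' @rdname prioritize_genes
#' @param x A `gene_prior_result`.
#' @param ... Unused.
#' @export
glance.gene_prior_result <- function(x, ...) {
  tibble(n_genes_tested = nrow(x), n_significant = sum(x$significant),
         alpha = attr(x, "alpha") %||% 0.05,
         fdr_method = attr(x, "fdr_method") %||% "BH")
}
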