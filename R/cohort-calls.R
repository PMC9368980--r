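#' Construct a cohort call set
#'
#' A `cohort_calls` object holds the merged multi-sample call matrix of the
#' cohort: a variant table (one row per biallelic variant after splitting of
#' multiallelic records), the sample identifiers, an allele-dosage matrix and
#' a callability ("covered") matrix. Coverage distinguishes non-covered from
#' non-mutated sites: a genotype is only defined where the site is callable
#' in that sample.
#'
#' @param variants A data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; one alternate allele per row, unique rows.
#' @param samples Character vector of unique sample identifiers.
#' @param genotype Integer matrix, variants x samples, values 0/1/2 alternate
#'   allele dosage or `NA` for missing.
#' @param covered Logical matrix, variants x samples; `FALSE` marks sites
#'   outside a sample's callable region. A defined genotype implies
#'   `covered = TRUE`; genotypes at uncovered cells are set to `NA`.
#'
#' @return An object of class `cohort_calls`.
#' @export
cohort_calls <- function(variants, samples, genotype, covered) {
  variants <- as_tibble(variants)
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(variants))) {
    abort(paste("variants must have columns:", paste(req, collapse = ", ")))
  }
  variants <- variants %>%
    mutate(chrom = as.character(.data$chrom), pos = as.integer(.data$pos),
           ref = as.character(.data$ref), alt = as.character(.data$alt),
           variant_id = variant_id(.data$chrom, .data$pos, .data$ref, .data$alt))
  if (anyDuplicated(variants$variant_id)) {
    abort("duplicate variant keys in cohort")
  }
  if (any(variants$pos < 1L)) abort("positions must be >= 1")
  if (any(variants$ref == variants$alt)) abort("ref and alt alleles must differ")
  samples <- as.character(samples)
  if (anyDuplicated(samples)) abort("duplicate sample ids")
  genotype <- as.matrix(genotype)
  covered <- as.matrix(covered)
  storage.mode(genotype) <- "integer"
  storage.mode(covered) <- "logical"
  dims <- c(nrow(variants), length(samples))
  if (!identical(dim(genotype), dims) || !identical(dim(covered), dims)) {
    abort("genotype/covered dimensions must be |variants| x |samples|")
  }
  if (any(!is.na(genotype) & !(genotype %in% 0:2))) {
    abort("genotype dosages must be 0, 1, 2 or NA")
  }
  # enforce: not covered => missing genotype
  genotype[!covered] <- NA_integer_
  dimnames(genotype) <- dimnames(covered) <- list(variants$variant_id, samples)
  structure(
    list(variants = variants, samples = samples,
         genotype = genotype, covered = covered),
    class = "cohort_calls"
  )
}

#' @export
print.cohort_calls <- function(x, ...) {
  cat("<cohort_calls> ", nrow(x$variants), " variants x ",
      length(x$samples), " samples\n", sep = "")
  cat("  callable cells: ",
      sprintf("%.1f%%", 100 * mean(x$covered)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.cohort_calls <- function(x) c(nrow(x$variants), length(x$samples))

#' Subset a cohort call set
#'
#' @param calls A [cohort_calls()] object.
#' @param variant_ids,sample_ids Optional character vectors selecting (in
#'   order) variants and/or samples to retain.
#' @return A `cohort_calls` object.
#' @export
subset_calls <- function(calls, variant_ids = NULL, sample_ids = NULL) {
  stopifnot(inherits(calls, "cohort_calls"))
  vi <- if (is.null(variant_ids)) calls$variants$variant_id else variant_ids
  si <- if (is.null(sample_ids)) calls$samples else sample_ids
  if (!all(vi %in% calls$variants$variant_id)) abort("unknown variant id")
  if (!all(si %in% calls$samples)) abort("unknown sample id")
  cohort_calls(
    calls$variants[match(vi, calls$variants$variant_id),
                   c("chrom", "pos", "ref", "alt")],
    si,
    calls$genotype[vi, si, drop = FALSE],
    calls$covered[vi, si, drop = FALSE]
  )
}

#' Genotypes as a tidy table
#'
#' @param calls A [cohort_calls()] object.
#' @return A tibble with one row per variant x sample: `variant_id`,
#'   `sample_id`, `dosage`, `covered`.
#' @export
tidy_genotypes <- function(calls) {
  stopifnot(inherits(calls, "cohort_calls"))
  tibble(
    variant_id = rep(calls$variants$variant_id, times = length(calls$samples)),
    sample_id = rep(calls$samples, each = nrow(calls$variants)),
    dosage = as.integer(calls$genotype),
    covered = as.logical(calls$covered)
  )
}
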