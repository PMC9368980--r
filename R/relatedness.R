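#' Prune SNPs for relatedness estimation
#'
#' Selects a set of common, well-genotyped, approximately independent SNVs
#' for identity-by-descent estimation: single-nucleotide variants genotyped
#' in at least `1 - max_missing` of samples, with minor-allele frequency at
#' least `min_maf`, then pairwise linkage-disequilibrium pruning in sliding
#' windows (one SNP of each pair with r-squared above `r2_threshold` is
#' dropped, keeping the one with the higher minor-allele frequency).
#'
#' @param calls A [cohort_calls()] object.
#' @param max_missing Maximum genotype missingness per SNP (default 0.05,
#'   i.e. genotyped in at least 95% of samples).
#' @param min_maf Minimum minor-allele frequency (default 0.05).
#' @param window,step,r2_threshold LD-pruning window size in SNPs, step in
#'   SNPs, and the r-squared cutoff (defaults 50, 5, 0.5).
#' @return A tibble of retained variants (`chrom`, `pos`, `ref`, `alt`,
#'   `variant_id`).
#' @export
prune_snps <- function(calls, max_missing = 0.05, min_maf = 0.05,
                       window = 50, step = 5, r2_threshold = 0.5) {
  stopifnot(inherits(calls, "cohort_calls"))
  v <- calls$variants
  is_snv <- nchar(v$ref) == 1 & nchar(v$alt) == 1
  geno <- calls$genotype
  missingness <- rowMeans(is.na(geno))
  af <- rowMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- which(is_snv & missingness <= max_missing &
                  !is.na(maf) & maf >= min_maf)
  if (length(keep) == 0) {
    abort("no SNPs survive missingness/MAF filters; relax thresholds")
  }
  # order along the genome, then windowed greedy LD pruning
  keep <- keep[order(v$chrom[keep], v$pos[keep])]
  alive <- rep(TRUE, length(keep))
  g <- t(geno[keep, , drop = FALSE])  # samples x snps for cor()
  start <- 1L
  while (start <= length(keep)) {
    idx <- seq(start, min(start + window - 1L, length(keep)))
    idx <- idx[alive[idx]]
    if (length(idx) >= 2) {
      r2 <- suppressWarnings(
        cor(g[, idx, drop = FALSE], use = "pairwise.complete.obs")^2)
      repeat {
        r2[!is.finite(r2)] <- 0
        diag(r2) <- 0
        mx <- which(r2 > r2_threshold, arr.ind = TRUE)
        if (nrow(mx) == 0) break
        pair <- mx[1, ]
        i1 <- idx[pair[1]]; i2 <- idx[pair[2]]
        # drop the lower-MAF member; tie -> the later one
        drop_local <- if (maf[keep[i1]] < maf[keep[i2]]) pair[1] else pair[2]
        alive[idx[drop_local]] <- FALSE
        r2[drop_local, ] <- 0
        r2[, drop_local] <- 0
      }
    }
    if (start + window - 1L >= length(keep)) break
    start <- start + step
  }
  v[keep[alive], c("chrom", "pos", "ref", "alt", "variant_id")]
}

#' Method-of-moments identity-by-descent estimation
#'
#' For every sample pair, counts identity-by-state (IBS) sharing over the
#' pruned SNPs and solves the method-of-moments equations for the
#' IBD-state probabilities (z0, z1, z2), using allele frequencies estimated
#' from the cohort itself. Estimates are clamped to `[0, 1]` and
#' renormalized; the genome-sharing coefficient is
#' `pi_hat = z2 + z1 / 2` (about 1 for duplicates or monozygotic twins,
#' about 0.5 for first-degree relatives, about 0 for unrelated pairs).
#'
#' @param calls A [cohort_calls()] object (at least 2 samples).
#' @param snps Variant table from [prune_snps()]; defaults to pruning
#'   `calls` with standard thresholds.
#' @param min_snps Below this many usable SNPs per pair the estimates are
#'   flagged low-confidence (default 100) with a warning.
#' @return A tibble: `sample1`, `sample2`, `n_snps`, `z0`, `z1`, `z2`,
#'   `pi_hat`, `low_confidence`.
#' @export
estimate_ibd <- function(calls, snps = prune_snps(calls), min_snps = 100) {
  stopifnot(inherits(calls, "cohort_calls"))
  if (length(calls$samples) < 2) abort("need at least 2 samples")
  ids <- intersect(snps$variant_id, calls$variants$variant_id)
  g <- calls$genotype[ids, , drop = FALSE]
  p <- rowMeans(g, na.rm = TRUE) / 2   # cohort alt-allele frequency
  q <- 1 - p
  # per-SNP conditional IBS probabilities given IBD state
  p0_0 <- 2 * p^2 * q^2
  p1_0 <- 4 * p^3 * q + 4 * p * q^3
  p2_0 <- 1 - p0_0 - p1_0
  p1_1 <- 2 * p * q
  p2_1 <- 1 - p1_1
  # pairwise IBS counts and expectation sums via indicator-matrix products
  ok <- !is.na(g)
  a0 <- ok & g == 0L; a1 <- ok & g == 1L; a2 <- ok & g == 2L
  storage.mode(a0) <- storage.mode(a1) <- storage.mode(a2) <- "double"
  okd <- ok; storage.mode(okd) <- "double"
  s0 <- crossprod(a0, a2); s0 <- s0 + t(s0)
  s1 <- crossprod(a0, a1) + crossprod(a1, a2)
  s1 <- s1 + t(s1)
  s2 <- crossprod(a0) + crossprod(a1) + crossprod(a2)
  L <- crossprod(okd)
  e00 <- crossprod(okd, p0_0 * okd)
  e10 <- crossprod(okd, p1_0 * okd)
  e20 <- crossprod(okd, p2_0 * okd)
  e11 <- crossprod(okd, p1_1 * okd)
  e21 <- crossprod(okd, p2_1 * okd)

  iu <- which(upper.tri(L), arr.ind = TRUE)
  li <- L[iu]
  z0 <- s0[iu] / e00[iu]
  z1 <- (s1[iu] - z0 * e10[iu]) / e11[iu]
  z2 <- (s2[iu] - z0 * e20[iu] - z1 * e21[iu]) / li
  zm <- pmin(pmax(cbind(z0, z1, z2), 0), 1)
  tot <- rowSums(zm)
  zm[tot == 0, ] <- rep(c(1, 0, 0), each = sum(tot == 0))
  tot[tot == 0] <- 1
  zm <- zm / tot
  out <- tibble(
    sample1 = calls$samples[iu[, 1]], sample2 = calls$samples[iu[, 2]],
    n_snps = as.integer(li),
    z0 = zm[, 1], z1 = zm[, 2], z2 = zm[, 3],
    pi_hat = pmin(pmax(zm[, 3] + zm[, 2] / 2, 0), 1),
    low_confidence = li < min_snps)
  out$z0[out$n_snps == 0] <- NA_real_
  out$z1[out$n_snps == 0] <- NA_real_
  out$z2[out$n_snps == 0] <- NA_real_
  out$pi_hat[out$n_snps == 0] <- NA_real_
  if (any(out$low_confidence)) {
    warn(paste0(sum(out$low_confidence), " pair(s) estimated from fewer than ",
                min_snps, " SNPs; flagged low-confidence"))
  }
  out
}

#' Resolve related sample pairs by greedy removal
#'
#' Builds the graph of sample pairs whose `pi_hat` exceeds `threshold` and
#' repeatedly removes the sample participating in the most flagged pairs
#' until none remain, so only the minimum necessary samples are dropped
#' (one of each duplicate pair, the shared child of a parent pair, ...).
#' Degree ties break deterministically on lexicographic sample id.
#'
#' @param estimates Pairwise IBD tibble from [estimate_ibd()].
#' @param threshold `pi_hat` above which a pair is considered related
#'   (default 0.35).
#' @return Character vector of sample ids to remove (possibly empty).
#' @export
drop_related <- function(estimates, threshold = 0.35) {
  flagged <- estimates %>%
    filter(!is.na(.data$pi_hat), .data$pi_hat > threshold)
  removed <- character()
  edges <- flagged[, c("sample1", "sample2")]
  while (nrow(edges) > 0) {
    deg <- sort(table(c(edges$sample1, edges$sample2)), decreasing = TRUE)
    top <- names(deg)[deg == max(deg)]
    victim <- sort(top)[1]
    removed <- c(removed, victim)
    edges <- edges[edges$sample1 != victim & edges$sample2 != victim, ,
                   drop = FALSE]
  }
  removed
}
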