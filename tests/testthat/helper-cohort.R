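# shared fixtures built in code

suppressMessages({
  library(dplyr)
  library(tibble)
})

# tiny hand-built call set: 4 variants x 4 samples
tiny_calls <- function() {
  variants <- tibble(
    chrom = c("chr1", "chr1", "chr2", "X"),
    pos = c(100L, 200L, 50L, 1000L),
    ref = c("A", "G", "T", "C"),
    alt = c("T", "C", "G", "A"))
  geno <- matrix(c(
    0L, 1L, 2L, NA,
    1L, 1L, 0L, 0L,
    2L, 0L, NA, 1L,
    0L, 1L, 0L, 1L), nrow = 4, byrow = TRUE)
  covered <- matrix(TRUE, 4, 4)
  covered[1, 4] <- FALSE
  covered[3, 3] <- FALSE
  cohort_calls(variants, paste0("S", 1:4), geno, covered)
}

tiny_meta <- function() {
  tibble(sample_id = paste0("S", 1:4),
         disease_group = c("IRD", "IRD", "NRD", "NRD"),
         diag_status = c("solved", "non_solved", "not_applicable",
                         "not_applicable"),
         subphenotype = c("syndromic", "non_syndromic", NA, NA),
         sex = c("male", "female", "male", "female"))
}

# HWE genotype matrix, variants x samples, at given alt AFs
hwe_genotypes <- function(afs, n_samples) {
  matrix(rbinom(length(afs) * n_samples, 2, rep(afs, n_samples)),
         nrow = length(afs))
}

# calls object of L independent HWE SNVs, fully covered
hwe_calls <- function(afs, n_samples, ids = sprintf("S%04d",
                                                    seq_len(n_samples))) {
  L <- length(afs)
  v <- tibble(chrom = "chr1", pos = seq_len(L) * 10L, ref = "A", alt = "G")
  cohort_calls(v, ids, hwe_genotypes(afs, n_samples),
               matrix(TRUE, L, n_samples))
}

# exact one-sided hypergeometric p for a 2x2 table (oracle for Fisher)
fisher_oracle_greater <- function(m) {
  # P(X >= m[1,1]) with X ~ Hypergeom(row1 total, row2 total, col1 total)
  k <- m[1, 1]
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(r1 + r2, c1)
  sum(probs[xs >= k])
}

# exact one-sided rank-sum p by full enumeration (oracle for Wilcoxon)
ranksum_oracle_greater <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v); m <- length(x)
  r_obs <- sum(rank(all_v)[seq_len(m)])
  combos <- utils::combn(n, m)
  rks <- rank(all_v)
  stat <- apply(combos, 2, function(ix) sum(rks[ix]))
  mean(stat >= r_obs)
}

# type-7 quantile oracle by linear interpolation of order statistics
quantile7_oracle <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# step-up BH oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  cummin(p[o] * m / (m - seq_along(p) + 1))[ro]
}
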