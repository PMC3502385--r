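# Independent oracle for the Weir-Cockerham (1984) theta estimator.
#
# Works from raw per-population genotype counts and evaluates the variance
# components a, b, c separately for each of the two alleles, combining them
# as ratio of summed components (the general multiallelic form). This is a
# distinct computational path from the package's single-allele
# implementation and is used to pin its output down to 1e-10.
wc_theta_oracle <- function(counts) {
  # counts: populations x 3 matrix of (hom_ref, het, hom_alt) counts
  n <- rowSums(counts)
  keep <- n > 0
  counts <- counts[keep, , drop = FALSE]
  n <- n[keep]
  r <- length(n)
  stopifnot(r >= 2)
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  h <- counts[, 2] / n
  p_ref <- (2 * counts[, 1] + counts[, 2]) / (2 * n)
  num <- den <- 0
  for (p in list(p_ref, 1 - p_ref)) {
    pbar <- sum(n * p) / sum(n)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / sum(n)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Genotype counts (populations x 3) of one locus of a genotype_table.
genotype_counts <- function(table, locus) {
  l <- match(locus, table$loci$id)
  t(sapply(table$populations, function(pop) {
    g <- table$calls[table$individuals$population == pop, l]
    g <- g[!is.na(g)]
    c(sum(g == 2), sum(g == 1), sum(g == 0))
  }))
}
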