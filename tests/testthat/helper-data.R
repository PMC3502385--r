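# Small constructors used across test files.

# One-locus table from per-population genotype counts c(hom_ref, het, hom_alt).
one_locus_table <- function(..., locus = "L1") {
  pops <- list(...)
  calls <- unlist(lapply(pops, function(ct) rep(c(2L, 1L, 0L), times = ct)))
  genotype_table(matrix(calls, ncol = 1), loci = locus,
                 populations = rep(paste0("pop", seq_along(pops)),
                                   vapply(pops, sum, numeric(1))))
}

# Random biallelic table: K populations of n individuals at L loci, each
# locus with its own uniform per-population frequencies (no structure
# assumed; this is raw material for invariance/oracle checks).
random_table <- function(K, n, L, seed, missing_rate = 0) {
  withr::with_seed(seed, {
    freqs <- matrix(runif(K * L, 0.05, 0.95), K, L)
    pop_of <- rep(seq_len(K), each = n)
    P <- freqs[pop_of, , drop = FALSE]
    calls <- matrix(rbinom(length(P), 2L, as.vector(P)), n * K, L)
    if (missing_rate > 0) {
      calls[runif(length(calls)) < missing_rate] <- NA_integer_
    }
    genotype_table(calls, loci = sprintf("L%03d", seq_len(L)),
                   populations = paste0("pop", pop_of))
  })
}
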