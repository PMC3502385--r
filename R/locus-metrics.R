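#' Per-locus Weir-Cockerham variance components and theta
#'
#' Estimates the among-population differentiation of every locus with the
#' Weir & Cockerham (1984) method-of-moments estimator
#' `theta = a / (a + b + c)`, where `a`, `b` and `c` are the among-
#' population, among-individual-within-population and within-individual
#' variance components computed from per-population sample sizes, allele
#' frequencies and observed heterozygote proportions. Negative estimates
#' are preserved (they are informative for ranking); a locus monomorphic
#' across all populations has no defined theta and gets `NA`.
#'
#' @param x A [genotype_table()], or an `allele_freq_matrix` carrying the
#'   observed heterozygote proportions (as produced by
#'   [compute_allele_frequencies()]).
#' @param loci Optional character vector restricting the computation to a
#'   locus subset.
#' @return Data frame with columns `locus`, `a`, `b`, `c`, `theta`,
#'   `defined`.
#' @export
wc_fst_per_locus <- function(x, loci = NULL) {
  afm <- if (inherits(x, "genotype_table")) compute_allele_frequencies(x)
         else x
  stopifnot(inherits(afm, "allele_freq_matrix"))
  if (is.null(afm$het)) {
    stop("observed heterozygote proportions are required for the ",
         "Weir-Cockerham components")
  }
  if (length(afm$populations) < 2) {
    stop("at least two populations are required")
  }
  ids <- if (is.null(loci)) afm$loci else loci
  idx <- match(ids, afm$loci)
  if (anyNA(idx)) stop("unknown locus id(s)")
  out <- data.frame(locus = ids, a = NA_real_, b = NA_real_, c = NA_real_,
                    theta = NA_real_, defined = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_along(idx)) {
    l <- idx[j]
    comp <- .wc_components(n = afm$n_genes[, l] / 2,
                           p = afm$freq[, l],
                           h = afm$het[, l])
    out$a[j] <- comp["a"]; out$b[j] <- comp["b"]; out$c[j] <- comp["c"]
    denom <- sum(comp)
    if (is.finite(denom) && denom != 0) {
      out$theta[j] <- comp["a"] / denom
      out$defined[j] <- TRUE
    }
  }
  out
}

# WC84 components for one biallelic locus.
# n: individuals sampled per population (non-missing), p: reference-allele
# frequency, h: observed heterozygote proportion.
.wc_components <- function(n, p, h) {
  keep <- !is.na(p) & n > 0
  n <- n[keep]; p <- p[keep]; h <- h[keep]
  r <- length(n)
  if (r < 2) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nbar <- mean(n)
  if (nbar <= 1) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Multilocus F_ST over a locus subset
#'
#' The ratio-of-sums estimator `sum(a) / sum(a + b + c)` over the loci with
#' defined Weir-Cockerham components.
#'
#' @inheritParams wc_fst_per_locus
#' @return A single numeric value.
#' @export
multilocus_fst <- function(x, loci = NULL) {
  comp <- wc_fst_per_locus(x, loci)
  comp <- comp[comp$defined, , drop = FALSE]
  if (!nrow(comp)) stop("no locus has defined variance components")
  sum(comp$a) / sum(comp$a + comp$b + comp$c)
}

#' Pairwise multilocus F_ST matrix
#'
#' Entry (i, j) is [multilocus_fst()] computed on populations i and j only,
#' over the given locus subset; the diagonal is zero.
#'
#' @param table A [genotype_table()] with at least two populations.
#' @param loci Optional locus subset.
#' @return Symmetric populations x populations matrix.
#' @export
pairwise_fst_matrix <- function(table, loci = NULL) {
  pops <- table$populations
  K <- length(pops)
  stopifnot(K >= 2)
  m <- matrix(0, K, K, dimnames = list(pops, pops))
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      v <- tryCatch(
        multilocus_fst(subset_populations(table, pops[c(i, j)]), loci),
        error = function(e) NA_real_)
      m[i, j] <- m[j, i] <- v
    }
  }
  m
}

#' Rosenberg's informativeness for assignment (I_n)
#'
#' For each locus, `I_n = sum over alleles of [ -pbar log pbar +
#' sum_i (p_i / K) log p_i ]` with natural logs, `0 log 0 = 0`, and `pbar`
#' the unweighted mean frequency over the `K` populations. `I_n` is zero
#' exactly when all populations share the same frequencies and reaches
#' `log 2` for two populations fixed for alternative alleles. Populations
#' with no data at a locus are excluded (with a warning); fewer than two
#' remaining is an error.
#'
#' @param freqs An `allele_freq_matrix` (or a [genotype_table()], converted
#'   internally).
#' @param loci Optional locus subset.
#' @return Named numeric vector of I_n values (non-negative; tiny negative
#'   rounding is clamped to zero).
#' @export
informativeness_in <- function(freqs, loci = NULL) {
  afm <- if (inherits(freqs, "genotype_table")) {
    compute_allele_frequencies(freqs)
  } else freqs
  ids <- if (is.null(loci)) afm$loci else loci
  idx <- match(ids, afm$loci)
  if (anyNA(idx)) stop("unknown locus id(s)")
  plog <- function(x) ifelse(x > 0, x * log(x), 0)
  out <- stats::setNames(numeric(length(ids)), ids)
  warned <- FALSE
  for (j in seq_along(idx)) {
    p <- afm$freq[, idx[j]]
    drop <- is.na(p) | afm$n_genes[, idx[j]] == 0
    if (any(drop)) {
      if (!warned) {
        warning("excluding population(s) with no data at some loci")
        warned <- TRUE
      }
      p <- p[!drop]
    }
    K <- length(p)
    if (K < 2) stop("fewer than 2 populations with data at locus ", ids[j])
    val <- 0
    for (q in list(p, 1 - p)) {
      qbar <- mean(q)
      val <- val - plog(qbar) + sum(plog(q)) / K
    }
    out[j] <- max(val, 0)
  }
  out
}

#' Rarefied allelic richness per population
#'
#' FSTAT-style hypergeometric rarefaction: the expected number of distinct
#' alleles in a random subsample of `g` gene copies,
#' `A_r = sum over alleles of [1 - choose(n - count, g) / choose(n, g)]`.
#' For biallelic data `1 <= A_r <= 2`.
#'
#' @param table A [genotype_table()].
#' @param locus Locus id.
#' @param g Rarefaction size in gene copies; defaults to the smallest
#'   non-missing gene-copy count across populations at the locus. Must be
#'   at least 2 and no larger than any population's count.
#' @return Named numeric vector, one value per population.
#' @export
allelic_richness_rarefied <- function(table, locus, g = NULL) {
  afm <- compute_allele_frequencies(table)
  l <- match(locus, afm$loci)
  if (is.na(l)) stop("unknown locus: ", locus)
  n <- afm$n_genes[, l]
  if (is.null(g)) g <- min(n)
  stopifnot(g >= 2)
  if (any(n < g)) {
    stop("rarefaction size g = ", g, " exceeds the gene-copy count of ",
         "population(s): ",
         paste(afm$populations[n < g], collapse = ", "))
  }
  ref_count <- round(afm$freq[, l] * n)
  sapply(seq_along(n), function(k) {
    counts <- c(ref_count[k], n[k] - ref_count[k])
    sum(1 - exp(lchoose(n[k] - counts, g) - lchoose(n[k], g)))
  }) |> stats::setNames(afm$populations)
}

#' Chi-square test of Hardy-Weinberg equilibrium in one population
#'
#' Compares observed genotype counts (hom-ref, het, hom-alt) with the
#' Hardy-Weinberg expectations computed from the sample allele frequency,
#' as a 1-df chi-square. Equivalent to `chi2 = n * Fhat^2`, where `Fhat` is
#' the within-population inbreeding coefficient, so the direction of the
#' departure (heterozygote excess or deficit) is reported alongside.
#'
#' @param table A [genotype_table()].
#' @param locus Locus id.
#' @param population Population label.
#' @return List with `chisq`, `df`, `p_value`, `direction` (`"excess"`,
#'   `"deficit"` or `"none"`), `n`, and `defined` (`FALSE` for a
#'   monomorphic sample, in which case the test statistics are `NA`).
#' @export
hwe_chisq_test <- function(table, locus, population) {
  stopifnot(population %in% table$populations)
  l <- match(locus, table$loci$id)
  if (is.na(l)) stop("unknown locus: ", locus)
  g <- table$calls[table$individuals$population == population, l]
  g <- g[!is.na(g)]
  if (!length(g)) stop("no non-missing genotypes")
  n <- length(g)
  obs <- c(sum(g == 2), sum(g == 1), sum(g == 0))
  p <- (2 * obs[1] + obs[2]) / (2 * n)
  if (p == 0 || p == 1) {
    return(list(chisq = NA_real_, df = 1L, p_value = NA_real_,
                direction = "none", n = n, defined = FALSE))
  }
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chisq <- sum((obs - expd)^2 / expd)
  dir <- if (obs[2] > expd[2]) "excess"
         else if (obs[2] < expd[2]) "deficit" else "none"
  list(chisq = chisq, df = 1L,
       p_value = stats::pchisq(chisq, 1, lower.tail = FALSE),
       direction = dir, n = n, defined = TRUE)
}

#' Permutation G-test of linkage disequilibrium between two loci
#'
#' Builds the 3x3 genotypic contingency table of the two loci in one
#' population and tests association with a log-likelihood-ratio G
#' statistic; the p-value comes from permuting one locus's genotypes among
#' individuals (`n_perm` seeded permutations), which keeps both genotypic
#' margins' distributions intact under the null of independence.
#'
#' @param table A [genotype_table()].
#' @param locus_a,locus_b Locus ids.
#' @param population Population label.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @return List with `g_statistic`, `p_value`, `n`, `defined` (`FALSE` when
#'   either locus is monomorphic in the sample or fewer than 5 individuals
#'   are jointly genotyped).
#' @export
ld_pairwise_test <- function(table, locus_a, locus_b, population,
                             n_perm = 1000, seed = 1L) {
  la <- match(locus_a, table$loci$id)
  lb <- match(locus_b, table$loci$id)
  if (is.na(la) || is.na(lb)) stop("unknown locus id")
  rows <- table$individuals$population == population
  ga <- table$calls[rows, la]
  gb <- table$calls[rows, lb]
  keep <- !is.na(ga) & !is.na(gb)
  ga <- ga[keep]; gb <- gb[keep]
  n <- length(ga)
  undefined <- list(g_statistic = NA_real_, p_value = NA_real_, n = n,
                    defined = FALSE)
  if (n < 5) return(undefined)
  if (length(unique(ga)) < 2 || length(unique(gb)) < 2) return(undefined)
  gstat <- function(a, b) {
    tab <- table(factor(a, 0:2), factor(b, 0:2))
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    o <- as.numeric(tab); e <- as.numeric(e)
    2 * sum(ifelse(o > 0, o * log(o / e), 0))
  }
  g_obs <- gstat(ga, gb)
  exceed <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm),
               function(i) gstat(ga, sample(gb)) >= g_obs - 1e-12,
               logical(1)))
  })
  list(g_statistic = g_obs, p_value = (exceed + 1) / (n_perm + 1), n = n,
       defined = TRUE)
}

#' Sequential Bonferroni (Holm step-down) correction
#'
#' Holm's step-down procedure: sort the p-values ascending and reject while
#' `p_(k) < alpha / (m - k + 1)`, stopping at the first non-rejection.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param alpha Family-wise error level (default 0.05).
#' @return Logical vector of rejection flags, in input order.
#' @export
sequential_bonferroni <- function(pvalues, alpha = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "holm") < alpha
}

#' Per-locus summary statistics table
#'
#' Convenience export combining observed and expected heterozygosity
#' (pooled over populations), per-locus theta and I_n into one data frame,
#' in the shape used for per-locus report tables.
#'
#' @param table A [genotype_table()].
#' @return Data frame with columns `locus`, `ho`, `he`, `fst`, `in_` .
#' @export
locus_summary <- function(table) {
  afm <- compute_allele_frequencies(table)
  wn <- afm$n_genes / 2
  ho <- colSums(afm$het * wn, na.rm = TRUE) / colSums(wn, na.rm = TRUE)
  he <- colMeans(2 * afm$freq * (1 - afm$freq), na.rm = TRUE)
  wc <- wc_fst_per_locus(afm)
  data.frame(locus = afm$loci, ho = ho, he = he, fst = wc$theta,
             in_ = as.numeric(informativeness_in(afm)),
             row.names = NULL, stringsAsFactors = FALSE)
}
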