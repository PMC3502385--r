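# Log-probabilities are clamped at this floor so that impossible genotypes
# (raw frequency exactly 0 or 1) stay representable in matrix arithmetic
# without producing 0 * -Inf = NaN; sums involving the floor still compare
# exactly across populations.
.LOG_FLOOR <- -1e12

.clog <- function(p) pmax(log(p), .LOG_FLOOR)

# N x K matrix of log-likelihoods of dosage matrix G (NA = missing, skipped)
# under HWE with per-population reference frequencies `freq` (K x L).
.loglik_matrix <- function(G, freq) {
  logp <- .clog(freq)
  logq <- .clog(1 - freq)
  G0 <- G; G0[is.na(G0)] <- 0L
  G2 <- 2L - G; G2[is.na(G2)] <- 0L
  const <- rowSums(G == 1L, na.rm = TRUE) * log(2)
  G0 %*% t(logp) + G2 %*% t(logq) + const
}

# Tie-aware assignment bookkeeping. Returns, per row of ll: the first
# maximizing population (input-order tie break), the number of (near-)tied
# maximizers, and the fractional credit given to the true population.
.assign_ll <- function(ll, true_idx = NULL, tol = 1e-9) {
  first <- max.col(ll, ties.method = "first")
  rmax <- ll[cbind(seq_len(nrow(ll)), first)]
  tied <- ll >= rmax - tol
  n_tied <- rowSums(tied)
  out <- list(assigned = max.col(tied, ties.method = "first"),
              n_tied = n_tied, max_ll = rmax)
  if (!is.null(true_idx)) {
    out$credit <- tied[cbind(seq_len(nrow(ll)), true_idx)] / n_tied
  }
  out
}

#' Estimate a baseline of smoothed allele frequencies
#'
#' Builds the reference object for likelihood assignment from a training
#' set: per population x locus, the posterior-mean reference-allele
#' frequency `(x + 0.5) / (n_genes + 1)` where `x` is the reference
#' gene count (a symmetric Dirichlet(1/2, 1/2)-style smoothing for two
#' alleles). Smoothing guarantees frequencies strictly inside (0, 1), hence
#' finite log-likelihoods for every genotype.
#'
#' @param training A [genotype_table()] of baseline individuals.
#' @param loci Panel to use: a `panel` object, a character vector of locus
#'   ids, or `NULL` for all loci.
#' @return Object of class `baseline`: list with `populations`, `loci`,
#'   `post_freq` (populations x loci, strictly in (0, 1)).
#' @export
estimate_baseline <- function(training, loci = NULL) {
  if (inherits(loci, "panel")) loci <- loci$loci
  if (!is.null(loci)) training <- subset_loci(training, loci)
  counts <- table(.pop_factor(training))
  if (length(counts) == 0 || any(counts == 0)) {
    stop("empty training population")
  }
  afm <- compute_allele_frequencies(training)
  x <- afm$freq * afm$n_genes
  x[is.na(x)] <- 0
  if (any(afm$n_genes == 0)) {
    warning("population(s) with no data at some loci; baseline falls back ",
            "to the prior mean 0.5 there")
  }
  post <- (x + 0.5) / (afm$n_genes + 1)
  structure(list(populations = afm$populations, loci = afm$loci,
                 post_freq = post),
            class = "baseline")
}

#' Assign individuals to baseline populations by maximum likelihood
#'
#' Each individual's log-likelihood for population k is the sum over its
#' non-missing panel loci of the log HWE genotype probability (`p^2`,
#' `2p(1-p)`, `(1-p)^2` with `p` the baseline's smoothed frequency).
#' Individuals are assigned to the maximizing population; exact ties are
#' flagged and broken by baseline population order. Individuals missing all
#' panel loci are flagged unassignable and excluded from the probabilities.
#'
#' @param holdout A [genotype_table()] whose loci include the baseline's.
#' @param baseline A [estimate_baseline()] result.
#' @return Object of class `assignment_result`: list with `individuals`
#'   (data frame: id, true population, assigned, max log-likelihood, tie,
#'   unassignable, correct), `per_population` (named vector of
#'   correct-assignment probabilities) and `overall` (their unweighted
#'   mean).
#' @export
assign_individuals <- function(holdout, baseline) {
  stopifnot(inherits(baseline, "baseline"))
  idx <- match(baseline$loci, holdout$loci$id)
  if (anyNA(idx)) stop("holdout table lacks baseline locus/loci")
  G <- holdout$calls[, idx, drop = FALSE]
  usable <- rowSums(!is.na(G)) > 0
  if (!all(usable)) {
    warning(sum(!usable), " individual(s) missing all panel loci: ",
            "unassignable, excluded from probabilities")
  }
  ll <- .loglik_matrix(G, baseline$post_freq)
  res <- .assign_ll(ll)
  assigned <- baseline$populations[res$assigned]
  truepop <- holdout$individuals$population
  correct <- assigned == truepop
  ind <- data.frame(id = holdout$individuals$id,
                    population = truepop,
                    assigned = ifelse(usable, assigned, NA_character_),
                    log_likelihood = ifelse(usable, res$max_ll, NA_real_),
                    tie = usable & res$n_tied > 1,
                    unassignable = !usable,
                    correct = ifelse(usable, correct, NA),
                    stringsAsFactors = FALSE)
  pops <- holdout$populations
  per_pop <- vapply(pops, function(p) {
    ok <- truepop == p & usable
    if (!any(ok)) return(NA_real_)
    mean(correct[ok])
  }, numeric(1))
  structure(list(individuals = ind, per_population = per_pop,
                 overall = mean(per_pop, na.rm = TRUE)),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat("assignment_result:", nrow(x$individuals), "individuals,",
      sprintf("overall correct = %.3f\n", x$overall))
  invisible(x)
}

#' Exact probability of correct assignment for a small panel
#'
#' Enumerates every multilocus genotype (3^L combinations) and computes,
#' for each population, the probability that an individual drawn from it is
#' assigned back to it by maximum likelihood against the same frequencies.
#' Ties among t maximizing populations earn credit 1/t. The result is the
#' unweighted mean over populations (the exact counterpart of f_ORCA).
#'
#' @param freqs Populations x loci matrix of reference-allele frequencies
#'   (raw, not smoothed; zeros and ones are allowed).
#' @param max_genotypes Enumeration guard (default 20000 combinations).
#' @return A single probability.
#' @export
orca_fcorrect_exact <- function(freqs, max_genotypes = 20000) {
  freqs <- as.matrix(freqs)
  K <- nrow(freqs); L <- ncol(freqs)
  stopifnot(K >= 2, L >= 1)
  if (3^L > max_genotypes) {
    stop("3^", L, " genotypes is too many to enumerate; ",
         "use orca_simulation() for panels this large")
  }
  gmat <- as.matrix(expand.grid(rep(list(0:2), L)))
  storage.mode(gmat) <- "integer"
  ll <- .loglik_matrix(gmat, freqs)
  P <- exp(ll)  # exact genotype probabilities; floor maps to exactly 0
  first <- max.col(ll, ties.method = "first")
  rmax <- ll[cbind(seq_len(nrow(ll)), first)]
  tied <- ll >= rmax - 1e-9
  n_tied <- rowSums(tied)
  per_pop <- vapply(seq_len(K), function(i) {
    sum(P[, i] * tied[, i] / n_tied)
  }, numeric(1))
  mean(per_pop)
}

#' Monte-Carlo simulation of assignment accuracy (f_ORCA)
#'
#' Repeats `n_reps` times: draw `n_individuals` split as evenly as possible
#' among the populations (any remainder goes to the first populations in
#' order), simulate each individual's genotypes as `Binomial(2, p)` from
#' its population's frequencies, assign by maximum likelihood against the
#' same frequencies, and record the frequency of correct assignment with
#' ties credited fractionally.
#'
#' @inheritParams orca_fcorrect_exact
#' @param n_reps Number of replicates (default 500).
#' @param n_individuals Individuals per replicate (default 1000).
#' @param seed Integer seed.
#' @return List with `reps` (per-replicate f_ORCA), `mean`, `q1`, `q3`,
#'   `n_reps`, `n_individuals`.
#' @export
orca_simulation <- function(freqs, n_reps = 500, n_individuals = 1000,
                            seed = 1L) {
  freqs <- as.matrix(freqs)
  K <- nrow(freqs); L <- ncol(freqs)
  if (K < 2) stop("at least two populations are required")
  n_k <- rep(n_individuals %/% K, K)
  rem <- n_individuals %% K
  if (rem > 0) n_k[seq_len(rem)] <- n_k[seq_len(rem)] + 1L
  pop_of <- rep(seq_len(K), times = n_k)
  Pmat <- freqs[pop_of, , drop = FALSE]
  reps <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(rep) {
      G <- matrix(stats::rbinom(length(Pmat), 2L, as.vector(Pmat)),
                  nrow(Pmat), L)
      ll <- .loglik_matrix(G, freqs)
      credit <- .assign_ll(ll, true_idx = pop_of)$credit
      mean(vapply(seq_len(K), function(i) mean(credit[pop_of == i]),
                  numeric(1)))
    }, numeric(1))
  })
  list(reps = reps, mean = mean(reps),
       q1 = unname(stats::quantile(reps, 0.25)),
       q3 = unname(stats::quantile(reps, 0.75)),
       n_reps = n_reps, n_individuals = n_individuals)
}
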