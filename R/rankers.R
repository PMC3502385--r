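#' Configuration for the assignment-performance rankers
#'
#' @param sim_pop_size Simulated individuals per population per resampling
#'   replicate (default 200).
#' @param iterations Number of resampling replicates (default 250).
#' @param min_correct Target correct-assignment proportion used by
#'   [whichloci_rank()] to report the minimum panel (default 0.95).
#' @param performance_target Correct-assignment proportion whose attainment
#'   [bels_rank()] optimizes toward; used to annotate the removal trace
#'   (default 1.0).
#' @param seed Integer seed for the common-random-number simulation.
#' @param locus_input_order Explicit locus ordering used to break ties (and
#'   to order candidate evaluation); defaults to the loci as given.
#' @return A list of class `ranker_config`.
#' @export
ranker_config <- function(sim_pop_size = 200, iterations = 250,
                          min_correct = 0.95, performance_target = 1.0,
                          seed = 1L, locus_input_order = NULL) {
  stopifnot(sim_pop_size >= 1, iterations >= 1,
            min_correct > 0, min_correct <= 1,
            performance_target > 0, performance_target <= 1)
  structure(list(sim_pop_size = sim_pop_size, iterations = iterations,
                 min_correct = min_correct,
                 performance_target = performance_target,
                 seed = as.integer(seed),
                 locus_input_order = locus_input_order),
            class = "ranker_config")
}

# Coerce the various frequency carriers to a plain K x L matrix.
.freq_matrix <- function(freqs, loci = NULL) {
  m <- if (inherits(freqs, "baseline")) freqs$post_freq
       else if (inherits(freqs, "allele_freq_matrix")) freqs$freq
       else if (inherits(freqs, "genotype_table")) {
         estimate_baseline(freqs)$post_freq
       } else as.matrix(freqs)
  if (!is.null(loci)) {
    idx <- match(loci, colnames(m))
    if (anyNA(idx)) stop("unknown locus id(s)")
    m <- m[, idx, drop = FALSE]
  }
  if (anyNA(m)) stop("undefined frequencies: rankers need a frequency for ",
                     "every population x locus cell")
  m
}

# One common-random-number simulation shared by every panel evaluated by a
# ranker: genotypes for iterations x sim_pop_size individuals per
# population, plus per-locus log-likelihood building blocks. Because the
# same simulated individuals are reused for the full panel and every
# leave-one-out panel, the score of a locus with identical frequencies in
# all populations is exactly zero.
.ranker_sim <- function(freqs, config) {
  K <- nrow(freqs); L <- ncol(freqs)
  if (K < 2) stop("at least two populations are required")
  s <- config$sim_pop_size; r <- config$iterations
  pop_of <- rep(rep(seq_len(K), each = s), times = r)
  rep_of <- rep(seq_len(r), each = s * K)
  Pmat <- freqs[pop_of, , drop = FALSE]
  G <- withr::with_seed(config$seed, {
    matrix(stats::rbinom(length(Pmat), 2L, as.vector(Pmat)),
           nrow(Pmat), L)
  })
  logp <- .clog(freqs); logq <- .clog(1 - freqs)
  list(G = G, G2 = 2L - G, pop_of = pop_of, rep_of = rep_of,
       logp = logp, logq = logq, K = K, L = L, r = r, per_rep = s * K)
}

# Per-replicate accuracy (fractional tie credit) of a summed log-likelihood
# matrix S (individuals x populations).
.rep_accuracy <- function(S, sim) {
  credit <- .assign_ll(S, true_idx = sim$pop_of)$credit
  as.numeric(rowsum(credit, sim$rep_of)) / sim$per_rep
}

.locus_ll <- function(sim, l) {
  outer(sim$G[, l], sim$logp[, l]) + outer(sim$G2[, l], sim$logq[, l])
}

.sum_ll <- function(sim, which_loci) {
  sim$G[, which_loci, drop = FALSE] %*%
    t(sim$logp[, which_loci, drop = FALSE]) +
    sim$G2[, which_loci, drop = FALSE] %*%
    t(sim$logq[, which_loci, drop = FALSE])
}

#' Jackknife (leave-one-locus-out) assignment-value scores
#'
#' Scores every locus by the assignment accuracy lost when it is removed
#' from the panel: simulated individuals are drawn from the given
#' population frequencies, assigned by maximum likelihood, and the mean
#' accuracy of the full panel is compared with each leave-one-out panel
#' using common random numbers (the same simulated individuals), so the
#' difference isolates the locus's contribution from Monte-Carlo noise.
#' Loci whose removal costs the most accuracy score highest.
#'
#' @param freqs Population frequencies: a `baseline`, `allele_freq_matrix`,
#'   plain populations x loci matrix, or a [genotype_table()] (converted
#'   via [estimate_baseline()], i.e. the rankers resample from smoothed
#'   frequencies for consistency with the assignment model).
#' @param loci Optional locus subset (default: all columns).
#' @param config A [ranker_config()].
#' @return Data frame with columns `locus`, `score` (accuracy lost),
#'   `se` (Monte-Carlo standard error of the paired per-replicate
#'   difference) and `accuracy_full` (mean full-panel accuracy, identical
#'   for every row).
#' @export
jackknife_locus_scores <- function(freqs, loci = NULL,
                                   config = ranker_config()) {
  m <- .freq_matrix(freqs, loci)
  if (ncol(m) < 2) stop("at least two loci are required")
  sim <- .ranker_sim(m, config)
  S <- .sum_ll(sim, seq_len(sim$L))
  acc_full <- .rep_accuracy(S, sim)
  score <- se <- numeric(sim$L)
  for (l in seq_len(sim$L)) {
    acc_l <- .rep_accuracy(S - .locus_ll(sim, l), sim)
    d <- acc_full - acc_l
    score[l] <- mean(d)
    se[l] <- stats::sd(d) / sqrt(sim$r)
  }
  data.frame(locus = colnames(m), score = score, se = se,
             accuracy_full = mean(acc_full), stringsAsFactors = FALSE)
}

.input_order_pos <- function(ids, config) {
  ord <- config$locus_input_order
  if (is.null(ord)) return(seq_along(ids))
  pos <- match(ids, ord)
  if (anyNA(pos)) stop("locus_input_order does not cover all loci")
  pos
}

#' Jackknife-based locus ranking with a minimum-panel report
#'
#' Ranks loci by descending jackknife score (ties broken by locus input
#' order) and additionally reports the smallest top-k prefix whose mean
#' simulated correct-assignment rate reaches `min_correct`, evaluated on
#' the same common-random-number simulation.
#'
#' @inheritParams jackknife_locus_scores
#' @return List with `ranking` (data frame: locus, score, se, rank),
#'   `min_panel` (character vector of loci, or `NULL` when the target is
#'   not attained), `min_panel_size` (`NA` if not attained),
#'   `prefix_accuracy` (mean accuracy of each top-k prefix) and `attained`.
#' @export
whichloci_rank <- function(freqs, loci = NULL, config = ranker_config()) {
  scores <- jackknife_locus_scores(freqs, loci, config)
  pos <- .input_order_pos(scores$locus, config)
  ord <- order(-scores$score, pos)
  ranking <- scores[ord, c("locus", "score", "se")]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL

  m <- .freq_matrix(freqs, loci)[, ranking$locus, drop = FALSE]
  sim <- .ranker_sim(m, config)
  prefix_acc <- numeric(ncol(m))
  S <- NULL
  for (k in seq_len(ncol(m))) {
    LLk <- .locus_ll(sim, k)
    S <- if (is.null(S)) LLk else S + LLk
    prefix_acc[k] <- mean(.rep_accuracy(S, sim))
  }
  hit <- which(prefix_acc >= config$min_correct)
  attained <- length(hit) > 0
  list(ranking = ranking,
       min_panel = if (attained) ranking$locus[seq_len(hit[1])],
       min_panel_size = if (attained) hit[1] else NA_integer_,
       prefix_accuracy = prefix_acc,
       attained = attained)
}

#' Backward-elimination locus ranking
#'
#' Repeatedly evaluates, with common random numbers, the mean simulated
#' assignment accuracy after removing each single locus from the current
#' set, then removes the locus whose removal leaves the highest accuracy
#' (ties broken by locus input order). The rank is the reverse removal
#' order: the last surviving locus is rank 1. The full removal trace is
#' returned, annotated with where accuracy first drops materially (more
#' than 3 Monte-Carlo standard errors) below its running maximum -- with a
#' correct-assignment target of 1.0 the eliminations beyond that point
#' discriminate little and the trace makes that visible.
#'
#' @inheritParams jackknife_locus_scores
#' @return List with `ranking` (data frame: locus, rank), `trace` (data
#'   frame: step, removed, n_remaining, accuracy, se, material_drop).
#' @export
bels_rank <- function(freqs, loci = NULL, config = ranker_config()) {
  m <- .freq_matrix(freqs, loci)
  if (ncol(m) < 2) stop("at least two loci are required")
  sim <- .ranker_sim(m, config)
  ids <- colnames(m)
  pos <- .input_order_pos(ids, config)
  current <- order(pos)  # evaluate candidates in input order
  S <- .sum_ll(sim, seq_len(sim$L))
  removed <- integer(0)
  acc_after <- se_after <- numeric(0)
  while (length(current) > 1) {
    best <- -Inf; best_l <- NA_integer_; best_reps <- NULL
    for (l in current) {
      reps <- .rep_accuracy(S - .locus_ll(sim, l), sim)
      a <- mean(reps)
      if (a > best + 1e-12) {
        best <- a; best_l <- l; best_reps <- reps
      }
    }
    S <- S - .locus_ll(sim, best_l)
    current <- current[current != best_l]
    removed <- c(removed, best_l)
    acc_after <- c(acc_after, best)
    se_after <- c(se_after, stats::sd(best_reps) / sqrt(sim$r))
  }
  order_out <- c(removed, current)  # first removed ... last survivor
  rank <- integer(sim$L)
  rank[order_out] <- rev(seq_len(sim$L))
  run_max <- cummax(acc_after)
  material <- acc_after < run_max - 3 * se_after
  list(ranking = data.frame(locus = ids, rank = rank,
                            stringsAsFactors = FALSE),
       trace = data.frame(step = seq_along(removed),
                          removed = ids[removed],
                          n_remaining = sim$L - seq_along(removed),
                          accuracy = acc_after,
                          se = se_after,
                          material_drop = material,
                          stringsAsFactors = FALSE))
}
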