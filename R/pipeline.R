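#' Split every population into training and holdout halves
#'
#' Per population, a seeded uniform random split into `ceiling(n/2)`
#' training and `floor(n/2)` holdout individuals (the extra individual of
#' an odd-sized population goes to the training set). Training and holdout
#' are disjoint and exhaustive, and both carry all loci. Locus ranking must
#' only ever see the training half; the holdout half is reserved for panel
#' evaluation, which keeps panel accuracy estimates free of the upward bias
#' of ranking and testing on the same individuals.
#'
#' @param table A [genotype_table()]; every population needs >= 2
#'   individuals.
#' @param seed Integer seed.
#' @return List with `training` and `holdout` genotype tables.
#' @export
training_holdout_split <- function(table, seed = 1L) {
  sizes <- table(.pop_factor(table))
  if (any(sizes < 2)) {
    stop("population(s) with fewer than 2 individuals: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  pf <- .pop_factor(table)
  in_training <- logical(n_individuals(table))
  withr::with_seed(seed, {
    for (pop in table$populations) {
      rows <- which(pf == pop)
      n_train <- ceiling(length(rows) / 2)
      in_training[sample(rows, n_train)] <- TRUE
    }
  })
  list(training = subset_individuals(table, in_training),
       holdout = subset_individuals(table, !in_training))
}

.rank_of_scores <- function(scores, pos) {
  ord <- order(-scores, pos)
  r <- integer(length(scores))
  r[ord] <- seq_along(scores)
  r
}

#' Rank every locus by all five measures
#'
#' Computes, on training data only: per-locus Weir-Cockerham theta,
#' Rosenberg's I_n, the LC score (average contribution to the first
#' `lc_components` principal components), and the two
#' assignment-performance rankings ([whichloci_rank()] and [bels_rank()],
#' which resample from the training set's smoothed baseline frequencies).
#' Scores become ranks (1 = best) with ties broken by locus input order;
#' the arithmetic mean of the five method ranks and a seeded random rank
#' (an independent uniform permutation) are appended.
#'
#' @param training A [genotype_table()] (training individuals only).
#' @param config A [ranker_config()] for the two resampling rankers.
#' @param lc_components Number of leading PCA axes in the LC average.
#' @param random_seed Seed for the random rank column.
#' @return A data frame of class `rank_table`: per locus, `score_*` and
#'   `rank_*` columns for fst / in / lc / whichloci, `rank_bels`,
#'   `rank_avg` (mean of the five method ranks) and `rank_random`.
#' @export
rank_all_methods <- function(training, config = ranker_config(),
                             lc_components = 5, random_seed = 1L) {
  stopifnot(length(training$populations) >= 2)
  afm <- compute_allele_frequencies(training)
  ids <- afm$loci
  L <- length(ids)
  if (L < 2) stop("at least two loci are required")
  pos <- .input_order_pos(ids, config)

  wc <- wc_fst_per_locus(afm)
  score_fst <- ifelse(wc$defined, wc$theta, -Inf)
  score_in <- as.numeric(informativeness_in(afm))
  score_lc <- as.numeric(
    locus_contribution_lc(population_pca(afm), lc_components))

  base <- estimate_baseline(training)
  wl <- whichloci_rank(base, config = config)
  score_wl <- wl$ranking$score[match(ids, wl$ranking$locus)]
  rank_wl <- wl$ranking$rank[match(ids, wl$ranking$locus)]
  bels <- bels_rank(base, config = config)
  rank_bels <- bels$ranking$rank[match(ids, bels$ranking$locus)]

  out <- data.frame(locus = ids,
                    score_fst = score_fst,
                    rank_fst = .rank_of_scores(score_fst, pos),
                    score_in = score_in,
                    rank_in = .rank_of_scores(score_in, pos),
                    score_lc = score_lc,
                    rank_lc = .rank_of_scores(score_lc, pos),
                    score_whichloci = score_wl,
                    rank_whichloci = rank_wl,
                    rank_bels = rank_bels,
                    stringsAsFactors = FALSE)
  out$rank_avg <- rowMeans(out[, c("rank_fst", "rank_in", "rank_lc",
                                   "rank_whichloci", "rank_bels")])
  out$rank_random <- withr::with_seed(random_seed, sample.int(L))
  class(out) <- c("rank_table", "data.frame")
  out
}

.panel <- function(method, size, loci, seed = NA_integer_) {
  structure(list(method = method, size = size, loci = loci, seed = seed),
            class = "panel")
}

#' @export
print.panel <- function(x, ...) {
  cat("panel:", x$method, "/", x$size, "loci\n")
  invisible(x)
}

#' Assemble fixed-size panels from a rank table
#'
#' For each requested size, builds seven panels: the top-k loci of each of
#' the five ranking methods, a top-k panel by average rank, and a random
#' panel (an independently drawn seeded k-subset per size).
#'
#' @param ranks A `rank_table` from [rank_all_methods()].
#' @param sizes Panel sizes (default `c(48, 96)`).
#' @param random_seed Seed for the random panels; each size uses
#'   `random_seed + size` so the draws are independent, not nested.
#' @return List of `panel` objects (7 per size).
#' @export
build_panels <- function(ranks, sizes = c(48, 96), random_seed = 1L) {
  L <- nrow(ranks)
  if (max(sizes) > L) stop("panel size exceeds the number of loci")
  rank_cols <- c(fst = "rank_fst", "in" = "rank_in", lc = "rank_lc",
                 bels = "rank_bels", whichloci = "rank_whichloci",
                 average = "rank_avg")
  panels <- list()
  for (size in sizes) {
    for (m in names(rank_cols)) {
      ord <- order(ranks[[rank_cols[m]]], seq_len(L))
      panels[[paste0(m, "_", size)]] <-
        .panel(m, size, ranks$locus[ord][seq_len(size)])
    }
    rseed <- as.integer(random_seed + size)
    panels[[paste0("random_", size)]] <-
      .panel("random", size,
             withr::with_seed(rseed, sample(ranks$locus, size)),
             seed = rseed)
  }
  panels
}

#' Evaluate panels empirically and by assignment simulation
#'
#' For each panel: (1) empirical evaluation -- estimate a baseline from the
#' training set restricted to the panel's loci and assign the holdout
#' individuals to it; (2) simulated evaluation -- run [orca_simulation()]
#' on the holdout set's smoothed allele frequencies, mirroring the use of
#' holdout-derived frequencies for simulated individuals.
#'
#' @param panels List of `panel` objects (see [build_panels()]).
#' @param training,holdout Genotype tables from [training_holdout_split()].
#' @param n_reps,n_individuals Simulation settings (defaults 500 x 1000).
#' @param seed Base seed; panel i uses `seed + i`.
#' @return List (one element per panel) of `panel_evaluation` objects:
#'   `panel`, `empirical` (an `assignment_result`), `forca` (an
#'   [orca_simulation()] summary), `empirical_mean`, `forca_mean`.
#' @export
evaluate_panels <- function(panels, training, holdout,
                            n_reps = 500, n_individuals = 1000, seed = 1L) {
  holdout_freqs <- estimate_baseline(holdout)
  out <- vector("list", length(panels))
  names(out) <- names(panels)
  for (i in seq_along(panels)) {
    p <- panels[[i]]
    emp <- assign_individuals(holdout,
                              estimate_baseline(training, p$loci))
    freqs <- holdout_freqs$post_freq[, p$loci, drop = FALSE]
    sim <- orca_simulation(freqs, n_reps = n_reps,
                           n_individuals = n_individuals,
                           seed = as.integer(seed + i))
    out[[i]] <- structure(list(panel = p, empirical = emp, forca = sim,
                               empirical_mean = emp$overall,
                               forca_mean = sim$mean),
                          class = "panel_evaluation")
  }
  out
}

#' @export
print.panel_evaluation <- function(x, ...) {
  cat(sprintf("panel_evaluation: %s/%d  empirical %.3f  f_ORCA %.3f\n",
              x$panel$method, x$panel$size, x$empirical_mean, x$forca_mean))
  invisible(x)
}

#' Assignment accuracy as loci are dropped by average rank
#'
#' Starting from the full locus set, removes the `step` worst average-rank
#' loci at a time down to `floor` loci, evaluating empirical holdout
#' assignment at each size. Quartiles are taken over the per-population
#' correct-assignment probabilities.
#'
#' @param ranks A `rank_table`.
#' @param training,holdout Genotype tables.
#' @param step Loci removed per step (default 5).
#' @param floor Smallest panel size evaluated (default 5).
#' @return Data frame with columns `size`, `mean`, `q1`, `q3`.
#' @export
dropoff_curve <- function(ranks, training, holdout, step = 5, floor = 5) {
  L <- nrow(ranks)
  stopifnot(L >= floor)
  ord <- order(ranks$rank_avg, seq_len(L))  # best first
  sizes <- seq(L, floor, by = -step)
  res <- lapply(sizes, function(size) {
    loci <- ranks$locus[ord][seq_len(size)]
    emp <- assign_individuals(holdout, estimate_baseline(training, loci))
    pp <- emp$per_population
    data.frame(size = size, mean = mean(pp, na.rm = TRUE),
               q1 = unname(stats::quantile(pp, 0.25, na.rm = TRUE)),
               q3 = unname(stats::quantile(pp, 0.75, na.rm = TRUE)))
  })
  do.call(rbind, res)
}

#' Compare two paired rank lists
#'
#' Spearman's rank correlation (with exact tie handling via midranks) plus
#' a two-sided Wilcoxon signed-rank test of the paired differences (zero
#' differences dropped, per convention, and flagged).
#'
#' @param ranks_a,ranks_b Equal-length paired numeric rank vectors.
#' @return List with `rho`, `wilcoxon_p` (`NA` when all differences are
#'   zero), `n_zero_diff`, `wilcoxon_defined`.
#' @export
compare_rank_lists <- function(ranks_a, ranks_b) {
  stopifnot(length(ranks_a) == length(ranks_b))
  rho <- if (all(ranks_a == ranks_b)) 1 else
    stats::cor(ranks_a, ranks_b, method = "spearman")
  n_zero <- sum(ranks_a == ranks_b)
  if (n_zero == length(ranks_a)) {
    return(list(rho = 1, wilcoxon_p = NA_real_, n_zero_diff = n_zero,
                wilcoxon_defined = FALSE))
  }
  p <- suppressWarnings(
    stats::wilcox.test(ranks_a, ranks_b, paired = TRUE)$p.value)
  list(rho = rho, wilcoxon_p = p, n_zero_diff = n_zero,
       wilcoxon_defined = TRUE)
}

#' One-way ANOVA plus Tukey HSD across panel score groups
#'
#' Observations are, for empirical evaluations, the per-population
#' correct-assignment probabilities of each panel, and for simulated
#' evaluations the per-replicate f_ORCA values.
#'
#' @param groups Named list of numeric score vectors (>= 2 groups, each
#'   with >= 2 observations).
#' @param alpha Significance level for the Tukey comparisons (default
#'   0.01).
#' @return List with `f_statistic`, `p_value`, `tukey` (data frame:
#'   comparison, diff, p_adj, significant), `degenerate` (`TRUE` when all
#'   groups have zero within-group variance, in which case the tests are
#'   `NA`).
#' @export
compare_panel_scores <- function(groups, alpha = 0.01) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  if (all(vapply(groups, stats::var, numeric(1)) == 0)) {
    return(list(f_statistic = NA_real_, p_value = NA_real_, tukey = NULL,
                degenerate = TRUE))
  }
  df <- data.frame(
    score = unlist(groups, use.names = FALSE),
    panel = factor(rep(names(groups), lengths(groups))))
  fit <- stats::aov(score ~ panel, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$panel
  list(f_statistic = an[["F value"]][1],
       p_value = an[["Pr(>F)"]][1],
       tukey = data.frame(comparison = rownames(tk),
                          diff = tk[, "diff"],
                          p_adj = tk[, "p adj"],
                          significant = tk[, "p adj"] < alpha,
                          row.names = NULL, stringsAsFactors = FALSE),
       degenerate = FALSE)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries with a seeded
#' permutation p-value (rows/columns permuted together).
#'
#' @param matrix_a,matrix_b Symmetric, zero-diagonal matrices of equal
#'   dimension.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed.
#' @return List with `r`, `p_value`, `n_perm`, `defined` (`FALSE` for
#'   degenerate input: fewer than 3 items or a constant matrix).
#' @export
mantel_test <- function(matrix_a, matrix_b, n_perm = 9999, seed = 1L) {
  a <- as.matrix(matrix_a); b <- as.matrix(matrix_b)
  stopifnot(dim(a)[1] == dim(a)[2], all(dim(a) == dim(b)))
  if (!isSymmetric(unname(a)) || !isSymmetric(unname(b))) {
    stop("matrices must be symmetric")
  }
  if (any(abs(c(diag(a), diag(b))) > 1e-12)) {
    stop("matrices must have zero diagonals")
  }
  off_a <- a[lower.tri(a)]; off_b <- b[lower.tri(b)]
  if (nrow(a) < 3 || stats::sd(off_a) == 0 || stats::sd(off_b) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n_perm = n_perm,
                defined = FALSE))
  }
  res <- withr::with_seed(seed, {
    vegan::mantel(stats::as.dist(a), stats::as.dist(b),
                  permutations = n_perm)
  })
  list(r = unname(res$statistic), p_value = res$signif, n_perm = n_perm,
       defined = TRUE)
}

#' Run the whole panel-ranking study on one genotype table
#'
#' Orchestrates the full design: filter individuals and monomorphic loci,
#' split into training and holdout halves, rank all loci by the five
#' methods on the training half, build the seven panel pairs, evaluate
#' every panel empirically and by simulation, and compute the drop-off
#' curve by average rank.
#'
#' @param table A [genotype_table()].
#' @param split_seed Seed for [training_holdout_split()].
#' @param ranker_config A [ranker_config()].
#' @param sizes Panel sizes (default `c(48, 96)`).
#' @param n_reps,n_individuals Simulation settings for [orca_simulation()].
#' @param seed Base seed for panel simulations and the random panel/rank.
#' @param max_missing_fraction Individual missingness threshold.
#' @return List with `table` (filtered), `training`, `holdout`, `ranks`,
#'   `panels`, `evaluations`, `dropoff`.
#' @export
run_panel_study <- function(table, split_seed = 1L,
                            ranker_config = panelrank::ranker_config(),
                            sizes = c(48, 96),
                            n_reps = 500, n_individuals = 1000,
                            seed = 1L, max_missing_fraction = 0.10) {
  table <- filter_individuals_by_missingness(table, max_missing_fraction)
  table <- filter_monomorphic_loci(table)
  split <- training_holdout_split(table, seed = split_seed)
  ranks <- rank_all_methods(split$training, config = ranker_config,
                            random_seed = as.integer(seed))
  panels <- build_panels(ranks, sizes = sizes,
                         random_seed = as.integer(seed))
  evals <- evaluate_panels(panels, split$training, split$holdout,
                           n_reps = n_reps, n_individuals = n_individuals,
                           seed = as.integer(seed))
  drop <- dropoff_curve(ranks, split$training, split$holdout)
  list(table = table, training = split$training, holdout = split$holdout,
       ranks = ranks, panels = panels, evaluations = evals, dropoff = drop)
}
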