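.toy_freqs <- function(cols) {
  m <- do.call(cbind, cols)
  colnames(m) <- paste0("L", seq_along(cols))
  m
}

# mean simulated assignment accuracy of a panel, via the public simulator
.ranker_check_accuracy <- function(freqs, cfg) {
  orca_simulation(freqs, n_reps = cfg$iterations,
                  n_individuals = cfg$sim_pop_size * nrow(freqs),
                  seed = cfg$seed)$mean
}

test_that("jackknife scores reward informative loci and zero out redundancy", {
  cfg <- ranker_config(sim_pop_size = 60, iterations = 25, seed = 2)
  # perfect marker + uninformative marker
  f <- .toy_freqs(list(c(0.999, 0.001), c(0.5, 0.5)))
  sc <- jackknife_locus_scores(f, config = cfg)
  expect_gt(sc$score[1], 0.4)
  expect_lt(abs(sc$score[2]), 0.02)

  # identical-frequency locus: exactly zero under common random numbers
  expect_identical(sc$score[2], 0)

  # duplicated perfect marker: each copy's leave-one-out loss ~ 0
  f2 <- .toy_freqs(list(c(0.999, 0.001), c(0.999, 0.001)))
  sc2 <- jackknife_locus_scores(f2, config = cfg)
  expect_gt(sc2$accuracy_full[1], 0.99)
  expect_lt(max(abs(sc2$score)), 0.01)
})

test_that("jackknife scores agree with exact leave-one-out differences", {
  withr::with_seed(14, {
    f <- matrix(runif(2 * 3, 0.2, 0.8), 2, 3)
  })
  colnames(f) <- c("a", "b", "c")
  cfg <- ranker_config(sim_pop_size = 300, iterations = 60, seed = 8)
  sc <- jackknife_locus_scores(f, config = cfg)
  full <- orca_fcorrect_exact(f)
  for (l in 1:3) {
    exact_loss <- full - orca_fcorrect_exact(f[, -l, drop = FALSE])
    expect_lt(abs(sc$score[l] - exact_loss), 3 * sc$se[l] + 0.01)
  }
})

test_that("whichloci ranking finds planted signal and reports the minimum panel", {
  cfg <- ranker_config(sim_pop_size = 50, iterations = 20, seed = 3,
                       min_correct = 0.95)
  withr::with_seed(21, {
    duds <- replicate(9, runif(2, 0.45, 0.55), simplify = FALSE)
  })
  f <- .toy_freqs(c(list(c(0.99, 0.01)), duds))
  wl <- whichloci_rank(f, config = cfg)
  expect_equal(wl$ranking$locus[1], "L1")
  expect_true(wl$attained)
  # the reported minimum panel attains the target on an independent seed
  cfg2 <- ranker_config(sim_pop_size = 50, iterations = 20, seed = 99)
  sub <- f[, wl$min_panel, drop = FALSE]
  sim <- .ranker_check_accuracy(sub, cfg2)
  expect_gte(sim, 0.95 - 0.02)

  # all-uninformative panel: not attained, scores near zero
  fd <- .toy_freqs(duds)
  wld <- whichloci_rank(fd, config = cfg)
  expect_false(wld$attained)
  expect_lt(max(abs(wld$ranking$score)), 0.05)
})

test_that("backward elimination keeps the planted marker to the end", {
  cfg <- ranker_config(sim_pop_size = 40, iterations = 15, seed = 6)
  withr::with_seed(31, {
    duds <- replicate(7, runif(2, 0.45, 0.55), simplify = FALSE)
  })
  f <- .toy_freqs(c(list(c(0.99, 0.01)), duds))
  res <- bels_rank(f, config = cfg)
  expect_equal(res$ranking$locus[res$ranking$rank == 1], "L1")
  expect_equal(nrow(res$trace), ncol(f) - 1)
  expect_equal(res$trace$n_remaining, (ncol(f) - 1):1)

  # two-locus set: the locus with the higher singleton exact f_ORCA wins
  f2 <- .toy_freqs(list(c(0.9, 0.1), c(0.6, 0.4)))
  stopifnot(orca_fcorrect_exact(f2[, 1, drop = FALSE]) >
              orca_fcorrect_exact(f2[, 2, drop = FALSE]))
  res2 <- bels_rank(f2, config = cfg)
  expect_equal(res2$ranking$rank, c(1L, 2L))
})

test_that("input order only permutes loci whose scores are within noise", {
  cfg_base <- ranker_config(sim_pop_size = 50, iterations = 25, seed = 12)
  withr::with_seed(41, {
    mids <- replicate(10, runif(2, 0.35, 0.65), simplify = FALSE)
  })
  f <- .toy_freqs(c(list(c(0.99, 0.01), c(0.95, 0.05)), mids))
  ids <- colnames(f)
  orders <- list(ids, rev(ids),
                 withr::with_seed(1, sample(ids)),
                 withr::with_seed(2, sample(ids)))
  sc <- jackknife_locus_scores(f, config = cfg_base)
  ranks <- sapply(orders, function(o) {
    cfg <- ranker_config(sim_pop_size = 50, iterations = 25, seed = 12,
                         locus_input_order = o)
    res <- bels_rank(f, config = cfg)
    res$ranking$rank[match(ids, res$ranking$locus)]
  })
  # the two planted strong loci stay at the top under every input order
  expect_true(all(ranks[1:2, ] <= 2))
  # loci whose relative order flips between runs have scores within
  # 3 combined Monte-Carlo standard errors
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i < j) {
        rel <- sign(ranks[i, ] - ranks[j, ])
        if (length(unique(rel)) > 1) {
          comb_se <- sqrt(sc$se[i]^2 + sc$se[j]^2)
          expect_lt(abs(sc$score[i] - sc$score[j]), 3 * comb_se + 1e-9)
        }
      }
    }
  }
})
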