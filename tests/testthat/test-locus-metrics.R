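test_that("theta matches the per-allele oracle and its analytic endpoints", {
  # identical populations, all heterozygotes: no among-population variance
  t <- one_locus_table(c(0, 50, 0), c(0, 50, 0))
  expect_lte(wc_fst_per_locus(t)$theta, 0)

  # fixed difference: theta exactly 1
  t <- one_locus_table(c(50, 0, 0), c(0, 0, 50))
  expect_identical(wc_fst_per_locus(t)$theta, 1)

  # spec'd two-population case against the oracle
  t <- one_locus_table(c(7, 2, 1), c(1, 2, 7))
  expect_equal(wc_fst_per_locus(t)$theta,
               wc_theta_oracle(genotype_counts(t, "L1")),
               tolerance = 1e-12)

  # monomorphic overall -> undefined
  t <- one_locus_table(c(10, 0, 0), c(10, 0, 0))
  res <- wc_fst_per_locus(t)
  expect_false(res$defined)
  expect_true(is.na(res$theta))

  expect_error(wc_fst_per_locus(one_locus_table(c(5, 5, 5))),
               "two populations")
})

test_that("theta is invariant to allele relabeling and population order", {
  t <- random_table(4, 25, 10, seed = 31)
  theta <- wc_fst_per_locus(t)$theta
  flipped <- t
  flipped$calls <- 2L - flipped$calls
  expect_equal(wc_fst_per_locus(flipped)$theta, theta, tolerance = 1e-12)
  reordered <- subset_populations(t, rev(t$populations))
  expect_equal(wc_fst_per_locus(reordered)$theta, theta, tolerance = 1e-12)
})

test_that("multilocus and pairwise F_ST behave as ratio-of-sums composites", {
  t <- random_table(3, 30, 6, seed = 8)
  one <- wc_fst_per_locus(t)
  expect_equal(multilocus_fst(t, "L001"), one$theta[1], tolerance = 1e-12)

  # identical populations across all loci -> non-positive
  calls <- do.call(rbind, rep(list(matrix(c(2L, 1L, 0L, 1L), 4, 3)), 2))
  same <- genotype_table(calls, c("a", "b", "c"),
                         rep(c("p1", "p2"), each = 4))
  expect_lte(multilocus_fst(same), 0)

  m <- pairwise_fst_matrix(t)
  expect_equal(m, t(m), tolerance = 1e-12)
  expect_equal(unname(diag(m)), rep(0, 3))

  # duplicated population: its pairwise entry is <= 0
  dup <- genotype_table(rbind(t$calls, t$calls[1:30, ]),
                        t$loci,
                        c(t$individuals$population, rep("pop1b", 30)))
  md <- pairwise_fst_matrix(dup)
  expect_lte(md["pop1", "pop1b"], 0)
})

test_that("within-region population pairs are less diverged than between-region pairs", {
  dat <- simulate_dataset(simulation_config(n_regions = 3,
                                            pops_per_region = 2,
                                            n_loci = 60, sample_sizes = 50,
                                            seed = 12))
  m <- pairwise_fst_matrix(dat$table)
  reg <- dat$table$regions
  same <- m[cbind(c("pop_1", "pop_3", "pop_5"),
                  c("pop_2", "pop_4", "pop_6"))]
  cross <- m[lower.tri(m)]
  cross <- setdiff(cross, same)
  expect_lt(mean(same), mean(cross))
})

test_that("informativeness matches its analytic values", {
  afm <- list(loci = "L1", populations = c("p1", "p2"),
              freq = matrix(c(0.3, 0.3), 2, 1,
                            dimnames = list(c("p1", "p2"), "L1")),
              n_genes = matrix(20, 2, 1), het = matrix(0, 2, 1))
  class(afm) <- "allele_freq_matrix"
  expect_equal(unname(informativeness_in(afm)), 0)

  afm$freq[, 1] <- c(1, 0)
  expect_equal(unname(informativeness_in(afm)), log(2), tolerance = 1e-9)

  afm$freq[, 1] <- c(0.5, 1)
  expect_lt(abs(unname(informativeness_in(afm)) - 0.215762), 1e-6)

  # population without data is excluded with a warning; error if < 2 remain
  afm3 <- afm
  afm3$populations <- c("p1", "p2", "p3")
  afm3$freq <- rbind(afm3$freq, NA)
  afm3$n_genes <- rbind(afm3$n_genes, 0)
  expect_warning(v <- informativeness_in(afm3), "no data")
  expect_lt(abs(unname(v) - 0.215762), 1e-6)
})

test_that("rarefied allelic richness matches the hypergeometric sum", {
  # 19/1 allele counts in 20 gene copies, g = 2 -> 1.1
  t <- one_locus_table(c(9, 1, 0))
  expect_equal(unname(allelic_richness_rarefied(t, "L1", g = 2)), 1.1)

  # monomorphic population -> exactly 1
  t <- one_locus_table(c(10, 0, 0), c(5, 5, 0))
  expect_equal(unname(allelic_richness_rarefied(t, "L1", g = 4))[1], 1)

  # g = n_genes -> observed allele count
  t <- one_locus_table(c(9, 1, 0))
  expect_equal(unname(allelic_richness_rarefied(t, "L1", g = 20)), 2)

  expect_error(allelic_richness_rarefied(t, "L1", g = 21), "exceeds")
})

test_that("HWE chi-square has its closed forms and directions", {
  t <- one_locus_table(c(25, 50, 25))
  res <- hwe_chisq_test(t, "L1", "pop1")
  expect_equal(res$chisq, 0)
  expect_equal(res$p_value, 1)

  t <- one_locus_table(c(50, 0, 50))
  res <- hwe_chisq_test(t, "L1", "pop1")
  expect_equal(res$chisq, 100)  # n * Fhat^2 with Fhat = 1
  expect_equal(res$direction, "deficit")

  t <- one_locus_table(c(10, 80, 10))
  expect_equal(hwe_chisq_test(t, "L1", "pop1")$direction, "excess")

  t <- one_locus_table(c(30, 0, 0))
  expect_false(hwe_chisq_test(t, "L1", "pop1")$defined)
})

test_that("HWE p-values are roughly uniform under the null", {
  pvals <- withr::with_seed(99, {
    replicate(400, {
      g <- rbinom(90, 2L, 0.4)
      t <- genotype_table(matrix(g, ncol = 1), "L1", rep("p1", 90))
      hwe_chisq_test(t, "L1", "p1")$p_value
    })
  })
  # 1-df chi-square is discrete-ish at n = 90 but the bulk must be flat
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("the LD permutation G-test finds association and stays calibrated", {
  t <- random_table(1, 90, 1, seed = 55)
  dup <- genotype_table(cbind(t$calls, t$calls), c("a", "b"),
                        t$individuals$population)
  res <- ld_pairwise_test(dup, "a", "b", "pop1", n_perm = 1000, seed = 1)
  expect_lt(res$p_value, 0.01)

  # independently simulated loci: null p approximately uniform
  pvals <- sapply(1:200, function(i) {
    ti <- random_table(1, 60, 2, seed = 1000 + i)
    ld_pairwise_test(ti, "L001", "L002", "pop1", n_perm = 200,
                     seed = i)$p_value
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)

  # monomorphic partner -> undefined
  mono <- genotype_table(cbind(t$calls, 2L), c("a", "b"),
                         t$individuals$population)
  expect_false(ld_pairwise_test(mono, "a", "b", "pop1")$defined)
})

test_that("sequential Bonferroni implements Holm's step-down", {
  expect_equal(sequential_bonferroni(c(0.01, 0.02, 0.04), 0.05),
               rep(TRUE, 3))
  expect_equal(sequential_bonferroni(0.04, 0.05), TRUE)
  expect_equal(sequential_bonferroni(c(0.03, 0.5), 0.05),
               c(FALSE, FALSE))
  # order-independence of the flags
  p <- c(0.001, 0.04, 0.012, 0.9)
  expect_equal(sequential_bonferroni(p, 0.05)[order(p)],
               sequential_bonferroni(sort(p), 0.05))
})
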