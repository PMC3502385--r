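test_that("allele frequencies match hand counts", {
  t <- one_locus_table(c(0, 10, 0))
  afm <- compute_allele_frequencies(t)
  expect_equal(afm$freq[1, 1], 0.5)
  expect_equal(afm$n_genes[1, 1], 20)
  expect_equal(afm$het[1, 1], 1)

  t <- one_locus_table(c(0, 0, 8))
  expect_equal(compute_allele_frequencies(t)$freq[1, 1], 0)

  t <- one_locus_table(c(3, 4, 3))
  afm <- compute_allele_frequencies(t)
  expect_equal(afm$freq[1, 1], 0.5)
  expect_equal(afm$n_genes[1, 1], 20)

  # missing calls shrink n_genes, not the frequency denominator's meaning
  calls <- matrix(c(2L, 1L, NA, 0L), ncol = 1)
  t <- genotype_table(calls, "L1", rep("p1", 4))
  afm <- compute_allele_frequencies(t)
  expect_equal(afm$n_genes[1, 1], 6)
  expect_equal(afm$freq[1, 1], 3 / 6)
})

test_that("missingness filter removes strictly above the threshold", {
  # 114 loci, 12 missing = 10.5% -> removed; 110 loci, 11 missing = 10% -> kept
  mk <- function(L, n_missing) {
    calls <- matrix(2L, 2, L)
    calls[1, seq_len(n_missing)] <- NA_integer_
    genotype_table(calls, sprintf("L%03d", 1:L), c("p1", "p1"))
  }
  out <- suppressMessages(filter_individuals_by_missingness(mk(114, 12)))
  expect_equal(n_individuals(out), 1)
  expect_equal(attr(out, "removed")$missing_fraction, 12 / 114)

  out <- filter_individuals_by_missingness(mk(110, 11))
  expect_equal(n_individuals(out), 2)

  out <- filter_individuals_by_missingness(mk(110, 0))
  expect_equal(n_individuals(out), 2)

  # idempotent
  once <- suppressMessages(filter_individuals_by_missingness(mk(114, 12)))
  expect_identical(filter_individuals_by_missingness(once)$calls, once$calls)
})

test_that("monomorphic loci are detected across pooled populations", {
  withr::with_seed(1, {
    calls <- cbind(matrix(rbinom(40 * 6, 2, 0.5), 40, 6),
                   matrix(2L, 40, 4))  # 4 loci fixed everywhere
  })
  t <- genotype_table(calls, sprintf("L%02d", 1:10),
                      rep(c("p1", "p2"), each = 20))
  out <- suppressMessages(filter_monomorphic_loci(t))
  expect_equal(n_loci(out), 6)
  expect_equal(attr(out, "removed"), sprintf("L%02d", 7:10))

  # polymorphic in exactly one population -> retained
  calls <- cbind(c(rep(2L, 10), rep(2L, 9), 1L))
  t <- genotype_table(calls, "L1", rep(c("p1", "p2"), each = 10))
  expect_equal(n_loci(filter_monomorphic_loci(t)), 1)

  # no monomorphic loci -> identity; all monomorphic -> error
  t <- random_table(2, 20, 5, seed = 3)
  expect_identical(filter_monomorphic_loci(t)$calls, t$calls)
  t_all <- genotype_table(matrix(0L, 6, 2), c("a", "b"),
                          rep(c("p1", "p2"), 3))
  expect_error(filter_monomorphic_loci(t_all), "monomorphic")
})

test_that("genepop round-trip is lossless in both dialects", {
  t <- random_table(3, 15, 8, seed = 11, missing_rate = 0.05)
  for (digits in c(2, 3)) {
    path <- withr::local_tempfile(fileext = ".gen")
    write_genepop(t, path, allele_digits = digits)
    back <- read_genepop(path, allele_digits = digits,
                         pop_names = t$populations)
    expect_identical(unname(back$calls), unname(t$calls))
    expect_identical(back$loci$id, t$loci$id)
    expect_identical(back$individuals$population,
                     t$individuals$population)
    # frequencies computed before and after the round trip agree exactly
    expect_identical(compute_allele_frequencies(back)$freq,
                     compute_allele_frequencies(t)$freq)
  }
})

test_that("genepop reader handles missing codes and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("title", "locA", "locB", "Pop",
               "i1 , 0101 0102",
               "i2 , 0100 0202",
               "Pop",
               "i3 , 0102 0202"), path)
  t <- read_genepop(path)
  expect_true(is.na(t$calls[2, 1]))   # half-missing code 0100 -> missing
  expect_equal(unname(t$calls[1, ]), c(2L, 1L))
  expect_equal(length(t$populations), 2)

  writeLines(c("title", "locA", "Pop",
               "i1 , 0102", "i2 , 0103"), path)
  expect_error(read_genepop(path), "locA")

  writeLines(c("title", "locA", "locB", "Pop",
               "i1 , 0101"), path)
  expect_error(read_genepop(path), "line")
})

test_that("writing an empty table errors; region maps round-trip", {
  t <- random_table(2, 5, 3, seed = 2)
  empty <- subset_individuals(t, rep(FALSE, n_individuals(t)))
  expect_error(write_genepop(empty, tempfile()), "no populations")

  t$regions[] <- c("regA", "regB")
  path <- withr::local_tempfile(fileext = ".csv")
  write_region_map(t, path)
  expect_identical(read_region_map(path), t$regions)
})

test_that("table invariants are enforced", {
  expect_error(genotype_table(matrix(0L, 2, 2), c("a", "a"),
                              c("p", "p")), "unique")
  expect_error(genotype_table(matrix(3L, 2, 1), "a", c("p", "p")),
               "0, 1, 2 or NA")
  expect_error(genotype_table(matrix(0L, 2, 1), "a", c("p1", "p2"),
                              regions = c(p1 = "r1")), "region")
  expect_error(genotype_table(matrix(0L, 2, 1), "a", c("p1", "p2"),
                              individual_ids = c("x", "x")),
               "unique")
  # blank or duplicated rownames (e.g. after rbind) fall back to generated
  # ids rather than being taken as identities
  m <- rbind(matrix(0L, 2, 1, dimnames = list(c("a", "b"), NULL)),
             matrix(1L, 2, 1))
  t <- genotype_table(m, "L1", rep(c("p1", "p2"), each = 2))
  expect_false(anyDuplicated(t$individuals$id) > 0)
  expect_true(all(nzchar(t$individuals$id)))
})
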