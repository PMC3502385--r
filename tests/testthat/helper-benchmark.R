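# The standard benchmark scenario (12 populations in 6 regional pairs,
# 110 loci, drift calibrated to mean theta 0.114) is expensive enough to
# build that test files share one memoised copy.

.bench_env <- new.env(parent = emptyenv())

benchmark_dataset <- function() {
  if (is.null(.bench_env$dat)) {
    .bench_env$dat <- paperlike_dataset()
  }
  .bench_env$dat
}

# Filtered table, training/holdout split and the full five-method rank
# table at the reduced resampling scale used throughout the test suite
# (50 simulated individuals per population, 20 replicates).
benchmark_study <- function() {
  if (is.null(.bench_env$study)) {
    dat <- benchmark_dataset()
    tbl <- suppressMessages(filter_monomorphic_loci(
      filter_individuals_by_missingness(dat$table)))
    split <- training_holdout_split(tbl, seed = 101)
    ranks <- rank_all_methods(
      split$training,
      config = ranker_config(sim_pop_size = 50, iterations = 20,
                             seed = 202),
      random_seed = 303)
    .bench_env$study <- list(table = tbl, training = split$training,
                             holdout = split$holdout, ranks = ranks,
                             truth = dat$truth, config = dat$config)
  }
  .bench_env$study
}
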