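#' Configuration for the hierarchical genotype simulator
#'
#' The simulator emulates a nested sampling design common in salmonid
#' population genetics: regions diverge from a shared ancestral gene pool,
#' and paired population samples diverge within each region. Allele
#' frequencies follow a two-level Balding-Nichols (beta) model: for each
#' locus the ancestral frequency `p0` is uniform on `ancestral_freq_range`,
#' each region draws `p_r ~ Beta(p0 (1-F_r)/F_r, (1-p0)(1-F_r)/F_r)`, and
#' each population within a region draws analogously around `p_r` with its
#' drift parameter `F_p`.
#'
#' Per-locus drift parameters vary around the base values `f_region` and
#' `f_pop` by a shared lognormal multiplier with log-sd
#' `locus_f_dispersion`, so every locus has a known, distinct true level of
#' differentiation (stored in the truth record). Optional outlier loci have
#' their population-level drift multiplied by `outlier_f_multiplier`,
#' mimicking markers under divergent selection.
#'
#' @param n_regions Number of regions (default 6).
#' @param pops_per_region Populations per region (default 2).
#' @param n_loci Number of polymorphic loci to simulate (default 110).
#' @param sample_sizes Per-population sample sizes; either a single count
#'   recycled to all populations or a vector of length
#'   `n_regions * pops_per_region`. `NULL` (default) draws sizes uniformly
#'   from `sample_size_range`.
#' @param sample_size_range Range sizes are drawn from when `sample_sizes`
#'   is `NULL` (default `c(61, 93)`, the span of the assessment samples the
#'   design emulates).
#' @param f_region Base drift of regions from the ancestral pool, in (0,1).
#' @param f_pop Base drift of populations from their region, in (0,1).
#' @param ancestral_freq_range Interval for ancestral frequencies.
#' @param locus_f_dispersion Log-sd of the per-locus lognormal drift
#'   multiplier (0 makes every locus share the base drift). The default of
#'   1 spreads per-locus differentiation over roughly an order of
#'   magnitude around the mean, the kind of wide per-locus F_ST
#'   distribution typical of SNP panels that mix neutral and
#'   high-divergence candidate markers.
#' @param n_outlier_loci Number of high-divergence outlier loci (default 0).
#' @param outlier_f_multiplier Drift multiplier for outlier loci (> 1).
#' @param missing_rate I.i.d. probability that a genotype call is missing.
#' @param n_monomorphic_loci Number of additional loci planted fixed for the
#'   reference allele in every population (default 0).
#' @param seed Integer seed; every downstream draw is reproducible from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_regions = 6,
                              pops_per_region = 2,
                              n_loci = 110,
                              sample_sizes = NULL,
                              sample_size_range = c(61, 93),
                              f_region = 0.08,
                              f_pop = 0.04,
                              ancestral_freq_range = c(0.05, 0.95),
                              locus_f_dispersion = 1.0,
                              n_outlier_loci = 0,
                              outlier_f_multiplier = 5,
                              missing_rate = 0.01,
                              n_monomorphic_loci = 0,
                              seed = 1L) {
  stopifnot(n_regions >= 1, pops_per_region >= 1, n_loci >= 1,
            f_region > 0, f_region < 1, f_pop > 0, f_pop < 1,
            locus_f_dispersion >= 0,
            n_outlier_loci >= 0, n_outlier_loci <= n_loci,
            outlier_f_multiplier > 1,
            missing_rate >= 0, missing_rate < 1,
            n_monomorphic_loci >= 0,
            length(ancestral_freq_range) == 2,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
            ancestral_freq_range[1] <= ancestral_freq_range[2])
  K <- n_regions * pops_per_region
  if (!is.null(sample_sizes)) {
    if (length(sample_sizes) == 1) sample_sizes <- rep(sample_sizes, K)
    stopifnot(length(sample_sizes) == K, all(sample_sizes >= 2))
  }
  structure(list(n_regions = n_regions, pops_per_region = pops_per_region,
                 n_loci = n_loci, sample_sizes = sample_sizes,
                 sample_size_range = sample_size_range,
                 f_region = f_region, f_pop = f_pop,
                 ancestral_freq_range = ancestral_freq_range,
                 locus_f_dispersion = locus_f_dispersion,
                 n_outlier_loci = n_outlier_loci,
                 outlier_f_multiplier = outlier_f_multiplier,
                 missing_rate = missing_rate,
                 n_monomorphic_loci = n_monomorphic_loci,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.bn_draw <- function(p, f) {
  # one Balding-Nichols draw per element; f may be a vector matched to p.
  # An allele already fixed (p of exactly 0 or 1) stays fixed: the beta
  # distribution degenerates there, so the draw is deterministic.
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1) ||
      any(!is.finite(f)) || any(f <= 0) || any(f >= 1)) {
    stop("invalid Balding-Nichols parameters (drift must be in (0, 1))")
  }
  out <- p
  free <- p > 0 & p < 1
  if (any(free)) {
    fv <- rep_len(f, length(p))[free]
    a <- p[free] * (1 - fv) / fv
    b <- (1 - p[free]) * (1 - fv) / fv
    out[free] <- stats::rbeta(sum(free), a, b)
  }
  out
}

#' Simulate hierarchical population allele frequencies
#'
#' Draws the ancestral, regional and population-level reference-allele
#' frequencies of every locus under the two-level Balding-Nichols model in
#' [simulation_config()], together with the per-locus drift parameters
#' actually used (the ground truth for parameter-recovery checks).
#'
#' @param config A [simulation_config()].
#' @return A list of class `truth_record` with elements `ancestral_freqs`
#'   (length `n_loci`), `regional_freqs` (regions x loci),
#'   `population_freqs` (populations x loci), `f_region_locus`,
#'   `f_pop_locus`, `f_total_locus` (per-locus drift actually used, with
#'   `f_total = f_region + (1 - f_region) f_pop`), `outlier` (logical) and
#'   the population/region labels.
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, .simulate_frequencies_impl(config))
}

.simulate_frequencies_impl <- function(config) {
  L <- config$n_loci
  R <- config$n_regions
  K <- R * config$pops_per_region
  pops <- paste0("pop_", seq_len(K))
  regs <- paste0("region_", seq_len(R))
  pop_region <- rep(seq_len(R), each = config$pops_per_region)

  mult <- if (config$locus_f_dispersion > 0) {
    exp(stats::rnorm(L, 0, config$locus_f_dispersion))
  } else rep(1, L)
  outlier <- rep(FALSE, L)
  if (config$n_outlier_loci > 0) {
    outlier[sample.int(L, config$n_outlier_loci)] <- TRUE
  }
  cap <- function(f) pmin(pmax(f, 1e-6), 0.99)
  f_reg <- cap(config$f_region * mult)
  f_pop <- cap(config$f_pop * mult *
                 ifelse(outlier, config$outlier_f_multiplier, 1))

  p0 <- stats::runif(L, config$ancestral_freq_range[1],
                     config$ancestral_freq_range[2])
  p_reg <- matrix(NA_real_, R, L, dimnames = list(regs, NULL))
  for (r in seq_len(R)) p_reg[r, ] <- .bn_draw(p0, f_reg)
  p_pop <- matrix(NA_real_, K, L, dimnames = list(pops, NULL))
  for (k in seq_len(K)) p_pop[k, ] <- .bn_draw(p_reg[pop_region[k], ], f_pop)

  structure(list(ancestral_freqs = p0,
                 regional_freqs = p_reg,
                 population_freqs = p_pop,
                 f_region_locus = f_reg,
                 f_pop_locus = f_pop,
                 f_total_locus = f_reg + (1 - f_reg) * f_pop,
                 outlier = outlier,
                 populations = pops, regions = regs,
                 pop_region = stats::setNames(regs[pop_region], pops)),
            class = "truth_record")
}

#' Simulate a genotype table from simulated frequencies
#'
#' Each individual's genotype at each locus is a `Binomial(2, p_k)` draw
#' under Hardy-Weinberg equilibrium within its population; missing calls
#' are planted i.i.d. at `missing_rate`; `n_monomorphic_loci` extra loci are
#' planted fixed in every population (to exercise the monomorphic-locus
#' filter). Sample sizes come from the config (drawn uniformly from
#' `sample_size_range` when unspecified).
#'
#' @param truth A `truth_record` from [simulate_frequencies()].
#' @param config The same [simulation_config()].
#' @return A [genotype_table()] with region labels attached.
#' @export
simulate_genotypes <- function(truth, config) {
  stopifnot(inherits(truth, "truth_record"),
            inherits(config, "simulation_config"))
  withr::with_seed(config$seed + 1L, .simulate_genotypes_impl(truth, config))
}

.simulate_genotypes_impl <- function(truth, config) {
  K <- length(truth$populations)
  sizes <- config$sample_sizes
  if (is.null(sizes)) {
    sizes <- sample(config$sample_size_range[1]:config$sample_size_range[2],
                    K, replace = TRUE)
  }
  pop_of <- rep(seq_len(K), times = sizes)
  N <- length(pop_of)
  L <- config$n_loci
  P <- truth$population_freqs[pop_of, , drop = FALSE]
  calls <- matrix(stats::rbinom(N * L, 2L, as.vector(P)), N, L)
  if (config$n_monomorphic_loci > 0) {
    calls <- cbind(calls, matrix(2L, N, config$n_monomorphic_loci))
  }
  if (config$missing_rate > 0) {
    calls[stats::runif(length(calls)) < config$missing_rate] <- NA_integer_
  }
  ids <- paste0(truth$populations[pop_of], "_",
                unlist(lapply(sizes, seq_len)))
  locus_ids <- c(sprintf("locus_%03d", seq_len(L)),
                 if (config$n_monomorphic_loci > 0)
                   sprintf("mono_%03d", seq_len(config$n_monomorphic_loci)))
  genotype_table(calls, loci = locus_ids,
                 populations = truth$populations[pop_of],
                 regions = truth$pop_region,
                 individual_ids = ids)
}

#' Simulate frequencies and genotypes in one call
#'
#' @param config A [simulation_config()].
#' @return List with elements `truth` and `table`.
#' @export
simulate_dataset <- function(config) {
  truth <- simulate_frequencies(config)
  list(truth = truth, table = simulate_genotypes(truth, config))
}

#' Calibrate the simulator to a target mean F_ST
#'
#' Scales the base drift parameters `f_region` and `f_pop` jointly (by
#' bisection on a multiplicative factor) until the realized mean per-locus
#' Weir-Cockerham theta, measured on a large-sample simulation
#' (`calib_sample_size` individuals per population, no missing data),
#' falls within `tol` of `target_fst`.
#'
#' @param target_fst Target mean per-locus theta, in (0, 0.5).
#' @param config Starting [simulation_config()].
#' @param tol Convergence tolerance on the realized mean (default 0.02).
#' @param max_iter Maximum bisection iterations (default 25).
#' @param calib_sample_size Individuals per population in the calibration
#'   simulations (default 200).
#' @return The calibrated `simulation_config`, with attributes
#'   `realized_mean_fst` and `scale`.
#' @export
calibrate_to_mean_fst <- function(target_fst, config = simulation_config(),
                                  tol = 0.02, max_iter = 25,
                                  calib_sample_size = 200) {
  stopifnot(target_fst > 0, target_fst < 0.5)
  realized <- function(s) {
    cfg <- config
    cfg$f_region <- min(config$f_region * s, 0.95)
    cfg$f_pop <- min(config$f_pop * s, 0.95)
    cfg$sample_sizes <- rep(calib_sample_size,
                            cfg$n_regions * cfg$pops_per_region)
    cfg$missing_rate <- 0
    cfg$n_monomorphic_loci <- 0
    dat <- simulate_dataset(cfg)
    mean(wc_fst_per_locus(dat$table)$theta, na.rm = TRUE)
  }
  lo <- 0.05; hi <- 1
  f_hi <- realized(hi)
  it <- 0
  while (f_hi < target_fst && hi < 64) {  # expand until target bracketed
    hi <- hi * 2
    f_hi <- realized(hi)
    it <- it + 1
    if (it > 10) break
  }
  s <- hi; f_s <- f_hi
  for (i in seq_len(max_iter)) {
    if (abs(f_s - target_fst) <= tol / 2) break
    s_try <- (lo + hi) / 2
    f_try <- realized(s_try)
    if (f_try < target_fst) lo <- s_try else hi <- s_try
    s <- s_try; f_s <- f_try
  }
  if (abs(f_s - target_fst) > tol) {
    stop(sprintf(paste0("calibration did not converge: realized %.4f vs ",
                        "target %.4f (scale %.3f)"), f_s, target_fst, s))
  }
  out <- config
  out$f_region <- min(config$f_region * s, 0.95)
  out$f_pop <- min(config$f_pop * s, 0.95)
  attr(out, "realized_mean_fst") <- f_s
  attr(out, "scale") <- s
  out
}

#' The package's standard benchmark dataset
#'
#' A fixed synthetic scenario mirroring the assessment design the package
#' targets: 12 populations in 6 regional pairs, 110 polymorphic loci,
#' sample sizes drawn from 61-93 individuals, ~1% missing calls, and base
#' drift calibrated so the realized mean per-locus Weir-Cockerham theta is
#' near 0.114.
#'
#' SNP panels are assembled from markers validated as polymorphic, so the
#' benchmark guarantees its nominal locus count after ascertainment:
#' `paperlike_dataset()` simulates a surplus of loci and keeps the first
#' `n_loci` that are polymorphic in the sampled genotypes (strong drift can
#' fix an allele in every population, which the generic simulator allows).
#'
#' @param seed Integer seed (default 20121120).
#' @param target_fst Mean per-locus theta the drift is calibrated to.
#' @param ... Further arguments passed to [simulation_config()].
#' @return `paperlike_config()` returns a calibrated `simulation_config`;
#'   `paperlike_dataset()` returns `list(truth, table, config)`.
#' @export
paperlike_config <- function(seed = 20121120, target_fst = 0.114, ...) {
  calibrate_to_mean_fst(target_fst,
                        simulation_config(seed = as.integer(seed), ...))
}

#' @rdname paperlike_config
#' @export
paperlike_dataset <- function(seed = 20121120, target_fst = 0.114, ...) {
  cfg <- paperlike_config(seed = seed, target_fst = target_fst, ...)
  n_target <- cfg$n_loci
  sim_cfg <- cfg
  # ascertainment surplus: extra raw loci so the polymorphic subset can be
  # trimmed back to the nominal panel size
  sim_cfg$n_loci <- n_target + max(10L, ceiling(0.15 * n_target))
  dat <- simulate_dataset(sim_cfg)
  calls <- dat$table$calls
  n <- colSums(!is.na(calls))
  dose <- colSums(calls, na.rm = TRUE)
  poly <- which(n > 0L & dose > 0L & dose < 2L * n)
  if (length(poly) < n_target) {
    stop("fewer than ", n_target, " polymorphic loci simulated; ",
         "increase the surplus or lower the drift")
  }
  keep <- poly[seq_len(n_target)]
  list(truth = .subset_truth(dat$truth, keep),
       table = subset_loci(dat$table, dat$table$loci$id[keep]),
       config = cfg)
}

.subset_truth <- function(truth, idx) {
  out <- truth
  for (fld in c("ancestral_freqs", "f_region_locus", "f_pop_locus",
                "f_total_locus", "outlier")) {
    out[[fld]] <- truth[[fld]][idx]
  }
  out$regional_freqs <- truth$regional_freqs[, idx, drop = FALSE]
  out$population_freqs <- truth$population_freqs[, idx, drop = FALSE]
  out
}

#' Write a simulated dataset to disk
#'
#' Emits the genotypes as a Genepop file, the population-to-region mapping
#' as a CSV, and the simulation truth (frequencies, per-locus drift,
#' outlier flags) as JSON.
#'
#' @param dataset A list with `truth` and `table` (see [simulate_dataset()]).
#' @param dir Output directory (created if needed).
#' @param basename File stem, default `"simulated"`.
#' @return Named character vector of the files written, invisibly.
#' @export
write_dataset <- function(dataset, dir, basename = "simulated") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gp <- file.path(dir, paste0(basename, ".gen"))
  rg <- file.path(dir, paste0(basename, "_regions.csv"))
  tj <- file.path(dir, paste0(basename, "_truth.json"))
  write_genepop(dataset$table, gp)
  write_region_map(dataset$table, rg)
  jsonlite::write_json(unclass(dataset$truth), tj, digits = NA,
                       auto_unbox = TRUE, matrix = "rowmajor")
  invisible(c(genepop = gp, regions = rg, truth = tj))
}
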