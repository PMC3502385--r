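#' Genotype table for diploid biallelic markers
#'
#' The central container of the package: a matrix of diploid biallelic
#' genotype calls for individuals grouped into population samples, with
#' populations optionally grouped into regions. Calls are stored as the
#' reference-allele dosage: `2` = homozygous reference, `1` = heterozygous,
#' `0` = homozygous alternate, `NA` = missing.
#'
#' @param calls Integer matrix, individuals x loci, values in `{0, 1, 2, NA}`.
#'   Row names (if present) are used as individual ids; column names as locus
#'   ids.
#' @param loci Either a character vector of locus ids or a data frame with
#'   columns `id`, `ref`, `alt` (allele symbols; `alt` may be `NA` for a locus
#'   at which only one allele has ever been observed).
#' @param populations Character or factor vector, one population label per
#'   individual. Population order follows first appearance.
#' @param regions Named character vector or data frame (`population`,
#'   `region`) mapping every population label to exactly one region label.
#'   Defaults to each population forming its own region.
#' @param individual_ids Optional character vector of individual ids;
#'   defaults to row names of `calls` or generated ids. Duplicated ids are
#'   allowed (with a warning) because Genepop files permit them; internal
#'   identity is (population, row index).
#'
#' @return An object of class `genotype_table`: a list with elements `calls`
#'   (integer matrix), `loci` (data frame `id`, `ref`, `alt`), `individuals`
#'   (data frame `id`, `population`), `populations` (ordered unique labels)
#'   and `regions` (named character vector, population -> region).
#' @export
genotype_table <- function(calls, loci, populations, regions = NULL,
                           individual_ids = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.character(loci)) {
    loci <- data.frame(id = loci, ref = "1", alt = "2",
                       stringsAsFactors = FALSE)
  }
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "ref", "alt") %in% names(loci)))
  if (anyDuplicated(loci$id)) {
    stop("locus ids must be unique")
  }
  bad <- !is.na(loci$alt) & loci$ref == loci$alt
  if (any(bad)) {
    stop("reference and alternate allele symbols must differ (locus ",
         loci$id[which(bad)[1]], ")")
  }
  if (ncol(calls) != nrow(loci)) {
    stop("calls has ", ncol(calls), " columns but ", nrow(loci),
         " loci were given")
  }
  populations <- as.character(populations)
  if (length(populations) != nrow(calls)) {
    stop("length(populations) must equal nrow(calls)")
  }
  if (is.null(individual_ids)) {
    # rownames are only an implicit id source; fall back to generated ids
    # when they are absent, blank or non-unique (e.g. after rbind())
    rn <- rownames(calls)
    usable <- !is.null(rn) && !anyNA(rn) && all(nzchar(rn)) &&
      !anyDuplicated(rn)
    individual_ids <- if (usable) rn else
      paste0("ind_", seq_len(nrow(calls)))
  }
  individual_ids <- as.character(individual_ids)
  if (length(individual_ids) != nrow(calls)) {
    stop("length(individual_ids) must equal nrow(calls)")
  }
  if (anyDuplicated(individual_ids)) {
    stop("individual ids must be unique")
  }
  ok <- is.na(calls) | (calls >= 0L & calls <= 2L)
  if (!all(ok)) stop("calls must be 0, 1, 2 or NA")
  pops <- unique(populations)
  regions <- .as_region_map(regions, pops)
  dimnames(calls) <- list(individual_ids, loci$id)
  structure(
    list(calls = calls,
         loci = loci,
         individuals = data.frame(id = individual_ids,
                                  population = populations,
                                  stringsAsFactors = FALSE),
         populations = pops,
         regions = regions),
    class = "genotype_table")
}

.as_region_map <- function(regions, pops) {
  if (is.null(regions)) {
    regions <- stats::setNames(pops, pops)
  } else if (is.data.frame(regions)) {
    stopifnot(all(c("population", "region") %in% names(regions)))
    regions <- stats::setNames(as.character(regions$region),
                               as.character(regions$population))
  }
  missing <- setdiff(pops, names(regions))
  if (length(missing)) {
    stop("no region label for population(s): ",
         paste(missing, collapse = ", "))
  }
  regions[pops]
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$calls), "individuals,",
      nrow(x$loci), "loci,", length(x$populations), "populations,",
      length(unique(x$regions)), "regions\n")
  n_mis <- sum(is.na(x$calls))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", n_mis,
              100 * n_mis / length(x$calls)))
  invisible(x)
}

#' Number of loci / individuals in a genotype table
#' @param table A `genotype_table`.
#' @return Integer count.
#' @export
n_loci <- function(table) nrow(table$loci)

#' @rdname n_loci
#' @export
n_individuals <- function(table) nrow(table$calls)

#' Subset a genotype table
#'
#' `subset_loci()` keeps the given loci (in the given order);
#' `subset_populations()` keeps whole population samples;
#' `subset_individuals()` keeps rows by index.
#'
#' @param table A `genotype_table`.
#' @param loci Character vector of locus ids.
#' @param populations Character vector of population labels.
#' @param idx Integer or logical row index.
#' @return A `genotype_table`.
#' @export
subset_loci <- function(table, loci) {
  keep <- match(loci, table$loci$id)
  if (anyNA(keep)) {
    stop("unknown locus id(s): ", paste(loci[is.na(keep)], collapse = ", "))
  }
  table$calls <- table$calls[, keep, drop = FALSE]
  table$loci <- table$loci[keep, , drop = FALSE]
  rownames(table$loci) <- NULL
  table
}

#' @rdname subset_loci
#' @export
subset_populations <- function(table, populations) {
  stopifnot(all(populations %in% table$populations))
  keep <- table$individuals$population %in% populations
  out <- subset_individuals(table, keep)
  out$populations <- populations
  out$regions <- table$regions[populations]
  out
}

#' @rdname subset_loci
#' @export
subset_individuals <- function(table, idx) {
  table$calls <- table$calls[idx, , drop = FALSE]
  table$individuals <- table$individuals[idx, , drop = FALSE]
  rownames(table$individuals) <- NULL
  table$populations <- intersect(table$populations,
                                 unique(table$individuals$population))
  table$regions <- table$regions[table$populations]
  table
}

.pop_factor <- function(table) {
  factor(table$individuals$population, levels = table$populations)
}

#' Per-population allele frequencies and gene-copy counts
#'
#' Computes, for every population x locus cell, the reference-allele
#' frequency `(2 * hom-ref + het) / n_genes` and the number of non-missing
#' gene copies (`2 *` non-missing individuals). Cells with no data get
#' frequency `NA` and `n_genes = 0`. The observed heterozygote proportion is
#' carried along because the Weir-Cockerham variance components need it.
#'
#' @param table A `genotype_table`.
#' @return An object of class `allele_freq_matrix`: list with `loci`,
#'   `populations`, and populations x loci matrices `freq`, `n_genes`, `het`
#'   (observed heterozygote proportion among non-missing individuals).
#' @export
compute_allele_frequencies <- function(table) {
  pf <- .pop_factor(table)
  K <- length(table$populations)
  L <- n_loci(table)
  freq <- ngen <- het <- matrix(NA_real_, K, L,
                                dimnames = list(table$populations,
                                                table$loci$id))
  calls <- table$calls
  for (k in seq_len(K)) {
    sub <- calls[pf == table$populations[k], , drop = FALSE]
    nn <- colSums(!is.na(sub))
    ngen[k, ] <- 2 * nn
    dose <- colSums(sub, na.rm = TRUE)
    freq[k, ] <- ifelse(nn > 0, dose / (2 * nn), NA_real_)
    het[k, ] <- ifelse(nn > 0, colSums(sub == 1L, na.rm = TRUE) / nn,
                       NA_real_)
  }
  structure(list(loci = table$loci$id, populations = table$populations,
                 freq = freq, n_genes = ngen, het = het),
            class = "allele_freq_matrix")
}

#' @export
print.allele_freq_matrix <- function(x, ...) {
  cat("allele_freq_matrix:", length(x$populations), "populations x",
      length(x$loci), "loci\n")
  invisible(x)
}

#' Remove individuals with too many missing genotypes
#'
#' Drops every individual whose fraction of missing calls is strictly
#' greater than `max_missing_fraction` (an individual missing exactly the
#' threshold fraction is retained). The removal log is attached as the
#' `"removed"` attribute and reported via `message()`.
#'
#' @param table A `genotype_table`.
#' @param max_missing_fraction Maximum tolerated missing-call fraction,
#'   default 0.10.
#' @return Filtered `genotype_table` with attribute `removed` (data frame of
#'   removed individuals and their missing fractions).
#' @export
filter_individuals_by_missingness <- function(table,
                                              max_missing_fraction = 0.10) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction < 1)
  frac <- rowMeans(is.na(table$calls))
  drop <- frac > max_missing_fraction
  removed <- data.frame(id = table$individuals$id[drop],
                        population = table$individuals$population[drop],
                        missing_fraction = frac[drop],
                        stringsAsFactors = FALSE)
  out <- subset_individuals(table, !drop)
  lost <- setdiff(table$populations, out$populations)
  if (length(lost)) {
    warning("population(s) emptied by missingness filter: ",
            paste(lost, collapse = ", "))
  }
  if (nrow(removed)) {
    message("removed ", nrow(removed), " individual(s) with > ",
            100 * max_missing_fraction, "% missing calls")
  }
  attr(out, "removed") <- removed
  out
}

#' Remove loci monomorphic across all populations
#'
#' A locus is monomorphic when only one allele is observed among all
#' non-missing calls in every population pooled together. Such loci carry no
#' information for any downstream measure and are removed; their ids are
#' attached as the `"removed"` attribute.
#'
#' @param table A `genotype_table`.
#' @return Filtered `genotype_table` with attribute `removed` (character
#'   vector of removed locus ids).
#' @export
filter_monomorphic_loci <- function(table) {
  calls <- table$calls
  n <- colSums(!is.na(calls))
  dose <- colSums(calls, na.rm = TRUE)
  mono <- n == 0L | dose == 0L | dose == 2L * n
  if (all(mono)) stop("all loci are monomorphic; nothing to analyze")
  removed <- table$loci$id[mono]
  out <- subset_loci(table, table$loci$id[!mono])
  if (length(removed)) {
    message("removed ", length(removed), " monomorphic locus/loci: ",
            paste(removed, collapse = ", "))
  }
  attr(out, "removed") <- removed
  out
}
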