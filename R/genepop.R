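#' Read a Genepop-format genotype file
#'
#' Parses the classic Genepop layout: a title line, one locus name per line
#' (or a single comma-separated line), then population blocks separated by
#' lines reading `Pop`, each individual on one line as
#' `id , g1 g2 ...` with each genotype a pair of fixed-width allele codes.
#' Allele code `00` (or `000` in the 3-digit dialect) denotes a missing
#' allele; a call with any missing allele is treated as a missing genotype.
#' For each locus the two distinct non-missing codes observed define the
#' alleles, the numerically smaller code being the reference allele.
#'
#' Genepop files do not name populations or regions; populations are
#' labelled `pop_1`, `pop_2`, ... in file order unless `pop_names` is given,
#' and regions come from the optional sidecar mapping (see
#' [read_region_map()]).
#'
#' @param path Path to the Genepop file.
#' @param allele_digits Width of one allele code: 2 (default) or 3.
#' @param pop_names Optional character vector of population labels, one per
#'   `Pop` block.
#' @param regions Optional region mapping: a named character vector, a data
#'   frame (`population`, `region`), or the path of a CSV with that header.
#' @return A [genotype_table()].
#' @export
read_genepop <- function(path, allele_digits = 2, pop_names = NULL,
                         regions = NULL) {
  stopifnot(allele_digits %in% c(2, 3))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("not a Genepop file: too few lines")
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("not a Genepop file: no 'Pop' separator")
  locus_lines <- lines[2:(first_pop - 1)]
  locus_ids <- trimws(unlist(strsplit(locus_lines, ",")))
  locus_ids <- locus_ids[nzchar(locus_ids)]
  L <- length(locus_ids)
  if (L == 0) stop("no locus names found")

  body <- lines[first_pop:length(lines)]
  body_pop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  pop_idx <- cumsum(body_pop)
  ind_lines <- body[!body_pop]
  ind_pop <- pop_idx[!body_pop]
  line_no <- (first_pop:length(lines))[!body_pop]
  if (!length(ind_lines)) stop("Genepop file contains no individuals")
  K <- max(ind_pop)
  if (is.null(pop_names)) pop_names <- paste0("pop_", seq_len(K))
  stopifnot(length(pop_names) == K)

  missing_code <- strrep("0", allele_digits)
  ids <- character(length(ind_lines))
  allele_codes <- matrix(NA_character_, length(ind_lines), 2L * L)
  for (i in seq_along(ind_lines)) {
    parts <- strsplit(ind_lines[i], ",")[[1]]
    if (length(parts) < 2) {
      stop("line ", line_no[i], ": expected 'id , genotypes'")
    }
    ids[i] <- trimws(parts[1])
    geno <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                     "\\s+")[[1]]
    if (length(geno) != L || any(nchar(geno) != 2 * allele_digits)) {
      stop("line ", line_no[i], ": expected ", L, " genotypes of ",
           2 * allele_digits, " digits")
    }
    allele_codes[i, ] <- c(rbind(substr(geno, 1, allele_digits),
                                 substr(geno, allele_digits + 1,
                                        2 * allele_digits)))
  }

  calls <- matrix(NA_integer_, length(ind_lines), L)
  ref <- alt <- character(L)
  for (l in seq_len(L)) {
    a1 <- allele_codes[, 2 * l - 1]
    a2 <- allele_codes[, 2 * l]
    obs <- c(a1, a2)
    obs <- sort(unique(obs[obs != missing_code]))
    if (length(obs) > 2) {
      stop("locus ", locus_ids[l], ": ", length(obs),
           " distinct allele codes observed (biallelic data required)")
    }
    ref[l] <- if (length(obs) >= 1) obs[1] else "01"
    alt[l] <- if (length(obs) == 2) obs[2] else NA_character_
    mis <- a1 == missing_code | a2 == missing_code
    calls[, l] <- ifelse(mis, NA_integer_,
                         (a1 == ref[l]) + (a2 == ref[l]))
  }

  if (is.character(regions) && length(regions) == 1 && file.exists(regions)) {
    regions <- read_region_map(regions)
  }
  genotype_table(calls,
                 loci = data.frame(id = locus_ids, ref = ref, alt = alt,
                                   stringsAsFactors = FALSE),
                 populations = pop_names[ind_pop],
                 regions = regions,
                 individual_ids = ids)
}

#' Write a genotype table to a Genepop-format file
#'
#' The inverse of [read_genepop()]: reference alleles are coded `01`
#' (`001` in the 3-digit dialect), alternate alleles `02`, missing alleles
#' `00`. Round-tripping preserves calls, locus order and population order.
#'
#' @param table A [genotype_table()].
#' @param path Output file path.
#' @param allele_digits 2 (default) or 3.
#' @param title Title line written as the first line of the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(table, path, allele_digits = 2,
                          title = "panelrank export") {
  stopifnot(allele_digits %in% c(2, 3))
  if (length(table$populations) == 0 || n_individuals(table) == 0) {
    stop("cannot write a Genepop file with no populations")
  }
  pad <- function(x) formatC(x, width = allele_digits, flag = "0")
  code <- c(paste0(pad(2), pad(2)),   # dose 0: alt/alt
            paste0(pad(1), pad(2)),   # dose 1: ref/alt
            paste0(pad(1), pad(1)))   # dose 2: ref/ref
  mis <- paste0(pad(0), pad(0))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, table$loci$id), con)
  pf <- .pop_factor(table)
  for (pop in table$populations) {
    writeLines("Pop", con)
    rows <- which(pf == pop)
    for (i in rows) {
      g <- table$calls[i, ]
      gcode <- ifelse(is.na(g), mis, code[g + 1L])
      writeLines(paste0(table$individuals$id[i], " ,  ",
                        paste(gcode, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read or write a population-to-region mapping CSV
#'
#' Genepop files carry no region concept, so regional structure travels in a
#' sidecar CSV with header `population,region`.
#'
#' @param path CSV path.
#' @param table For `write_region_map()`, the `genotype_table` whose region
#'   mapping should be written.
#' @return `read_region_map()` returns a named character vector
#'   (population -> region); `write_region_map()` returns `path` invisibly.
#' @export
read_region_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("population", "region") %in% names(df)))
  stats::setNames(as.character(df$region), as.character(df$population))
}

#' @rdname read_region_map
#' @export
write_region_map <- function(table, path) {
  utils::write.csv(data.frame(population = names(table$regions),
                              region = unname(table$regions)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
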