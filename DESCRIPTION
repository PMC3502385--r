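Package: panelrank
Title: Ranking and Evaluation of SNP Panels for Population Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating panels of biallelic SNP
    markers for genetic stock identification. Scores every locus by five
    ranking measures (Weir-Cockerham F_ST, Rosenberg's informativeness for
    assignment, average locus contribution to leading principal components,
    and two assignment-performance rankers: a jackknife scorer and a
    backward-elimination scorer), assembles fixed-size panels from the
    top-ranked loci, and measures panel performance both by empirical
    holdout assignment and by simulated assignment (f_ORCA), including
    locus drop-off curves. Includes Genepop-format I/O, standard per-locus
    QC (Hardy-Weinberg chi-square tests, rarefied allelic richness,
    permutation tests of linkage disequilibrium, sequential Bonferroni
    correction), and a hierarchical Balding-Nichols simulator of structured
    diploid genotype data with known per-locus differentiation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vegan,
    withr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
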