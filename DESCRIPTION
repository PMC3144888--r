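Package: barcodiv
Title: Diversification Analysis of DNA Barcode Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative diversification analysis of aligned COI
    DNA-barcode libraries: Kimura two-parameter distances with pairwise
    deletion, neighbour-joining trees, per-species intraspecific summaries
    and deep-haplogroup detection, non-redundant nearest-congeneric-neighbour
    and sister-species divergence comparisons across biogeographic regions,
    regional inferential statistics (one-way ANOVA, Scheffe contrasts,
    two-sample Kolmogorov-Smirnov, 2x2 chi-square), and relative-rate
    calibration of the COI molecular clock against cytochrome b.  Includes a
    sequence simulator under the Kimura two-parameter substitution process so
    the whole pipeline can be exercised against known truth.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    seqinr,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
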