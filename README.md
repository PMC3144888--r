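# barcodiv

Comparative diversification analysis of DNA barcode libraries.

Large COI barcode surveys do more than identify specimens: because every
specimen carries the same ~648 bp mitochondrial marker, a regional library
doubles as a standardized sample of how deeply the species of that region
have diverged.  `barcodiv` implements the full analysis chain needed to
compare regions on that basis — for ornithologists and barcoding groups who
hold aligned COI libraries with specimen metadata and want reproducible,
scriptable answers to questions like *are avian sister species younger in
the temperate Nearctic than in the southern Neotropics?*

## What it computes

* **Kimura two-parameter distances** between all specimens, with pairwise
  deletion of gaps/ambiguities:
  *d* = −½ ln[(1 − 2*P* − *Q*)·√(1 − 2*Q*)], where *P* and *Q* are the
  transition (A↔G, C↔T) and transversion proportions over the compared
  sites.  Saturated pairs are reported as missing, never clamped.
* **Neighbour-joining trees** (Saitou–Nei agglomeration, Studier–Keppler
  *Q*-criterion) with a deterministic lexicographic tie-break, plus Newick
  serialization that round-trips quoted labels.
* **Intraspecific structure**: per-species mean/maximum within distance;
  deep haplogroups as single-linkage components at a 1.5% threshold; a
  species with ≥2 haplogroups and maximum intraspecific distance >1.5% is
  flagged *highly variable*.  Regional averages weight each species equally
  and are reported with and without the variable species.
* **Species-pair comparisons**: non-redundant nearest-congeneric-neighbour
  pairs by mutual-nearest matching (no species counted twice), sister-pair
  annotation from published lists, divergence means ± SD, and the
  proportion of pairs diverging by less than 1%.
* **Regional statistics**, from closed forms: one-way ANOVA, Scheffé
  post-hoc contrasts, the asymptotic two-sample Kolmogorov–Smirnov *Z*
  test, and the uncorrected 2×2 chi-square.
* **COI clock calibration**: the COI/cytochrome *b* slowdown from sister
  pairs sequenced at both loci (ratio-of-means or mean-of-ratios), the
  calibrated rate (2.1 %/My × (1 − 0.35) ≈ 1.4 %/My), divergence-to-age
  conversion and epoch binning (a 1% pair diverged within the last
  ~0.7 My; 2.8% sits on the 2.0 My Plio-Pleistocene boundary).
* **A sequence simulator** under the K2P substitution process
  (`simulate_region()`), which generates whole regional libraries with a
  known truth table so every stage can be validated by parameter recovery.

## Worked example

A small synthetic library (60 specimens, 20 species, 10 genera, labelled
synthetic in its filenames) ships with the package:

```r
library(barcodiv)
fa <- system.file("extdata", "synthetic_demo.fasta", package = "barcodiv")
md <- system.file("extdata", "synthetic_demo_metadata.tsv", package = "barcodiv")
sl <- read.delim(system.file("extdata", "synthetic_demo_sisters.tsv",
                             package = "barcodiv"))
lib <- read_barcode_library(fa, md, region = "Demo")
srv <- barcode_survey(lib, sister_lists = sl)
srv
```

```
Barcode diversification survey: 1 region(s)

Region: Demo
  60 specimens read, 0 filtered; 20 species with >= 2 specimens
Mean intraspecific distance: 0.30% +/- 0.57% (20 species)
  highly variable species: 1 of 20 (5.0%)
  nearest congeners: 5.0% +/- 4.4% (n = 9), 11.1% below 1%
  sister pairs: 2.1% +/- 1.0% (n = 5), 20.0% below 1%
```

Reading the report: the average of the species-level mean intraspecific
distances is 0.30% — shallow, as expected for barcodes — while one species
(5%) carries two haplogroups more than 1.5% apart and is excluded from the
nearest-congener list.  Nine independent congener pairs average 5.0%
divergence; of the five annotated sister pairs, one (20%) diverges by less
than 1%, i.e. within roughly the last 700,000 years at the calibrated COI
rate.  The epoch table of the same report bins each sister pair's age:

```r
srv$reports$Demo$epochs
#> mid-to-late Pleistocene       early Pleistocene                Pliocene
#>                       1                       3                       1
#>            pre-Pliocene
#>                       0
```

With two or more regions, `srv$tests` holds the cross-region ANOVA/Scheffé,
Kolmogorov–Smirnov and chi-square table, and `write_report(srv, dir)`
exports all tables as TSV.  See the vignette
(`vignettes/barcode-diversification.Rmd`) for the model, parameter and
design discussion.

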