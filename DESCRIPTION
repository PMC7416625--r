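Package: genomescapes
Title: Genome Landscape Analyses: Retrotransposon Demography, Gene
    Insulae, Colinearity and Recombination
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical analyses of large repeat-rich plant genomes:
    dating of long terminal repeat (LTR) retrotransposon insertions from
    LTR-pair divergence with a gamma-Poisson (negative binomial) maximum
    likelihood model, exponential survival of elements and normalized
    insertion-intensity curves; a likelihood-ratio test of gene clustering
    ("insulae") based on an exponential mixture model for intergenic
    distances fitted by EM with parametric-bootstrap calibration; detection
    of colinear gene runs between genomes, classification of chromosome
    rearrangements (inversions, translocations, duplications, deletions)
    and parsimony assignment of events to phylogenetic branches; Marey-map
    recombination-rate estimation by local polynomial smoothing and its
    correlation with gene density; and sequence scanners for telomeric
    repeat arrays, microsatellites, k-mer uniqueness and organellar
    insertion intervals.  A synthetic-genome generator produces all inputs
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    KernSmooth
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, Software, StatisticalMethod, Transposon,
    WholeGenome, Annotation
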