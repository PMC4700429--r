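Package: pombe3d
Title: Contact-Restrained Coarse-Grained Genome Ensembles and Nuclear
    Density Maps for Fission Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the Schizosaccharomyces pombe genome as worm-like
    polymer chains of 30 nm granules (3.5 kb each) confined to the nucleus,
    excluded from the nucleolus, tethered at centromeres and telomeres, and
    restrained by proximity-ligation (GCC/Hi-C style) contact subsets drawn
    with frequency-proportional probability. Generates Metropolis Monte
    Carlo ensembles of independently optimized conformations, calibrates
    the contact-subset size against a target radius of gyration, maps
    linear feature tracks (ChIP enrichment, replication origins with
    firing-time and efficiency classes) onto granules, and computes
    rotationally projected density grids, Dempf-regularized relative
    density maps, top-signal contour masks, difference maps, per-granule
    impact profiles, and linear/spatial overlap statistics. Includes a
    synthetic-data generator emulating contact distance decay,
    centromere/telomere clustering and compartment-biased ChIP tracks so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
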