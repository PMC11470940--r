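Package: baokit
Title: Polyploid Genome Characterization: Ploidy, Repeats, LTR Dynamics,
    Whole-Genome Multiplication and Population Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream characterization analyses for polyploid plant
    genomes: allele-balance ploidy inference from heterozygous biallelic
    sites (fixed-mean Gaussian mixture model selection), k-mer spectrum
    genome profiling (size, unique/repeat partition, heterozygosity),
    solo versus intact LTR retrotransposon classification and insertion-age
    dating, tandem-repeat monomer and higher-order repeat detection with
    telomere tract measurement, Nei-Gojobori synonymous-distance (Ks)
    computation with peak detection and whole-genome multiplication dating,
    collinear anchor chaining with syntenic depth and gene-retention
    profiles, and Weir-Cockerham Fst, genotype PCA and windowed local-PCA
    partitioning.  Every pipeline input can be generated synthetically with
    recorded ground truth, so each stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
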