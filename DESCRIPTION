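Package: haploscan
Title: Cross-Population Haplotype Selection Scans with Simulation-Based
    Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects recent positive selection from phased diploid genotypes
    of two populations. Implements extended haplotype homozygosity (EHH),
    integrated EHH (iHH) and the cross-population XP-EHH statistic with
    genome-wide standardization; 50-kb window summarization with SNP-count
    binning and rank-based empirical P-values for outlier calling; windowed
    nucleotide diversity and runs-of-homozygosity profiling; variant
    hard-filtering and genotype concordance; and a two-population synthetic
    haplotype generator (structured coalescent with split and bottleneck,
    plus a forward Wright-Fisher phase for selective sweeps) so that the
    whole scan can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
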