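Package: ecdnaspatial
Title: Spatial Statistics and Dosage Analysis for Extrachromosomal DNA Foci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analyses of the nuclear organisation and
    transcriptional output of extrachromosomal DNA (ecDNA) in cancer nuclei.
    Provides per-nucleus 3D Ripley's K clustering tests against Monte-Carlo
    complete-spatial-randomness nulls with empirical p-values and
    Benjamini-Hochberg false-discovery control; nearest-neighbour distance
    summaries and proximity fractions for FISH focus coordinates; equal-area
    nuclear erosion-shell radial intensity profiling with DAPI normalisation;
    copy-number-normalized transcription statistics (RNA:DNA focus ratios,
    per-exon RNA/WGS normalisation, amplicon SNP allele-frequency ratios);
    and synthetic-data generators (uniform, Thomas-clustered and doublet
    point patterns in a bounded nucleus, radially biased images, and
    copy-number-driven count/SNP tables) so every stage is testable without
    microscopy or sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    EBImage,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
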