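Package: insituseq
Title: Targeted In Situ Sequencing: Probe Design, Simulation, Decoding and
    Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained toolkit for targeted in situ sequencing (ISS)
    of mRNA with barcoded padlock probes and rolling circle amplification.
    Designs gene-specific chimeric padlock probes from a transcriptome
    (30-mer target slicing, GC and ligation-junction filters, Hamming-based
    specificity screening, cross-species panels), builds and validates
    combinatorial gene-to-color-sequence codebooks, simulates tiled
    multi-cycle multi-channel fluorescence datasets with per-spot ground
    truth, preprocesses raw tiles (maximum z-projection, stitching,
    cross-cycle registration, reslicing), decodes amplicons into a
    quality-scored read table, and quantifies reads per cell via nuclei
    segmentation into a cell-by-gene count matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    EBImage,
    Matrix,
    S4Vectors,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    SingleCellExperiment,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
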