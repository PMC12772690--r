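Package: gagarec
Title: GAGA-Motif/RSS Recombination Units: Motif Scanning, ATAC
    Fragment Signals, and V(D)J Repertoire Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the extended recombination unit formed by a
    5' GAGA motif and a recombination signal sequence (RSS) at immunoglobulin
    and T-cell receptor J gene segments. Provides RSS (heptamer/spacer/nonamer)
    and GAGA/GA-repeat motif scanners with spacing reports, nucleosome-occupancy
    and chromatin-accessibility signal tracks built from paired-end ATAC-seq
    fragments partitioned by insert size (with housekeeping-normalised region
    quantification and nucleosome dyad calling), Vk-Jk clone classification
    (Jk assignment by local alignment, reading-frame and productivity calls,
    per-group usage tables with unpaired t-test comparisons), delta-delta-Ct
    qPCR quantification, and a synthetic-data module that generates toy loci,
    ATAC fragment sets and clone repertoires with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
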