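Package: mosaicseg
Title: Detection of Mosaic Allelic Imbalances from SNP Array Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects mosaic copy-number and copy-neutral chromosomal
    alterations (deletions, duplications, trisomies and uniparental
    disomies present in only a fraction of cells) from SNP-array
    B-allele frequency (BAF) and log R ratio (LRR) tracks. Per-probe
    deviations of BAF from the expected genotype cluster are probit
    transformed and segmented by a sparse candidate-breakpoint search
    followed by backward elimination on t-statistics; called segments
    receive p-values and a conservative genome-wide false discovery
    rate estimate, are classified by their mean LRR relative to the
    diploid baseline, and the affected cell fraction is estimated from
    the magnitude of the allelic imbalance. Includes a simulator of
    SNP-array tracks with known mosaic events and benchmark utilities
    (sensitivity curves, ROC tables, FDR calibration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
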