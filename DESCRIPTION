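Package: sevscan
Title: Stochastic Epigenetic Variation Analysis for DNA Methylation Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects stochastic epigenetic variations (SEVs) in Illumina-style
    beta-value methylation matrices by per-CpG extreme-outlier fences
    (Q1 - 3*IQR, Q3 + 3*IQR) computed against reference populations, screens
    per-subject SEV burden for genomic enrichment in sliding windows, genes and
    imprinted differentially methylated regions with the hypergeometric
    cumulative distribution, reduces mixed phenotype tables with factor
    analysis of mixed data (FAMD), and associates log SEV burden with
    phenotype dimensions across reference modes via Fisher's combined
    probability test. Includes a synthetic methylome and phenotype generator
    with recorded ground truth, probe/sample quality control (flag-based probe
    filtering and greedy removal of unreliable rows/columns), an ordinary
    least squares per-site scan with genomic inflation diagnostics, and an
    end-to-end reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
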