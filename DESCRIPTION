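Package: circatemp
Title: Circadian Temperature Compensation and Alternative Polyadenylation
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying temperature compensation of the circadian
    clock and its posttranscriptional regulation. Estimates free-running
    periods from plate-format bioluminescence recordings by moving-average
    detrending and damped-cosine fitting; tests period-temperature slopes
    between genotypes with a pooled-variance differential-slope statistic
    and converts fitted periods to Q10 temperature coefficients with
    first-order error propagation; quantifies alternative polyadenylation
    from 3'-end sequencing read profiles via the normalized center of mass
    (NCOM) of reads along annotated 3' UTRs, including scanning-window
    polyadenylation-site discovery, annotation extension, and
    median-of-ratios normalization; fits mRNA half-lives from
    transcription-shutoff time courses; and runs genome-scale differential
    temperature-response screens across 3' UTR length, transcript, and
    protein layers with Benjamini-Hochberg correction and cross-layer
    Fisher enrichment. A synthetic-data module generates all input kinds
    with the generative structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
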