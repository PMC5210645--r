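Package: metapeaks
Title: Consensus Transcription-Factor Binding Sites from Multi-Caller
    ChIP-seq Peaks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds non-redundant sets of transcription-factor binding
    sites from heterogeneous ChIP-seq peak-caller outputs. Peaks for one
    factor and one caller are reduced to caller-specific point centers and
    merged across experiments into clusters by single-linkage chaining at
    50 bp; clusters are summarised by the median center, the standard
    deviation of member centers and a width of motif length plus four
    standard deviations. Clusters from different callers are then merged
    into cross-caller metaclusters, represented by the member from the
    highest-priority caller (callers ranked by median within-cluster
    standard deviation) and filtered to require support from at least two
    callers. Includes readers for ENCODE narrowPeak and a normalized
    interchange format, BED-like writers, a ground-truth peak simulator
    and recovery metrics for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    rtracklayer,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
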