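Package: svensemble
Title: Ensemble Merging and Benchmarking of Structural Variant Call Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for combining structural variant (SV) calls from multiple
    short-read callers and benchmarking them against truth sets. Caller VCFs
    are refined in four steps (type/length annotation, sub-50 bp exclusion,
    paired-breakend deduplication, PASS filtering), pooled calls are clustered
    into neighbor groups within a breakpoint-distance window, and merged call
    sets are produced under multiple-agreement, union, or direct-merge
    strategies. Evaluation matches calls to truth variants by position and
    type, reports precision, recall and F1 per dataset, and micro-averages
    counts across datasets. A call-set simulator generates truth sets and
    per-caller call sets with realistic recall, false-positive load,
    breakpoint jitter and caller output dialects, so the whole pipeline runs
    and can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
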