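Package: camieval
Title: Benchmarking Metrics for Metagenome Assembly, Binning and Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores metagenome analysis results against simulation-derived gold
    standards using the evaluation conventions of community benchmarking
    challenges. Reads CAMI bioboxes binning and profiling formats and NCBI-style
    taxonomy dumps; computes base-pair-weighted genome-binning metrics (purity,
    completeness, adjusted Rand index, quality-tier counts), per-rank taxonomic
    binning metrics with 1 percent small-bin filtering, taxonomic profiling
    metrics (presence/absence, L1 norm, Bray-Curtis, Shannon equitability and
    earth-mover's-distance weighted UniFrac on the taxonomic tree), and
    strain-resolved assembly summaries (strain recall and precision, NGA50
    conventions). Aggregates per-sample metrics into placement-score rankings
    and ships a deterministic synthetic fixture generator so every metric is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    boot,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
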