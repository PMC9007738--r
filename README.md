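# camieval

Benchmarking metrics for metagenome assembly, genome binning, taxonomic
binning and taxonomic profiling, scored against simulation-derived gold
standards.

## Who this is for

Developers of metagenome analysis tools and organizers of benchmarking
efforts who need to score submissions in the CAMI bioboxes formats against
a known ground truth — and anyone who wants the standard evaluation
metrics of this field (bp-weighted adjusted Rand index, per-rank
purity/completeness with 1 % small-bin filtering, EMD-based weighted
UniFrac, strain recall/precision) as tested, documented R functions rather
than one-off scripts.

## The metrics in brief

* **Genome binning** — per-bin purity $\mathrm{TP}_b/(\mathrm{TP}_b +
  \mathrm{FP}_b)$ with $\mathrm{TP}_b$ the bp of the bin's most abundant
  genome; average completeness over $|B| + |X|$ (bins plus genomes
  recovered by no bin); the adjusted Rand index computed bp-weighted on
  the binned portion only, read together with the binned fraction; counts
  of moderate (>50 % complete, <10 % contaminated) and high-quality
  (>90 %, <5 %) bins.
* **Taxonomic binning** — purity, completeness and accuracy per major
  taxonomic rank after projecting labels through an NCBI-style taxonomy
  (merged-ID aliases resolved); each metric also in a filtered variant
  that removes the smallest predicted bins up to 1 % of cumulative size.
* **Taxonomic profiling** — presence/absence purity, completeness and F1;
  L1 norm error (range 0–2) and Bray–Curtis distance over the taxon
  union; Shannon equitability error; and weighted UniFrac: the
  earth-mover's distance between the two abundance distributions placed
  on the taxonomic tree with unit branch lengths, ranging 0 (identical)
  to 16 (all mass at species depth in different kingdoms).
* **Assembly** — consumes per-genome MetaQUAST-style report tables;
  strain recall (fraction of ground-truth genomes assembled with genome
  fraction > 90 % and mismatches < 0.5 %, preset-configurable) and strain
  precision; cross-genome means with NGA50 set to 0 below 50 % genome
  fraction before averaging.
* **Ranking** — metrics averaged over samples per tool, then converted to
  placement scores (0 = first place, ties share the better score,
  per-rank metrics summed over taxonomic levels, missing metrics scored
  worst); the summary statistic is the per-tool score sum.

A deterministic synthetic-community generator (`community_spec()`,
`generate_gold()`, `corrupt_binning()`, `corrupt_profile()`,
`generate_assembly_report()`, `write_fixture_bundle()`) produces toy
taxonomies, gold standards and controlled-error submissions, so the whole
stack is testable without downloading anything.

## Worked example

Generate a toy community, corrupt it at two different error rates, score
both "binners", and rank them:

```r
library(camieval)

spec   <- community_spec(n_genomes = 8, n_samples = 2, seed = 7)
bundle <- generate_gold(spec)
g      <- bundle$gold[[1]]

good <- corrupt_binning(g, misbin_rate = 0.05, unassigned_rate = 0.02, seed = 1)
poor <- corrupt_binning(g, misbin_rate = 0.30, unassigned_rate = 0.15, seed = 1)

tab <- rbind(genome_binning_metrics(g, good, tool = "binner_A"),
             genome_binning_metrics(g, poor, tool = "binner_B"))
print(tab, digits = 3)
#>     sample     tool average_purity average_completeness    f1   ari
#> 1 sample_1 binner_A          0.928                0.967 0.947 0.972
#> 2 sample_1 binner_B          0.553                0.204 0.298 0.429
#>   binned_fraction n_moderate n_high
#> 1           0.993          6      6
#> 2           0.896          0      0

rank_tools(average_over_samples(tab, metric_registry("genome_binning")),
           metric_registry("genome_binning"))
#> <ranking_table> 2 tools, 7 ranked metric(/rank) columns
#> summary statistic (lower is better):
#>      tool total
#>  binner_A     0
#>  binner_B     7
```

`binner_A` mis-assigns 5 % of sequences and recovers six of the eight
genomes as moderate-and-high-quality bins; `binner_B`'s 30 % mis-binning
destroys completeness (each genome's bp is scattered, so its majority bin
holds only a fifth of it) and with first place in every one of the seven
metrics `binner_A` earns the perfect summary statistic of 0.

File-based evaluations run the same way through `run_evaluation()` (a
config list or YAML file naming gold standards, submissions and the
taxonomy directory) or the thin CLI in `inst/scripts/camieval` with
subcommands `fixtures`, `genome-binning`, `tax-binning`, `profiling`,
`assembly` and `rank`.

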