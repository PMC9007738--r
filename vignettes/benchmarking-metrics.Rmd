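---
title: "Benchmarking metagenome analysis tools against gold standards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking metagenome analysis tools against gold standards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camieval)
```

`camieval` scores metagenome analysis results — assemblies, genome
binnings, taxonomic binnings and taxonomic profiles — against
simulation-derived gold standards, and aggregates the per-sample metrics
into a placement-score ranking. This vignette explains the models behind
each metric, the tunable parameters, the synthetic data generator used
throughout the test suite, and the design decisions that were genuinely
open.

## The evaluation model

All binning metrics are **base-pair weighted**: a sequence contributes its
gold-standard length, not a count of one, so a mis-binned 100 kb contig
costs a thousand times more than a mis-binned 100 bp fragment. Sequence
identifiers are opaque strings and no FASTA access is ever needed — the
gold standard carries the lengths, which keeps the evaluator
alignment-free.

### Genome binning

For every predicted bin $b$, $\mathrm{TP}_b$ is the bp of the most
abundant genome $g$ in $b$, $\mathrm{FP}_b$ the bp of all other genomes in
$b$, and $\mathrm{FN}_b$ the bp of $g$ outside $b$. Purity of a bin is
$\mathrm{TP}_b/(\mathrm{TP}_b+\mathrm{FP}_b)$; average purity is the
unweighted mean over bins. Average completeness sums, per bin, the
completeness of the bin's majority genome and divides by $|B|+|X|$, where
$X$ is the set of genomes that are the majority genome of **no** bin — a
binner that misses genomes entirely pays for them. Both equations need a
single genome-to-bin mapping to be well formed; we map each bin to its
most abundant genome (ties broken by lexicographic genome ID, which keeps
the bookkeeping deterministic; the purity value itself is tie-invariant).

The adjusted Rand index treats every binned base pair as an item and
compares the genome partition with the bin partition through the standard
pair-counting closed form on the bp contingency cells. Because unbinned
data would make the ARI meaningless, it is computed on the binned portion
only and must be read together with the binned fraction. The near-zero
"worst case" is reported as computed — slightly negative values are
possible and are not clamped.

Quality-tier counts use strict inequalities: completeness $> 0.5$ and
contamination $< 0.10$ for moderate-or-higher bins, $> 0.9$ and $< 0.05$
for high-quality bins.

The category F1 score is the harmonic mean of average purity and average
completeness. The alternative reading — averaging per-bin F1 — was
rejected because it leaves the unrecovered-genome set $X$ without any
influence on the score.

### Taxonomic binning

Metrics are computed per major rank after projecting both gold and
predicted taxon labels onto that rank. Gold sequences whose lineage has no
node at the rank are excluded from the gold-standard scope (`GS`, $n$);
predictions that project to nothing contribute no bin. Average purity
averages over predicted bins (including bins for taxa absent from the
sample — they have $\mathrm{TP}=0$ and drag purity down, which is exactly
why unfiltered purity is low in practice); average completeness divides by
$|GS|$; accuracy is the correctly assigned bp over all gold bp at the
rank.

The 1 % filter sorts bins by increasing size and removes the leading bins
whose cumulative size is $\leq$ 1 % of the summed bin size. Bin size is
the **predicted** size $\mathrm{TP}_b+\mathrm{FP}_b$ — the only size an
evaluator knows before truth matching. `GS` and $n$ are unchanged by
filtering, so filtered completeness and accuracy can only decrease
(asserted property-style in the tests), while filtered purity typically
increases. Filtering is not idempotent in general: removing bins shrinks
the total, so a second pass can remove more.

### Taxonomic profiling

Presence/absence metrics compare the taxon sets with positive abundance at
a rank. The L1 norm sums $|x_t - x_t^\ast|$ over the union of taxa, so a
taxon absent from one profile contributes its full abundance — this is
what makes the upper bound of 2 attainable. Bray–Curtis divides the L1 by
the summed abundances and equals L1/2 exactly when both profiles account
for 100 % of the data.

The Shannon equitability (Pielou evenness) of a profile at a rank is
$-\sum_t p_t \ln p_t / \ln m$ with $m$ the number of taxa with positive
abundance, defined as 0 when $m = 1$; abundances are renormalized within
the rank first so that incomplete profiles are judged on their shape, not
their coverage. We implement the standard non-negative form; written
without the minus sign the quantity would be $\leq 0$ and could not range
from 0 to 1.

**Weighted UniFrac** is the earth-mover's distance between the two
profiles' mass distributions on the taxonomic tree. Each profile's mass is
placed at its *most specific annotated taxa* (entries none of whose
descendants also carry mass — profiles are cumulative across ranks, so
placing mass at every rank would double-count and change the scale) and
normalized to total 1. The tree spans the major-rank ancestors of the
massed nodes; every edge between consecutive present ancestors has unit
length and a virtual root joins the superkingdoms. The EMD is computed by
the exact tree algorithm — accumulate, over edges in decreasing depth
order, |net mass imbalance of the subtree| × branch length. With full
eight-rank lineages the worst case is 16: all mass at species depth under
one kingdom versus another, eight branches up and eight down. The test
suite cross-checks this algorithm against an independent
linear-programming transportation solution on random trees.

Profile taxa that cannot be resolved in the taxonomy are dropped from
UniFrac with renormalization (a flag disables the renormalization);
presence metrics keep them as false positives, because presence is
ID-based while UniFrac is tree-based.

### Assembly

The evaluator consumes per-genome statistics tables (genome fraction,
mismatches per 100 kb, duplication ratio, NGA50, misassemblies) produced
by an external alignment-based assessment; it does not align. Strain
recall is the fraction of all ground-truth genomes assembled with genome
fraction strictly above and mismatch rate strictly below the thresholds;
genomes absent from a report count as not recovered. Strain precision is
the fraction of low-mismatch assemblies among the high-genome-fraction
ones, and is *undefined* (not zero) when nothing clears the fraction
threshold. Two presets ship: `"marine"` (fraction > 90 %, mismatches
< 0.5 % ≡ 500/100 kb) and `"strain-madness"` (fraction > 75 %, same
mismatch bound, for communities where assembly is generally harder). The
marine mismatch bound is a documented package default, not an externally
fixed constant. Mismatch thresholds may be given per 100 kb or as percent
of aligned bases; they are stored per 100 kb.

Cross-genome summaries average per genome, with NGA50 set to 0 for
genomes under 50 % genome fraction (where it is undefined) *before*
averaging, so unrecovered halves of a community drag the average down
instead of silently vanishing.

### Ranking

Per-sample metric values are averaged per tool (undefined values excluded
from the mean, with a count logged), then each metric — and each
taxonomic level of the per-rank metrics — is turned into placement
scores: 0 for first place, 1 for second, and so on, orientation-aware.
Ties share the better (minimum) score: competition ranking is
deterministic and independent of input order, which an average-rank
scheme would not need but a sequential one would. A tool missing a metric
receives the worst score rather than being excluded, keeping totals
comparable across tools (prominently logged). The overall summary
statistic is the per-tool sum of scores, optionally weighted per metric
(default weight 1). We average metrics over samples first and rank once,
rather than ranking per sample and averaging scores; with few samples the
latter is dominated by ranking noise.

## The taxonomy

The eight major ranks default to superkingdom, kingdom, phylum, class,
order, family, genus, species — eight levels ending at species, which is
what makes the species-depth UniFrac worst case equal 16. The list is
configurable. Non-major ranks ("no rank", strain) are never metric keys;
they are only traversed during projection. Merged-ID aliases (as in
NCBI's `merged.dmp`) are resolved before any lookup, following chains.
Unknown taxon IDs in predictions are dropped with a warning and counted;
`strict = TRUE` turns this into a failure. The taxonomy is an input, not
a pinned version — evaluations are only comparable when run against the
same dump.

## The synthetic community generator

`community_spec()` defines the study conditions; `generate_gold()` emits
an internally consistent bundle (taxonomy, per-sample sequence maps, gold
profiles whose per-rank abundances are exactly the bp-weighted genome
shares). The defaults describe a small but non-degenerate community:

* 10 genomes, 2 samples; per-sample genome abundance factors are
  log-normal with $\sigma = 1$, giving the skewed abundance distributions
  typical of real communities.
* about 20 contigs per genome at average abundance, log-normal lengths
  (median ≈ 3 kb, minimum 500 bp) — so bp-weighting genuinely differs from
  sequence counting and count-vs-bp bugs surface in tests.
* one "common" genome pair sharing a species node (two strain-level
  leaves), the bookkeeping analogue of two genomes within 95 % average
  nucleotide identity; the rest are one species each.
* three decoy species that exist in the taxonomy but carry no genomes, as
  every reference database does; mislabeled predictions can land on them
  and become false positives.
* a species tree built by nested interval splits whose group counts grow
  geometrically from two superkingdom-level clades down to singleton
  species, so ranks genuinely aggregate (rather than collapsing to
  identical partitions at every level, as naive repeated halving does for
  small communities).

The corruption operators are controlled-error models, not realism claims:
`corrupt_binning()` leaves each sequence unassigned or reassigns it to a
uniformly chosen wrong label at the given rates; `corrupt_profile()`
perturbs leaf abundances by Dirichlet resampling around the gold
proportions (concentration → ∞ recovers the gold) and then drops or
relabels the lowest-abundance taxa first, emulating the detection limit
where real profilers actually lose and confuse taxa. Dropped mass is not
restored, so corrupted profiles are incomplete — which is what makes
Bray–Curtis exceed L1/2, as it should.

Two behaviors of these models are worth knowing when reading test
results. First, forced-*wrong* reassignment retains a small positive
chance association between truth and prediction when labels are few — with
two genomes it reproduces the gold partition exactly — so the "full
mis-binning gives ARI ≈ 0" limit only emerges for communities of roughly
ten genomes or more. Second, with ~10 leaf taxa any corruption event on
the dominant taxon moves abundance metrics by large discrete jumps; the
detection-limit model concentrates corruption on rare taxa precisely so
that the corruption *rate* — not a single coin flip on the dominant
organism — determines expected metric values.

What the generator does **not** emulate: read-level sequencing error,
chimeric contigs, coverage-dependent assembly quality, and real taxonomies
with thousands of irregular lineages. Passing tests demonstrate the
correctness of the metric implementations and the discriminative power of
the ranking on controlled errors — not profiler performance on real data.

## Numerical choices and degenerate inputs

* Abundances are fractions in $[0,1]$ internally; the 0–100 percentage
  scale exists only in files. Per-rank profile sums are validated to
  $\leq 1 + 10^{-6}$.
* Undefined metrics (empty bin purity, precision with no high-fraction
  assembly, UniFrac of a zero-mass profile, presence metrics at an empty
  gold rank) raise classed errors or return `NA`; they are never silently
  0. Averaging excludes them; ranking assigns the worst score.
* The ARI denominator degenerates when a single genome meets a single
  bin; that case is a perfect match and returns 1.
* Tie-breaks (majority genomes, filter order) are lexicographic, making
  every table byte-reproducible across runs.
* Parameter-recovery simulations in the test suite use communities of 8
  genomes × 3 samples and corruption levels 0.02 / 0.15 / 0.4 / 0.8,
  with every quality dimension of a synthetic tool (including duplication
  and misassembly rates for assemblies) degrading with its level —
  "strictly increasing corruption" means the tools are ordered in every
  respect, and the chosen community size keeps 100 trials per category
  within a desktop minute.

## Limitations

Leaderboard-scale results are out of reach by design: reproducing
challenge rankings would require the original multi-hundred-gigabyte
datasets and dozens of external tools. The package reproduces the metric
*definitions* exactly and verifies them against independent oracles
(brute-force pair counting for the ARI, linear-programming transport for
UniFrac), which is the part that must be right for any such leaderboard to
mean anything.
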