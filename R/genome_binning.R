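#' Build the bp-weighted genome x bin contingency table
#'
#' Every sequence assigned by the prediction contributes its gold-standard
#' length to exactly one (genome, bin) cell. Sequences predicted but absent
#' from the gold standard are dropped with a warning; gold sequences left
#' unassigned appear only in the per-genome totals, so the binned fraction
#' and the completeness denominators see them.
#'
#' @param gold a [gold_standard()].
#' @param pred a [binning_result()] of kind `"genome"` (kind is not
#'   enforced; taxonomic labels work identically for the bookkeeping).
#' @return Object of class `contingency_table`: cell counts in bp, per-genome
#'   and per-bin totals, total binned bp and total gold bp.
#' @export
build_contingency <- function(gold, pred) {
  stopifnot(inherits(gold, "gold_standard"), inherits(pred, "binning_result"))
  g <- gold$records
  a <- pred$assignments
  hit <- match(a$seq_id, g$seq_id)
  if (all(is.na(hit)) || nrow(a) == 0L)
    stop("no overlap between predicted and gold-standard sequence IDs ",
         "(sample '", gold$sample_id, "'): nothing to evaluate", call. = FALSE)
  if (anyNA(hit))
    warning(sum(is.na(hit)), " predicted sequence(s) absent from the gold ",
            "standard were dropped", call. = FALSE)
  a <- a[!is.na(hit), , drop = FALSE]
  hit <- hit[!is.na(hit)]

  cell <- stats::aggregate(list(bp = g$length[hit]),
                           by = list(genome_id = g$genome_id[hit],
                                     bin_id = a$bin_id),
                           FUN = sum)
  cell <- cell[order(cell$genome_id, cell$bin_id), , drop = FALSE]
  rownames(cell) <- NULL
  genome_totals <- tapply(g$length, g$genome_id, sum)
  bin_totals <- tapply(cell$bp, cell$bin_id, sum)

  structure(list(counts = cell,
                 genome_totals = genome_totals[sort(names(genome_totals))],
                 bin_totals = bin_totals[sort(names(bin_totals))],
                 binned_bp = sum(cell$bp),
                 total_bp = sum(g$length)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table> ", length(x$genome_totals), " genomes x ",
      length(x$bin_totals), " bins; ",
      format(x$binned_bp, big.mark = ","), " / ",
      format(x$total_bp, big.mark = ","), " bp binned\n", sep = "")
  invisible(x)
}

# per-bin majority genome (TP_b = largest cell); ties broken by
# lexicographic genome ID so the bookkeeping is deterministic
.bin_majority <- function(t) {
  cell <- t$counts[order(t$counts$bin_id, -t$counts$bp, t$counts$genome_id), ]
  first <- !duplicated(cell$bin_id)
  data.frame(bin_id = cell$bin_id[first], genome_id = cell$genome_id[first],
             tp = cell$bp[first],
             bin_bp = unname(t$bin_totals[cell$bin_id[first]]),
             stringsAsFactors = FALSE)
}

#' Per-bin purity
#'
#' `TP_b / (TP_b + FP_b)` where `TP_b` is the bp of the most abundant genome
#' in the bin and `FP_b` the bp of all other genomes in it.
#'
#' @param t a [build_contingency()] table.
#' @param bin_id a single bin ID present in `t`.
#' @return Purity in `[0, 1]`.
#' @export
bin_purity <- function(t, bin_id) {
  maj <- .bin_majority(t)
  i <- match(as.character(bin_id), maj$bin_id)
  if (is.na(i) || maj$bin_bp[i] <= 0)
    stop("bin '", bin_id, "' is empty or absent: purity undefined")
  maj$tp[i] / maj$bin_bp[i]
}

#' Average purity over all predicted bins
#'
#' Simple (unweighted) mean of per-bin purity.
#'
#' @inheritParams bin_purity
#' @return Fraction in `[0, 1]`.
#' @export
average_purity <- function(t) {
  maj <- .bin_majority(t)
  if (nrow(maj) == 0L) stop("no bins: average purity undefined")
  mean(maj$tp / maj$bin_bp)
}

#' Average completeness over bins and unrecovered genomes
#'
#' Each bin contributes the completeness of its majority genome `g`,
#' `TP_b / total bp of g` (all gold bp of the genome, including unbinned).
#' The denominator is `|B| + |X|`, where `X` is the set of gold genomes that
#' are the majority genome of no bin, so missing entire genomes is punished.
#'
#' @inheritParams bin_purity
#' @return Fraction in `[0, 1]`.
#' @export
average_completeness <- function(t) {
  maj <- .bin_majority(t)
  if (nrow(maj) == 0L) stop("no bins: average completeness undefined")
  compl <- maj$tp / unname(t$genome_totals[maj$genome_id])
  n_missed <- length(setdiff(names(t$genome_totals), maj$genome_id))
  sum(compl) / (nrow(maj) + n_missed)
}

#' bp-weighted adjusted Rand index of the binned portion
#'
#' Treats every binned base pair as an item and compares the partition by
#' gold genome with the partition by predicted bin, using the standard
#' pair-counting closed form on the bp contingency cells. Unbinned base
#' pairs are excluded (report alongside [binned_fraction()]).
#'
#' @inheritParams bin_purity
#' @return ARI in `(-1, 1]`; 1 means the partitions agree perfectly. May be
#'   slightly negative for worse-than-chance agreement (not clamped).
#' @export
adjusted_rand_index <- function(t) {
  if (t$binned_bp < 2) stop("fewer than 2 binned bp: ARI undefined")
  ch2 <- function(n) n * (n - 1) / 2
  n <- t$binned_bp
  row_bp <- tapply(t$counts$bp, t$counts$genome_id, sum)  # binned bp per genome
  sum_cells <- sum(ch2(t$counts$bp))
  sum_rows <- sum(ch2(row_bp))
  sum_cols <- sum(ch2(t$bin_totals))
  expected <- sum_rows * sum_cols / ch2(n)
  max_index <- (sum_rows + sum_cols) / 2
  if (max_index == expected) return(1)  # single genome in a single bin
  (sum_cells - expected) / (max_index - expected)
}

#' Fraction of gold-standard base pairs that were binned
#'
#' @inheritParams bin_purity
#' @return Fraction in `[0, 1]`.
#' @export
binned_fraction <- function(t) t$binned_bp / t$total_bp

#' Count bins meeting completeness/contamination quality tiers
#'
#' A bin passes when its completeness strictly exceeds `completeness_min`
#' and its contamination (1 - purity) is strictly below `contamination_max`.
#' The conventional tiers are moderate-or-higher (`>0.5`, `<0.10`) and
#' high quality (`>0.9`, `<0.05`).
#'
#' @inheritParams bin_purity
#' @param completeness_min,contamination_max thresholds as fractions.
#' @return Integer count of passing bins.
#' @export
count_quality_bins <- function(t, completeness_min, contamination_max) {
  stopifnot(completeness_min >= 0, completeness_min <= 1,
            contamination_max >= 0, contamination_max <= 1)
  maj <- .bin_majority(t)
  if (nrow(maj) == 0L) return(0L)
  compl <- maj$tp / unname(t$genome_totals[maj$genome_id])
  contam <- 1 - maj$tp / maj$bin_bp
  sum(compl > completeness_min & contam < contamination_max)
}

#' All genome-binning metrics for one sample
#'
#' @param gold a [gold_standard()].
#' @param pred a [binning_result()].
#' @param tool label recorded in the output table.
#' @return One-row data frame: `sample`, `tool`, `average_purity`,
#'   `average_completeness`, `f1` (harmonic mean of the two averages),
#'   `ari`, `binned_fraction`, `n_moderate`, `n_high`.
#' @export
genome_binning_metrics <- function(gold, pred, tool = "tool") {
  t <- build_contingency(gold, pred)
  p <- average_purity(t)
  c_ <- average_completeness(t)
  f1 <- if (p + c_ > 0) 2 * p * c_ / (p + c_) else 0
  data.frame(sample = gold$sample_id, tool = tool,
             average_purity = p, average_completeness = c_, f1 = f1,
             ari = adjusted_rand_index(t),
             binned_fraction = binned_fraction(t),
             n_moderate = count_quality_bins(t, 0.5, 0.10),
             n_high = count_quality_bins(t, 0.9, 0.05),
             stringsAsFactors = FALSE)
}
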