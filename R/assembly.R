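#' Strain-quality thresholds for assembly evaluation
#'
#' A high-quality, strain-resolved assembly of a genome must exceed
#' `genome_fraction_min` percent genome fraction and stay below
#' `mismatch_max` mismatches. The mismatch threshold may be given per
#' 100 kb or as a percentage of aligned bases (0.5% = 500 per 100 kb);
#' it is stored per 100 kb.
#'
#' @param genome_fraction_min minimum genome fraction, percent in (0, 100].
#' @param mismatch_max maximum mismatch rate (strictly below passes).
#' @param mismatch_units `"per100kb"` or `"percent"`.
#' @return Object of class `strain_thresholds`.
#' @seealso [strain_preset()] for the named dataset presets.
#' @export
strain_thresholds <- function(genome_fraction_min, mismatch_max,
                              mismatch_units = c("per100kb", "percent")) {
  mismatch_units <- match.arg(mismatch_units)
  stopifnot(genome_fraction_min > 0, genome_fraction_min <= 100,
            mismatch_max > 0)
  if (mismatch_units == "percent") mismatch_max <- mismatch_max * 1000
  structure(list(genome_fraction_min = genome_fraction_min,
                 mismatch_max = mismatch_max),
            class = "strain_thresholds")
}

#' Named threshold presets
#'
#' `"marine"`: genome fraction > 90% and mismatches < 0.5% (500 per
#' 100 kb). `"strain-madness"`: genome fraction relaxed to > 75% with the
#' same mismatch bound, for communities where assembly quality is generally
#' lower.
#'
#' @param name preset name.
#' @return A [strain_thresholds()].
#' @export
strain_preset <- function(name = c("marine", "strain-madness")) {
  name <- match.arg(name)
  switch(name,
         "marine" = strain_thresholds(90, 0.5, "percent"),
         "strain-madness" = strain_thresholds(75, 0.5, "percent"))
}

# per-genome pass/fail against thresholds; genomes absent from the report
# count as genome fraction 0 (not recovered)
.strain_flags <- function(report, genomes, th) {
  i <- match(genomes, report$genome_id)
  gf <- ifelse(is.na(i), 0, report$genome_fraction[i])
  gf[is.na(gf)] <- 0
  mm <- report$mismatches_per_100kb[i]
  high_gf <- gf > th$genome_fraction_min
  low_mm <- !is.na(mm) & mm < th$mismatch_max
  data.frame(genome_id = genomes, high_gf = high_gf,
             pass = high_gf & low_mm, stringsAsFactors = FALSE)
}

#' Strain recall
#'
#' Fraction of all ground-truth genomes recovered as high-quality,
#' strain-resolved assemblies: genome fraction strictly above and mismatch
#' rate strictly below the thresholds. Genomes missing from the report are
#' counted as not recovered.
#'
#' @param report an [assembly_report()].
#' @param gold_genomes character vector of all ground-truth genome IDs.
#' @param th a [strain_thresholds()].
#' @return Fraction in `[0, 1]`.
#' @export
strain_recall <- function(report, gold_genomes, th) {
  stopifnot(inherits(th, "strain_thresholds"))
  gold_genomes <- unique(as.character(gold_genomes))
  if (length(gold_genomes) == 0L)
    stop("empty gold genome set: strain recall undefined")
  fl <- .strain_flags(report, gold_genomes, th)
  sum(fl$pass) / nrow(fl)
}

#' Strain precision
#'
#' Among the assemblies exceeding the genome-fraction threshold, the
#' fraction that also stay below the mismatch threshold.
#'
#' @inheritParams strain_recall
#' @return Fraction in `[0, 1]`, or `NA` (undefined, with a warning) when
#'   no assembly exceeds the genome-fraction threshold.
#' @export
strain_precision <- function(report, th) {
  stopifnot(inherits(th, "strain_thresholds"))
  fl <- .strain_flags(report, report$genome_id, th)
  if (!any(fl$high_gf)) {
    warning("no assembly above ", th$genome_fraction_min,
            "% genome fraction: strain precision undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(fl$pass) / sum(fl$high_gf)
}

#' Cross-genome assembly summary
#'
#' Per-metric means across the reported genomes. NGA50 is set to 0 for
#' genomes below 50% genome fraction (where it is undefined) before
#' averaging, so missing half a genome drags the average down instead of
#' being silently skipped; other undefined cells are excluded from their
#' means.
#'
#' @param report an [assembly_report()].
#' @return One-row data frame: `genome_fraction_mean`, `mismatches_mean`,
#'   `duplication_mean`, `nga50_mean`, `misassemblies_mean`, `n_genomes`.
#' @export
summarize_assembly <- function(report) {
  if (nrow(report) == 0L) stop("empty assembly report")
  nga <- report$nga50
  nga[is.na(nga) | is.na(report$genome_fraction) |
        report$genome_fraction < 50] <- 0
  data.frame(genome_fraction_mean = mean(report$genome_fraction, na.rm = TRUE),
             mismatches_mean = mean(report$mismatches_per_100kb, na.rm = TRUE),
             duplication_mean = mean(report$duplication_ratio, na.rm = TRUE),
             nga50_mean = mean(nga),
             misassemblies_mean = mean(report$misassemblies, na.rm = TRUE),
             n_genomes = nrow(report))
}

#' All assembly metrics for one submission
#'
#' @inheritParams strain_recall
#' @param tool,dataset labels recorded in the output table.
#' @param partition optional named character vector mapping genome IDs to
#'   partition labels (e.g. `"unique"` / `"common"` by 95% average
#'   nucleotide identity); when given, per-partition summary rows are
#'   appended (partition label in column `subset`).
#' @return Data frame with one row per genome subset: labels, the
#'   [summarize_assembly()] means, `strain_recall`, `strain_precision`.
#' @export
assembly_metrics <- function(report, gold_genomes, th = strain_preset("marine"),
                             tool = "tool", dataset = "dataset",
                             partition = NULL) {
  one <- function(rep_sub, gold_sub, label) {
    s <- if (nrow(rep_sub) > 0L) summarize_assembly(rep_sub) else
      data.frame(genome_fraction_mean = 0, mismatches_mean = NA_real_,
                 duplication_mean = NA_real_, nga50_mean = 0,
                 misassemblies_mean = NA_real_, n_genomes = 0L)
    cbind(data.frame(tool = tool, dataset = dataset, subset = label,
                     stringsAsFactors = FALSE),
          s,
          data.frame(strain_recall = strain_recall(rep_sub, gold_sub, th),
                     strain_precision = suppressWarnings(
                       strain_precision(rep_sub, th))))
  }
  out <- one(report, gold_genomes, "all")
  if (!is.null(partition)) {
    for (lab in sort(unique(unname(partition)))) {
      genomes <- names(partition)[partition == lab]
      rep_sub <- report[report$genome_id %in% genomes, , drop = FALSE]
      out <- rbind(out, one(rep_sub, intersect(gold_genomes, genomes), lab))
    }
  }
  rownames(out) <- NULL
  out
}
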