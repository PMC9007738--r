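#' Run a full category evaluation from a configuration
#'
#' Orchestrates one benchmarking category end to end: reads the gold
#' standard(s), every tool's submission(s), computes the per-sample metric
#' tables, averages them per tool, ranks the tools, and writes
#' tab-separated tables plus a structured summary to `out_dir`. Everything
#' is deterministic given the inputs.
#'
#' The configuration is a list (or a path to a YAML file) with fields:
#' \describe{
#'   \item{category}{`"genome_binning"`, `"taxonomic_binning"`,
#'     `"profiling"` or `"assembly"`.}
#'   \item{gold}{character vector of gold-standard paths (mapping files,
#'     or gold profiles for profiling; for assembly, a vector of gold
#'     genome IDs or a gold mapping path from which they are taken).}
#'   \item{predictions}{named list: tool label -> character vector of
#'     submission paths (binning/profile files matched to gold samples by
#'     their `@SampleID`; one assembly report per tool).}
#'   \item{taxonomy_dir}{directory holding nodes.dmp/names.dmp (and
#'     optionally merged.dmp); required for taxonomic binning and
#'     profiling.}
#'   \item{ranks}{optional rank subset (default: all major ranks).}
#'   \item{filter_fraction}{small-bin filter fraction (default 0.01).}
#'   \item{thresholds_preset}{assembly preset name (default `"marine"`).}
#'   \item{out_dir}{output directory; omit to skip writing.}
#'   \item{strict}{fail on unknown taxon IDs instead of dropping them.}
#' }
#'
#' @param config list or YAML file path.
#' @return Invisibly, a list: `per_sample` (metric table), `per_tool`
#'   (averaged), `ranking` ([rank_tools()] result if >= 2 tools, else
#'   `NULL`), `paths` of files written.
#' @export
run_evaluation <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  category <- match.arg(config$category,
                        c("genome_binning", "taxonomic_binning",
                          "profiling", "assembly"))
  for (p in unlist(config$predictions))
    if (!file.exists(p)) stop("submission file does not exist: ", p)

  db <- NULL
  if (category %in% c("taxonomic_binning", "profiling")) {
    if (is.null(config$taxonomy_dir))
      stop("category '", category, "' needs taxonomy_dir")
    nodes <- file.path(config$taxonomy_dir, "nodes.dmp")
    if (!file.exists(nodes)) stop("taxonomy file does not exist: ", nodes)
    names_p <- file.path(config$taxonomy_dir, "names.dmp")
    merged_p <- file.path(config$taxonomy_dir, "merged.dmp")
    db <- load_taxonomy(nodes,
                        if (file.exists(names_p)) names_p,
                        if (file.exists(merged_p)) merged_p)
  }
  ranks <- config$ranks %||% if (!is.null(db)) db$major_ranks else cami_ranks()
  strict <- isTRUE(config$strict)

  per_sample <- switch(category,
    assembly = .eval_assembly(config),
    profiling = .eval_profiling(config, db, ranks),
    .eval_binning(config, db, ranks, category, strict))

  registry <- metric_registry(category)
  per_tool <- average_over_samples(per_sample, registry)
  ranking <- if (length(unique(per_tool$tool)) >= 2L)
    rank_tools(per_tool, registry) else NULL

  paths <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, name) {
      p <- file.path(config$out_dir, name)
      utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    }
    paths <- c(w(per_sample, "metrics_per_sample.tsv"),
               w(per_tool, "metrics_per_tool.tsv"))
    if (!is.null(ranking)) {
      paths <- c(paths, w(ranking$scores, "ranking_scores.tsv"))
      summary <- list(category = category,
                      tools = ranking$totals$tool,
                      summary_statistic = ranking$totals$total)
      p <- file.path(config$out_dir, "summary.yaml")
      yaml::write_yaml(summary, p)
      paths <- c(paths, p)
    }
  }
  invisible(list(per_sample = per_sample, per_tool = per_tool,
                 ranking = ranking, paths = paths))
}

.read_golds <- function(config) {
  for (p in config$gold)
    if (!file.exists(p)) stop("gold-standard file does not exist: ", p)
  golds <- lapply(config$gold, read_gold_standard)
  stats::setNames(golds, vapply(golds, `[[`, "", "sample_id"))
}

.eval_binning <- function(config, db, ranks, category, strict) {
  golds <- .read_golds(config)
  rows <- lapply(names(config$predictions), function(tool) {
    preds <- lapply(config$predictions[[tool]], read_binning)
    do.call(rbind, lapply(preds, function(pr) {
      g <- golds[[pr$sample_id]]
      if (is.null(g))
        stop("submission sample '", pr$sample_id, "' of tool '", tool,
             "' has no matching gold standard")
      if (category == "genome_binning")
        genome_binning_metrics(g, pr, tool = tool)
      else
        taxonomic_binning_metrics(g, pr, db, ranks = ranks,
                                  filter_fraction =
                                    config$filter_fraction %||% 0.01,
                                  tool = tool, strict = strict)
    }))
  })
  do.call(rbind, rows)
}

.eval_profiling <- function(config, db, ranks) {
  golds <- list()
  for (p in config$gold) {
    if (!file.exists(p)) stop("gold profile does not exist: ", p)
    for (pr in read_profile(p)) golds[[pr$sample_id]] <- pr
  }
  rows <- lapply(names(config$predictions), function(tool) {
    preds <- unlist(lapply(config$predictions[[tool]], read_profile),
                    recursive = FALSE)
    do.call(rbind, lapply(preds, function(pr) {
      g <- golds[[pr$sample_id]]
      if (is.null(g))
        stop("submission sample '", pr$sample_id, "' of tool '", tool,
             "' has no matching gold profile")
      profiling_metrics(g, pr, db, ranks = ranks, tool = tool)
    }))
  })
  do.call(rbind, rows)
}

.eval_assembly <- function(config) {
  gold_genomes <- config$gold_genomes
  if (is.null(gold_genomes)) {
    golds <- .read_golds(config)
    gold_genomes <- unique(unlist(lapply(golds, function(g)
      g$records$genome_id)))
  }
  th <- strain_preset(config$thresholds_preset %||% "marine")
  rows <- lapply(names(config$predictions), function(tool) {
    rep <- read_assembly_report(config$predictions[[tool]][1L])
    m <- assembly_metrics(rep, gold_genomes, th, tool = tool,
                          dataset = config$dataset %||% "dataset")
    m <- m[m$subset == "all", , drop = FALSE]
    m$sample <- "all"
    m
  })
  do.call(rbind, rows)
}
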