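#' Metric registry: orientation and structure of every ranked metric
#'
#' Every metric that enters a ranking needs an orientation (whether larger
#' or smaller values are better) and a flag saying whether it is computed
#' per taxonomic rank (per-rank metrics contribute the sum of their
#' per-level placement scores).
#'
#' @param category optionally restrict to one category.
#' @return Data frame: `metric`, `orientation` (`"higher"`/`"lower"`),
#'   `category`, `per_rank`.
#' @export
metric_registry <- function(category = NULL) {
  reg <- rbind(
    data.frame(metric = c("genome_fraction_mean", "nga50_mean",
                          "strain_recall", "strain_precision"),
               orientation = "higher", category = "assembly",
               per_rank = FALSE),
    data.frame(metric = c("mismatches_mean", "misassemblies_mean",
                          "duplication_mean"),
               orientation = "lower", category = "assembly",
               per_rank = FALSE),
    data.frame(metric = c("average_purity", "average_completeness", "f1",
                          "ari", "binned_fraction", "n_moderate", "n_high"),
               orientation = "higher", category = "genome_binning",
               per_rank = FALSE),
    data.frame(metric = c("purity", "completeness", "accuracy",
                          "purity_f", "completeness_f", "accuracy_f"),
               orientation = "higher", category = "taxonomic_binning",
               per_rank = TRUE),
    data.frame(metric = c("purity", "completeness", "f1"),
               orientation = "higher", category = "profiling",
               per_rank = TRUE),
    data.frame(metric = c("l1", "bray_curtis", "shannon_error"),
               orientation = "lower", category = "profiling",
               per_rank = TRUE),
    data.frame(metric = "weighted_unifrac", orientation = "lower",
               category = "profiling", per_rank = FALSE))
  if (!is.null(category)) reg <- reg[reg$category == category, , drop = FALSE]
  rownames(reg) <- NULL
  reg
}

# wide per-sample metric table -> long (sample, tool, metric, rank, value)
.metrics_long <- function(tab, registry) {
  metrics <- intersect(registry$metric, names(tab))
  rank <- if ("rank" %in% names(tab)) tab$rank else NA_character_
  do.call(rbind, lapply(metrics, function(m) {
    per_rank <- registry$per_rank[match(m, registry$metric)]
    data.frame(sample = tab$sample %||% "sample_1",
               tool = tab$tool,
               metric = m,
               rank = if (per_rank) rank else NA_character_,
               value = as.numeric(tab[[m]]),
               stringsAsFactors = FALSE)
  }))
}

#' Average per-sample metric values per tool
#'
#' Simple mean over samples for each (tool, metric, rank); undefined
#' (`NA`) sample values are excluded from the mean, with a message counting
#' them. A tool with no defined value at all for a metric is left out of
#' that metric's table (and later scored worst by [rank_tools()]).
#'
#' @param metrics long-format data frame with columns `sample`, `tool`,
#'   `metric`, `value` and optionally `rank` (use `NA` for rank-independent
#'   metrics), as produced by the per-category `*_metrics()` functions via
#'   their `tool`/`sample` columns.
#' @param registry a [metric_registry()] used to pivot wide tables; ignored
#'   when `metrics` is already long.
#' @return Data frame `tool`, `metric`, `rank`, `value` (per-tool means).
#' @export
average_over_samples <- function(metrics, registry = metric_registry()) {
  if (!all(c("metric", "value") %in% names(metrics)))
    metrics <- .metrics_long(metrics, registry)
  if (!"rank" %in% names(metrics)) metrics$rank <- NA_character_
  n_na <- sum(is.na(metrics$value))
  if (n_na > 0L)
    message(n_na, " undefined per-sample value(s) excluded from averaging")
  def <- metrics[!is.na(metrics$value), , drop = FALSE]
  if (nrow(def) == 0L) stop("no defined metric values to average")
  key <- paste(def$tool, def$metric,
               ifelse(is.na(def$rank), "NA", def$rank), sep = "\r")
  agg <- tapply(def$value, key, mean)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(tool = vapply(parts, `[[`, "", 1L),
                    metric = vapply(parts, `[[`, "", 2L),
                    rank = vapply(parts, `[[`, "", 3L),
                    value = unname(as.numeric(agg)),
                    stringsAsFactors = FALSE)
  out$rank[out$rank == "NA"] <- NA_character_
  out[order(out$metric, out$rank, out$tool), , drop = FALSE]
}

#' Rank tools per metric and sum placement scores
#'
#' For each metric (and, for per-rank metrics, each taxonomic level) tools
#' are ordered by their averaged value, orientation-aware, and assigned
#' placement scores: 0 for first place, 1 for second, and so on; ties share
#' the better (minimum) score. Per-rank metrics contribute the sum of their
#' level scores. A tool missing a metric entirely receives the worst score
#' (number of tools - 1), with a warning. The overall summary statistic per
#' tool is the (optionally weighted) sum of its scores over all metrics.
#'
#' @param values per-tool table from [average_over_samples()].
#' @param registry a [metric_registry()]; only metrics present in both
#'   `values` and the registry are ranked.
#' @param weights optional named numeric vector of per-metric weights
#'   (default 1 for every metric).
#' @return Object of class `ranking_table`: `$scores` with one row per
#'   (tool, metric, rank) and `$totals` mapping each tool to its summary
#'   statistic, best (lowest) first.
#' @export
rank_tools <- function(values, registry = metric_registry(), weights = NULL) {
  tools <- sort(unique(values$tool))
  if (length(tools) < 2L)
    stop("ranking needs at least 2 tools, got ", length(tools))
  values <- values[values$metric %in% registry$metric, , drop = FALSE]
  worst <- length(tools) - 1L

  score_one <- function(sub) {
    o <- registry$orientation[match(sub$metric[1L], registry$metric)]
    v <- sub$value[match(tools, sub$tool)]
    v_cmp <- if (o == "lower") v else -v
    score <- vapply(seq_along(tools), function(i) {
      if (is.na(v_cmp[i])) return(worst)
      sum(v_cmp < v_cmp[i], na.rm = TRUE)  # competition rank, ties -> min
    }, 0L)
    if (anyNA(v))
      warning("tool(s) ", paste(tools[is.na(v)], collapse = ", "),
              " missing metric '", sub$metric[1L],
              "' (rank ", sub$rank[1L], "): assigned worst score",
              call. = FALSE)
    data.frame(tool = tools, metric = sub$metric[1L], rank = sub$rank[1L],
               value = v, score = score, stringsAsFactors = FALSE)
  }

  key <- paste(values$metric, values$rank, sep = "\r")
  scores <- do.call(rbind, lapply(split(values, key), score_one))
  rownames(scores) <- NULL

  w <- stats::setNames(rep(1, nrow(scores)), NULL)
  if (!is.null(weights)) {
    hit <- match(scores$metric, names(weights))
    w[!is.na(hit)] <- weights[hit[!is.na(hit)]]
  }
  totals <- tapply(scores$score * w, scores$tool, sum)
  totals <- data.frame(tool = names(totals), total = unname(as.numeric(totals)),
                       stringsAsFactors = FALSE)
  totals <- totals[order(totals$total, totals$tool), , drop = FALSE]
  rownames(totals) <- NULL
  structure(list(scores = scores, totals = totals, n_tools = length(tools)),
            class = "ranking_table")
}

#' @export
print.ranking_table <- function(x, ...) {
  cat("<ranking_table> ", x$n_tools, " tools, ",
      length(unique(paste(x$scores$metric, x$scores$rank))),
      " ranked metric(/rank) columns\n", sep = "")
  cat("summary statistic (lower is better):\n")
  print(x$totals, row.names = FALSE)
  invisible(x)
}
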