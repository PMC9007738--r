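#' Per-rank taxon confusion counts for a taxonomic binning
#'
#' Projects both gold and predicted taxon assignments onto `rank` and
#' accumulates, per predicted taxon bin `b`, the true-positive bp (gold
#' taxon equals `b`), false-positive bp (gold taxon differs) and, per gold
#' taxon, the false-negative bp. Sequences whose gold lineage has no node at
#' `rank` are excluded from the gold-standard scope (`GS` and `n`);
#' predictions that project to nothing at `rank` contribute no bin.
#'
#' @param gold a [gold_standard()] whose `taxid` column holds the true taxa.
#' @param pred a [binning_result()] of kind `"taxonomic"`.
#' @param db a [taxonomy_db()].
#' @param rank rank name, one of `db$major_ranks`.
#' @param strict if `TRUE`, unknown predicted taxon IDs are an error;
#'   otherwise they are dropped with a warning and counted in
#'   `attr(, "n_rejected")`.
#' @return Object of class `rank_confusion`: `$taxa` has one row per taxon
#'   involved at this rank with columns `taxid`, `tp`, `fp`, `fn`,
#'   `gold_bp`, `predicted`; `$gold_taxa` is `GS`, `$total_gold_bp` is `n`.
#' @export
rank_confusion <- function(gold, pred, db, rank, strict = FALSE) {
  stopifnot(inherits(gold, "gold_standard"), inherits(pred, "binning_result"),
            inherits(db, "taxonomy_db"), rank %in% db$major_ranks)
  g <- gold$records
  gold_rank <- project_to_rank(db, g$taxid, rank, on_unknown = "error")
  in_scope <- !is.na(gold_rank)

  a <- pred$assignments
  mode <- if (strict) "error" else "na"
  pred_rank_all <- project_to_rank(db, a$bin_id, rank, on_unknown = mode)
  n_rejected <- sum(is.na(resolve_taxid(db, a$bin_id, on_unknown = "na")))
  if (!strict && n_rejected > 0L)
    warning(n_rejected, " predicted taxon ID(s) not in the taxonomy were ",
            "dropped", call. = FALSE)

  hit <- match(a$seq_id, g$seq_id)
  ok <- !is.na(hit) & in_scope[ifelse(is.na(hit), 1L, hit)] &
    !is.na(pred_rank_all)
  pred_len <- g$length[hit[ok]]
  pred_taxon <- pred_rank_all[ok]
  true_taxon <- gold_rank[hit[ok]]

  gold_bp <- tapply(g$length[in_scope], gold_rank[in_scope], sum)
  gs <- sort(names(gold_bp))
  n_total <- sum(g$length[in_scope])
  if (length(gs) == 0L)
    stop("gold standard has no sequences annotated at rank '", rank, "'")

  bins <- sort(unique(pred_taxon))
  taxa <- sort(unique(c(bins, gs)))
  tp <- fp <- stats::setNames(numeric(length(taxa)), taxa)
  if (length(pred_taxon) > 0L) {
    correct <- pred_taxon == true_taxon
    tp_agg <- tapply(pred_len[correct], pred_taxon[correct], sum)
    fp_agg <- tapply(pred_len[!correct], pred_taxon[!correct], sum)
    tp[names(tp_agg)] <- tp_agg
    fp[names(fp_agg)] <- fp_agg
  }
  gbp <- stats::setNames(numeric(length(taxa)), taxa)
  gbp[gs] <- gold_bp[gs]

  out <- structure(list(rank = rank,
                        taxa = data.frame(taxid = taxa,
                                          tp = unname(tp), fp = unname(fp),
                                          fn = unname(gbp - tp),
                                          gold_bp = unname(gbp),
                                          predicted = taxa %in% bins,
                                          stringsAsFactors = FALSE),
                        gold_taxa = gs, total_gold_bp = n_total),
                   class = "rank_confusion")
  attr(out, "n_rejected") <- n_rejected
  out
}

#' @export
print.rank_confusion <- function(x, ...) {
  cat("<rank_confusion> rank=", x$rank, ": ", sum(x$taxa$predicted),
      " predicted bins, |GS|=", length(x$gold_taxa), ", n=",
      format(x$total_gold_bp, big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Average purity, average completeness and accuracy at one rank
#'
#' Average purity is the simple mean of `TP_b/(TP_b+FP_b)` over the
#' predicted bins `B` (taxa predicted but absent from the sample count as
#' bins with `TP = 0`). Average completeness sums per-bin completeness
#' `TP_b/(TP_b+FN_b)` and divides by `|GS|`, the number of gold taxa at the
#' rank. Accuracy is the correctly assigned bp over `n`, all gold bp at the
#' rank.
#'
#' @param conf a [rank_confusion()].
#' @return One-row data frame: `purity`, `completeness`, `accuracy`,
#'   `n_bins`, `n_gs_taxa`. With no predicted bins, purity is `NA`
#'   (undefined) while completeness and accuracy are 0.
#' @export
rank_metrics <- function(conf) {
  stopifnot(inherits(conf, "rank_confusion"))
  b <- conf$taxa[conf$taxa$predicted, , drop = FALSE]
  n_gs <- length(conf$gold_taxa)
  if (n_gs == 0L) stop("empty gold standard at rank '", conf$rank, "'")
  if (nrow(b) == 0L) {
    return(data.frame(purity = NA_real_, completeness = 0, accuracy = 0,
                      n_bins = 0L, n_gs_taxa = n_gs))
  }
  purity_b <- b$tp / (b$tp + b$fp)
  compl_b <- ifelse(b$gold_bp > 0, b$tp / b$gold_bp, 0)
  data.frame(purity = mean(purity_b),
             completeness = sum(compl_b) / n_gs,
             accuracy = sum(b$tp) / conf$total_gold_bp,
             n_bins = nrow(b), n_gs_taxa = n_gs)
}

#' Remove the smallest predicted bins up to a cumulative size fraction
#'
#' Sorts the predicted bins by increasing size (total predicted bp,
#' `TP_b + FP_b`) and removes the leading bins whose cumulative size is
#' smaller than or equal to `fraction` of the summed size of all bins.
#' The gold-standard scope (`GS`, `n`) is unchanged, so filtered
#' completeness and accuracy keep their denominators and can only decrease.
#'
#' @param conf a [rank_confusion()].
#' @param fraction cumulative size fraction in `[0, 1)`; the conventional
#'   post-processing value is 0.01.
#' @return A [rank_confusion()] restricted to the surviving bins.
#' @export
filter_small_bins <- function(conf, fraction = 0.01) {
  stopifnot(inherits(conf, "rank_confusion"),
            fraction >= 0, fraction < 1)
  taxa <- conf$taxa
  b <- which(taxa$predicted)
  if (length(b) == 0L || fraction == 0) return(conf)
  size <- taxa$tp[b] + taxa$fp[b]
  ord <- b[order(size, taxa$taxid[b])]
  cum <- cumsum(taxa$tp[ord] + taxa$fp[ord])
  drop <- ord[cum <= fraction * sum(size)]
  if (length(drop) > 0L) {
    # removed bins become unpredicted: their bp no longer counts toward any
    # numerator, their gold taxa (if any) stay in GS with full FN
    taxa$predicted[drop] <- FALSE
    taxa$tp[drop] <- 0
    taxa$fp[drop] <- 0
    taxa$fn[drop] <- taxa$gold_bp[drop]
    keep <- taxa$predicted | taxa$gold_bp > 0
    taxa <- taxa[keep, , drop = FALSE]
    rownames(taxa) <- NULL
  }
  out <- conf
  out$taxa <- taxa
  out
}

#' All taxonomic-binning metrics, per rank, for one sample
#'
#' @inheritParams rank_confusion
#' @param ranks ranks to evaluate (default: all major ranks present in the
#'   gold standard's lineages).
#' @param filter_fraction cumulative small-bin filter fraction for the
#'   `_f` metric variants (see [filter_small_bins()]).
#' @param tool label recorded in the output table.
#' @return Data frame with one row per rank: `sample`, `tool`, `rank`,
#'   `purity`, `completeness`, `accuracy`, `purity_f`, `completeness_f`,
#'   `accuracy_f`, `n_bins`, `n_gs_taxa`. Ranks at which the gold standard
#'   has no annotated sequence are skipped.
#' @export
taxonomic_binning_metrics <- function(gold, pred, db, ranks = db$major_ranks,
                                      filter_fraction = 0.01, tool = "tool",
                                      strict = FALSE) {
  rows <- lapply(ranks, function(r) {
    conf <- tryCatch(rank_confusion(gold, pred, db, r, strict = strict),
                     error = function(e) NULL)
    if (is.null(conf)) return(NULL)
    m <- rank_metrics(conf)
    mf <- rank_metrics(filter_small_bins(conf, filter_fraction))
    data.frame(sample = gold$sample_id, tool = tool, rank = r,
               purity = m$purity, completeness = m$completeness,
               accuracy = m$accuracy,
               purity_f = mf$purity, completeness_f = mf$completeness,
               accuracy_f = mf$accuracy,
               n_bins = m$n_bins, n_gs_taxa = m$n_gs_taxa,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
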