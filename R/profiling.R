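#' @title Taxonomic profiling metrics
#' @description Presence/absence metrics, abundance error metrics (L1 norm,
#'   Bray-Curtis) and diversity metrics (Shannon equitability, EMD-based
#'   weighted UniFrac) comparing a predicted profile against a gold
#'   standard. All abundances are fractions in `[0,1]`.
#' @name profiling_eval
NULL

# entries of a profile at one rank, keeping positive abundances only and
# summing duplicate taxids
.rank_abundances <- function(profile, rank) {
  e <- profile$entries
  e <- e[e$rank == rank & e$abundance > 0, , drop = FALSE]
  if (nrow(e) == 0L) return(stats::setNames(numeric(), character()))
  tapply(e$abundance, e$taxid, sum)
}

#' Presence/absence metrics at one rank
#'
#' Compares the sets of taxa with positive abundance, ignoring the
#' abundances themselves: purity (precision) is `TP/(TP+FP)`, completeness
#' (recall) is `TP/(TP+FN)`, and F1 their harmonic mean.
#'
#' @param gold,pred [taxon_profile()] objects.
#' @param rank rank name at which to compare.
#' @return One-row data frame `purity`, `completeness`, `f1`. An empty gold
#'   rank is an error; an empty prediction gives purity `NA` and
#'   completeness 0.
#' @export
presence_metrics <- function(gold, pred, rank) {
  gs <- names(.rank_abundances(gold, rank))
  ps <- names(.rank_abundances(pred, rank))
  if (length(gs) == 0L)
    stop("gold profile has no taxa at rank '", rank, "': presence metrics ",
         "undefined")
  tp <- length(intersect(gs, ps))
  purity <- if (length(ps) > 0L) tp / length(ps) else NA_real_
  completeness <- tp / length(gs)
  f1 <- if (!is.na(purity) && purity + completeness > 0)
    2 * purity * completeness / (purity + completeness)
  else if (is.na(purity)) NA_real_ else 0
  data.frame(purity = purity, completeness = completeness, f1 = f1)
}

#' L1 norm error between two profiles at one rank
#'
#' Total absolute abundance difference over the union of taxa at the rank;
#' a taxon absent from one profile contributes its full abundance. Ranges
#' from 0 (identical) to 2 (disjoint complete profiles).
#'
#' @inheritParams presence_metrics
#' @return Value in `[0, 2]`.
#' @export
l1_norm <- function(gold, pred, rank) {
  x <- .rank_abundances(gold, rank)
  y <- .rank_abundances(pred, rank)
  taxa <- union(names(x), names(y))
  xv <- ifelse(taxa %in% names(x), x[taxa], 0)
  yv <- ifelse(taxa %in% names(y), y[taxa], 0)
  sum(abs(xv - yv))
}

#' Bray-Curtis distance between two profiles at one rank
#'
#' The L1 norm error divided by the summed abundances of both profiles at
#' the rank. Equals half the L1 norm when both profiles account for 100%
#' of the data, and is larger when the prediction is incomplete.
#'
#' @inheritParams presence_metrics
#' @return Value in `[0, 1]`, or an error when both profiles are empty at
#'   the rank.
#' @export
bray_curtis <- function(gold, pred, rank) {
  x <- .rank_abundances(gold, rank)
  y <- .rank_abundances(pred, rank)
  denom <- sum(x) + sum(y)
  if (denom == 0)
    stop("both profiles empty at rank '", rank, "': Bray-Curtis undefined")
  l1_norm(gold, pred, rank) / denom
}

#' Shannon equitability (Pielou evenness) of a profile at one rank
#'
#' Shannon entropy of the rank's abundance distribution (renormalized to
#' sum to 1) divided by `ln(m)`, `m` the number of taxa with positive
#' abundance; defined as 0 when `m = 1`. Ranges from 0 to 1, with 1
#' indicating complete evenness.
#'
#' @param profile a [taxon_profile()].
#' @param rank rank name.
#' @return Value in `[0, 1]`.
#' @export
shannon_equitability <- function(profile, rank) {
  x <- .rank_abundances(profile, rank)
  if (length(x) == 0L)
    stop("no taxa with positive abundance at rank '", rank,
         "': equitability undefined")
  if (length(x) == 1L) return(0)
  p <- x / sum(x)
  -sum(p * log(p)) / log(length(p))
}

#' Absolute Shannon-equitability difference between prediction and gold
#'
#' @inheritParams presence_metrics
#' @return `|equitability(pred) - equitability(gold)|`.
#' @export
diversity_error <- function(gold, pred, rank) {
  abs(shannon_equitability(pred, rank) - shannon_equitability(gold, rank))
}

# Mass placement for UniFrac: each profile's mass sits at its most specific
# annotated taxon (an entry none of whose descendants is also in the
# profile), normalized to total 1. Returns named vector taxid -> mass.
.leaf_masses <- function(profile, db, renormalize = TRUE) {
  e <- profile$entries
  e <- e[e$abundance > 0, , drop = FALSE]
  if (nrow(e) == 0L) stop("profile '", profile$sample_id,
                          "' has zero total mass: UniFrac undefined")
  resolved <- resolve_taxid(db, e$taxid, on_unknown = "na")
  if (anyNA(resolved)) {
    warning(sum(is.na(resolved)), " profile tax(a) not in the taxonomy ",
            "dropped before UniFrac", call. = FALSE)
    e <- e[!is.na(resolved), , drop = FALSE]
    resolved <- resolved[!is.na(resolved)]
  }
  if (nrow(e) == 0L) stop("no profile taxa resolvable in the taxonomy")
  mass <- tapply(e$abundance, resolved, sum)
  ids <- names(mass)
  # drop taxa that have a descendant also carrying mass (cumulative profiles)
  is_internal <- rep(FALSE, length(ids))
  for (id in ids) {
    cur <- id
    while (cur != db$root) {
      cur <- unname(db$parent[cur])
      if (cur %in% ids) is_internal[match(cur, ids)] <- TRUE
    }
  }
  mass <- mass[!is_internal]
  total <- sum(mass)
  if (renormalize) mass <- mass / total
  mass
}

# depth of a taxon in the UniFrac tree: position of its rank among the
# major ranks; non-major-rank taxa sit at their deepest major-rank ancestor
.major_node <- function(db, taxid) {
  cur <- taxid
  repeat {
    r <- unname(db$rank[cur])
    i <- match(r, db$major_ranks)
    if (!is.na(i)) return(c(node = cur, depth = i))
    if (cur == db$root) return(c(node = db$root, depth = 0))
    cur <- unname(db$parent[cur])
  }
}

#' EMD-based weighted UniFrac between two profiles
#'
#' Both profiles' masses are placed on the shared taxonomic tree at their
#' most specific annotated taxa and the earth-mover's distance between the
#' two unit-mass distributions is computed on the tree spanned by the
#' major-rank ancestors of the massed nodes, with unit branch lengths: a
#' virtual root joins the superkingdoms and every edge between consecutive
#' present major-rank ancestors has length 1 (lineages missing an
#' intermediate rank are collapsed, not padded). With full eight-rank
#' lineages the worst case — all mass at species depth under different
#' superkingdoms — is 16 (eight branches up, eight down); identical
#' profiles give 0.
#'
#' @inheritParams presence_metrics
#' @param db a [taxonomy_db()].
#' @param renormalize renormalize each profile's placed mass to 1 (default);
#'   with `FALSE`, profiles must already carry total mass 1.
#' @return Value in `[0, 16]` for the default eight-rank tree.
#' @export
weighted_unifrac <- function(gold, pred, db, renormalize = TRUE) {
  m_gold <- .leaf_masses(gold, db, renormalize = renormalize)
  m_pred <- .leaf_masses(pred, db, renormalize = renormalize)
  if (!renormalize &&
      (abs(sum(m_gold) - 1) > 1e-9 || abs(sum(m_pred) - 1) > 1e-9))
    stop("profile mass does not sum to 1 and renormalize = FALSE")

  # collapse each massed taxon to its major-rank node
  place <- function(m) {
    pos <- t(vapply(names(m), function(id) .major_node(db, id),
                    c(node = "", depth = "")))
    # taxa above the highest major rank collapse onto the virtual root
    pos[, "node"] <- ifelse(pos[, "depth"] == "0", "<root>", pos[, "node"])
    out <- tapply(as.numeric(m), pos[, "node"], sum)
    depth <- as.integer(pos[match(names(out), pos[, "node"]), "depth"])
    list(mass = out, depth = stats::setNames(depth, names(out)))
  }
  pg <- place(m_gold)
  pp <- place(m_pred)

  # build the spanning tree over all major-rank ancestors of massed nodes
  nodes <- character()
  depth <- integer()
  parent <- character()
  plen <- integer()
  add_chain <- function(taxid) {
    lin <- .rank_lineage(db, taxid)
    lin <- lin[!is.na(lin)]
    ids <- unname(lin)
    dps <- match(names(lin), db$major_ranks)
    prev <- "<root>"
    prev_d <- 0L
    for (k in seq_along(ids)) {
      if (!(ids[k] %in% nodes)) {
        nodes <<- c(nodes, ids[k])
        depth <<- c(depth, dps[k])
        parent <<- c(parent, prev)
        plen <<- c(plen, 1L)  # unit branch length per present edge
      }
      prev <- ids[k]
      prev_d <- dps[k]
    }
  }
  for (id in unique(c(names(pg$mass), names(pp$mass)))) add_chain(id)

  net <- stats::setNames(numeric(length(nodes) + 1L), c(nodes, "<root>"))
  net[names(pg$mass)] <- net[names(pg$mass)] + as.numeric(pg$mass)
  net[names(pp$mass)] <- net[names(pp$mass)] - as.numeric(pp$mass)

  emd <- 0
  for (i in order(depth, decreasing = TRUE)) {
    emd <- emd + abs(net[[nodes[i]]]) * plen[i]
    net[[parent[i]]] <- net[[parent[i]]] + net[[nodes[i]]]
  }
  unname(emd)
}

#' All profiling metrics for one sample
#'
#' @inheritParams weighted_unifrac
#' @param ranks ranks at which the per-rank metrics are computed (ranks
#'   where the gold profile is empty are skipped).
#' @param tool label recorded in the output table.
#' @return Data frame, one row per evaluated rank: `sample`, `tool`,
#'   `rank`, `purity`, `completeness`, `f1`, `l1`, `bray_curtis`,
#'   `shannon_error`, plus the rank-independent `weighted_unifrac` repeated
#'   on every row.
#' @export
profiling_metrics <- function(gold, pred, db, ranks = db$major_ranks,
                              tool = "tool") {
  uf <- tryCatch(weighted_unifrac(gold, pred, db),
                 error = function(e) NA_real_)
  rows <- lapply(ranks, function(r) {
    if (length(.rank_abundances(gold, r)) == 0L) return(NULL)
    pm <- presence_metrics(gold, pred, r)
    sh <- tryCatch(diversity_error(gold, pred, r),
                   error = function(e) NA_real_)
    data.frame(sample = gold$sample_id, tool = tool, rank = r,
               purity = pm$purity, completeness = pm$completeness,
               f1 = pm$f1,
               l1 = l1_norm(gold, pred, r),
               bray_curtis = tryCatch(bray_curtis(gold, pred, r),
                                      error = function(e) NA_real_),
               shannon_error = sh,
               weighted_unifrac = uf,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
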