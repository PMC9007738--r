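# Shared fixtures and independent oracles used across the test files.

# toy taxonomy: two superkingdoms, each a full 8-rank lineage to one species
two_kingdom_db <- function() {
  ranks <- cami_ranks()
  ids <- c("1", paste0("L", 1:8), paste0("R", 1:8))
  parents <- c("1", "1", paste0("L", 1:7), "1", paste0("R", 1:7))
  taxonomy_db(ids, parents, c("no rank", ranks, ranks))
}

# the worked genome-binning example: gold A:100, B:100, C:50 bp;
# bin1 = {A:80, B:20}, bin2 = {B:60}; 90 bp unassigned
worked_binning_example <- function() {
  gold <- gold_standard("s1", paste0("x", 1:6),
                        c("A", "B", "B", "B", "C", "A"), "1",
                        c(80, 20, 60, 20, 50, 20))
  pred <- binning_result("s1", paste0("x", 1:3), c("bin1", "bin1", "bin2"),
                         kind = "genome")
  list(gold = gold, pred = pred)
}

# brute-force pair-counting ARI over individual base pairs; independent of
# the closed-form implementation
oracle_ari <- function(cells) {
  g <- rep(cells$genome_id, cells$bp)
  b <- rep(cells$bin_id, cells$bp)
  n <- length(g)
  ut <- upper.tri(matrix(0, n, n))
  same_g <- outer(g, g, "==")[ut]
  same_b <- outer(b, b, "==")[ut]
  a <- sum(same_g & same_b)          # pairs together in both partitions
  sum_rows <- sum(same_g)
  sum_cols <- sum(same_b)
  n2 <- n * (n - 1) / 2
  expected <- sum_rows * sum_cols / n2
  max_index <- (sum_rows + sum_cols) / 2
  if (max_index == expected) return(1)
  (a - expected) / (max_index - expected)
}

# random bp contingency structure as (gold, pred) with one sequence per
# cell, total bp <= max_bp
random_binning_case <- function(seed, max_bp = 300) {
  set.seed(seed)
  n_genomes <- sample(2:4, 1)
  n_bins <- sample(2:4, 1)
  cells <- expand.grid(genome_id = paste0("g", seq_len(n_genomes)),
                       bin_id = paste0("b", seq_len(n_bins)),
                       stringsAsFactors = FALSE)
  cells <- cells[sample(nrow(cells), sample(2:nrow(cells), 1)), ]
  cells$bp <- sample(1:25, nrow(cells), replace = TRUE)
  while (sum(cells$bp) > max_bp) cells$bp <- pmax(1, cells$bp - 5)
  cells$seq_id <- paste0("q", seq_len(nrow(cells)))
  gold <- gold_standard("s", cells$seq_id, cells$genome_id, "1", cells$bp)
  pred <- binning_result("s", cells$seq_id, cells$bin_id, kind = "genome")
  list(gold = gold, pred = pred, cells = cells)
}

# unit-branch tree distance between two taxa: count present major-rank
# ancestor steps up to the lowest common ancestor (virtual root included)
oracle_tree_distance <- function(db, a, b) {
  chain <- function(id) {
    out <- character()
    cur <- id
    repeat {
      if (unname(db$rank[cur]) %in% db$major_ranks) out <- c(cur, out)
      if (cur == db$root) break
      cur <- unname(db$parent[cur])
    }
    c("<root>", out)
  }
  ca <- chain(a)
  cb <- chain(b)
  k <- 0L
  while (k < min(length(ca), length(cb)) && ca[k + 1L] == cb[k + 1L])
    k <- k + 1L
  (length(ca) - k) + (length(cb) - k)
}

# exact EMD between two mass assignments via the transportation LP
# (boot::simplex), with costs from oracle_tree_distance; independent of the
# tree-traversal algorithm in weighted_unifrac
oracle_emd_lp <- function(db, mass_a, mass_b) {
  src <- names(mass_a)
  dst <- names(mass_b)
  cost <- outer(src, dst, Vectorize(function(i, j)
    oracle_tree_distance(db, i, j)))
  nv <- length(src) * length(dst)
  A1 <- t(vapply(seq_along(src), function(i) {
    m <- matrix(0, length(src), length(dst)); m[i, ] <- 1; as.vector(t(m))
  }, numeric(nv)))
  A2 <- t(vapply(seq_along(dst), function(j) {
    m <- matrix(0, length(src), length(dst)); m[, j] <- 1; as.vector(t(m))
  }, numeric(nv)))
  s <- boot::simplex(a = as.vector(t(cost)), A1 = A1, b1 = as.numeric(mass_a),
                     A2 = A2, b2 = as.numeric(mass_b), maxi = FALSE)
  unname(s$value)
}

# random taxonomy whose nodes all sit at major ranks, plus two random
# unit-mass profiles on its leaves
random_unifrac_case <- function(seed, max_nodes = 30) {
  set.seed(seed)
  ranks <- cami_ranks()
  n <- sample(5:max_nodes, 1)
  taxid <- "1"; parent <- "1"; rank_v <- "no rank"
  depth <- c(`1` = 0L)
  for (i in 2:n) {
    cand <- names(depth)[depth < 8L]
    p <- cand[sample.int(length(cand), 1L)]
    d <- depth[[p]] + sample.int(8L - depth[[p]], 1L)
    id <- as.character(i)
    taxid <- c(taxid, id); parent <- c(parent, p); rank_v <- c(rank_v, ranks[d])
    depth[[id]] <- d
  }
  db <- taxonomy_db(taxid, parent, rank_v)
  leaves <- setdiff(taxid, parent)
  rand_profile <- function(sid) {
    k <- sample.int(length(leaves), sample.int(min(6L, length(leaves)), 1L))
    m <- stats::runif(length(k)) + 0.05
    m <- m / sum(m)
    taxon_profile(sid, leaves[k], unname(db$rank[leaves[k]]), m)
  }
  list(db = db, p1 = rand_profile("a"), p2 = rand_profile("b"),
       leaves = leaves)
}

# leaf mass assignment of a profile (for feeding the LP oracle): every
# entry is already most specific in profiles from random_unifrac_case
profile_masses <- function(p) {
  stats::setNames(p$entries$abundance, p$entries$taxid)
}

write_toy_nodes <- function(lines) {
  path <- tempfile(fileext = ".dmp")
  writeLines(lines, path)
  path
}
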