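# taxonomy with one shared lineage down to family, three genera below it
three_genus_db <- function() {
  ranks <- cami_ranks()
  ids <- c("1", paste0("A", 1:6), "g1", "g2", "g3")
  taxonomy_db(ids, c("1", "1", paste0("A", 1:5), "A6", "A6", "A6"),
              c("no rank", ranks[1:6], "genus", "genus", "genus"))
}

test_that("the worked per-rank confusion yields the textbook metrics", {
  db <- three_genus_db()
  # gold: taxon g1 100 bp, g2 100 bp; 90 bp -> g1 correct, 10 bp of g2 -> g1,
  # 50 bp -> g2 correct, 50 bp unassigned
  gold <- gold_standard("s1", paste0("x", 1:5),
                        c("G1", "G2", "G2", "G2", "G1"),
                        c("g1", "g2", "g2", "g2", "g1"),
                        c(90, 10, 50, 40, 10))
  pred <- binning_result("s1", paste0("x", 1:3), c("g1", "g1", "g2"),
                         kind = "taxonomic")
  conf <- rank_confusion(gold, pred, db, "genus")
  taxa <- conf$taxa[conf$taxa$predicted, ]
  expect_equal(taxa$tp[taxa$taxid == "g1"], 90)
  expect_equal(taxa$fp[taxa$taxid == "g1"], 10)
  expect_equal(taxa$tp[taxa$taxid == "g2"], 50)
  expect_equal(taxa$fp[taxa$taxid == "g2"], 0)
  m <- rank_metrics(conf)
  expect_equal(m$purity, 0.95)
  expect_equal(m$completeness, 0.7)
  expect_equal(m$accuracy, 0.7)
})

test_that("deeper predictions aggregate up to the evaluated rank", {
  bundle <- generate_gold(community_spec(n_genomes = 6, n_samples = 1,
                                         n_common_pairs = 1, seed = 9))
  g <- bundle$gold[[1]]
  pred <- corrupt_binning(g, 0, 0, seed = 1, kind = "taxonomic",
                          genome_taxid = bundle$genome_taxid)
  for (r in c("genus", "phylum", "superkingdom")) {
    m <- rank_metrics(rank_confusion(g, pred, bundle$taxonomy, r))
    expect_equal(m$purity, 1)
    expect_equal(m$completeness, 1)
    expect_equal(m$accuracy, 1)
  }
})

test_that("metrics at a rank ignore relabeling below that rank", {
  bundle <- generate_gold(community_spec(n_genomes = 6, n_samples = 1,
                                         n_common_pairs = 2, seed = 13))
  g <- bundle$gold[[1]]
  db <- bundle$taxonomy
  pred <- corrupt_binning(g, 0.3, 0.1, seed = 2, kind = "taxonomic",
                          genome_taxid = bundle$genome_taxid)
  base <- rank_metrics(rank_confusion(g, pred, db, "genus"))
  # swap labels within each species (strain-level relabeling)
  relab <- pred
  species <- project_to_rank(db, relab$assignments$bin_id, "species")
  relab$assignments$bin_id <- species  # collapse below-species structure
  after <- rank_metrics(rank_confusion(g, relab, db, "genus"))
  expect_equal(after, base)
})

test_that("the cumulative 1% filter removes exactly the worked bins", {
  db <- three_genus_db()
  gold <- gold_standard("s1", paste0("y", 1:3), c("GA", "GB", "GC"),
                        c("g1", "g2", "g3"), c(1, 1, 98))
  pred <- binning_result("s1", paste0("y", 1:3), c("g1", "g2", "g3"),
                         kind = "taxonomic")
  conf <- rank_confusion(gold, pred, db, "genus")
  filt <- filter_small_bins(conf, 0.01)
  # sizes [1,1,98]: cum 1 <= 1 -> dropped, cum 2 > 1 -> kept
  expect_equal(sum(filt$taxa$predicted), 2L)
  expect_identical(filter_small_bins(conf, 0), conf)       # fraction 0
  # a single bin is never removed (its cumulative sum is 100%)
  solo <- rank_confusion(gold_standard("s", "z", "G", "g1", 10),
                         binning_result("s", "z", "g1", "taxonomic"),
                         db, "genus")
  expect_equal(sum(filter_small_bins(solo, 0.01)$taxa$predicted), 1L)
  # GS and n are unchanged by filtering
  expect_identical(filt$gold_taxa, conf$gold_taxa)
  expect_equal(filt$total_gold_bp, conf$total_gold_bp)
})

test_that("filtered completeness and accuracy never exceed the unfiltered", {
  for (seed in 1:8) {
    bundle <- generate_gold(community_spec(n_genomes = 7, n_samples = 1,
                                           seed = seed))
    g <- bundle$gold[[1]]
    pred <- corrupt_binning(g, 0.4, 0.2, seed = seed, kind = "taxonomic",
                            genome_taxid = bundle$genome_taxid)
    for (r in c("species", "genus", "phylum")) {
      conf <- rank_confusion(g, pred, bundle$taxonomy, r)
      m <- rank_metrics(conf)
      mf <- rank_metrics(filter_small_bins(conf, 0.05))
      expect_lte(mf$completeness, m$completeness + 1e-12)
      expect_lte(mf$accuracy, m$accuracy + 1e-12)
      expect_lte(mf$n_bins, m$n_bins)
    }
  }
})

test_that("degenerate predictions give undefined purity, zero recovery", {
  db <- three_genus_db()
  gold <- gold_standard("s", "x", "G", "g1", 100)
  none <- binning_result("s", "x", "A3", kind = "taxonomic")  # above genus
  m <- rank_metrics(rank_confusion(gold, none, db, "genus"))
  expect_true(is.na(m$purity))
  expect_equal(m$completeness, 0)
  expect_equal(m$accuracy, 0)
})

test_that("unknown predicted taxa are dropped (or fatal in strict mode)", {
  db <- three_genus_db()
  gold <- gold_standard("s", c("x", "y"), "G", c("g1", "g1"), c(60, 40))
  pred <- binning_result("s", c("x", "y"), c("g1", "424242"), "taxonomic")
  expect_warning(conf <- rank_confusion(gold, pred, db, "genus"), "dropped")
  expect_equal(attr(conf, "n_rejected"), 1L)
  expect_equal(conf$taxa$tp[conf$taxa$taxid == "g1"], 60)
  expect_error(suppressWarnings(rank_confusion(gold, pred, db, "genus",
                                               strict = TRUE)),
               "unknown taxon")
})

test_that("per-sample table covers requested ranks with filtered variants", {
  bundle <- generate_gold(community_spec(n_genomes = 6, n_samples = 1,
                                         seed = 21))
  g <- bundle$gold[[1]]
  pred <- corrupt_binning(g, 0.2, 0.1, seed = 3, kind = "taxonomic",
                          genome_taxid = bundle$genome_taxid)
  tab <- taxonomic_binning_metrics(g, pred, bundle$taxonomy, tool = "t1")
  expect_setequal(tab$rank, cami_ranks())
  expect_true(all(c("purity_f", "completeness_f", "accuracy_f") %in%
                    names(tab)))
  expect_true(all(tab$completeness_f <= tab$completeness + 1e-12))
})
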