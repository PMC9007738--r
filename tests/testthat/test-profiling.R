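test_that("presence metrics count detected taxa, not abundances", {
  g <- taxon_profile("s", c("A", "B", "C"), "genus", c(0.5, 0.3, 0.2))
  p <- taxon_profile("s", c("A", "B", "D"), "genus", c(0.1, 0.1, 0.8))
  m <- presence_metrics(g, p, "genus")
  expect_equal(unlist(m), c(purity = 2 / 3, completeness = 2 / 3, f1 = 2 / 3))
  expect_equal(unlist(presence_metrics(g, g, "genus")),
               c(purity = 1, completeness = 1, f1 = 1))
  disj <- taxon_profile("s", c("X", "Y"), "genus", c(0.5, 0.5))
  m0 <- presence_metrics(g, disj, "genus")
  expect_equal(unlist(m0), c(purity = 0, completeness = 0, f1 = 0))
  expect_error(presence_metrics(disj, g, "family"), "no taxa")
})

test_that("L1 norm attains its bounds and sums over the taxon union", {
  g <- taxon_profile("s", c("a", "b"), "phylum", c(0.7, 0.3))
  p <- taxon_profile("s", c("a", "b"), "phylum", c(0.5, 0.5))
  expect_equal(l1_norm(g, p, "phylum"), 0.4)
  expect_equal(l1_norm(g, g, "phylum"), 0)
  disj <- taxon_profile("s", c("c", "d"), "phylum", c(0.6, 0.4))
  expect_equal(l1_norm(g, disj, "phylum"), 2)  # disjoint complete profiles
})

test_that("Bray-Curtis halves the L1 for complete predictions, exceeds it otherwise", {
  g <- taxon_profile("s", c("a", "b"), "phylum", c(0.5, 0.5))
  disj <- taxon_profile("s", c("c", "d"), "phylum", c(0.5, 0.5))
  expect_equal(bray_curtis(g, disj, "phylum"), 1)
  expect_equal(bray_curtis(g, g, "phylum"), 0)
  # prediction covering 50% of the data, same composition
  half <- taxon_profile("s", c("a", "b"), "phylum", c(0.25, 0.25))
  expect_equal(l1_norm(g, half, "phylum"), 0.5)
  expect_equal(bray_curtis(g, half, "phylum"), 0.5 / 1.5)
  expect_gt(bray_curtis(g, half, "phylum"), l1_norm(g, half, "phylum") / 2)
  # equality whenever both profiles sum to 1
  for (seed in 1:5) {
    set.seed(seed)
    x <- stats::runif(4); x <- x / sum(x)
    y <- stats::runif(4); y <- y / sum(y)
    a <- taxon_profile("s", paste0("t", 1:4), "genus", x)
    b <- taxon_profile("s", paste0("t", 1:4), "genus", y)
    expect_equal(bray_curtis(a, b, "genus"), l1_norm(a, b, "genus") / 2,
                 tolerance = 1e-12)
  }
})

test_that("Shannon equitability is 1 when even, 0 for a single taxon", {
  even <- taxon_profile("s", paste0("t", 1:10), "genus", rep(0.1, 10))
  expect_equal(shannon_equitability(even, "genus"), 1)
  solo <- taxon_profile("s", "t1", "genus", 1)
  expect_equal(shannon_equitability(solo, "genus"), 0)
  skew <- taxon_profile("s", c("a", "b", "c"), "genus", c(0.5, 0.25, 0.25))
  expect_equal(shannon_equitability(skew, "genus"), 0.9463946,
               tolerance = 1e-6)
  expect_equal(diversity_error(skew, skew, "genus"), 0)
  u3 <- taxon_profile("s", c("a", "b", "c"), "genus", rep(1, 3) / 3)
  expect_equal(diversity_error(skew, u3, "genus"), 1 - 0.9463946,
               tolerance = 1e-6)
  expect_equal(diversity_error(even,
                               taxon_profile("s", "t1", "genus", 1), "genus"),
               1)
})

test_that("weighted UniFrac spans its 0-16 range on the two-kingdom tree", {
  db <- two_kingdom_db()
  a <- taxon_profile("s", "L8", "species", 1)
  b <- taxon_profile("s", "R8", "species", 1)
  expect_equal(weighted_unifrac(a, b, db), 16)
  expect_equal(weighted_unifrac(a, a, db), 0)
  # sibling phyla under one superkingdom: up one branch, down one
  db2 <- taxonomy_db(c("1", "sk", "p1", "p2"), c("1", "1", "sk", "sk"),
                     c("no rank", "superkingdom", "phylum", "phylum"))
  expect_equal(weighted_unifrac(taxon_profile("s", "p1", "phylum", 1),
                                taxon_profile("s", "p2", "phylum", 1), db2),
               2)
})

test_that("UniFrac places mass at the most specific node of cumulative profiles", {
  db <- two_kingdom_db()
  # cumulative profile: every rank annotated, all mass in one lineage
  full_a <- taxon_profile("s", paste0("L", 1:8), cami_ranks(), rep(1, 8))
  full_b <- taxon_profile("s", paste0("R", 1:8), cami_ranks(), rep(1, 8))
  expect_equal(weighted_unifrac(full_a, full_b, db), 16)
  expect_equal(weighted_unifrac(full_a, full_a, db), 0)
  # unresolvable taxa are dropped with renormalization
  with_junk <- taxon_profile("s", c("L8", "zz"), "species", c(0.5, 0.5))
  expect_warning(u <- weighted_unifrac(with_junk, full_a, db), "dropped")
  expect_equal(u, 0)
})

test_that("UniFrac is a symmetric metric agreeing with the LP transport oracle", {
  for (seed in 1:12) {
    case <- random_unifrac_case(seed)
    u12 <- weighted_unifrac(case$p1, case$p2, case$db)
    expect_equal(u12, weighted_unifrac(case$p2, case$p1, case$db),
                 tolerance = 1e-12)
    expect_equal(u12, oracle_emd_lp(case$db, profile_masses(case$p1),
                                    profile_masses(case$p2)),
                 tolerance = 1e-6, info = paste("seed", seed))
  }
})

test_that("UniFrac satisfies the triangle inequality and zero-iff-equal", {
  for (seed in 1:8) {
    case <- random_unifrac_case(seed + 50)
    set.seed(seed + 999)
    k <- sample.int(length(case$leaves), 1)
    m3 <- stats::runif(k) + 0.05
    p3 <- taxon_profile("c", case$leaves[seq_len(k)],
                        unname(case$db$rank[case$leaves[seq_len(k)]]),
                        m3 / sum(m3))
    u12 <- weighted_unifrac(case$p1, case$p2, case$db)
    u13 <- weighted_unifrac(case$p1, p3, case$db)
    u23 <- weighted_unifrac(p3, case$p2, case$db)
    expect_lte(u12, u13 + u23 + 1e-9)
    expect_equal(weighted_unifrac(case$p1, case$p1, case$db), 0)
    if (u12 > 1e-9) {
      # differing mass assignments must not collapse to zero
      expect_false(identical(profile_masses(case$p1),
                             profile_masses(case$p2)))
    }
  }
})

test_that("profiling metrics are invariant to entry order", {
  bundle <- generate_gold(community_spec(n_genomes = 6, n_samples = 1,
                                         seed = 31))
  g <- bundle$profiles[[1]]
  p <- corrupt_profile(g, bundle$taxonomy, concentration = 20,
                       drop_rate = 0.2, relabel_rate = 0.2, seed = 4)
  shuffle <- function(pr) {
    pr$entries <- pr$entries[rev(seq_len(nrow(pr$entries))), ]
    rownames(pr$entries) <- NULL
    pr
  }
  m1 <- profiling_metrics(g, p, bundle$taxonomy, tool = "t")
  m2 <- profiling_metrics(shuffle(g), shuffle(p), bundle$taxonomy, tool = "t")
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("zero-mass profiles make UniFrac undefined", {
  db <- two_kingdom_db()
  empty <- taxon_profile("s", character(), character(), numeric())
  full <- taxon_profile("s", "L8", "species", 1)
  expect_error(weighted_unifrac(empty, full, db), "zero total mass")
})
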