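test_that("the generator is deterministic and internally consistent", {
  spec <- community_spec(n_genomes = 7, n_samples = 2, n_common_pairs = 1,
                         seed = 7)
  b1 <- generate_gold(spec)
  b2 <- generate_gold(spec)
  expect_identical(b1$gold[[1]]$records, b2$gold[[1]]$records)
  expect_identical(b1$profiles[[2]]$entries, b2$profiles[[2]]$entries)
  # per-rank gold profile sums are exactly 1
  for (p in b1$profiles) {
    sums <- tapply(p$entries$abundance, p$entries$rank, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
  # paired strains collapse under shared species; decoys add taxonomy-only
  # species that never carry community genomes
  expect_equal(sum(b1$taxonomy$rank == "species"),
               7 - 1 + spec$decoy_species)
  expect_equal(sum(b1$taxonomy$rank == "strain"), 2)
  expect_false(any(b1$genome_taxid %in%
                     names(b1$taxonomy$rank)[grepl("decoy",
                                                   b1$taxonomy$name)]))
  # profile abundances equal bp-weighted genome shares projected per rank
  g <- b1$gold[[1]]$records
  sk_share <- tapply(g$length, project_to_rank(b1$taxonomy, g$taxid,
                                               "superkingdom"), sum)
  sk_share <- sk_share / sum(sk_share)
  e <- b1$profiles[[1]]$entries
  prof_sk <- stats::setNames(e$abundance, e$taxid)[names(sk_share)]
  expect_equal(unname(prof_sk), unname(as.numeric(sk_share)),
               tolerance = 1e-12)
  expect_error(community_spec(n_genomes = 0), "n_genomes")
})

test_that("uncorrupted predictions reproduce the gold standard exactly", {
  bundle <- generate_gold(community_spec(n_genomes = 6, seed = 19))
  g <- bundle$gold[[1]]
  pb <- corrupt_binning(g, 0, 0, seed = 1)
  expect_identical(pb$assignments$bin_id, g$records$genome_id)
  m <- genome_binning_metrics(g, pb)
  expect_equal(m$ari, 1)
  expect_equal(m$binned_fraction, 1)
  pp <- corrupt_profile(bundle$profiles[[1]], bundle$taxonomy,
                        concentration = Inf, seed = 1)
  expect_equal(l1_norm(bundle$profiles[[1]], pp, "species"), 0)
  expect_equal(weighted_unifrac(bundle$profiles[[1]], pp, bundle$taxonomy), 0)
})

test_that("unassignment thins binned bp at its nominal rate", {
  spec <- community_spec(n_genomes = 6, n_samples = 1, seed = 3)
  bundle <- generate_gold(spec)
  g <- bundle$gold[[1]]
  bf <- vapply(1:20, function(s) {
    pred <- corrupt_binning(g, 0, 0.5, seed = s)
    binned_fraction(build_contingency(g, pred))
  }, 0)
  expect_equal(mean(bf), 0.5, tolerance = 0.1)
})

test_that("full mis-binning drives the expected ARI toward zero", {
  # forced-wrong reassignment keeps a small positive chance association
  # when labels are few (with 2 genomes it even reproduces the gold
  # partition), so the near-zero limit needs a reasonably sized community
  spec <- community_spec(n_genomes = 10, n_samples = 1, seed = 17)
  bundle <- generate_gold(spec)
  g <- bundle$gold[[1]]
  ari <- vapply(1:20, function(s)
    adjusted_rand_index(build_contingency(g, corrupt_binning(g, 1, 0,
                                                             seed = s))), 0)
  expect_lt(abs(mean(ari)), 0.1)
  expect_lt(mean(ari),
            mean(vapply(1:20, function(s)
              adjusted_rand_index(build_contingency(
                g, corrupt_binning(g, 0.5, 0, seed = s))), 0)))
})

test_that("metric degradation is monotone in the corruption rate", {
  spec <- community_spec(n_genomes = 6, n_samples = 1, seed = 23)
  bundle <- generate_gold(spec)
  g <- bundle$gold[[1]]
  mean_ari <- vapply(c(0, 0.25, 0.6), function(rate) {
    mean(vapply(1:20, function(s)
      adjusted_rand_index(build_contingency(
        g, corrupt_binning(g, rate, 0, seed = 100 + s))), 0))
  }, 0)
  expect_true(all(diff(mean_ari) < 0))
})

test_that("profile corruption responds to its parameters as designed", {
  spec <- community_spec(n_genomes = 6, n_samples = 1, seed = 29)
  bundle <- generate_gold(spec)
  gp <- bundle$profiles[[1]]
  db <- bundle$taxonomy
  # drop_rate 1 removes every taxon: completeness 0 at species rank
  dropped <- corrupt_profile(gp, db, drop_rate = 1, seed = 1)
  expect_equal(nrow(dropped$entries), 0L)
  m <- presence_metrics(gp, dropped, "species")
  expect_equal(m$completeness, 0)
  # L1 decreases in expectation as concentration grows
  l1_at <- function(conc) mean(vapply(1:20, function(s)
    l1_norm(gp, corrupt_profile(gp, db, concentration = conc, seed = s),
            "species"), 0))
  expect_gt(l1_at(2), l1_at(200))
  # relabeling moves mass to wrong species: in a complete community that
  # shows up as lost taxa and abundance error, not as false positives
  relab <- corrupt_profile(gp, db, relabel_rate = 0.9, seed = 5)
  expect_lt(presence_metrics(gp, relab, "species")$completeness, 1)
  expect_gt(l1_norm(gp, relab, "species"), 0)
})

test_that("synthetic assembly reports are seeded and subsettable", {
  ids <- sprintf("g%02d", 1:10)
  r1 <- generate_assembly_report(ids, seed = 4)
  r2 <- generate_assembly_report(ids, seed = 4)
  expect_identical(r1, r2)
  half <- generate_assembly_report(ids, omit_fraction = 0.5, seed = 4)
  expect_lt(nrow(half), 10L)
  th <- strain_preset("marine")
  perfect <- assembly_report(ids, 100, 1e-9)
  expect_equal(strain_recall(perfect, ids, th), 1)
  expect_lte(strain_recall(half, ids, th), nrow(half) / 10)
})
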