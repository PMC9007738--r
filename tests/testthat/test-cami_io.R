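test_that("binning files parse, infer kind, and apply first-wins on duplicates", {
  p <- tempfile()
  writeLines(c("@Version:0.9.0", "@SampleID:s1", "@@SEQUENCEID\tBINID",
               "s1\tbinA", "s2\tbinA", "s3\tbinB"), p)
  b <- read_binning(p)
  expect_identical(b$kind, "genome")
  expect_identical(b$sample_id, "s1")
  expect_equal(nrow(b$assignments), 3L)
  expect_length(unique(b$assignments$bin_id), 2L)

  writeLines(c("@SampleID:s1", "@@SEQUENCEID\tBINID",
               "s1\tbinA", "s1\tbinB"), p)
  expect_warning(b2 <- read_binning(p), "duplicate")
  expect_equal(nrow(b2$assignments), 1L)
  expect_identical(b2$assignments$bin_id, "binA")

  writeLines(c("@SampleID:s1", "s1\tbinA"), p)
  expect_error(read_binning(p), "@@")

  writeLines(c("@@SEQUENCEID\tTAXID", "s1\t123"), p)
  expect_identical(read_binning(p)$kind, "taxonomic")

  writeLines(c("@@SEQUENCEID\tBINID", "s1\tbinA\textra"), p)
  expect_error(read_binning(p), "columns")
})

test_that("binning round-trips through write_binning", {
  b <- binning_result("sX", c("s1", "s2", "s3"), c("binA", "binA", "binB"),
                      kind = "genome")
  p <- tempfile()
  write_binning(b, p)
  b2 <- read_binning(p)
  expect_identical(b2$assignments, b$assignments)
  expect_identical(b2$sample_id, "sX")
  # empty result still yields a valid header-only file
  e <- binning_result("sY", character(), character(), kind = "taxonomic")
  write_binning(e, p)
  expect_equal(nrow(read_binning(p)$assignments), 0L)
})

test_that("profiles convert percentages to fractions, split sample blocks", {
  p <- tempfile()
  writeLines(c("@SampleID:sA", "@Version:0.9.1",
               "@Ranks:superkingdom|phylum",
               "@@TAXID\tRANK\tTAXPATH\tTAXPATHSN\tPERCENTAGE",
               "2\tphylum\t1|2\tr|p\t60",
               "3\tphylum\t1|3\tr|q\t40",
               "@SampleID:sB",
               "@@TAXID\tRANK\tTAXPATH\tTAXPATHSN\tPERCENTAGE",
               "2\tphylum\t1|2\tr|p\t100"), p)
  prof <- read_profile(p)
  expect_length(prof, 2L)
  expect_equal(sort(prof[[1]]$entries$abundance), c(0.4, 0.6))
  expect_identical(prof[[2]]$sample_id, "sB")

  writeLines(c("@SampleID:sA",
               "@@TAXID\tRANK\tTAXPATH\tTAXPATHSN\tPERCENTAGE",
               "2\tphylum\t1|2\tr|p\t-5"), p)
  expect_error(read_profile(p), "negative")

  writeLines(c("@SampleID:sA",
               "@@TAXID\tRANK\tTAXPATH\tTAXPATHSN\tPERCENTAGE",
               "2\tmorph\t1|2\tr|p\t50"), p)
  expect_warning(read_profile(p, rank_vocabulary = cami_ranks()), "morph")
})

test_that("profiles round-trip with >= 6 significant digits", {
  pr <- taxon_profile("sZ", c("2", "3"), "phylum", c(0.6, 0.4),
                      taxpath = c("1|2", "1|3"))
  p <- tempfile()
  write_profile(pr, p)
  back <- read_profile(p)[[1]]
  expect_equal(back$entries$abundance, pr$entries$abundance, tolerance = 1e-9)
  expect_identical(back$entries$taxid, pr$entries$taxid)
  # odd fractions survive the percentage scale
  pr2 <- taxon_profile("sW", c("2", "3", "4"), "genus", c(1, 1, 1) / 3)
  write_profile(pr2, p)
  expect_equal(read_profile(p)[[1]]$entries$abundance, pr2$entries$abundance,
               tolerance = 1e-9)
})

test_that("gold standards validate and round-trip", {
  g <- gold_standard("s1", c("a", "b"), c("G1", "G2"), c("5", "6"), c(10, 20))
  p <- tempfile()
  write_gold_standard(g, p)
  g2 <- read_gold_standard(p)
  expect_identical(g2$records, g$records)
  expect_error(gold_standard("s", c("a", "a"), "G", "1", c(1, 1)), "duplicate")
  expect_error(gold_standard("s", "a", "G", "1", 0), "positive")
})

test_that("assembly reports distinguish undefined cells and validate ranges", {
  p <- tempfile()
  writeLines(c(paste("Genome", "Genome fraction (%)", "mismatches per 100 kbp",
                     "Duplication ratio", "NGA50", "misassemblies", sep = "\t"),
               "g1\t95.2\t120.5\t1.01\t50000\t3",
               "g2\t30.0\t10.0\t1.00\t-\t0",
               "g3\t88.8\t5.5\t-\t12000\t1"), p)
  rep <- read_assembly_report(p)
  expect_equal(nrow(rep), 3L)
  expect_true(is.na(rep$nga50[2]))
  expect_false(is.na(rep$nga50[1]))
  expect_true(is.na(rep$duplication_ratio[3]))

  writeLines(c("Genome\tGenome fraction (%)\tmismatches per 100 kbp",
               "g1\t101\t5"), p)
  expect_error(read_assembly_report(p), "range")
  writeLines(c("Genome\tNGA50", "g1\t100"), p)
  expect_error(read_assembly_report(p), "mismatches")
})

test_that("assembly reports round-trip including NA cells", {
  rep <- assembly_report(c("g1", "g2"), c(95, 40), c(10, NA),
                         nga50 = c(1000, NA), misassemblies = c(2, 0))
  p <- tempfile()
  write_assembly_report(rep, p)
  back <- read_assembly_report(p)
  expect_equal(back$genome_fraction, rep$genome_fraction)
  expect_equal(back$nga50, rep$nga50)
  expect_true(is.na(back$mismatches_per_100kb[2]))
})

test_that("readers are total on writers' output over random fixtures", {
  for (seed in 1:5) {
    bundle <- generate_gold(community_spec(n_genomes = 5, n_samples = 1,
                                           contigs_per_genome = 4,
                                           seed = seed))
    g <- bundle$gold[[1]]
    p <- tempfile()
    write_gold_standard(g, p)
    expect_identical(read_gold_standard(p)$records, g$records)
    pr <- bundle$profiles[[1]]
    write_profile(pr, p)
    back <- read_profile(p)[[1]]
    expect_equal(back$entries$abundance, pr$entries$abundance,
                 tolerance = 1e-9)
    bn <- corrupt_binning(g, 0.3, 0.2, seed = seed)
    write_binning(bn, p)
    expect_identical(read_binning(p)$assignments, bn$assignments)
  }
})
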