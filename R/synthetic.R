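#' Specification of a synthetic toy community
#'
#' Defines the study conditions for the fixture generator: community size,
#' per-sample log-normal abundance variation, a log-normal contig-length
#' model (minimum 500 bp, so bp weighting genuinely differs from sequence
#' counting), and a strain structure in which `n_common_pairs` genome pairs
#' share one species node (the bookkeeping analogue of genomes within 95%
#' average nucleotide identity).
#'
#' @param n_genomes number of genomes in the community.
#' @param n_samples number of samples to generate.
#' @param n_common_pairs number of genome pairs placed under a shared
#'   species ("common" strains); the rest get one species each.
#' @param decoy_species extra species present in the taxonomy but absent
#'   from the community, as reference databases always contain; mislabeled
#'   predictions can land on them.
#' @param abundance_log_mean,abundance_log_sigma log-normal parameters of
#'   the per-sample genome abundance (sequencing-depth) factors.
#' @param contigs_per_genome expected contig count per genome at average
#'   abundance.
#' @param contig_log_mean,contig_log_sigma log-normal contig length
#'   parameters (defaults give a median around 3 kb).
#' @param min_contig_length minimum contig length in bp.
#' @param seed integer seed; every generator operation is deterministic
#'   given the spec.
#' @return Object of class `community_spec`.
#' @export
community_spec <- function(n_genomes = 10, n_samples = 2, n_common_pairs = 1,
                           decoy_species = 3,
                           abundance_log_mean = 0, abundance_log_sigma = 1,
                           contigs_per_genome = 20,
                           contig_log_mean = log(3000),
                           contig_log_sigma = 0.7,
                           min_contig_length = 500, seed = 42) {
  stopifnot(n_genomes >= 1, n_samples >= 1, n_common_pairs >= 0,
            decoy_species >= 0,
            2 * n_common_pairs <= n_genomes, contigs_per_genome >= 1,
            min_contig_length >= 1)
  structure(as.list(environment()), class = "community_spec")
}

# nested interval splits with gradually growing group counts: n species are
# partitioned at each of `depth` levels, from two superkingdom-level clades
# down to n singleton species, by repeatedly halving the largest interval;
# splits only refine earlier levels, so the groups nest by construction
.nested_groups <- function(n, depth) {
  k <- pmin(n, pmax(ceiling(n^(seq_len(depth) / depth)),
                    if (n > 1L) 2L else 1L))
  k[depth] <- n
  k <- cummax(k)
  intervals <- list(seq_len(n))
  out <- matrix(1L, nrow = n, ncol = depth)
  for (level in seq_len(depth)) {
    while (length(intervals) < k[level]) {
      sizes <- lengths(intervals)
      i <- which.max(sizes)
      idx <- intervals[[i]]
      half <- ceiling(length(idx) / 2)
      intervals <- append(intervals[-i],
                          list(idx[seq_len(half)], idx[-seq_len(half)]))
    }
    for (grp in seq_along(intervals))
      out[intervals[[grp]], level] <- intervals[[grp]][1L]
  }
  for (j in seq_len(depth)) out[, j] <- match(out[, j], unique(out[, j]))
  out
}

# build the toy taxonomy: full 8-rank lineages for n_species species,
# plus strain nodes under shared species for "common" genome pairs and
# n_decoy extra species (taxa present in the reference taxonomy but absent
# from the community, as real reference databases always have).
# Returns list(db, genome_taxid (named by genome ID), species_taxid)
.synthetic_taxonomy <- function(n_species, genome_ids, pair_of,
                                n_decoy = 0L) {
  ranks <- cami_ranks()
  depth <- length(ranks)
  grp <- .nested_groups(n_species, depth)

  taxid <- "1"; parent <- "1"; rank <- "no rank"; name <- "root"
  node_id <- new.env(parent = emptyenv())
  next_id <- 2L
  get_node <- function(level, g, parent_id) {
    key <- paste(level, g, sep = ":")
    if (!is.null(node_id[[key]])) return(node_id[[key]])
    id <- as.character(next_id)
    next_id <<- next_id + 1L
    taxid <<- c(taxid, id)
    parent <<- c(parent, parent_id)
    rank <<- c(rank, ranks[level])
    name <<- c(name, paste0(ranks[level], "_", g))
    node_id[[key]] <- id
    id
  }
  species_taxid <- character(n_species)
  for (i in seq_len(n_species)) {
    pid <- "1"
    for (level in seq_len(depth)) pid <- get_node(level, grp[i, level], pid)
    species_taxid[i] <- pid
  }

  # decoy species under existing genera, cycling through them
  genus_ids <- unique(vapply(seq_len(n_species), function(i)
    node_id[[paste(depth - 1L, grp[i, depth - 1L], sep = ":")]], ""))
  for (d in seq_len(n_decoy)) {
    id <- as.character(next_id)
    next_id <- next_id + 1L
    taxid <- c(taxid, id)
    parent <- c(parent, genus_ids[(d - 1L) %% length(genus_ids) + 1L])
    rank <- c(rank, "species")
    name <- c(name, paste0("decoy_species_", d))
  }

  # genomes: each unpaired genome sits at its species node; each member of
  # a common pair gets its own strain node below the shared species
  genome_taxid <- stats::setNames(character(length(genome_ids)), genome_ids)
  for (k in seq_along(genome_ids)) {
    sp <- species_taxid[pair_of$species[k]]
    if (pair_of$strain[k]) {
      id <- as.character(next_id)
      next_id <- next_id + 1L
      taxid <- c(taxid, id)
      parent <- c(parent, sp)
      rank <- c(rank, "strain")
      name <- c(name, paste0("strain_", genome_ids[k]))
      genome_taxid[k] <- id
    } else {
      genome_taxid[k] <- sp
    }
  }
  list(db = taxonomy_db(taxid, parent, rank, name),
       genome_taxid = genome_taxid, species_taxid = species_taxid)
}

#' Generate a toy gold standard
#'
#' Builds an internally consistent bundle: a toy taxonomy with full
#' eight-rank lineages, per-sample gold-standard sequence maps (contig ->
#' genome, taxon, length) and per-sample gold taxonomic profiles whose
#' per-rank abundances are exactly the bp-weighted genome shares projected
#' to each rank. Deterministic given `spec$seed`.
#'
#' @param spec a [community_spec()].
#' @return List with elements `taxonomy` ([taxonomy_db()]), `genome_taxid`
#'   (named vector genome ID -> leaf taxon), `gold` (list of
#'   [gold_standard()], one per sample) and `profiles` (list of
#'   [taxon_profile()], one per sample).
#' @export
generate_gold <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(spec$seed)
  n <- spec$n_genomes
  genome_ids <- sprintf("G%02d", seq_len(n))
  n_species <- n - spec$n_common_pairs
  # genomes 1..2*pairs pair up under species 1..pairs; the rest are singles
  species_of <- integer(n)
  is_strain <- logical(n)
  if (spec$n_common_pairs > 0) {
    species_of[seq_len(2 * spec$n_common_pairs)] <-
      rep(seq_len(spec$n_common_pairs), each = 2)
    is_strain[seq_len(2 * spec$n_common_pairs)] <- TRUE
  }
  rest <- which(species_of == 0L)
  species_of[rest] <- spec$n_common_pairs + seq_along(rest)
  tax <- .synthetic_taxonomy(n_species, genome_ids,
                             list(species = species_of, strain = is_strain),
                             n_decoy = spec$decoy_species)
  db <- tax$db

  make_sample <- function(s) {
    w <- stats::rlnorm(n, spec$abundance_log_mean, spec$abundance_log_sigma)
    n_contigs <- pmax(1L, stats::rpois(n, spec$contigs_per_genome * w / mean(w)))
    genome <- rep(genome_ids, n_contigs)
    len <- pmax(spec$min_contig_length,
                round(stats::rlnorm(sum(n_contigs), spec$contig_log_mean,
                                    spec$contig_log_sigma)))
    seq_id <- sprintf("S%d_C%05d", s, seq_along(genome))
    gold_standard(sample_id = paste0("sample_", s),
                  seq_id = seq_id, genome_id = genome,
                  taxid = unname(tax$genome_taxid[genome]),
                  length = len)
  }
  gold <- lapply(seq_len(spec$n_samples), make_sample)

  profiles <- lapply(gold, function(g) .profile_from_gold(g, db))
  list(taxonomy = db, genome_taxid = tax$genome_taxid,
       gold = gold, profiles = profiles)
}

# bp-weighted genome shares of a gold standard projected to every major
# rank -> cumulative taxon_profile (abundances sum to 1 per rank)
.profile_from_gold <- function(gold, db) {
  g <- gold$records
  bp <- tapply(g$length, g$taxid, sum)
  share <- bp / sum(bp)
  taxid <- character(); rank <- character(); ab <- numeric(); tp <- character()
  for (r in db$major_ranks) {
    proj <- project_to_rank(db, names(share), r)
    keep <- !is.na(proj)
    if (!any(keep)) next
    agg <- tapply(share[keep], proj[keep], sum)
    lin <- vapply(names(agg), function(id) {
      l <- .rank_lineage(db, id)
      paste(l[!is.na(l)], collapse = "|")
    }, "")
    taxid <- c(taxid, names(agg))
    rank <- c(rank, rep(r, length(agg)))
    ab <- c(ab, as.numeric(agg))
    tp <- c(tp, lin)
  }
  taxon_profile(sample_id = gold$sample_id, taxid = taxid, rank = rank,
                abundance = ab, taxpath = tp)
}

#' Corrupt a gold standard into an imperfect binning
#'
#' Each sequence is independently left unassigned with probability
#' `unassigned_rate`, otherwise mis-binned to a uniformly chosen wrong
#' label with probability `misbin_rate`, otherwise assigned its true label.
#' With both rates 0 the prediction is perfect. Labels are genome IDs
#' (`kind = "genome"`) or the genomes' leaf taxon IDs
#' (`kind = "taxonomic"`).
#'
#' @param gold a [gold_standard()].
#' @param misbin_rate,unassigned_rate corruption rates in `[0, 1]`.
#' @param seed integer seed.
#' @param kind binning kind to emit.
#' @param genome_taxid named vector genome ID -> taxon ID, required for
#'   `kind = "taxonomic"` (as returned by [generate_gold()]).
#' @return A [binning_result()].
#' @export
corrupt_binning <- function(gold, misbin_rate = 0, unassigned_rate = 0,
                            seed = 1, kind = c("genome", "taxonomic"),
                            genome_taxid = NULL) {
  kind <- match.arg(kind)
  stopifnot(misbin_rate >= 0, misbin_rate <= 1,
            unassigned_rate >= 0, unassigned_rate <= 1)
  g <- gold$records
  truth <- if (kind == "genome") g$genome_id else {
    if (is.null(genome_taxid)) g$taxid else unname(genome_taxid[g$genome_id])
  }
  labels <- unique(truth)
  set.seed(seed)
  keep <- stats::runif(nrow(g)) >= unassigned_rate
  assigned <- truth
  if (length(labels) > 1L) {
    flip <- stats::runif(nrow(g)) < misbin_rate
    wrong <- vapply(truth[flip], function(tr)
      sample(setdiff(labels, tr), 1L), "")
    assigned[flip] <- wrong
  }
  binning_result(sample_id = gold$sample_id,
                 seq_id = g$seq_id[keep], bin_id = assigned[keep],
                 kind = kind)
}

# Dirichlet sample via independent gammas; shape 0 -> exact 0 mass
.rdirichlet1 <- function(alpha) {
  y <- vapply(alpha, function(a) if (a <= 0) 0 else stats::rgamma(1L, a), 0)
  if (sum(y) == 0) return(y)
  y / sum(y)
}

#' Corrupt a gold profile into an imperfect taxonomic profile
#'
#' Abundance noise is applied at the most specific (leaf) taxa by Dirichlet
#' resampling around the gold proportions with the given concentration
#' (larger = closer to gold; `Inf` = exact). An expected fraction
#' `drop_rate` of the leaf taxa is then lost and a further expected
#' fraction `relabel_rate` is relabeled to sibling species, both hitting
#' the lowest-abundance taxa first — where real profilers lose signal.
#' Dropped mass is not restored (the profile becomes incomplete, a false
#' negative); relabeled mass becomes a false positive plus false negative
#' when the sibling is outside the community. Per-rank entries are rebuilt
#' by projection, so the output is a consistent cumulative profile.
#'
#' @param profile a gold [taxon_profile()] (cumulative over ranks).
#' @param db the [taxonomy_db()] the profile lives in.
#' @param concentration Dirichlet concentration parameter (> 0, may be
#'   `Inf`).
#' @param drop_rate,relabel_rate corruption rates in `[0, 1]`.
#' @param seed integer seed.
#' @return A [taxon_profile()].
#' @export
corrupt_profile <- function(profile, db, concentration = Inf,
                            drop_rate = 0, relabel_rate = 0, seed = 1) {
  stopifnot(concentration > 0, drop_rate >= 0, drop_rate <= 1,
            relabel_rate >= 0, relabel_rate <= 1)
  mass <- .leaf_masses(profile, db)
  set.seed(seed)
  if (is.finite(concentration))
    mass[] <- .rdirichlet1(concentration * as.numeric(mass) / sum(mass))

  ids <- names(mass)
  # detection-limit errors: both dropout and misannotation hit the
  # lowest-abundance taxa first, where real profilers lose signal; the
  # affected counts are binomial in the nominal rates
  ord <- order(as.numeric(mass), ids)
  n_drop <- stats::rbinom(1L, length(ids), drop_rate)
  dropped <- seq_along(ids) %in% ord[seq_len(n_drop)]
  surv <- ord[!(ord %in% ord[seq_len(n_drop)])]
  n_rel <- stats::rbinom(1L, length(surv), relabel_rate)
  relabeled <- seq_along(ids) %in% surv[seq_len(n_rel)]

  species <- names(db$rank)[unname(db$rank) == "species"]
  new_ids <- ids
  for (i in which(relabeled)) {
    sp <- project_to_rank(db, ids[i], "species")
    genus <- project_to_rank(db, ids[i], "genus")
    sibs <- species[species != sp &
                      project_to_rank(db, species, "genus") == genus]
    if (length(sibs) == 0L) sibs <- setdiff(species, sp)
    if (length(sibs) == 0L) next
    new_ids[i] <- sibs[sample.int(length(sibs), 1L)]
  }
  keep <- !dropped & as.numeric(mass) > 0
  leaf <- tapply(as.numeric(mass)[keep], new_ids[keep], sum)
  if (length(leaf) == 0L) {
    return(taxon_profile(sample_id = profile$sample_id, taxid = character(),
                         rank = character(), abundance = numeric()))
  }

  taxid <- character(); rank <- character(); ab <- numeric(); tp <- character()
  for (r in db$major_ranks) {
    proj <- project_to_rank(db, names(leaf), r)
    ok <- !is.na(proj)
    if (!any(ok)) next
    agg <- tapply(as.numeric(leaf)[ok], proj[ok], sum)
    lin <- vapply(names(agg), function(id) {
      l <- .rank_lineage(db, id)
      paste(l[!is.na(l)], collapse = "|")
    }, "")
    taxid <- c(taxid, names(agg))
    rank <- c(rank, rep(r, length(agg)))
    ab <- c(ab, as.numeric(agg))
    tp <- c(tp, lin)
  }
  taxon_profile(sample_id = profile$sample_id, taxid = taxid, rank = rank,
                abundance = ab, taxpath = tp)
}

#' Generate a synthetic per-genome assembly report
#'
#' Draws per-genome statistics around configurable quality levels:
#' genome fraction from a normal clamped to `[0, 100]`, mismatch rates from
#' an exponential, duplication near 1, NGA50 proportional to genome
#' fraction (undefined below 50%), Poisson misassemblies. A subset of
#' genomes can be omitted entirely (unrecovered genomes).
#'
#' @param genome_ids character vector of genome IDs to draw rows for.
#' @param gf_mean,gf_sd genome-fraction distribution (percent).
#' @param mm_mean mean mismatches per 100 kb.
#' @param misassembly_mean mean misassembly count.
#' @param dup_excess mean duplication-ratio excess over 1.
#' @param omit_fraction fraction of genomes dropped from the report.
#' @param seed integer seed.
#' @return An [assembly_report()].
#' @export
generate_assembly_report <- function(genome_ids, gf_mean = 90, gf_sd = 10,
                                     mm_mean = 100, misassembly_mean = 2,
                                     dup_excess = 0.05, omit_fraction = 0,
                                     seed = 1) {
  stopifnot(omit_fraction >= 0, omit_fraction <= 1, dup_excess >= 0)
  set.seed(seed)
  n <- length(genome_ids)
  keep <- stats::runif(n) >= omit_fraction
  genome_ids <- genome_ids[keep]
  n <- length(genome_ids)
  gf <- pmin(100, pmax(0, stats::rnorm(n, gf_mean, gf_sd)))
  mm <- if (mm_mean > 0) stats::rexp(n, 1 / mm_mean) else rep(0, n)
  nga <- ifelse(gf >= 50, round(1000 + 2000 * gf / 100 *
                                  stats::rlnorm(n, 0, 0.3)), NA_real_)
  assembly_report(genome_id = genome_ids, genome_fraction = gf,
                  mismatches_per_100kb = mm,
                  duplication_ratio = 1 + abs(stats::rnorm(n, dup_excess,
                                                           dup_excess / 2)),
                  nga50 = nga,
                  misassemblies = stats::rpois(n, misassembly_mean))
}

#' Derive the perfect prediction for each category
#'
#' @param bundle output of [generate_gold()].
#' @param sample index of the sample.
#' @return List with the gold-matching `genome_binning`,
#'   `taxonomic_binning` ([binning_result()]s), `profile`
#'   ([taxon_profile()]) and `assembly` ([assembly_report()]: genome
#'   fraction 100, zero mismatches/misassemblies).
#' @export
perfect_predictions <- function(bundle, sample = 1L) {
  g <- bundle$gold[[sample]]
  genomes <- unique(g$records$genome_id)
  total_bp <- tapply(g$records$length, g$records$genome_id, sum)
  list(genome_binning = corrupt_binning(g, 0, 0, seed = 0, kind = "genome"),
       taxonomic_binning = corrupt_binning(g, 0, 0, seed = 0,
                                           kind = "taxonomic",
                                           genome_taxid = bundle$genome_taxid),
       profile = bundle$profiles[[sample]],
       assembly = assembly_report(genome_id = genomes,
                                  genome_fraction = 100,
                                  mismatches_per_100kb = 0,
                                  duplication_ratio = 1,
                                  nga50 = as.numeric(total_bp[genomes]),
                                  misassemblies = 0))
}

#' Write a complete toy benchmark directory
#'
#' Emits a self-contained fixture bundle: taxonomy dump files, per-sample
#' gold standards and gold profiles, and for each requested corruption
#' level one submission per category (genome binning, taxonomic binning,
#' profiling, assembly), labeled `tool_1` (least corrupted) to `tool_N`.
#'
#' @param dir output directory.
#' @param spec a [community_spec()].
#' @param corruption_levels numeric vector in `[0, 1)`, one per synthetic
#'   tool, used as mis-binning/unassignment/drop rates; Dirichlet
#'   concentration scales inversely.
#' @return Invisibly, a list describing the written layout.
#' @export
write_fixture_bundle <- function(dir, spec = community_spec(),
                                 corruption_levels = c(0, 0.1, 0.3)) {
  bundle <- generate_gold(spec)
  dir.create(file.path(dir, "taxonomy"), showWarnings = FALSE, recursive = TRUE)
  write_taxonomy_dump(bundle$taxonomy, file.path(dir, "taxonomy"))

  layout <- list(taxonomy = file.path(dir, "taxonomy"),
                 gold = list(), tools = list())
  for (s in seq_along(bundle$gold)) {
    sid <- bundle$gold[[s]]$sample_id
    gdir <- file.path(dir, "gold")
    dir.create(gdir, showWarnings = FALSE)
    gs_path <- file.path(gdir, paste0(sid, "_mapping.tsv"))
    pr_path <- file.path(gdir, paste0(sid, "_profile.tsv"))
    write_gold_standard(bundle$gold[[s]], gs_path)
    write_profile(bundle$profiles[[s]], pr_path)
    layout$gold[[sid]] <- list(mapping = gs_path, profile = pr_path)
  }

  genomes <- names(bundle$genome_taxid)
  for (k in seq_along(corruption_levels)) {
    lv <- corruption_levels[k]
    tool <- sprintf("tool_%d", k)
    tdir <- file.path(dir, tool)
    dir.create(tdir, showWarnings = FALSE)
    paths <- list()
    for (s in seq_along(bundle$gold)) {
      g <- bundle$gold[[s]]
      sid <- g$sample_id
      sseed <- spec$seed + 1000L * k + s
      gb <- corrupt_binning(g, misbin_rate = lv, unassigned_rate = lv / 2,
                            seed = sseed, kind = "genome")
      tb <- corrupt_binning(g, misbin_rate = lv, unassigned_rate = lv / 2,
                            seed = sseed + 1L, kind = "taxonomic",
                            genome_taxid = bundle$genome_taxid)
      pf <- corrupt_profile(bundle$profiles[[s]], bundle$taxonomy,
                            concentration = if (lv == 0) Inf else 50 / lv,
                            drop_rate = lv / 2, relabel_rate = lv / 2,
                            seed = sseed + 2L)
      paths[[sid]] <- list(
        genome_binning = write_binning(gb, file.path(
          tdir, paste0(sid, "_genome_binning.tsv"))),
        taxonomic_binning = write_binning(tb, file.path(
          tdir, paste0(sid, "_tax_binning.tsv"))),
        profile = write_profile(pf, file.path(
          tdir, paste0(sid, "_profile.tsv"))))
    }
    rep <- if (lv == 0) perfect_predictions(bundle)$assembly else
      generate_assembly_report(genomes, gf_mean = 95 - 60 * lv,
                               gf_sd = 5 + 20 * lv, mm_mean = 2000 * lv,
                               omit_fraction = lv / 2,
                               seed = spec$seed + 77L * k)
    paths$assembly <- write_assembly_report(rep, file.path(
      tdir, "assembly_report.tsv"))
    layout$tools[[tool]] <- paths
  }
  invisible(layout)
}
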