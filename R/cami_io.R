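#' @title CAMI bioboxes file I/O
#' @description Readers and writers for the tab-separated community formats:
#'   binning files (`@@SEQUENCEID` + `BINID`/`TAXID` body), profiling files
#'   (`TAXID RANK TAXPATH TAXPATHSN PERCENTAGE` body, one block per
#'   `@SampleID`), the 4-column gold-standard mapping, and per-genome
#'   assembly report tables. Abundances are fractions in `[0,1]` everywhere
#'   inside the package; the 0-100 percentage scale exists only in files.
#' @name cami_io
NULL

# split a file into "@"-metadata, the "@@" column header, and body rows
.read_cami_blocks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  list(lines = lines[keep], lineno = which(keep))
}

.parse_header_meta <- function(lines) {
  meta_lines <- lines[startsWith(lines, "@") & !startsWith(lines, "@@")]
  kv <- regmatches(meta_lines, regexec("^@([^:]+):(.*)$", meta_lines))
  keys <- vapply(kv, function(x) if (length(x) == 3L) x[2L] else NA_character_, "")
  vals <- vapply(kv, function(x) if (length(x) == 3L) trimws(x[3L]) else NA_character_, "")
  stats::setNames(as.list(vals[!is.na(keys)]), tolower(keys[!is.na(keys)]))
}

#' Construct a binning result
#'
#' @param sample_id sample identifier.
#' @param seq_id,bin_id parallel character vectors: each sequence's bin label
#'   (a genome bin ID or a taxon ID). Duplicate sequence IDs keep the first
#'   occurrence, with a warning.
#' @param kind `"genome"` or `"taxonomic"`.
#' @param meta optional named list of header metadata.
#' @return Object of class `binning_result` with a data frame `$assignments`
#'   (columns `seq_id`, `bin_id`).
#' @export
binning_result <- function(sample_id, seq_id, bin_id,
                           kind = c("genome", "taxonomic"), meta = list()) {
  kind <- match.arg(kind)
  seq_id <- as.character(seq_id)
  bin_id <- as.character(bin_id)
  if (length(bin_id) == 1L) bin_id <- rep_len(bin_id, length(seq_id))
  stopifnot(length(seq_id) == length(bin_id))
  dup <- duplicated(seq_id)
  if (any(dup)) {
    warning(sum(dup), " duplicate sequence assignment(s) in sample '",
            sample_id, "'; keeping first occurrence", call. = FALSE)
    seq_id <- seq_id[!dup]
    bin_id <- bin_id[!dup]
  }
  structure(list(sample_id = sample_id, kind = kind, meta = meta,
                 assignments = data.frame(seq_id = seq_id, bin_id = bin_id,
                                          stringsAsFactors = FALSE)),
            class = "binning_result")
}

#' @export
print.binning_result <- function(x, ...) {
  cat("<binning_result> sample=", x$sample_id, " kind=", x$kind, ": ",
      nrow(x$assignments), " sequences in ",
      length(unique(x$assignments$bin_id)), " bins\n", sep = "")
  invisible(x)
}

#' Read a CAMI binning file
#'
#' The kind is inferred from the columns present: a `BINID` column means
#' genome binning; `TAXID` only means taxonomic binning.
#'
#' @param path file path.
#' @return A [binning_result()].
#' @export
read_binning <- function(path) {
  blk <- .read_cami_blocks(path)
  lines <- blk$lines
  meta <- .parse_header_meta(lines)
  hdr_i <- which(startsWith(lines, "@@"))
  if (length(hdr_i) == 0L)
    stop("not a CAMI binning file (missing @@ column header): ", path)
  hdr_i <- hdr_i[1L]
  cols <- toupper(strsplit(sub("^@@", "", lines[hdr_i]), "\t", fixed = TRUE)[[1L]])
  if (cols[1L] != "SEQUENCEID")
    stop("first column must be SEQUENCEID in ", path)
  has_bin <- "BINID" %in% cols
  has_tax <- "TAXID" %in% cols
  if (!has_bin && !has_tax)
    stop("binning file needs a BINID and/or TAXID column: ", path)

  body <- lines[-seq_len(hdr_i)]
  body <- body[!startsWith(body, "@")]
  lineno <- blk$lineno[-seq_len(hdr_i)][!startsWith(lines[-seq_len(hdr_i)], "@")]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(cols))
  if (length(bad) > 0L)
    stop("line ", lineno[bad[1L]], " of '", path, "' has ",
         lengths(fields)[bad[1L]], " columns, expected ", length(cols))
  get_col <- function(nm) vapply(fields, `[[`, "", match(nm, cols))
  seq_id <- if (length(fields)) get_col("SEQUENCEID") else character()
  label_col <- if (has_bin) "BINID" else "TAXID"
  bin_id <- if (length(fields)) get_col(label_col) else character()
  binning_result(sample_id = meta$sampleid %||% "sample_1",
                 seq_id = seq_id, bin_id = bin_id,
                 kind = if (has_bin) "genome" else "taxonomic",
                 meta = meta)
}

#' Write a CAMI binning file
#'
#' @param result a [binning_result()].
#' @param path output path.
#' @return Invisibly, `path`. Reading the file back reproduces the
#'   assignments up to row order.
#' @export
write_binning <- function(result, path) {
  stopifnot(inherits(result, "binning_result"))
  col <- if (result$kind == "genome") "BINID" else "TAXID"
  hdr <- c("@Version:0.9.0",
           paste0("@SampleID:", result$sample_id),
           paste0("@@SEQUENCEID\t", col))
  body <- paste0(result$assignments$seq_id, "\t", result$assignments$bin_id)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Construct a taxonomic profile
#'
#' @param sample_id sample identifier.
#' @param taxid,rank,abundance parallel vectors; `abundance` are relative
#'   abundances as fractions in `[0,1]`.
#' @param taxpath optional pipe-delimited lineage strings.
#' @param meta optional named list of header metadata.
#' @return Object of class `taxon_profile` with a data frame `$entries`.
#'   Per rank, abundances must sum to at most 1 (+1e-6).
#' @export
taxon_profile <- function(sample_id, taxid, rank, abundance,
                          taxpath = NA_character_, meta = list()) {
  taxid <- as.character(taxid)
  rank <- as.character(rank)
  abundance <- as.numeric(abundance)
  if (length(rank) == 1L) rank <- rep_len(rank, length(taxid))
  stopifnot(length(taxid) == length(rank), length(taxid) == length(abundance))
  if (any(abundance < 0))
    stop("negative abundance in profile for sample '", sample_id, "'")
  sums <- tapply(abundance, rank, sum)
  if (any(sums > 1 + 1e-6))
    stop("abundances at rank '", names(sums)[which(sums > 1 + 1e-6)[1L]],
         "' sum to ", max(sums), " > 1 in sample '", sample_id, "'")
  structure(list(sample_id = sample_id, meta = meta,
                 entries = data.frame(taxid = taxid, rank = rank,
                                      taxpath = rep_len(as.character(taxpath),
                                                        length(taxid)),
                                      abundance = abundance,
                                      stringsAsFactors = FALSE)),
            class = "taxon_profile")
}

#' @export
print.taxon_profile <- function(x, ...) {
  cat("<taxon_profile> sample=", x$sample_id, ": ", nrow(x$entries),
      " entries over ", length(unique(x$entries$rank)), " ranks\n", sep = "")
  invisible(x)
}

#' Read a CAMI profiling file
#'
#' Expects `TAXID`, `RANK`, `TAXPATH`, `TAXPATHSN`, `PERCENTAGE` columns;
#' multiple `@SampleID` blocks yield multiple profiles. Percentages (0-100)
#' are converted to fractions.
#'
#' @param path file path.
#' @param rank_vocabulary optional character vector; entries whose rank is
#'   outside it trigger a warning (they are kept verbatim).
#' @return A list of [taxon_profile()] objects, one per sample block.
#' @export
read_profile <- function(path, rank_vocabulary = NULL) {
  blk <- .read_cami_blocks(path)
  lines <- blk$lines
  starts <- which(grepl("^@SampleID:", lines, ignore.case = TRUE))
  if (length(starts) == 0L) starts <- 1L
  ends <- c(starts[-1L] - 1L, length(lines))

  lapply(seq_along(starts), function(b) {
    chunk <- lines[starts[b]:ends[b]]
    chunk_lineno <- blk$lineno[starts[b]:ends[b]]
    meta <- .parse_header_meta(chunk)
    hdr_i <- which(startsWith(chunk, "@@"))
    cols <- c("TAXID", "RANK", "TAXPATH", "TAXPATHSN", "PERCENTAGE")
    if (length(hdr_i) > 0L) {
      cols <- toupper(strsplit(sub("^@@", "", chunk[hdr_i[1L]]),
                               "\t", fixed = TRUE)[[1L]])
      body_from <- hdr_i[1L] + 1L
    } else {
      body_from <- 1L
    }
    need <- c("TAXID", "RANK", "TAXPATH", "PERCENTAGE")
    if (!all(need %in% cols))
      stop("profiling file '", path, "' lacks required column(s): ",
           paste(setdiff(need, cols), collapse = ", "))
    body_sel <- seq(body_from, length(chunk))
    body <- chunk[body_sel]
    keep <- !startsWith(body, "@")
    body <- body[keep]
    lineno <- chunk_lineno[body_sel][keep]
    fields <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != length(cols))
    if (length(bad) > 0L)
      stop("line ", lineno[bad[1L]], " of '", path, "' has ",
           lengths(fields)[bad[1L]], " columns, expected ", length(cols))
    get_col <- function(nm) vapply(fields, `[[`, "", match(nm, cols))
    pct <- if (length(fields)) as.numeric(get_col("PERCENTAGE")) else numeric()
    if (any(is.na(pct)))
      stop("non-numeric PERCENTAGE in '", path, "'")
    if (any(pct < 0))
      stop("negative PERCENTAGE in '", path, "'")
    rank <- if (length(fields)) get_col("RANK") else character()
    if (!is.null(rank_vocabulary)) {
      odd <- setdiff(unique(rank), rank_vocabulary)
      if (length(odd) > 0L)
        warning("rank(s) outside vocabulary kept verbatim in '", path, "': ",
                paste(odd, collapse = ", "), call. = FALSE)
    }
    taxon_profile(sample_id = meta$sampleid %||% paste0("sample_", b),
                  taxid = if (length(fields)) get_col("TAXID") else character(),
                  rank = rank,
                  abundance = pct / 100,
                  taxpath = if (length(fields)) get_col("TAXPATH") else character(),
                  meta = meta)
  })
}

#' Write CAMI profiling file(s)
#'
#' @param profiles a [taxon_profile()] or list of them (one block per sample).
#' @param path output path. Fractions are written as percentages with full
#'   precision.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profiles, path) {
  if (inherits(profiles, "taxon_profile")) profiles <- list(profiles)
  blocks <- lapply(profiles, function(p) {
    e <- p$entries
    c(paste0("@SampleID:", p$sample_id),
      "@Version:0.9.1",
      paste0("@Ranks:", paste(unique(e$rank), collapse = "|")),
      "@@TAXID\tRANK\tTAXPATH\tTAXPATHSN\tPERCENTAGE",
      if (nrow(e) > 0L)
        paste0(e$taxid, "\t", e$rank, "\t",
               ifelse(is.na(e$taxpath), e$taxid, e$taxpath), "\t",
               ifelse(is.na(e$taxpath), e$taxid, e$taxpath), "\t",
               format(e$abundance * 100, digits = 12, scientific = FALSE,
                      trim = TRUE)))
  })
  writeLines(unlist(blocks), path)
  invisible(path)
}

#' Construct a gold-standard mapping
#'
#' @param sample_id sample identifier.
#' @param seq_id,genome_id,taxid,length parallel vectors mapping each
#'   sequence to its source genome, its taxon, and its length in bp.
#' @return Object of class `gold_standard` with data frame `$records`.
#' @export
gold_standard <- function(sample_id, seq_id, genome_id, taxid, length) {
  seq_id <- as.character(seq_id)
  length <- as.numeric(length)
  if (length(genome_id) == 1L) genome_id <- rep_len(genome_id, length(seq_id))
  if (length(taxid) == 1L) taxid <- rep_len(taxid, length(seq_id))
  stopifnot(length(seq_id) == length(genome_id),
            length(seq_id) == length(taxid),
            length(seq_id) == length(length))
  if (anyDuplicated(seq_id))
    stop("duplicate sequence IDs in gold standard for sample '", sample_id, "'")
  if (any(!is.finite(length)) || any(length <= 0))
    stop("gold-standard sequence lengths must be strictly positive")
  structure(list(sample_id = sample_id,
                 records = data.frame(seq_id = seq_id,
                                      genome_id = as.character(genome_id),
                                      taxid = as.character(taxid),
                                      length = length,
                                      stringsAsFactors = FALSE)),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("<gold_standard> sample=", x$sample_id, ": ", nrow(x$records),
      " sequences, ", length(unique(x$records$genome_id)), " genomes, ",
      format(sum(x$records$length), big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Read / write the tab-separated gold-standard mapping
#'
#' Four columns, `SEQUENCEID BINID TAXID LENGTH` (genome ID in `BINID`),
#' preceded by optional `@`-metadata and a `@@` header row.
#'
#' @param path file path.
#' @return [read_gold_standard()]: a [gold_standard()];
#'   [write_gold_standard()]: invisibly, `path`.
#' @export
read_gold_standard <- function(path) {
  blk <- .read_cami_blocks(path)
  lines <- blk$lines
  meta <- .parse_header_meta(lines)
  hdr_i <- which(startsWith(lines, "@@"))
  if (length(hdr_i) == 0L)
    stop("not a gold-standard file (missing @@ column header): ", path)
  cols <- toupper(strsplit(sub("^@@", "", lines[hdr_i[1L]]),
                           "\t", fixed = TRUE)[[1L]])
  need <- c("SEQUENCEID", "BINID", "TAXID", "LENGTH")
  if (!all(need %in% cols))
    stop("gold-standard file '", path, "' lacks column(s): ",
         paste(setdiff(need, cols), collapse = ", "))
  body <- lines[-seq_len(hdr_i[1L])]
  body <- body[!startsWith(body, "@")]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(cols))
  if (length(bad) > 0L)
    stop("malformed row in '", path, "' (expected ", length(cols), " columns)")
  get_col <- function(nm) vapply(fields, `[[`, "", match(nm, cols))
  gold_standard(sample_id = meta$sampleid %||% "sample_1",
                seq_id = get_col("SEQUENCEID"),
                genome_id = get_col("BINID"),
                taxid = get_col("TAXID"),
                length = as.numeric(get_col("LENGTH")))
}

#' @rdname read_gold_standard
#' @param gold a [gold_standard()].
#' @export
write_gold_standard <- function(gold, path) {
  stopifnot(inherits(gold, "gold_standard"))
  r <- gold$records
  writeLines(c("@Version:0.9.0",
               paste0("@SampleID:", gold$sample_id),
               "@@SEQUENCEID\tBINID\tTAXID\tLENGTH",
               paste0(r$seq_id, "\t", r$genome_id, "\t", r$taxid, "\t",
                      format(r$length, scientific = FALSE, trim = TRUE))),
             path)
  invisible(path)
}

# column-name normalization for assembly report tables: lowercase, drop
# everything non-alphanumeric, so "Genome fraction (%)" == "genome_fraction"
.norm_col <- function(x) gsub("[^a-z0-9]", "", tolower(x))

.assembly_cols <- c(genome_id = "genomeid", genome_id2 = "assembly",
                    genome_id3 = "genome",
                    genome_fraction = "genomefraction",
                    mismatches_per_100kb = "mismatchesper100kb",
                    mismatches_per_100kbp = "mismatchesper100kbp",
                    duplication_ratio = "duplicationratio",
                    nga50 = "nga50", misassemblies = "misassemblies",
                    coverage = "coverage")

#' Construct a per-genome assembly report
#'
#' @param genome_id character vector of reference genome IDs.
#' @param genome_fraction percentage (0-100) of each reference covered.
#' @param mismatches_per_100kb mismatch rate in the contig-reference
#'   alignments; `NA` = undefined.
#' @param duplication_ratio,nga50,misassemblies,coverage further MetaQUAST
#'   style statistics; `NA` = undefined (an undefined NGA50 is distinct
#'   from an NGA50 of 0).
#' @return Object of class `assembly_report` (a data frame).
#' @export
assembly_report <- function(genome_id, genome_fraction, mismatches_per_100kb,
                            duplication_ratio = NA_real_, nga50 = NA_real_,
                            misassemblies = NA_real_, coverage = NA_real_) {
  genome_id <- as.character(genome_id)
  gf <- as.numeric(genome_fraction)
  if (any(gf < 0 | gf > 100, na.rm = TRUE))
    stop("genome fraction out of range [0, 100]")
  mm <- as.numeric(mismatches_per_100kb)
  if (any(mm < 0, na.rm = TRUE)) stop("negative mismatch rate")
  ms <- as.numeric(misassemblies)
  if (any(ms < 0, na.rm = TRUE)) stop("negative misassembly count")
  out <- data.frame(genome_id = genome_id, genome_fraction = gf,
                    mismatches_per_100kb = mm,
                    duplication_ratio = rep_len(as.numeric(duplication_ratio),
                                                length(genome_id)),
                    nga50 = rep_len(as.numeric(nga50), length(genome_id)),
                    misassemblies = rep_len(ms, length(genome_id)),
                    coverage = rep_len(as.numeric(coverage), length(genome_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("assembly_report", "data.frame")
  out
}

#' Read a per-genome assembly statistics table
#'
#' Tab-separated, one row per reference genome, with named columns in
#' MetaQUAST style; `-` or empty cells become `NA` (undefined), which for
#' NGA50 is distinct from 0.
#'
#' @param path file path.
#' @return An [assembly_report()].
#' @export
read_assembly_report <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("-", "", "NA"))
  nc <- .norm_col(names(tab))
  pick <- function(keys) {
    i <- which(nc %in% keys)
    if (length(i) == 0L) NULL else tab[[i[1L]]]
  }
  gid <- pick(c("genomeid", "genome", "assembly", "references"))
  if (is.null(gid)) gid <- tab[[1L]]
  gf <- pick("genomefraction")
  mm <- pick(c("mismatchesper100kb", "mismatchesper100kbp"))
  if (is.null(gf) || is.null(mm))
    stop("assembly report '", path,
         "' lacks a genome fraction and/or mismatches per 100 kb column")
  assembly_report(genome_id = gid, genome_fraction = gf,
                  mismatches_per_100kb = mm,
                  duplication_ratio = pick("duplicationratio") %||% NA_real_,
                  nga50 = pick("nga50") %||% NA_real_,
                  misassemblies = pick("misassemblies") %||% NA_real_,
                  coverage = pick(c("coverage", "avgcoverage")) %||% NA_real_)
}

#' Write a per-genome assembly statistics table
#'
#' @param report an [assembly_report()].
#' @param path output path; `NA` cells are written as `-`.
#' @return Invisibly, `path`.
#' @export
write_assembly_report <- function(report, path) {
  out <- as.data.frame(report)
  names(out) <- c("genome_id", "genome_fraction", "mismatches_per_100kb",
                  "duplication_ratio", "NGA50", "misassemblies", "coverage")
  fmt <- vapply(seq_len(nrow(out)), function(i) {
    cells <- vapply(out[i, ], function(v)
      if (is.na(v)) "-" else format(v, scientific = FALSE, trim = TRUE), "")
    paste(cells, collapse = "\t")
  }, "")
  writeLines(c(paste(names(out), collapse = "\t"), fmt), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
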