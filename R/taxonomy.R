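#' Major taxonomic ranks used throughout the evaluation
#'
#' The eight major NCBI ranks, ordered from most general to most specific.
#' All per-rank metrics iterate over (a subset of) this vector, and the
#' weighted UniFrac tree places a node at depth equal to its rank's position
#' here, so a species-level node sits eight unit branches below the root.
#'
#' @return Character vector of length 8 ending in `"species"`.
#' @export
#' @examples
#' cami_ranks()
cami_ranks <- function() {
  c("superkingdom", "kingdom", "phylum", "class", "order",
    "family", "genus", "species")
}

#' Construct a taxonomy database
#'
#' Low-level constructor used by [load_taxonomy()] and the synthetic fixture
#' generator. Validates the structural invariants: exactly one root (a node
#' that is its own parent), every parent present, and no cycles.
#'
#' @param taxid character vector of taxon IDs.
#' @param parent character vector of parent taxon IDs (same length).
#' @param rank character vector of rank names (free vocabulary; only
#'   `major_ranks` are used for metric projection).
#' @param name character vector of scientific names.
#' @param merged named character vector mapping old (merged) IDs to current
#'   IDs, as in NCBI's merged.dmp.
#' @param major_ranks ordered rank vector, most general first; must have
#'   length 8 and end with `"species"` unless you know what you are doing.
#' @return An object of class `taxonomy_db`.
#' @export
taxonomy_db <- function(taxid, parent, rank, name = taxid,
                        merged = character(), major_ranks = cami_ranks()) {
  taxid <- as.character(taxid)
  parent <- as.character(parent)
  rank <- as.character(rank)
  name <- as.character(name)
  stopifnot(length(parent) == length(taxid), length(rank) == length(taxid),
            length(name) == length(taxid))
  if (anyDuplicated(taxid))
    stop("duplicate taxon IDs in taxonomy: ",
         paste(utils::head(taxid[duplicated(taxid)], 3), collapse = ", "))
  root <- taxid[taxid == parent]
  if (length(root) != 1L)
    stop("taxonomy must have exactly one root (self-parent node), found ",
         length(root))
  missing_parent <- setdiff(parent, taxid)
  if (length(missing_parent) > 0L)
    stop("taxonomy parent(s) absent from node table: ",
         paste(utils::head(missing_parent, 3), collapse = ", "))

  names(parent) <- taxid
  names(rank) <- taxid
  names(name) <- taxid

  # cycle check: repeated parent hops must reach the root within n steps
  cur <- taxid
  at_root <- cur == root
  for (i in seq_len(length(taxid) + 1L)) {
    if (all(at_root)) break
    cur[!at_root] <- unname(parent[cur[!at_root]])
    at_root <- cur == root
  }
  if (!all(at_root))
    stop("cyclic parent chain in taxonomy involving taxid ",
         taxid[which(!at_root)[1L]])

  structure(list(parent = parent, rank = rank, name = name,
                 merged = merged, root = root,
                 major_ranks = major_ranks),
            class = "taxonomy_db")
}

#' @export
print.taxonomy_db <- function(x, ...) {
  cat("<taxonomy_db> ", length(x$parent), " nodes, root=", x$root,
      ", ", length(x$merged), " merged aliases\n", sep = "")
  cat("  major ranks: ", paste(x$major_ranks, collapse = " > "), "\n", sep = "")
  invisible(x)
}

# split an NCBI dump file into fields; dumps delimit fields with "\t|\t"
# and terminate lines with "\t|"
.parse_dmp <- function(path, min_fields, what) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(sub("\t\\|$", "", lines), "\t|\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < min_fields)
  if (length(bad) > 0L)
    stop("malformed ", what, " line ", bad[1L], " in '", path,
         "': expected >= ", min_fields, " fields, got ", nf[bad[1L]])
  fields
}

#' Load an NCBI-style taxonomy dump
#'
#' Parses `nodes.dmp` (taxid, parent, rank), `names.dmp` (scientific names
#' only) and optionally `merged.dmp` (old ID -> current ID aliases) in the
#' pipe-and-tab NCBI dump dialect.
#'
#' @param nodes_path path to nodes.dmp.
#' @param names_path path to names.dmp, or `NULL` to use taxids as names.
#' @param merged_path optional path to merged.dmp.
#' @param major_ranks see [taxonomy_db()].
#' @return A [taxonomy_db()] object.
#' @export
load_taxonomy <- function(nodes_path, names_path = NULL, merged_path = NULL,
                          major_ranks = cami_ranks()) {
  nodes <- .parse_dmp(nodes_path, 3L, "nodes.dmp")
  taxid <- vapply(nodes, `[[`, "", 1L)
  parent <- vapply(nodes, `[[`, "", 2L)
  rank <- vapply(nodes, `[[`, "", 3L)

  name <- taxid
  if (!is.null(names_path)) {
    nm <- .parse_dmp(names_path, 4L, "names.dmp")
    cls <- vapply(nm, `[[`, "", 4L)
    nm <- nm[cls == "scientific name"]
    nm_id <- vapply(nm, `[[`, "", 1L)
    nm_txt <- vapply(nm, `[[`, "", 2L)
    hit <- match(taxid, nm_id)
    name[!is.na(hit)] <- nm_txt[hit[!is.na(hit)]]
  }

  merged <- character()
  if (!is.null(merged_path)) {
    mg <- .parse_dmp(merged_path, 2L, "merged.dmp")
    merged <- vapply(mg, `[[`, "", 2L)
    names(merged) <- vapply(mg, `[[`, "", 1L)
  }

  taxonomy_db(taxid, parent, rank, name, merged = merged,
              major_ranks = major_ranks)
}

#' Resolve taxon IDs through the merged-ID alias table
#'
#' Returns the current ID for each input: IDs present in the node table are
#' returned unchanged; IDs present in the merged table are chased (chains of
#' merges are followed) until a node in the taxonomy is reached.
#'
#' @param db a [taxonomy_db()].
#' @param taxid character (or coercible) vector of taxon IDs.
#' @param on_unknown `"error"` to fail on IDs absent from both tables
#'   (default), `"na"` to return `NA` for them.
#' @return Character vector of current taxon IDs (with `NA` where unknown and
#'   `on_unknown = "na"`).
#' @export
resolve_taxid <- function(db, taxid, on_unknown = c("error", "na")) {
  on_unknown <- match.arg(on_unknown)
  cur <- as.character(taxid)
  known <- cur %in% names(db$parent)
  for (i in seq_len(20L)) {
    in_merged <- !known & cur %in% names(db$merged)
    if (!any(in_merged)) break
    cur[in_merged] <- unname(db$merged[cur[in_merged]])
    known <- cur %in% names(db$parent)
  }
  if (!all(known | is.na(cur))) {
    bad <- unique(as.character(taxid)[!known & !is.na(cur)])
    if (on_unknown == "error")
      stop("unknown taxon ID(s): ", paste(utils::head(bad, 5), collapse = ", "),
           call. = FALSE)
    cur[!known] <- NA_character_
  }
  cur
}

#' Project taxon IDs onto a major rank
#'
#' Walks the parent chain from each taxon and returns the first node
#' (possibly the taxon itself) whose rank equals `rank`; `NA` if the lineage
#' has no node at that rank. Input IDs are first resolved through the merged
#' table.
#'
#' @inheritParams resolve_taxid
#' @param rank a single rank name, normally one of `db$major_ranks`.
#' @return Character vector of projected taxon IDs, `NA` where the rank is
#'   absent from the lineage (or where the input was unknown and
#'   `on_unknown = "na"`).
#' @export
project_to_rank <- function(db, taxid, rank, on_unknown = c("error", "na")) {
  stopifnot(length(rank) == 1L)
  cur <- resolve_taxid(db, taxid, on_unknown = on_unknown)
  out <- rep(NA_character_, length(cur))
  active <- !is.na(cur)
  for (i in seq_len(length(db$parent) + 1L)) {
    if (!any(active)) break
    hit <- active & !is.na(cur) & unname(db$rank[cur]) == rank
    out[hit] <- cur[hit]
    active[hit] <- FALSE
    at_root <- active & cur == db$root
    active[at_root] <- FALSE
    cur[active] <- unname(db$parent[cur[active]])
  }
  out
}

# full major-rank lineage of one taxid: named character vector over
# db$major_ranks (NA where the lineage lacks a rank)
.rank_lineage <- function(db, taxid) {
  out <- stats::setNames(rep(NA_character_, length(db$major_ranks)),
                         db$major_ranks)
  cur <- taxid
  repeat {
    r <- unname(db$rank[cur])
    if (r %in% db$major_ranks) out[r] <- cur
    if (cur == db$root) break
    cur <- unname(db$parent[cur])
  }
  out
}

#' Write a taxonomy as NCBI-style dump files
#'
#' Emits `nodes.dmp`, `names.dmp` and `merged.dmp` (the latter only when
#' aliases exist) in the pipe-and-tab dialect read by [load_taxonomy()].
#'
#' @param db a [taxonomy_db()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_taxonomy_dump <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(db$parent)
  nodes <- paste0(ids, "\t|\t", unname(db$parent), "\t|\t",
                  unname(db$rank[ids]), "\t|")
  nms <- paste0(ids, "\t|\t", unname(db$name[ids]),
                "\t|\t\t|\tscientific name\t|")
  paths <- c(file.path(dir, "nodes.dmp"), file.path(dir, "names.dmp"))
  writeLines(nodes, paths[1L])
  writeLines(nms, paths[2L])
  if (length(db$merged) > 0L) {
    mg <- paste0(names(db$merged), "\t|\t", unname(db$merged), "\t|")
    paths <- c(paths, file.path(dir, "merged.dmp"))
    writeLines(mg, paths[3L])
  }
  invisible(paths)
}
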