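# BLAST-hit aggregation: bit-score filtering, lowest-common-ancestor
# taxonomy assignment, MAG annotation by longest contig, and exact
# normalization of composition tables for time-series display.

#' Read BLAST tabular (outfmt 6) hits and attach lineages
#'
#' @param path BLAST `-outfmt 6` TSV (qseqid, sseqid, pident, length,
#'   mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore).
#' @param lineage Optional data.frame `sseqid`, `lineage`
#'   (semicolon-delimited); joined onto the hits. Subjects without an
#'   entry get `NA` lineage (treated as unresolved).
#' @return data.frame `query_id`, `subject_id`, `bitscore`, `lineage`.
#' @export
readBlastHits <- function(path, lineage = NULL) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12) stop("expected >= 12 outfmt-6 columns, got ", ncol(df))
  out <- data.frame(query_id = as.character(df[[1]]),
                    subject_id = as.character(df[[2]]),
                    bitscore = as.numeric(df[[12]]),
                    lineage = NA_character_)
  if (!is.null(lineage))
    out$lineage <- lineage$lineage[match(out$subject_id, lineage$sseqid)]
  out
}

#' Keep BLAST hits with bit score strictly above a threshold
#'
#' @param hits data.frame with a `bitscore` column.
#' @param min_bitscore Threshold; a hit survives iff
#'   `bitscore > min_bitscore` (strict; default 100).
#' @return The filtered data.frame, original order preserved.
#' @export
filterHits <- function(hits, min_bitscore = 100) {
  if (!"bitscore" %in% names(hits)) stop("hits need a bitscore column")
  if (any(!is.finite(hits$bitscore))) stop("bitscore must be finite")
  hits[hits$bitscore > min_bitscore, , drop = FALSE]
}

# deepest taxonomy node shared by all lineages; character(0) if the
# roots already disagree
sharedPrefix <- function(lineages) {
  paths <- splitLineage(lineages)
  ref <- paths[[1]]
  depth <- length(ref)
  for (p in paths[-1]) {
    k <- min(depth, length(p))
    same <- which(ref[seq_len(k)] != p[seq_len(k)])
    depth <- if (length(same)) same[1] - 1L else k
    if (depth == 0) return(character(0))
  }
  ref[seq_len(depth)]
}

#' Lowest-common-ancestor assignment for one query's hits
#'
#' With `top_percent` set, only hits scoring within that percentage of
#' the best bit score participate (`bitscore >= (1 - top_percent/100) *
#' max`). The assignment is the deepest taxonomy node shared by all
#' participating lineages. Lineages under incompatible roots collapse to
#' the synthetic root (`"root"`, still `status = "assigned"`). Hits with
#' unresolved (`NA`) lineages are ignored; a query whose every hit is
#' unresolved gets `status = "unresolved"`, and a query with no hits at
#' all `status = "no_hit"`.
#'
#' @param hits data.frame `bitscore`, `lineage` for one query (already
#'   bit-score filtered).
#' @param top_percent Participation window as a percentage of the best
#'   bit score; `NULL` disables the window. Default 10.
#' @return list `lineage` (semicolon string or `NA`), `status`.
#' @export
lcaAssign <- function(hits, top_percent = 10) {
  if (is.null(hits) || nrow(hits) == 0)
    return(list(lineage = NA_character_, status = "no_hit"))
  hits <- hits[!is.na(hits$lineage) & nzchar(hits$lineage), , drop = FALSE]
  if (!nrow(hits))
    return(list(lineage = NA_character_, status = "unresolved"))
  if (!is.null(top_percent)) {
    cut <- (1 - top_percent / 100) * max(hits$bitscore)
    hits <- hits[hits$bitscore >= cut, , drop = FALSE]
  }
  lca <- sharedPrefix(hits$lineage)
  if (!length(lca)) lca <- "root"
  list(lineage = joinLineage(lca), status = "assigned")
}

#' LCA assignment for every query in a filtered hit table
#'
#' @param hits data.frame `query_id`, `bitscore`, `lineage`.
#' @inheritParams lcaAssign
#' @param query_ids Optional universe of queries; queries without hits
#'   are reported with `status = "no_hit"`.
#' @return data.frame `query_id`, `lineage`, `status`.
#' @export
lcaAssignAll <- function(hits, top_percent = 10, query_ids = NULL) {
  ids <- query_ids %||% sort(unique(hits$query_id))
  rows <- lapply(ids, function(q) {
    a <- lcaAssign(hits[hits$query_id == q, , drop = FALSE], top_percent)
    data.frame(query_id = q, lineage = a$lineage, status = a$status)
  })
  do.call(rbind, rows)
}

#' Annotate MAGs with the assignment of their longest contig
#'
#' The rule is longest-only: if the longest member contig has no hit,
#' the MAG has no hit, regardless of shorter members.
#'
#' @param mags A [MAGSet-class] (with `longest_contig_id` filled).
#' @param assignments data.frame `query_id`, `lineage`, `status` keyed by
#'   contig id, as from [lcaAssignAll()].
#' @return data.frame `mag_id`, `longest_contig_id`, `lineage`, `status`.
#' @export
blastMagAnnotation <- function(mags, assignments) {
  info <- magInfo(mags)
  if (anyNA(info$longest_contig_id))
    stop("MAGSet lacks longest_contig_id (missing contig lengths?)")
  idx <- match(info$longest_contig_id, assignments$query_id)
  if (anyNA(idx))
    stop("no assignment for longest contig(s): ",
         paste(info$longest_contig_id[is.na(idx)], collapse = ", "))
  data.frame(mag_id = info$mag_id,
             longest_contig_id = info$longest_contig_id,
             lineage = assignments$lineage[idx],
             status = assignments$status[idx])
}

#' Scale taxon counts to an exact fixed total
#'
#' Rescales a composition so the retained bins sum exactly to `total`
#' (default 1000) using largest-remainder rounding; optionally drops the
#' no-hit bin first. Used to make per-sample compositions comparable
#' across time points with different sequencing depths.
#'
#' @param counts Named non-negative numeric vector (taxon -> count).
#' @param total Target sum (default 1000).
#' @param exclude_no_hit Drop the `no_hit_label` bin before scaling.
#' @param no_hit_label Name of the no-hit bin (default `"no_hit"`).
#' @return Named integer vector summing exactly to `total`.
#' @export
normalizeComposition <- function(counts, total = 1000,
                                 exclude_no_hit = TRUE,
                                 no_hit_label = "no_hit") {
  stopifnot(total >= 1, !is.null(names(counts)))
  if (exclude_no_hit) counts <- counts[names(counts) != no_hit_label]
  if (!length(counts) || sum(counts) == 0)
    stop("no non-zero taxa to normalize")
  largestRemainder(counts, total)
}
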