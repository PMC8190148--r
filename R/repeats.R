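# Tandem-repeat (microsatellite) detection in reads. A run is a maximal
# stretch of >= min_copies tandem copies of a primitive 2-10 bp unit
# (partial trailing copies count in whole bases). Units are grouped by
# rotation class (TAG/AGT/GTA are one repeat) and named by their
# lexicographically smallest rotation. A read is a "repeat read" when
# the bases covered by its best class exceed 70% of the read length
# (strictly; the 70-of-100-bp rule, scaled proportionally for other
# read lengths).

#' Canonical form and rotation class of a repeat unit
#'
#' `canonicalUnit` returns the lexicographically smallest rotation;
#' `rotationClass` returns all rotations, sorted (the alias list used in
#' reports, e.g. TAG is written as class AGT/GTA/TAG).
#'
#' @param unit Nucleotide string.
#' @return A string, or character vector of rotations.
#' @export
canonicalUnit <- function(unit) {
  vapply(unit, function(u) sort(rotationsOf(u))[1], character(1),
         USE.NAMES = FALSE)
}

#' @rdname canonicalUnit
#' @export
rotationClass <- function(unit) sort(rotationsOf(unit))

rotationsOf <- function(u) {
  k <- nchar(u)
  d <- paste0(u, u)
  unique(substring(d, seq_len(k), seq_len(k) + k - 1L))
}

# TRUE iff the unit is not a whole-number power of a shorter unit
isPrimitive <- function(u) {
  k <- nchar(u)
  if (k == 1) return(TRUE)
  for (d in seq_len(k - 1)) {
    if (k %% d == 0 &&
        u == strrep(substr(u, 1, d), k / d)) return(FALSE)
  }
  TRUE
}

#' Find maximal tandem-repeat runs in a sequence
#'
#' For every unit length `k` in `unit_lengths`, positions where
#' `s[i] == s[i+k]` are chained into maximal periodic regions; a region
#' of total length `L` is a run when it holds at least `min_copies` full
#' copies (`L >= min_copies * k`) and its unit is primitive (not a power
#' of a shorter unit, which guarantees each repeat is reported exactly
#' once, at its fundamental period). Partial trailing copies count
#' toward the run length in whole bases; `N` breaks runs. Maximality:
#' extending a run one base in either direction breaks the periodicity.
#'
#' @param sequence Nucleotide string over `A,C,G,T,N` (case-insensitive).
#' @param unit_lengths Integer range of unit sizes (default `2:10`).
#' @param min_copies Minimum number of full unit copies (default 2).
#' @return data.frame `unit` (canonical rotation), `unit_length`,
#'   `start` (0-based inclusive), `end` (0-based exclusive), `length_bp`.
#' @examples
#' findRepeatRuns("TAGTAGTAGTAG")  # one 12-bp run of class AGT
#' @export
findRepeatRuns <- function(sequence, unit_lengths = 2:10, min_copies = 2) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  empty <- data.frame(unit = character(), unit_length = integer(),
                      start = integer(), end = integer(),
                      length_bp = integer())
  if (n == 0) return(empty)
  ch <- strsplit(sequence, "")[[1]]
  if (!all(ch %in% c("A", "C", "G", "T", "N")))
    stop("sequence contains characters outside A,C,G,T,N")
  ok <- ch != "N"
  out <- list()
  for (k in unit_lengths) {
    if (n < 2 * k) next
    m <- ch[seq_len(n - k)] == ch[(k + 1):n] &
      ok[seq_len(n - k)] & ok[(k + 1):n]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values)
    for (h in hit) {
      i <- starts[h]                      # 1-based start of match stretch
      L <- r$lengths[h] + k               # total periodic region length
      if (L < min_copies * k) next
      unit <- substr(sequence, i, i + k - 1L)
      if (!isPrimitive(unit)) next
      out[[length(out) + 1L]] <- data.frame(
        unit = canonicalUnit(unit), unit_length = k,
        start = i - 1L, end = i - 1L + L, length_bp = L)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$start, res$unit_length), , drop = FALSE]
}

#' Classify one read by its tandem-repeat content
#'
#' Coverage is accumulated per rotation class as the union of bases
#' covered by that class's runs (different phases and rotations of one
#' class may combine). The best class is the one with maximal coverage
#' (ties broken by lexicographic canonical unit); the read is a repeat
#' read iff that coverage strictly exceeds
#' `threshold_bp_per_100 / 100 * read_length`. Reads that are more than
#' half `N` are skipped (scanned but never repeat reads).
#'
#' @param sequence Read sequence.
#' @param read_id Identifier carried through to the output.
#' @param threshold_bp_per_100 Repeat bases required per 100 bp of read
#'   (default 70; strict `>`).
#' @param unit_lengths,min_copies Passed to [findRepeatRuns()].
#' @return One-row data.frame: `read_id`, `read_length`, `best_unit`
#'   (canonical, or `NA`), `repeat_bases`, `is_repeat_read`, `skipped`.
#' @export
classifyReadRepeat <- function(sequence, read_id = "read",
                               threshold_bp_per_100 = 70,
                               unit_lengths = 2:10, min_copies = 2) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  base <- data.frame(read_id = read_id, read_length = n,
                     best_unit = NA_character_, repeat_bases = 0L,
                     is_repeat_read = FALSE, skipped = FALSE)
  if (n == 0) return(base)
  nN <- lengths(regmatches(sequence, gregexpr("N", sequence)))
  if (nN > n / 2) { base$skipped <- TRUE; return(base) }
  runs <- findRepeatRuns(sequence, unit_lengths, min_copies)
  if (!nrow(runs)) return(base)
  cov <- vapply(split(runs, runs$unit), function(rr) {
    mask <- logical(n)
    for (i in seq_len(nrow(rr)))
      mask[(rr$start[i] + 1L):rr$end[i]] <- TRUE
    sum(mask)
  }, integer(1))
  cov <- cov[order(-cov, names(cov))]
  base$best_unit <- names(cov)[1]
  base$repeat_bases <- unname(cov[1])
  base$is_repeat_read <- cov[1] > threshold_bp_per_100 * n / 100
  base
}

#' Classify every read in a set
#'
#' @param reads Named character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @inheritParams classifyReadRepeat
#' @return data.frame with one row per read (see [classifyReadRepeat()]).
#' @export
classifyReads <- function(reads, threshold_bp_per_100 = 70,
                          unit_lengths = 2:10, min_copies = 2) {
  if (is(reads, "DNAStringSet")) reads <- setNames(as.character(reads),
                                                   names(reads))
  if (is.null(names(reads)))
    names(reads) <- paste0("read_", seq_along(reads))
  rows <- lapply(names(reads), function(id)
    classifyReadRepeat(reads[[id]], id, threshold_bp_per_100,
                       unit_lengths, min_copies))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-sample summary of repeat-read frequencies by unit class
#'
#' Fractions are computed over all reads in the sample (including
#' non-repeat and skipped reads); classes are ranked by fraction
#' descending, ties by lexicographic canonical unit. Each class is also
#' reported with its paper-style alias (the full sorted rotation list).
#'
#' @param calls data.frame from [classifyReads()].
#' @param sample_id Sample label for the report.
#' @return data.frame `sample_id`, `unit_class` (canonical),
#'   `rotations`, `repeat_reads`, `total_reads`, `fraction`, `rank`.
#' @export
summarizeRepeatSample <- function(calls, sample_id = "sample") {
  total <- nrow(calls)
  if (total == 0) stop("zero reads in sample")
  rep_calls <- calls[calls$is_repeat_read, , drop = FALSE]
  if (!nrow(rep_calls))
    return(data.frame(sample_id = character(), unit_class = character(),
                      rotations = character(), repeat_reads = integer(),
                      total_reads = integer(), fraction = numeric(),
                      rank = integer()))
  tab <- table(rep_calls$best_unit)
  df <- data.frame(sample_id = sample_id,
                   unit_class = names(tab),
                   rotations = vapply(names(tab), function(u)
                     paste(rotationClass(u), collapse = "/"), character(1)),
                   repeat_reads = as.integer(tab),
                   total_reads = total,
                   fraction = as.integer(tab) / total)
  df <- df[order(-df$fraction, df$unit_class), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
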