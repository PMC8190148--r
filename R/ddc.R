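# Simplified digital DNA chip (DDC): in-silico hybridization of a
# sample's reads against environment-labelled probes, a majority-vote
# inference of environmental labels from the positive spots, and a
# microarray-like grid rendering (red = positive, black = negative).

#' Read a probe table
#'
#' Accepts a TSV with header (`probe_id`, `sequence`, `label_category`,
#' `label_value`) or a FASTA whose headers are
#' `probe_id|category|value`.
#'
#' @param path File to read.
#' @return data.frame `probe_id`, `sequence`, `label_category`,
#'   `label_value`.
#' @export
readProbes <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, ">")) {
    ss <- Biostrings::readDNAStringSet(path)
    parts <- strsplit(names(ss), "|", fixed = TRUE)
    bad <- lengths(parts) != 3
    if (any(bad)) stop("FASTA probe headers must be probe_id|category|value")
    return(data.frame(
      probe_id = vapply(parts, `[`, character(1), 1),
      sequence = unname(as.character(ss)),
      label_category = vapply(parts, `[`, character(1), 2),
      label_value = vapply(parts, `[`, character(1), 3),
      row.names = NULL))
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "sequence", "label_category", "label_value")
  if (!all(need %in% names(df)))
    stop("probe TSV needs columns: ", paste(need, collapse = ", "))
  df[need]
}

# near-square grid that fits n cells: rows = ceiling(sqrt(n))
chipGrid <- function(n) {
  rows <- as.integer(ceiling(sqrt(n)))
  cols <- as.integer(ceiling(n / max(rows, 1L)))
  c(rows = rows, cols = cols)
}

#' Hybridize reads against a probe set in silico
#'
#' A read "hybridizes" to a probe when the probe occurs as a substring
#' of the read (allowing up to `max_mismatches` Hamming mismatches over
#' a window of probe length) on either strand. `hit_count` is the
#' number of reads hybridizing; a probe is positive iff
#' `hit_count >= min_hits`.
#'
#' @param reads Character vector or [Biostrings::DNAStringSet] of read
#'   sequences.
#' @param probes data.frame as returned by [readProbes()].
#' @param min_hits Reads required for a positive spot (default 1).
#' @param max_mismatches Hamming mismatches tolerated (default 0 =
#'   exact containment).
#' @return A [ChipResult-class].
#' @export
digitalHybridize <- function(reads, probes, min_hits = 1,
                             max_mismatches = 0) {
  if (!nrow(probes)) stop("empty probe set")
  stopifnot(min_hits >= 1, max_mismatches >= 0)
  if (!is(reads, "DNAStringSet"))
    reads <- Biostrings::DNAStringSet(toupper(as.character(reads)))
  hits <- vapply(probes$sequence, function(p) {
    pat <- Biostrings::DNAString(toupper(p))
    fwd <- Biostrings::vcountPattern(pat, reads,
                                     max.mismatch = max_mismatches)
    rev <- Biostrings::vcountPattern(Biostrings::reverseComplement(pat),
                                     reads, max.mismatch = max_mismatches)
    sum(fwd + rev > 0)
  }, integer(1), USE.NAMES = FALSE)
  calls <- S4Vectors::DataFrame(probe_id = probes$probe_id,
                                hit_count = hits,
                                positive = hits >= min_hits)
  new("ChipResult", calls = calls, layout = unname(chipGrid(nrow(probes))),
      params = list(min_hits = min_hits, max_mismatches = max_mismatches,
                    n_reads = length(reads)))
}

#' Infer environmental labels from positive chip spots
#'
#' Per label category, the value with the most positive probes wins
#' (majority vote); exact ties are reported as a sorted set, and a
#' category with no positive probes is `"undetermined"`.
#'
#' @param chip A [ChipResult-class].
#' @param probes The probe table used for hybridization.
#' @return Named list: category -> character vector of winning value(s)
#'   or `"undetermined"`.
#' @export
inferEnvironment <- function(chip, probes) {
  calls <- chipCalls(chip)
  stopifnot(nrow(calls) == nrow(probes))
  cats <- sort(unique(probes$label_category))
  out <- lapply(cats, function(cc) {
    sel <- probes$label_category == cc & calls$positive
    if (!any(sel)) return("undetermined")
    votes <- table(probes$label_value[sel])
    sort(names(votes)[votes == max(votes)])
  })
  names(out) <- cats
  out
}

#' Render a chip as an ASCII grid and/or a portable pixmap
#'
#' Text rendering: `#` positive, `.` negative, space for blank trailing
#' cells. PPM rendering (plain-text P3): red positive, black negative
#' and blank, `cell_px` pixels per cell. Both are bit-exact for a fixed
#' chip.
#'
#' @param chip A [ChipResult-class].
#' @param ppm_file Optional path to write a P3 portable pixmap.
#' @param cell_px Pixels per grid cell in the pixmap (default 4).
#' @return Character vector of grid lines (invisibly when written).
#' @export
renderChip <- function(chip, ppm_file = NULL, cell_px = 4) {
  calls <- chipCalls(chip)
  dims <- chipLayout(chip)
  n <- prod(dims)
  cell <- c(ifelse(calls$positive, "#", "."),
            rep(" ", n - nrow(calls)))
  grid <- matrix(cell, nrow = dims[1], ncol = dims[2], byrow = TRUE)
  lines <- apply(grid, 1, paste, collapse = "")
  if (!is.null(ppm_file)) {
    red <- c("255 0 0"); black <- c("0 0 0")
    px <- matrix(ifelse(grid == "#", red, black), nrow = dims[1])
    rows <- lapply(seq_len(dims[1]), function(i)
      rep(paste(rep(px[i, ], each = cell_px), collapse = " "), cell_px))
    writeLines(c("P3",
                 paste(dims[2] * cell_px, dims[1] * cell_px),
                 "255", unlist(rows)), ppm_file)
    return(invisible(lines))
  }
  lines
}
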