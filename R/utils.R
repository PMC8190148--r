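#' @importFrom stats aggregate cor rbinom rexp rgamma rlnorm rmultinom runif setNames sd
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson correlation with a defined sentinel for flat vectors
#'
#' Plain product-moment correlation, except that a zero-variance input
#' (for which the coefficient is undefined) returns `NA_real_` silently
#' instead of warning. Callers treat `NA` as "undefined correlation" and
#' exclude the pair from threshold decisions.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A single numeric in `[-1, 1]`, or `NA_real_` if either vector
#'   has zero variance.
#' @examples
#' profileCorrelation(c(1, 2, 3), c(2, 4, 6))  # 1
#' profileCorrelation(c(1, 1, 1), c(1, 2, 3))  # NA: undefined
#' @export
profileCorrelation <- function(u, v) {
  stopifnot(length(u) == length(v), length(u) >= 2)
  if (anyNA(u) || anyNA(v)) stop("abundance vectors must not contain NA")
  if (sd(u) == 0 || sd(v) == 0) return(NA_real_)
  as.numeric(cor(u, v))
}

# Largest-remainder apportionment: scale non-negative counts so they sum
# exactly to `total`. Ties in the fractional remainders are broken by name
# so the result is deterministic.
largestRemainder <- function(counts, total) {
  stopifnot(all(counts >= 0), total >= 1)
  s <- sum(counts)
  if (s == 0) stop("all counts are zero; nothing to apportion")
  quota <- counts / s * total
  base <- floor(quota)
  left <- as.integer(round(total - sum(base)))
  out <- base
  if (left > 0) {
    ord <- order(-(quota - base), names(counts))
    out[ord[seq_len(left)]] <- out[ord[seq_len(left)]] + 1
  }
  storage.mode(out) <- "integer"
  out
}

# Split semicolon-delimited lineage strings into character vectors.
splitLineage <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), trimws)
}

joinLineage <- function(x) paste(x, collapse = ";")

#' Months elapsed since the first date, rounded to whole months
#'
#' Calendar month arithmetic: the index is `12 * (year - year0) +
#' (month - month0)` plus a day-of-month correction, rounded to the
#' nearest integer, so mid-month sampling dates land on month bins.
#'
#' @param dates A `Date` vector (or strings coercible to dates).
#' @param origin Optional reference date; defaults to `min(dates)`.
#' @return Integer vector of month indices (origin = 0).
#' @export
monthIndex <- function(dates, origin = NULL) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("unparseable dates")
  origin <- as.Date(origin %||% min(dates))
  lt <- as.POSIXlt(dates)
  l0 <- as.POSIXlt(origin)
  raw <- 12 * (lt$year - l0$year) + (lt$mon - l0$mon) +
    (lt$mday - l0$mday) / 30.44
  as.integer(round(raw))
}

# reverse complement for plain character vectors of ACGTN
revComp <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}
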