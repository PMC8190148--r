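# Peak-recurrence classification of abundance time series. A peak
# "recurs" when another peak of at least 25% of its height appears one
# year later, within one month; a series is completely cyclic when
# every year-to-year transition it spans has a recurring peak.

#' Detect peaks in an abundance time series
#'
#' A point is a peak iff it is strictly greater than both neighbours
#' (endpoints are tested one-sided), its height is positive, and its
#' height is at least `min_height_frac` of the global maximum (a floor
#' that discards minor noise bumps).
#'
#' @param dates `Date` vector (strictly increasing).
#' @param values Non-negative abundances, same length.
#' @param min_height_frac Fraction of the global maximum a peak must
#'   reach (default 0.10).
#' @return data.frame `index`, `date`, `month` (rounded month index from
#'   the first sample), `height`, sorted by date.
#' @export
detectPeaks <- function(dates, values, min_height_frac = 0.10) {
  stopifnot(length(dates) == length(values),
            min_height_frac > 0, min_height_frac < 1)
  dates <- as.Date(dates)
  if (is.unsorted(dates, strictly = TRUE)) stop("dates must strictly increase")
  if (any(values < 0)) stop("abundances must be non-negative")
  n <- length(values)
  empty <- data.frame(index = integer(), date = as.Date(character()),
                      month = integer(), height = numeric())
  if (n == 0 || max(values) == 0) return(empty)
  floorH <- min_height_frac * max(values)
  left <- c(-Inf, values[-n])
  right <- c(values[-1], -Inf)
  isPeak <- values > left & values > right & values > 0 & values >= floorH
  idx <- which(isPeak)
  data.frame(index = idx, date = dates[idx],
             month = monthIndex(dates, origin = min(dates))[idx],
             height = values[idx])
}

#' Classify a series as complete/incomplete cyclic, transient or irregular
#'
#' A peak at month `m` *recurs* iff some peak exists at month `m'` with
#' `m' - m` in `[12 - month_tolerance, 12 + month_tolerance]` and height
#' at least `recurrence_frac` of the reference peak's height. The series
#' span is divided into year windows from the first sample
#' (`[0,12), [12,24), ...`, one per whole year spanned); a transition is
#' covered when some peak in its window recurs. A peak is only
#' *required* to recur when the date one year after it lies inside the
#' observed span (`month + 12 <= last month`); a
#' window holding only such end-censored peaks counts as covered, but a
#' window with no peak at all is a failed transition. Classes:
#' `COMPLETE_CYCLIC` — every transition covered and at least one
#' recurrence observed; `INCOMPLETE_CYCLIC` — at least one recurrence
#' but not all transitions covered; `TRANSIENT` — exactly one peak;
#' `IRREGULAR` — two or more peaks, no recurrence (and, degenerately,
#' no peaks at all, with a warning).
#'
#' @param peaks data.frame from [detectPeaks()].
#' @param dates The full series dates (used for the span).
#' @param month_tolerance Window half-width in months (default 1).
#' @param recurrence_frac Height ratio required (default 0.25,
#'   inclusive).
#' @return list `class` (one of the four labels), `n_peaks`,
#'   `n_recurrences`, `n_transitions`, `n_covered`.
#' @export
classifyPattern <- function(peaks, dates, month_tolerance = 1,
                            recurrence_frac = 0.25) {
  dates <- as.Date(dates)
  months <- monthIndex(dates, origin = min(dates))
  span <- max(months) - min(months)
  nTrans <- span %/% 12
  if (nrow(peaks) == 0) {
    warning("no peaks detected; classifying as IRREGULAR")
    return(list(class = "IRREGULAR", n_peaks = 0L, n_recurrences = 0L,
                n_transitions = nTrans, n_covered = 0L))
  }
  if (nrow(peaks) == 1)
    return(list(class = "TRANSIENT", n_peaks = 1L, n_recurrences = 0L,
                n_transitions = nTrans, n_covered = 0L))
  recurs <- vapply(seq_len(nrow(peaks)), function(i) {
    dm <- peaks$month - peaks$month[i]
    any(dm >= 12 - month_tolerance & dm <= 12 + month_tolerance &
          peaks$height >= recurrence_frac * peaks$height[i])
  }, logical(1))
  # a peak can only fail recurrence if the date one year after it was
  # actually observed (end-of-series censoring)
  required <- peaks$month + 12 <= max(months)
  covered <- vapply(seq_len(nTrans), function(t) {
    lo <- min(months) + 12 * (t - 1)
    inWin <- peaks$month >= lo & peaks$month < lo + 12
    any(recurs & inWin) || (any(inWin) && !any(inWin & required))
  }, logical(1))
  cls <- if (nTrans >= 1 && all(covered) && any(recurs)) "COMPLETE_CYCLIC"
         else if (any(recurs)) "INCOMPLETE_CYCLIC"
         else "IRREGULAR"
  list(class = cls, n_peaks = nrow(peaks),
       n_recurrences = sum(recurs), n_transitions = nTrans,
       n_covered = sum(covered))
}

#' Classify many abundance time series at once
#'
#' @param profiles Matrix (series x time points) with one row per MAG or
#'   contig, or a long data.frame `mag_id`, `date`, `abundance`.
#' @param dates Sample dates matching the matrix columns (ignored for
#'   long input).
#' @param min_height_frac,month_tolerance,recurrence_frac See
#'   [detectPeaks()] and [classifyPattern()].
#' @return data.frame `mag_id`, `class`, `n_peaks`, `n_recurrences`,
#'   `n_transitions`.
#' @export
classifyPeriodicity <- function(profiles, dates = NULL,
                                min_height_frac = 0.10,
                                month_tolerance = 1,
                                recurrence_frac = 0.25) {
  if (is.data.frame(profiles)) {
    stopifnot(all(c("mag_id", "date", "abundance") %in% names(profiles)))
    sp <- split(profiles, profiles$mag_id)
    rows <- lapply(names(sp), function(id) {
      d <- sp[[id]][order(as.Date(sp[[id]]$date)), ]
      one <- classifyOne(d$date, d$abundance, min_height_frac,
                         month_tolerance, recurrence_frac)
      cbind(data.frame(mag_id = id), one)
    })
    return(do.call(rbind, rows))
  }
  stopifnot(!is.null(dates), ncol(profiles) == length(dates))
  ids <- rownames(profiles) %||% paste0("series_", seq_len(nrow(profiles)))
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    one <- classifyOne(dates, profiles[i, ], min_height_frac,
                       month_tolerance, recurrence_frac)
    cbind(data.frame(mag_id = ids[i]), one)
  })
  do.call(rbind, rows)
}

classifyOne <- function(dates, values, min_height_frac, month_tolerance,
                        recurrence_frac) {
  if (length(values) < 4) stop("need >= 4 time points to classify")
  pk <- detectPeaks(dates, values, min_height_frac)
  cl <- suppressWarnings(
    classifyPattern(pk, dates, month_tolerance, recurrence_frac))
  data.frame(class = cl$class, n_peaks = cl$n_peaks,
             n_recurrences = cl$n_recurrences,
             n_transitions = cl$n_transitions)
}
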