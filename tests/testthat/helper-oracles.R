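# Independent brute-force oracles used to validate the fast
# implementations on small instances. These deliberately use naive
# per-offset loops and dense vectors, not the package's algorithms.

# --- tandem repeats -------------------------------------------------
# For every start offset and unit length, extend the periodicity one
# character at a time; accumulate per-rotation-class coverage masks.
oracleClassifyRead <- function(sequence, threshold_bp_per_100 = 70,
                               unit_lengths = 2:10, min_copies = 2) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  n <- length(ch)
  cov <- list()
  for (k in unit_lengths) {
    if (n < 2 * k) next
    for (i in seq_len(n - 2 * k + 1)) {
      unit <- paste(ch[i:(i + k - 1)], collapse = "")
      if (grepl("N", unit)) next
      if (!oraclePrimitive(unit)) next
      j <- i + k
      while (j <= n && ch[j] != "N" && ch[j] == ch[j - k]) j <- j + 1
      ext <- j - i
      if (ext < min_copies * k) next
      cls <- oracleCanonical(unit)
      mask <- cov[[cls]]
      if (is.null(mask)) mask <- logical(n)
      mask[i:(j - 1)] <- TRUE
      cov[[cls]] <- mask
    }
  }
  if (!length(cov))
    return(list(best_unit = NA_character_, repeat_bases = 0L,
                is_repeat_read = FALSE))
  bases <- vapply(cov, sum, integer(1))
  bases <- bases[order(-bases, names(bases))]
  list(best_unit = names(bases)[1],
       repeat_bases = unname(bases[1]),
       is_repeat_read = unname(bases[1]) > threshold_bp_per_100 * n / 100)
}

oraclePrimitive <- function(u) {
  k <- nchar(u)
  for (d in seq_len(k - 1))
    if (k %% d == 0 && u == paste(rep(substr(u, 1, d), k / d),
                                  collapse = "")) return(FALSE)
  TRUE
}

oracleCanonical <- function(u) {
  k <- nchar(u)
  rots <- vapply(seq_len(k), function(i)
    paste(substring(u, c(i:k, seq_len(i - 1)), c(i:k, seq_len(i - 1))),
          collapse = ""), character(1))
  sort(rots)[1]
}

# --- CCP classification ---------------------------------------------
# Dense-vector classification: embed every profile in the full
# vocabulary and take stats::cor per reference.
oracleCcpBest <- function(query, profiles) {
  vocab <- sort(unique(c(names(query), unlist(lapply(profiles, names)))))
  dense <- function(p) {
    v <- setNames(numeric(length(vocab)), vocab)
    v[names(p)] <- p
    v
  }
  q <- dense(query)
  rs <- vapply(profiles, function(p) {
    keys <- sort(union(names(query), names(p)))
    suppressWarnings(stats::cor(q[keys], dense(p)[keys]))
  }, numeric(1))
  shared <- vapply(profiles, function(p)
    length(intersect(names(query), names(p))), integer(1))
  ids <- names(profiles)
  ord <- order(-rs, -shared, ids, na.last = TRUE)
  ord <- ord[!is.na(rs[ord])]
  list(best = ids[ord[1]], r = unname(rs[ord[1]]))
}

# --- LCA -------------------------------------------------------------
# Deepest common node by enumerating every prefix of the first lineage.
oracleLca <- function(lineages) {
  paths <- lapply(strsplit(lineages, ";", fixed = TRUE), trimws)
  best <- character(0)
  for (d in seq_along(paths[[1]])) {
    pre <- paths[[1]][seq_len(d)]
    if (all(vapply(paths, function(p)
      length(p) >= d && identical(p[seq_len(d)], pre), logical(1))))
      best <- pre else break
  }
  best
}

# random reads for oracle comparisons
randomReadSet <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
    character(1))
}
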