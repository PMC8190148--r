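# Co-abundance canopy clustering of contigs into MAGs. Contigs whose
# appearance pattern across the sample series correlates at Pearson
# r >= 0.95 with a canopy are grouped into one metagenome-assembled
# genome; seeds are taken greedily in order of total abundance and each
# canopy's centroid (mean member profile) is refined to a fixed point.

#' Cluster contigs into MAGs by Pearson co-abundance canopies
#'
#' Greedy seeded canopy clustering: contigs are ordered (by total
#' abundance, descending, or input order); the first unassigned contig
#' seeds a canopy that gathers every unassigned contig whose profile
#' correlates with the canopy profile at `r >= r_threshold`. With
#' `refine = TRUE` the canopy centroid (mean of member rows) is
#' recomputed and membership re-gathered until stable (or
#' `max_iterations`); the seed always remains a member. Assigned contigs
#' are removed from the pool and the next seed is taken. Contigs with
#' zero-variance (flat) profiles have undefined correlations and are
#' reported as unclustered rather than seeding canopies. Singleton
#' canopies are allowed; the procedure is fully deterministic.
#'
#' @param x An [AbundanceMatrix-class] or a numeric matrix with contigs
#'   as rows and samples as columns.
#' @param r_threshold Pearson threshold for membership (default 0.95,
#'   inclusive).
#' @param min_samples Minimum number of samples required (default 3).
#' @param max_iterations Cap on centroid-refinement sweeps per canopy.
#' @param seed_order `"by_total_abundance"` (ties by contig id) or
#'   `"input_order"`.
#' @param refine Recompute the centroid and re-gather until stable; with
#'   `FALSE`, a single gather against the seed's own profile is used.
#' @param log1p Correlate `log1p`-transformed profiles instead of raw
#'   copies per liter (off by default).
#' @param contigs Optional data.frame `contig_id`, `length_bp` used for
#'   MAG length summaries; taken from `rowData(x)` when `x` is an
#'   `AbundanceMatrix`.
#' @return A [MAGSet-class].
#' @export
canopyCluster <- function(x, r_threshold = 0.95, min_samples = 3,
                          max_iterations = 100,
                          seed_order = c("by_total_abundance", "input_order"),
                          refine = TRUE, log1p = FALSE, contigs = NULL) {
  seed_order <- match.arg(seed_order)
  stopifnot(r_threshold > 0, r_threshold <= 1, min_samples >= 3)
  if (is(x, "AbundanceMatrix")) {
    if (is.null(contigs) && "length_bp" %in% names(rowData(x)))
      contigs <- data.frame(contig_id = rownames(x),
                            length_bp = rowData(x)$length_bp)
    m <- cplAssay(x)
  } else m <- as.matrix(x)
  if (ncol(m) < min_samples)
    stop("need at least ", min_samples, " samples; got ", ncol(m))
  if (nrow(m) == 0)
    return(newMAGSet(list(), m, contigs, character(),
                     clusterParams(r_threshold, min_samples, max_iterations,
                                   seed_order, refine, log1p)))
  if (is.null(rownames(m))) rownames(m) <- paste0("contig_", seq_len(nrow(m)))
  mm <- if (log1p) log1p(m) else m

  sds <- apply(mm, 1, sd)
  flat <- rownames(mm)[sds == 0]
  ids <- setdiff(rownames(mm), flat)

  ord <- if (seed_order == "by_total_abundance") {
    tot <- rowSums(m[ids, , drop = FALSE])
    ids[order(-tot, ids)]
  } else ids

  assigned <- character(0)
  canopies <- list()
  for (seedId in ord) {
    if (seedId %in% assigned) next
    pool <- setdiff(ord, assigned)
    centroid <- mm[seedId, ]
    members <- seedId
    for (it in seq_len(max_iterations)) {
      r <- suppressWarnings(as.numeric(cor(centroid, t(mm[pool, , drop = FALSE]))))
      gathered <- pool[!is.na(r) & r >= r_threshold]
      newMembers <- union(seedId, gathered)
      if (!refine || setequal(newMembers, members)) { members <- newMembers; break }
      members <- newMembers
      centroid <- colMeans(mm[members, , drop = FALSE])
    }
    canopies[[length(canopies) + 1L]] <- members
    assigned <- c(assigned, members)
  }
  newMAGSet(canopies, m, contigs, flat,
            clusterParams(r_threshold, min_samples, max_iterations,
                          seed_order, refine, log1p))
}

clusterParams <- function(r_threshold, min_samples, max_iterations,
                          seed_order, refine, log1p) {
  list(r_threshold = r_threshold, min_samples = min_samples,
       max_iterations = max_iterations, seed_order = seed_order,
       refine = refine, log1p = log1p)
}

# Assemble the MAGSet container from member lists. Profiles are the mean
# (centroid) and sum of member rows on the raw copies-per-liter scale.
newMAGSet <- function(canopies, m, contigs, unclustered, params) {
  nMag <- length(canopies)
  magId <- sprintf("MAG_%04d", seq_len(nMag))
  membership <- S4Vectors::DataFrame(
    contig_id = unlist(canopies, use.names = FALSE) %||% character(0),
    mag_id = rep(magId, lengths(canopies)))
  prof <- matrix(0, nMag, ncol(m), dimnames = list(magId, colnames(m)))
  profSum <- prof
  lenBp <- rep(NA_integer_, nMag)
  longest <- rep(NA_character_, nMag)
  for (i in seq_len(nMag)) {
    rows <- m[canopies[[i]], , drop = FALSE]
    prof[i, ] <- colMeans(rows)
    profSum[i, ] <- colSums(rows)
    if (!is.null(contigs)) {
      idx <- match(canopies[[i]], contigs$contig_id)
      if (!anyNA(idx)) {
        lens <- contigs$length_bp[idx]
        lenBp[i] <- sum(lens)
        cand <- canopies[[i]][lens == max(lens)]
        longest[i] <- sort(cand)[1]
      }
    }
  }
  info <- S4Vectors::DataFrame(
    mag_id = magId, n_contigs = lengths(canopies) %||% integer(0),
    length_bp = lenBp, longest_contig_id = longest)
  new("MAGSet", membership = membership, info = info, profiles = prof,
      profileSums = profSum, unclustered = as.character(unclustered),
      params = params)
}

#' Summarize explicit MAG member sets against an abundance matrix
#'
#' Builds a [MAGSet-class] from externally supplied membership (e.g. a
#' membership table read back from disk): per MAG it fills the summed
#' length, the mean per-sample profile of member rows, and the longest
#' member contig (ties broken by lexicographic id).
#'
#' @param members Named list of character vectors (MAG id -> contig ids),
#'   or a data.frame with columns `contig_id`, `mag_id`.
#' @param x An [AbundanceMatrix-class] or numeric matrix (contig rows).
#' @param contigs data.frame `contig_id`, `length_bp`; optional when `x`
#'   is an `AbundanceMatrix` carrying lengths.
#' @return A [MAGSet-class]; MAG ids are taken from `members`.
#' @export
summarizeMAGs <- function(members, x, contigs = NULL) {
  if (is(x, "AbundanceMatrix")) {
    if (is.null(contigs) && "length_bp" %in% names(rowData(x)))
      contigs <- data.frame(contig_id = rownames(x),
                            length_bp = rowData(x)$length_bp)
    m <- cplAssay(x)
  } else m <- as.matrix(x)
  if (is.data.frame(members))
    members <- split(as.character(members$contig_id),
                     as.character(members$mag_id))
  if (any(lengths(members) == 0)) stop("empty MAG member set")
  miss <- setdiff(unlist(members), rownames(m))
  if (length(miss))
    stop("member contigs absent from abundance matrix: ",
         paste(miss, collapse = ", "))
  if (!is.null(contigs)) {
    missL <- setdiff(unlist(members), contigs$contig_id)
    if (length(missL))
      stop("member contigs missing length metadata: ",
           paste(missL, collapse = ", "))
  }
  ms <- newMAGSet(unname(members), m, contigs, character(0), list())
  ms@info$mag_id <- names(members)
  rownames(ms@profiles) <- names(members)
  rownames(ms@profileSums) <- names(members)
  ms@membership$mag_id <- rep(names(members), lengths(members))
  validObject(ms)
  ms
}
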