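# Quantification of contig abundance as absolute copies per liter of
# seawater. The conversion assumes the extracted DNA mass is partitioned
# across contigs in proportion to their mapped-read fraction, and turns
# mass into molecule count with Avogadro's number over the molar mass of
# double-stranded DNA (g/mol per bp) times the target length.

#' Average molar mass of one double-stranded DNA base pair (g/mol)
#' @export
BP_MOLAR_MASS <- 616

#' Avogadro's number as used in the copy-number conversion
#' @export
AVOGADRO <- 6.02e23

#' Copies of a target sequence per liter of seawater
#'
#' Converts the mapped-read fraction of a contig (or MAG) into an
#' absolute molecule count per liter:
#'
#' `copies/L = dna_g * (mapped/total) * A / (m_bp * L_bp) / V`
#'
#' with `A` Avogadro's number and `m_bp` the molar mass per base pair.
#' The result is linear in the DNA mass and in the mapped-read fraction,
#' and inversely proportional to target length and water volume.
#'
#' @param total_dna_g Total extracted DNA mass for the sample, in grams.
#' @param mapped_reads Reads assigned to the target (>= 0).
#' @param total_reads Total reads sequenced for the sample (>= 1).
#' @param target_length_bp Length of the target contig or MAG in bp.
#' @param water_volume_L Filtered seawater volume in liters.
#' @param avogadro,bp_molar_mass Physical constants; override only for
#'   sensitivity analyses.
#' @return Copies per liter (non-negative numeric, vectorised).
#' @examples
#' copiesPerLiter(1e-9, 1e3, 1e6, 1e6, 1)  # ~977.27
#' @export
copiesPerLiter <- function(total_dna_g, mapped_reads, total_reads,
                           target_length_bp, water_volume_L,
                           avogadro = AVOGADRO,
                           bp_molar_mass = BP_MOLAR_MASS) {
  if (any(total_dna_g <= 0)) stop("total_dna_g must be positive")
  if (any(total_reads < 1)) stop("total_reads must be >= 1")
  if (any(mapped_reads < 0)) stop("mapped_reads must be >= 0")
  if (any(mapped_reads > total_reads))
    stop("mapped_reads cannot exceed total_reads")
  if (any(target_length_bp <= 0))
    stop("target_length_bp must be positive")
  if (any(water_volume_L <= 0))
    stop("water_volume_L must be positive")
  total_dna_g * (mapped_reads / total_reads) *
    (avogadro / (bp_molar_mass * target_length_bp)) / water_volume_L
}

#' Count reads passing the percent-identity filter per (contig, sample)
#'
#' A read-level alignment record contributes one count to its
#' (contig, sample) cell iff its identity is strictly greater than
#' `min_identity`; all other records are dropped.
#'
#' @param alignments data.frame with columns `read_id`, `contig_id`,
#'   `sample_id`, `identity` (fraction in `[0, 1]`).
#' @param contig_ids Character vector of known contig ids; records naming
#'   an unknown contig are an error.
#' @param min_identity Identity threshold, strict (default 0.90).
#' @return data.frame `contig_id`, `sample_id`, `count` with one row per
#'   non-zero cell, ordered by contig then sample.
#' @export
filterAlignments <- function(alignments, contig_ids, min_identity = 0.90) {
  need <- c("contig_id", "sample_id", "identity")
  if (!all(need %in% names(alignments)))
    stop("alignments must have columns: ", paste(need, collapse = ", "))
  idt <- alignments$identity
  if (any(is.na(idt)) || any(idt < 0) || any(idt > 1))
    stop("identity values must lie in [0, 1]")
  unknown <- setdiff(unique(alignments$contig_id), contig_ids)
  if (length(unknown))
    stop("alignments reference unknown contig ids: ",
         paste(unknown, collapse = ", "))
  keep <- alignments[idt > min_identity, c("contig_id", "sample_id")]
  if (nrow(keep) == 0)
    return(data.frame(contig_id = character(), sample_id = character(),
                      count = integer()))
  agg <- aggregate(list(count = rep(1L, nrow(keep))),
                   by = keep[c("contig_id", "sample_id")], FUN = sum)
  agg <- agg[order(agg$contig_id, agg$sample_id), ]
  rownames(agg) <- NULL
  agg$count <- as.integer(agg$count)
  agg
}

#' Assemble the contig x sample copies-per-liter matrix
#'
#' Applies [copiesPerLiter()] cell by cell using each sample's metadata
#' and each contig's length. Optionally keeps only the `top_n` contigs
#' with the highest total mapped-read count across samples (ties broken
#' by lexicographic contig id). Output rows are ordered by rank (total
#' count descending, then id); columns by sample date then id.
#'
#' @param samples data.frame with columns `sample_id`, `date`,
#'   `water_volume_L`, `total_dna_g`, `total_reads` (extra metadata
#'   columns such as `station`, `depth_layer`, `filter_fraction` are kept
#'   in `colData`).
#' @param contigs data.frame with columns `contig_id`, `length_bp`.
#' @param counts data.frame `contig_id`, `sample_id`, `count` as returned
#'   by [filterAlignments()].
#' @param top_n Optional; keep only this many contigs by total count.
#' @return An [AbundanceMatrix-class].
#' @export
buildAbundanceMatrix <- function(samples, contigs, counts, top_n = NULL) {
  stopifnot(all(c("sample_id", "water_volume_L", "total_dna_g",
                  "total_reads") %in% names(samples)),
            all(c("contig_id", "length_bp") %in% names(contigs)))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  if (anyDuplicated(contigs$contig_id)) stop("duplicate contig ids")
  if (any(samples$water_volume_L <= 0) || any(samples$total_dna_g <= 0) ||
      any(samples$total_reads < 1))
    stop("invalid sample metadata (volume, DNA mass, total reads)")
  if (any(contigs$length_bp < 1)) stop("contig lengths must be >= 1")

  missSam <- setdiff(unique(counts$sample_id), samples$sample_id)
  if (length(missSam))
    stop("counts reference samples with no metadata: ",
         paste(missSam, collapse = ", "))
  missCtg <- setdiff(unique(counts$contig_id), contigs$contig_id)
  if (length(missCtg))
    stop("counts reference unknown contigs: ",
         paste(missCtg, collapse = ", "))

  cid <- as.character(contigs$contig_id)
  sid <- as.character(samples$sample_id)
  cmat <- matrix(0L, nrow = length(cid), ncol = length(sid),
                 dimnames = list(cid, sid))
  if (nrow(counts))
    cmat[cbind(match(counts$contig_id, cid),
               match(counts$sample_id, sid))] <- as.integer(counts$count)

  perSample <- colSums(cmat)
  over <- perSample > samples$total_reads[match(colnames(cmat), sid)]
  if (any(over))
    stop("mapped counts exceed total reads for sample(s): ",
         paste(colnames(cmat)[over], collapse = ", "))

  total <- rowSums(cmat)
  ord <- order(-total, cid)
  if (!is.null(top_n)) {
    stopifnot(top_n >= 1)
    ord <- ord[seq_len(min(top_n, length(ord)))]
  }
  cmat <- cmat[ord, , drop = FALSE]
  contigs <- contigs[match(rownames(cmat), contigs$contig_id), ]

  # deterministic column order: by date (if present) then sample id
  if ("date" %in% names(samples)) {
    sord <- order(as.Date(samples$date), samples$sample_id)
  } else sord <- order(samples$sample_id)
  samples <- samples[sord, ]
  cmat <- cmat[, as.character(samples$sample_id), drop = FALSE]

  cpl <- matrix(0, nrow = nrow(cmat), ncol = ncol(cmat),
                dimnames = dimnames(cmat))
  for (j in seq_len(ncol(cmat))) {
    cpl[, j] <- copiesPerLiter(
      total_dna_g = samples$total_dna_g[j],
      mapped_reads = cmat[, j],
      total_reads = samples$total_reads[j],
      target_length_bp = contigs$length_bp,
      water_volume_L = samples$water_volume_L[j])
  }

  AbundanceMatrix(
    cpl,
    rowData = S4Vectors::DataFrame(
      length_bp = contigs$length_bp,
      total_mapped = rowSums(cmat),
      row.names = rownames(cmat)),
    colData = S4Vectors::DataFrame(
      samples[setdiff(names(samples), "sample_id")],
      row.names = samples$sample_id),
    params = list(top_n = top_n, avogadro = AVOGADRO,
                  bp_molar_mass = BP_MOLAR_MASS))
}
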