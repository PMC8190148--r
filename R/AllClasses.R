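#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' AbundanceMatrix: contig x sample copies-per-liter container
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' assay `"cpl"` of per-contig, per-sample abundances in copies per liter
#' of seawater. Rows are contigs (with `length_bp` and total mapped-read
#' counts in `rowData`), columns are samples (full sample metadata in
#' `colData`: station, date, depth layer, filter fraction, water volume,
#' total DNA mass, total reads).
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @aliases AbundanceMatrix
#' @export
setClass("AbundanceMatrix", contains = "SummarizedExperiment")

setValidity("AbundanceMatrix", function(object) {
  if (!"cpl" %in% SummarizedExperiment::assayNames(object))
    return("assay 'cpl' is required")
  a <- assay(object, "cpl")
  if (any(a < 0)) return("copies-per-liter values must be non-negative")
  if (anyDuplicated(rownames(object))) return("duplicate contig ids")
  if (anyDuplicated(colnames(object))) return("duplicate sample ids")
  TRUE
})

#' Construct an AbundanceMatrix
#'
#' @param cpl Numeric matrix of copies-per-liter values; rownames are
#'   contig ids, colnames are sample ids.
#' @param rowData Optional `DataFrame`/data.frame of per-contig fields
#'   (at least `length_bp`).
#' @param colData Optional `DataFrame`/data.frame of sample metadata.
#' @param params Named list of provenance parameters stored in
#'   `metadata()`.
#' @return An [AbundanceMatrix-class] object.
#' @export
AbundanceMatrix <- function(cpl, rowData = NULL, colData = NULL,
                            params = list()) {
  cpl <- as.matrix(cpl)
  se <- SummarizedExperiment(
    assays = list(cpl = cpl),
    rowData = if (is.null(rowData)) DataFrame(row.names = rownames(cpl))
              else DataFrame(rowData, row.names = rownames(cpl)),
    colData = if (is.null(colData)) DataFrame(row.names = colnames(cpl))
              else DataFrame(colData, row.names = colnames(cpl)))
  obj <- new("AbundanceMatrix", se)
  metadata(obj)$params <- params
  obj
}

#' Copies-per-liter assay accessor
#' @param x An [AbundanceMatrix-class].
#' @return The numeric contig x sample matrix.
#' @export
cplAssay <- function(x) assay(x, "cpl")

#' MAGSet: result of co-abundance canopy clustering
#'
#' Holds the contig-to-MAG membership, per-MAG summaries (member count,
#' summed length, longest contig), per-MAG abundance profiles (mean and
#' sum of member rows), the ids of contigs left unclustered
#' (zero-variance profiles), and the clustering parameters.
#'
#' @slot membership `DataFrame` with columns `contig_id`, `mag_id`.
#' @slot info `DataFrame` with columns `mag_id`, `n_contigs`, `length_bp`,
#'   `longest_contig_id`.
#' @slot profiles numeric matrix, MAG x sample, mean member abundance.
#' @slot profileSums numeric matrix, MAG x sample, summed member abundance.
#' @slot unclustered character vector of contig ids.
#' @slot params named list of clustering parameters.
#' @export
setClass("MAGSet", representation(
  membership  = "DataFrame",
  info        = "DataFrame",
  profiles    = "matrix",
  profileSums = "matrix",
  unclustered = "character",
  params      = "list"))

setValidity("MAGSet", function(object) {
  mem <- object@membership
  if (anyDuplicated(mem$contig_id)) return("a contig belongs to > 1 MAG")
  if (length(intersect(mem$contig_id, object@unclustered)))
    return("contig both clustered and unclustered")
  if (!setequal(unique(mem$mag_id), object@info$mag_id))
    return("membership and info disagree on MAG ids")
  TRUE
})

#' @describeIn MAGSet-class number of MAGs
#' @param x,object A `MAGSet`.
#' @export
magIds <- function(x) as.character(x@info$mag_id)

#' @describeIn MAGSet-class contig-to-MAG membership table
#' @export
magMembership <- function(x) x@membership

#' @describeIn MAGSet-class per-MAG summary table
#' @export
magInfo <- function(x) x@info

#' @describeIn MAGSet-class MAG x sample mean abundance profiles
#' @param what `"mean"` (canopy centroid) or `"sum"`.
#' @export
magProfiles <- function(x, what = c("mean", "sum")) {
  what <- match.arg(what)
  if (what == "mean") x@profiles else x@profileSums
}

#' @describeIn MAGSet-class ids of contigs left unclustered
#' @export
unclusteredContigs <- function(x) x@unclustered

setMethod("show", "MAGSet", function(object) {
  cat("MAGSet with", nrow(object@info), "MAGs over",
      nrow(object@membership), "contigs;",
      length(object@unclustered), "unclustered\n")
  cat("  r threshold:", object@params$r_threshold %||% NA, "\n")
})

#' PfamReferenceDb: per-genome Pfam domain-count profiles with taxonomy
#'
#' The reference side of classification-by-clustering-with-Pfam (CCP):
#' for each reference genome, a sparse profile of Pfam accession counts
#' plus its taxonomic lineage (superkingdom first).
#'
#' @slot profiles named list; each element a named integer vector
#'   (Pfam accession -> count) for one genome.
#' @slot lineage named character vector of semicolon-delimited lineages.
#' @slot zeroDomain character vector of genome ids with empty profiles.
#' @export
setClass("PfamReferenceDb", representation(
  profiles   = "list",
  lineage    = "character",
  zeroDomain = "character"))

setValidity("PfamReferenceDb", function(object) {
  ids <- names(object@profiles)
  if (length(object@profiles) &&
      (is.null(ids) || anyDuplicated(ids)))
    return("genome ids missing/duplicated")
  if (!setequal(ids, names(object@lineage)))
    return("profiles and lineage name different genomes")
  ok <- vapply(object@profiles, function(p)
    length(p) == 0 || (all(p >= 1) && !is.null(names(p))), logical(1))
  if (!all(ok)) return("stored profile counts must be >= 1 and named")
  sk <- vapply(splitLineage(object@lineage), `[`, character(1), 1)
  if (!all(sk %in% c("Viruses", "Bacteria", "Archaea", "Eukaryota")))
    return("lineages must start with a superkingdom")
  TRUE
})

#' @describeIn PfamReferenceDb-class genome ids in the database
#' @param x,object A `PfamReferenceDb`.
#' @export
refGenomeIds <- function(x) names(x@profiles)

#' @describeIn PfamReferenceDb-class one genome's domain-count profile
#' @param genome_id Genome to look up.
#' @export
refProfile <- function(x, genome_id) {
  if (!genome_id %in% names(x@profiles)) stop("unknown genome: ", genome_id)
  x@profiles[[genome_id]]
}

#' @describeIn PfamReferenceDb-class lineages (semicolon-delimited)
#' @export
refLineage <- function(x) x@lineage

setMethod("show", "PfamReferenceDb", function(object) {
  sk <- vapply(splitLineage(object@lineage), `[`, character(1), 1)
  cat("PfamReferenceDb with", length(object@profiles), "genomes (",
      paste(sprintf("%s: %d", names(table(sk)), as.integer(table(sk))),
            collapse = ", "), ")\n")
  if (length(object@zeroDomain))
    cat("  zero-domain genomes:", length(object@zeroDomain), "\n")
})

#' ChipResult: outcome of in-silico digital-DNA-chip hybridization
#'
#' @slot calls `DataFrame` with `probe_id`, `hit_count`, `positive`.
#' @slot layout integer vector `c(rows, cols)` of the display grid; probes
#'   fill the grid row-major in input order, trailing cells are blank.
#' @slot params list: `min_hits`, `max_mismatches`, `n_reads`.
#' @export
setClass("ChipResult", representation(
  calls  = "DataFrame",
  layout = "integer",
  params = "list"))

setValidity("ChipResult", function(object) {
  if (nrow(object@calls) == 0) return(TRUE)
  if (prod(object@layout) < nrow(object@calls))
    return("layout smaller than probe count")
  mh <- object@params$min_hits %||% 1
  if (!all(object@calls$positive == (object@calls$hit_count >= mh)))
    return("positive flag inconsistent with min_hits")
  TRUE
})

#' @describeIn ChipResult-class per-probe hit table
#' @param x,object A `ChipResult`.
#' @export
chipCalls <- function(x) x@calls

#' @describeIn ChipResult-class grid dimensions `c(rows, cols)`
#' @export
chipLayout <- function(x) x@layout

setMethod("show", "ChipResult", function(object) {
  cat("ChipResult:", nrow(object@calls), "probes on a",
      paste(object@layout, collapse = " x "), "grid;",
      sum(object@calls$positive), "positive\n")
})
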