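# Readers and writers for the tabular and sequence formats the pipeline
# exchanges: sample metadata TSV, pre-digested alignment TSV or SAM,
# contig FASTA/TSV, abundance TSV, and FASTA/FASTQ reads.

#' Read sample metadata
#'
#' TSV with header columns `sample_id`, `station`, `date` (ISO-8601),
#' `depth_layer`, `filter_fraction`, `water_volume_L`, `total_dna_ng`,
#' `total_reads`. The DNA mass is converted from nanograms to grams
#' (`total_dna_g`), the unit the copy-number conversion uses.
#'
#' @param path TSV file.
#' @return data.frame with a `total_dna_g` column added.
#' @export
readSampleMeta <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "date", "water_volume_L", "total_dna_ng",
            "total_reads")
  if (!all(need %in% names(df)))
    stop("sample metadata needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id")
  df$date <- as.Date(df$date)
  df$total_dna_g <- df$total_dna_ng * 1e-9
  df
}

#' Read pre-digested per-read alignments
#'
#' TSV with header `read_id`, `contig_id`, `sample_id`, `identity`
#' (fraction in `[0,1]`).
#'
#' @param path TSV file.
#' @return data.frame ready for [filterAlignments()].
#' @export
readAlignmentsTSV <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "contig_id", "sample_id", "identity")
  if (!all(need %in% names(df)))
    stop("alignment table needs columns: ", paste(need, collapse = ", "))
  df
}

#' Read per-read alignments from SAM/BAM
#'
#' Primary mapped records are extracted with their `NM` tag; identity is
#' computed as `1 - NM / aligned_length`, with the aligned length taken
#' from the CIGAR `M/I/D/=/X` operations (the edit-distance
#' denominator).
#'
#' @param path SAM or BAM file.
#' @param sample_id Sample the file belongs to.
#' @return data.frame `read_id`, `contig_id`, `sample_id`, `identity`.
#' @export
readAlignmentsSAM <- function(path, sample_id) {
  if (grepl("\\.sam$", path)) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(),
                            overwrite = TRUE, indexDestination = FALSE)
  } else bam <- path
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "cigar", "flag"), tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  nm <- x$tag$NM
  if (is.null(nm)) stop("SAM records lack the NM tag")
  alnLen <- vapply(x$cigar, cigarAlnLen, numeric(1), USE.NAMES = FALSE)
  data.frame(read_id = x$qname,
             contig_id = as.character(x$rname),
             sample_id = sample_id,
             identity = pmax(0, 1 - nm / alnLen))
}

cigarAlnLen <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.numeric(sub("[A-Z=]$", "", toks))
  kinds <- sub("^\\d+", "", toks)
  sum(lens[kinds %in% c("M", "I", "D", "=", "X")])
}

#' Read contig records from FASTA or TSV
#'
#' FASTA lengths are measured from the sequences; a TSV must have
#' columns `contig_id`, `length_bp`.
#'
#' @param path FASTA (`.fa`, `.fasta`, possibly gzipped) or TSV file.
#' @return data.frame `contig_id`, `length_bp`.
#' @export
readContigs <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, ">")) {
    ss <- Biostrings::readDNAStringSet(path)
    id <- sub("\\s.*$", "", names(ss))
    return(data.frame(contig_id = id, length_bp = Biostrings::width(ss)))
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("contig_id", "length_bp") %in% names(df)))
    stop("contig TSV needs columns contig_id, length_bp")
  df
}

#' Read sequencing reads from FASTA or FASTQ
#'
#' @param path Reads file (gzip allowed); format detected from the first
#'   character (`@` = FASTQ, `>` = FASTA).
#' @return Named character vector of sequences.
#' @export
readReads <- function(path) {
  con <- gzfile(path, "rt"); first <- readLines(con, n = 1); close(con)
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write reads as FASTA or FASTQ
#'
#' @param reads Named character vector of sequences.
#' @param path Destination; `.fastq`/`.fq` suffix selects FASTQ (with a
#'   constant `I` quality line), anything else FASTA.
#' @return The path, invisibly.
#' @export
writeReads <- function(reads, path) {
  if (grepl("\\.f(ast)?q$", path)) {
    lines <- as.vector(rbind(paste0("@", names(reads)),
                             unname(reads),
                             "+",
                             strrep("I", nchar(reads))))
    writeLines(lines, path)
  } else {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(reads), path)
  }
  invisible(path)
}

#' Write / read an abundance matrix as TSV
#'
#' Rows are contigs, columns samples; the first column holds contig
#' ids. A sidecar JSON of build parameters is written alongside when
#' the matrix carries them.
#'
#' @param x An [AbundanceMatrix-class] or plain matrix.
#' @param path Destination TSV.
#' @param sidecar Write `<path>.params.json` with build parameters.
#' @return The path, invisibly.
#' @export
writeAbundance <- function(x, path, sidecar = TRUE) {
  m <- if (is(x, "AbundanceMatrix")) cplAssay(x) else as.matrix(x)
  df <- data.frame(contig_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (sidecar && is(x, "AbundanceMatrix")) {
    p <- metadata(x)$params
    if (length(p))
      jsonlite::write_json(p, paste0(path, ".params.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname writeAbundance
#' @export
readAbundance <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
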