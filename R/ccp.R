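# Classification by clustering with Pfam (CCP): a MAG is annotated with
# the reference genome whose Pfam domain-count profile has the highest
# Pearson correlation with the MAG's aggregated profile. Correlations
# are computed over the union of accessions present in either profile,
# with zeros for absences.

#' Read Pfam domain hits from pfam_scan-style or simplified tables
#'
#' Accepts either the whitespace-delimited `pfam_scan.pl` output
#' (comment lines starting with `#` ignored; sequence id in column 1,
#' HMM accession in column 6, version suffix stripped) or a two-plus
#' column TSV with a header naming `seq_id` and `pfam_accession`.
#'
#' @param path File to read.
#' @return data.frame with columns `seq_id`, `accession`.
#' @export
readPfamHits <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(seq_id = character(), accession = character()))
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (any(c("seq_id", "pfam_accession") %in% first)) {
    df <- read.delim(textConnection(lines), sep = "\t",
                     stringsAsFactors = FALSE)
    need <- c("seq_id", "pfam_accession")
    if (!all(need %in% names(df)))
      stop("simplified hit table needs columns: ",
           paste(need, collapse = ", "))
    return(data.frame(seq_id = as.character(df$seq_id),
                      accession = sub("\\.\\d+$", "", df$pfam_accession)))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(fields) < 6)
  if (length(bad))
    stop("malformed pfam_scan row at line ", bad[1],
         ": fewer than 6 fields")
  data.frame(
    seq_id = vapply(fields, `[`, character(1), 1),
    accession = sub("\\.\\d+$", "", vapply(fields, `[`, character(1), 6)))
}

# hits (seq_id, accession) -> named integer count vector
tallyDomains <- function(accessions) {
  if (!length(accessions)) return(setNames(integer(0), character(0)))
  tab <- table(as.character(accessions))
  setNames(as.integer(tab), names(tab))[order(names(tab))]
}

#' Build a CCP reference database of per-genome Pfam profiles
#'
#' Counts each Pfam accession over all of a genome's sequences. Multiple
#' hit tables for one genome are summed. Genomes with zero hits are
#' retained but flagged (`@zeroDomain`); they can never win a
#' classification.
#'
#' @param hits data.frame with columns `genome_id`, `accession` (e.g. the
#'   output of [readPfamHits()] with `seq_id` renamed/mapped to its
#'   genome), or a named list of such data.frames.
#' @param taxonomy data.frame `genome_id`, `lineage` (semicolon-delimited,
#'   superkingdom first). Every genome in `hits` must have a lineage;
#'   genomes present only in `taxonomy` get empty (zero-domain) profiles.
#' @return A [PfamReferenceDb-class].
#' @export
buildReferenceDb <- function(hits, taxonomy) {
  if (is.list(hits) && !is.data.frame(hits))
    hits <- do.call(rbind, hits)
  stopifnot(all(c("genome_id", "accession") %in% names(hits)),
            all(c("genome_id", "lineage") %in% names(taxonomy)))
  if (anyDuplicated(taxonomy$genome_id)) stop("duplicate genome_id in taxonomy")
  orphan <- setdiff(unique(hits$genome_id), taxonomy$genome_id)
  if (length(orphan))
    stop("genomes without taxonomy: ", paste(orphan, collapse = ", "))
  ids <- as.character(taxonomy$genome_id)
  profs <- lapply(ids, function(g)
    tallyDomains(hits$accession[hits$genome_id == g]))
  names(profs) <- ids
  zero <- ids[lengths(profs) == 0]
  new("PfamReferenceDb",
      profiles = profs,
      lineage = setNames(as.character(taxonomy$lineage), ids),
      zeroDomain = zero)
}

#' Save / load a CCP reference database as a portable JSON archive
#'
#' The archive stores, per genome, the lineage and the accession -> count
#' map; reloading reproduces the database exactly.
#'
#' @param db A [PfamReferenceDb-class].
#' @param path Destination / source file.
#' @return `loadReferenceDb` returns the [PfamReferenceDb-class].
#' @export
saveReferenceDb <- function(db, path) {
  obj <- list(
    format = "ccp-refdb", version = 1L,
    genomes = lapply(names(db@profiles), function(g) {
      p <- db@profiles[[g]]
      list(genome_id = g, lineage = unname(db@lineage[[g]]),
           domains = as.list(setNames(as.integer(p), names(p))))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname saveReferenceDb
#' @export
loadReferenceDb <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "ccp-refdb"))
    stop("not a CCP reference database archive: ", path)
  ids <- vapply(obj$genomes, `[[`, character(1), "genome_id")
  profs <- lapply(obj$genomes, function(g) {
    d <- unlist(g$domains)
    if (is.null(d)) return(setNames(integer(0), character(0)))
    setNames(as.integer(d), names(d))[order(names(d))]
  })
  names(profs) <- ids
  new("PfamReferenceDb",
      profiles = profs,
      lineage = setNames(vapply(obj$genomes, `[[`, character(1), "lineage"),
                         ids),
      zeroDomain = ids[lengths(profs) == 0])
}

#' Aggregate per-contig Pfam hits into one MAG profile
#'
#' Domain counts are summed over all member contigs; contigs with no
#' hits contribute nothing (missing contigs are fine and simply add no
#' counts).
#'
#' @param hits data.frame `seq_id` (contig id), `accession`.
#' @param contig_ids Character vector of the MAG's member contig ids.
#' @return Named integer vector: accession -> count.
#' @export
aggregateMagProfile <- function(hits, contig_ids) {
  if (!length(contig_ids)) stop("MAG has no member contigs")
  tallyDomains(hits$accession[hits$seq_id %in% contig_ids])
}

# Pearson correlation of two sparse count profiles over the union of
# their accessions (absent = 0). NA when undefined (either side flat).
unionCorrelation <- function(q, r) {
  keys <- union(names(q), names(r))
  if (length(keys) < 2) return(NA_real_)
  x <- unname(ifelse(is.na(q[keys]), 0, q[keys]))
  y <- unname(ifelse(is.na(r[keys]), 0, r[keys]))
  profileCorrelation(as.numeric(x), as.numeric(y))
}

#' Classify one query Pfam profile against the CCP reference database
#'
#' For every reference genome the Pearson correlation between query and
#' reference count vectors is computed over the union of Pfam accessions
#' present in either profile (absences count as zero). The genome with
#' the highest defined correlation wins; exact ties are broken by the
#' larger number of shared accessions, then by lexicographic genome id.
#' The query is `"unclassified"` when it carries fewer than
#' `min_domains` total domain instances or no reference yields a defined
#' correlation.
#'
#' @param query Named integer vector (accession -> count).
#' @param db A [PfamReferenceDb-class].
#' @param min_domains Minimum total domain instances required (default 5).
#' @param top_k How many runners-up to report (default 5).
#' @param binary Correlate presence/absence (0/1) instead of counts.
#' @return A list with `best_genome_id`, `r_best`, `lineage`,
#'   `n_domains_used`, and `runners_up` (data.frame `genome_id`, `r`).
#' @export
ccpClassify <- function(query, db, min_domains = 5, top_k = 5,
                        binary = FALSE) {
  if (!length(db@profiles)) stop("empty reference database")
  nDom <- sum(query)
  unclass <- list(best_genome_id = "unclassified", r_best = NA_real_,
                  lineage = NA_character_, n_domains_used = as.integer(nDom),
                  runners_up = data.frame(genome_id = character(),
                                          r = numeric()))
  if (nDom < min_domains) return(unclass)
  q <- if (binary) setNames(rep(1L, length(query)), names(query)) else query
  rs <- vapply(db@profiles, function(p) {
    p2 <- if (binary) setNames(rep(1L, length(p)), names(p)) else p
    unionCorrelation(q, p2)
  }, numeric(1))
  if (all(is.na(rs))) return(unclass)
  shared <- vapply(db@profiles, function(p)
    length(intersect(names(query), names(p))), integer(1))
  ids <- names(db@profiles)
  ord <- order(-rs, -shared, ids, na.last = TRUE)
  ord <- ord[!is.na(rs[ord])]
  best <- ids[ord[1]]
  ru <- ord[seq_len(min(top_k, length(ord) - 1)) + 1]
  list(best_genome_id = best,
       r_best = unname(rs[ord[1]]),
       lineage = unname(db@lineage[best]),
       n_domains_used = as.integer(nDom),
       runners_up = data.frame(genome_id = ids[ru],
                               r = unname(rs[ru])))
}

#' Classify many MAG profiles at once
#'
#' @param profiles Named list of query profiles (MAG id -> named counts).
#' @inheritParams ccpClassify
#' @return data.frame `mag_id`, `best_genome_id`, `r_best`, `lineage`,
#'   `n_domains_used`.
#' @export
ccpClassifyAll <- function(profiles, db, min_domains = 5, top_k = 5,
                           binary = FALSE) {
  rows <- lapply(names(profiles), function(id) {
    a <- ccpClassify(profiles[[id]], db, min_domains, top_k, binary)
    data.frame(mag_id = id, best_genome_id = a$best_genome_id,
               r_best = a$r_best, lineage = a$lineage,
               n_domains_used = a$n_domains_used)
  })
  do.call(rbind, rows)
}

#' Agreement between CCP and BLAST annotations at a taxonomy rank
#'
#' Restricted to MAGs annotated by both methods (CCP not
#' `"unclassified"`, BLAST assignment present and non-empty). At rank
#' `"virus"` the comparison is the binary label virus vs cellular
#' (superkingdom `Viruses` or not); otherwise the lineage element at the
#' requested depth is compared (1 = superkingdom).
#'
#' @param ccp data.frame `mag_id`, `best_genome_id`, `lineage` as from
#'   [ccpClassifyAll()].
#' @param blast data.frame `mag_id`, `lineage`.
#' @param rank `"virus"`, `"superkingdom"`, or an integer lineage depth.
#' @return list: `agreement` (fraction in `[0,1]`), `n_compared`, and
#'   `table` (CCP x BLAST contingency table of the compared labels).
#' @export
annotationAgreement <- function(ccp, blast, rank = "superkingdom") {
  both <- merge(ccp[ccp$best_genome_id != "unclassified" & !is.na(ccp$lineage),
                    c("mag_id", "lineage")],
                blast[!is.na(blast$lineage) & nzchar(blast$lineage),
                      c("mag_id", "lineage")],
                by = "mag_id", suffixes = c("_ccp", "_blast"))
  if (!nrow(both)) stop("no co-annotated MAGs")
  labelAt <- function(lin) {
    parts <- splitLineage(lin)
    if (identical(rank, "virus"))
      return(ifelse(vapply(parts, `[`, character(1), 1) == "Viruses",
                    "virus", "cellular"))
    depth <- if (identical(rank, "superkingdom")) 1L else as.integer(rank)
    vapply(parts, function(p)
      if (length(p) >= depth) p[depth] else NA_character_, character(1))
  }
  a <- labelAt(both$lineage_ccp)
  b <- labelAt(both$lineage_blast)
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) stop("no co-annotated MAGs resolve at this rank")
  list(agreement = mean(a[keep] == b[keep]),
       n_compared = sum(keep),
       table = table(CCP = a[keep], BLAST = b[keep]))
}
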