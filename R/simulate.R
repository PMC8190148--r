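# Seeded generators for every input the pipeline consumes, with ground
# truth, so the whole analysis is testable offline. All generators are
# bit-deterministic given their seed (R's default Mersenne Twister).

# lognormal multiplicative noise with mean 1 and the given coefficient
# of variation
lnormNoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

randomRead <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate reads with planted tandem repeats
#'
#' Exactly `round(repeat_fraction * n_reads)` reads carry a planted run
#' of the stated unit class covering strictly more than
#' `threshold_bp_per_100`% of the read; the remaining reads are uniform
#' random sequence, rejection-sampled until they contain no qualifying
#' run of any 2-10 bp class. The truth table records each read's
#' planted class, so a scanner run over the output must reproduce the
#' planted fraction exactly.
#'
#' @param n_reads Number of reads (default 1000).
#' @param read_length Read length in bp (default 100, the platform's).
#' @param repeat_fraction Planted fraction of repeat reads in `[0, 1]`.
#' @param unit Repeat unit of the planted class (default `"TAG"`).
#' @param threshold_bp_per_100 The repeat-read rule the plant must beat
#'   (default 70).
#' @param seed Integer seed.
#' @return list: `reads` (named character vector), `truth` (data.frame
#'   `read_id`, `is_repeat_read`, `unit_class`).
#' @export
simulateRepeatReads <- function(n_reads = 1000, read_length = 100,
                                repeat_fraction = 0.05, unit = "TAG",
                                threshold_bp_per_100 = 70, seed = 1) {
  stopifnot(repeat_fraction >= 0, repeat_fraction <= 1, n_reads >= 1)
  set.seed(seed)
  k <- nchar(unit)
  canon <- canonicalUnit(unit)
  nRep <- round(repeat_fraction * n_reads)
  whichRep <- sort(sample(n_reads, nRep))
  minRun <- floor(threshold_bp_per_100 * read_length / 100) + 1L
  reads <- character(n_reads)
  for (i in seq_len(n_reads)) {
    if (i %in% whichRep) {
      repeat {
        runLen <- sample(minRun:read_length, 1)
        offset <- sample(0:(read_length - runLen), 1)
        phase <- sample(0:(k - 1), 1)
        run <- substr(strrep(unit, ceiling((runLen + phase) / k) + 1),
                      phase + 1, phase + runLen)
        left <- if (offset > 0) randomRead(offset) else ""
        right <- if (read_length - offset - runLen > 0)
          randomRead(read_length - offset - runLen) else ""
        rd <- paste0(left, run, right)
        cl <- classifyReadRepeat(rd, threshold_bp_per_100 = threshold_bp_per_100)
        if (cl$is_repeat_read && identical(cl$best_unit, canon)) break
      }
    } else {
      repeat {
        rd <- randomRead(read_length)
        cl <- classifyReadRepeat(rd, threshold_bp_per_100 = threshold_bp_per_100)
        if (!cl$is_repeat_read) break
      }
    }
    reads[i] <- rd
  }
  ids <- sprintf("read_%05d", seq_len(n_reads))
  names(reads) <- ids
  list(reads = reads,
       truth = data.frame(read_id = ids,
                          is_repeat_read = seq_len(n_reads) %in% whichRep,
                          unit_class = ifelse(seq_len(n_reads) %in% whichRep,
                                              canon, NA_character_)))
}

# one archetype template over monthly time points; peak months relative
# to the series start
patternTemplate <- function(archetype, n_months, phase, second_pulse = NULL) {
  t <- seq_len(n_months) - 1
  gauss <- function(mu) exp(-(t - mu)^2 / (2 * 1.2^2))
  switch(archetype,
    complete = 0.02 + pmax(cos(2 * pi * (t - phase) / 12), 0)^3,
    incomplete = {
      # cycles in the first two years, missing the final year's peak
      y <- 0.02 + pmax(cos(2 * pi * (t - phase) / 12), 0)^3
      last <- phase + 24
      y[t >= last - 2 & t <= last + 2] <- 0.02
      y
    },
    transient = 0.02 + gauss(phase),
    irregular = 0.02 + gauss(phase) +
      0.8 * gauss(second_pulse %||% (phase + 7)),
    stop("unknown archetype: ", archetype))
}

# a second pulse month inside the series, >= 5 months from the first
# and outside the 12 +/- 1 month recurrence window
drawSecondPulse <- function(phase, n_months) {
  cand <- 0:(n_months - 1)
  d <- abs(cand - phase)
  cand <- cand[d >= 5 & !(d >= 11 & d <= 13)]
  if (!length(cand)) stop("series too short for two unrelated pulses")
  if (length(cand) == 1) cand else sample(cand, 1)
}

#' Simulate a monthly community time series with planted MAG structure
#'
#' Each planted MAG gets a temporal template drawn from the four
#' archetypes (12-month cycle; cycle with one suppressed year; single
#' pulse; two unrelated pulses), with phases chosen so templates of
#' different MAGs correlate below 0.8 (redrawn deterministically
#' otherwise). Each member contig's profile is the template times a
#' contig-specific positive scale (lognormal, sdlog 1) times
#' per-time-point lognormal noise at the stated coefficient of
#' variation. Sample metadata (monthly dates, volumes, DNA masses, read
#' totals) is generated alongside, and the truth holds membership and
#' per-MAG archetype.
#'
#' @param n_contigs,n_mags,n_samples Community dimensions (defaults
#'   500 contigs, 20 MAGs, 25 monthly samples).
#' @param cv Lognormal noise coefficient of variation (default 0.1).
#' @param seed Integer seed.
#' @param start_date First sampling date (mid-month).
#' @return list: `abundance` (contig x sample matrix), `samples`
#'   (metadata data.frame), `contigs` (`contig_id`, `length_bp`),
#'   `truth` (`contig_id`, `mag_id`), `mag_truth` (`mag_id`,
#'   `archetype`), `dates`.
#' @export
simulateCommunityTimeSeries <- function(n_contigs = 500, n_mags = 20,
                                        n_samples = 25, cv = 0.1,
                                        seed = 1,
                                        start_date = "2012-03-15") {
  stopifnot(n_mags <= n_contigs, n_samples >= 4)
  set.seed(seed)
  archetypes <- rep(c("complete", "incomplete", "transient", "irregular"),
                    length.out = n_mags)
  # Each MAG template = archetype shape + a MAG-specific additive
  # fingerprint (exponential monthly jitter), which keeps within-MAG
  # profiles perfectly correlated while decorrelating MAGs that share an
  # archetype and phase. Up to 20 seeded redraws aim for pairwise
  # template correlation < 0.8; the most separated draw is kept.
  templates <- matrix(0, n_mags, n_samples)
  for (i in seq_len(n_mags)) {
    best <- NULL; bestR <- Inf
    for (try in 1:20) {
      phase <- sample(0:min(11, max(0, n_samples - 6)), 1)
      second <- drawSecondPulse(phase, n_samples)
      tmpl <- patternTemplate(archetypes[i], n_samples, phase, second) +
        0.3 * rexp(n_samples)
      rmax <- if (i == 1) -Inf else
        max(apply(templates[seq_len(i - 1), , drop = FALSE], 1,
                  function(x) abs(profileCorrelation(x, tmpl) %|NA|% 0)))
      if (rmax < bestR) { bestR <- rmax; best <- tmpl }
      if (rmax < 0.8) break
    }
    templates[i, ] <- best
  }
  membership <- sort(rep(seq_len(n_mags), length.out = n_contigs))
  scale <- rlnorm(n_contigs, meanlog = 2, sdlog = 1)
  abundance <- templates[membership, , drop = FALSE] * scale *
    matrix(lnormNoise(n_contigs * n_samples, cv), n_contigs, n_samples)
  contig_id <- sprintf("contig_%04d", seq_len(n_contigs))
  rownames(abundance) <- contig_id
  dates <- seq(as.Date(start_date), by = "month", length.out = n_samples)
  sample_id <- sprintf("S%03d", seq_len(n_samples))
  colnames(abundance) <- sample_id
  samples <- data.frame(
    sample_id = sample_id, station = "C5",
    date = dates, depth_layer = "SUF", filter_fraction = "0.2-0.8",
    water_volume_L = 9, total_dna_g = 50e-9,
    total_reads = 1e7)
  list(abundance = abundance, samples = samples,
       contigs = data.frame(contig_id = contig_id,
                            length_bp = sample(1000:50000, n_contigs,
                                               replace = TRUE)),
       truth = data.frame(contig_id = contig_id,
                          mag_id = sprintf("true_%02d", membership)),
       mag_truth = data.frame(mag_id = sprintf("true_%02d", seq_len(n_mags)),
                              archetype = archetypes),
       dates = dates)
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a

#' Simulate a Pfam reference database and thinned query profiles
#'
#' Reference profiles are sparse multinomial counts over a shared domain
#' vocabulary (per-genome Dirichlet(1) concentrations over a random
#' support). Each query is a binomial thinning (at `retention`) of one
#' reference's domain instances, plus contamination instances drawn
#' uniformly from the vocabulary at rate `contamination` of the thinned
#' total. The truth maps each query to its source genome.
#'
#' @param n_refs,n_domains Database dimensions (defaults 50 genomes,
#'   100 domain types).
#' @param n_queries Number of query profiles (default 200).
#' @param retention Binomial retention probability (default 0.5).
#' @param contamination Contaminant instances per retained instance
#'   (default 0.02).
#' @param seed Integer seed.
#' @return list: `db` ([PfamReferenceDb-class]), `queries` (named list
#'   of profiles), `truth` (data.frame `query_id`, `genome_id`).
#' @export
simulatePfamProfiles <- function(n_refs = 50, n_domains = 100,
                                 n_queries = 200, retention = 0.5,
                                 contamination = 0.02, seed = 1) {
  stopifnot(n_refs >= 2, n_domains >= 20, retention > 0, retention <= 1)
  set.seed(seed)
  vocab <- sprintf("PF%05d", seq_len(n_domains))
  sk <- c("Viruses", "Bacteria", "Archaea", "Eukaryota")
  ids <- sprintf("genome_%03d", seq_len(n_refs))
  profs <- vector("list", n_refs)
  lo <- max(5L, as.integer(round(0.3 * n_domains)))
  hi <- min(n_domains, max(lo + 1L, as.integer(round(0.7 * n_domains))))
  for (i in seq_len(n_refs)) {
    support <- sort(sample(n_domains, sample(lo:hi, 1)))
    p <- rgamma(length(support), 1)
    total <- sample(300:800, 1)
    cnt <- as.integer(rmultinom(1, total, p / sum(p)))
    keep <- cnt > 0
    profs[[i]] <- setNames(cnt[keep], vocab[support][keep])
    profs[[i]] <- profs[[i]][order(names(profs[[i]]))]
  }
  names(profs) <- ids
  lin <- setNames(sprintf("%s;Phylum_%02d;Genus_%03d;%s",
                          sk[(seq_len(n_refs) - 1) %% 4 + 1],
                          (seq_len(n_refs) - 1) %% 10 + 1,
                          seq_len(n_refs), ids), ids)
  db <- new("PfamReferenceDb", profiles = profs, lineage = lin,
            zeroDomain = character(0))
  src <- ids[(seq_len(n_queries) - 1) %% n_refs + 1]
  queries <- vector("list", n_queries)
  for (q in seq_len(n_queries)) {
    ref <- profs[[src[q]]]
    thin <- rbinom(length(ref), ref, retention)
    names(thin) <- names(ref)
    nContam <- rbinom(1, sum(thin), contamination)
    if (nContam > 0) {
      extra <- table(sample(vocab, nContam, replace = TRUE))
      thin[names(extra)] <- ifelse(is.na(thin[names(extra)]), 0,
                                   thin[names(extra)]) + as.integer(extra)
    }
    thin <- thin[thin > 0]
    queries[[q]] <- setNames(as.integer(thin), names(thin))
    queries[[q]] <- queries[[q]][order(names(queries[[q]]))]
  }
  qid <- sprintf("query_%03d", seq_len(n_queries))
  names(queries) <- qid
  list(db = db, queries = queries,
       truth = data.frame(query_id = qid, genome_id = src))
}

#' Simulate a bank of abundance series with planted temporal archetypes
#'
#' For each of the four archetypes (complete cyclic, incomplete cyclic,
#' transient, irregular), `n_per_class` monthly series are generated
#' over `n_months` with multiplicative lognormal noise at the stated
#' coefficient of variation. Cyclic archetypes are anchored near the
#' series start (phase 0-1), mirroring spring-bloom cyclers observed in
#' series that begin at a bloom: a 25-month window can only witness the
#' third annual peak when the cycle is start-aligned. Transient and
#' irregular phases are free.
#'
#' @param n_per_class Series per archetype (default 25).
#' @param n_months Series length in months (default 25).
#' @param cv Noise coefficient of variation (default 0.1).
#' @param seed Integer seed.
#' @param start_date First sampling date.
#' @return list: `series` (matrix, one row per series), `dates`, `truth`
#'   (data.frame `series_id`, `archetype`, `expected_class`).
#' @export
simulatePatternBank <- function(n_per_class = 25, n_months = 25, cv = 0.1,
                                seed = 1, start_date = "2012-03-15") {
  set.seed(seed)
  arch <- c("complete", "incomplete", "transient", "irregular")
  expected <- c(complete = "COMPLETE_CYCLIC",
                incomplete = "INCOMPLETE_CYCLIC",
                transient = "TRANSIENT", irregular = "IRREGULAR")
  n <- 4 * n_per_class
  series <- matrix(0, n, n_months)
  truth <- data.frame(series_id = sprintf("ts_%03d", seq_len(n)),
                      archetype = rep(arch, each = n_per_class),
                      expected_class = rep(unname(expected[arch]),
                                           each = n_per_class))
  for (i in seq_len(n)) {
    a <- truth$archetype[i]
    # the incomplete plant's missing third peak must fall inside the
    # window, or the truncation is indistinguishable from a complete
    # cycle; complete plants may be bloom-anchored at phase 0 or 1
    phase <- if (a == "incomplete") sample(0:max(0, n_months - 25), 1)
             else if (a == "complete") sample(0:1, 1)
             else sample(0:min(11, max(0, n_months - 6)), 1)
    second <- drawSecondPulse(phase, n_months)
    series[i, ] <- patternTemplate(a, n_months, phase, second) *
      lnormNoise(n_months, cv)
  }
  rownames(series) <- truth$series_id
  list(series = series,
       dates = seq(as.Date(start_date), by = "month",
                   length.out = n_months),
       truth = truth)
}
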