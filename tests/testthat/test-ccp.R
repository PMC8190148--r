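test_that("reference profiles count domain hits per genome", {
  hits <- data.frame(genome_id = c("g1", "g1", "g1", "g2"),
                     accession = c("PF00001", "PF00001", "PF00002",
                                   "PF00009"))
  tax <- data.frame(genome_id = c("g1", "g2", "g3"),
                    lineage = c("Bacteria;Proteo;X", "Viruses;Caudo;Y",
                                "Archaea;Eury;Z"))
  db <- buildReferenceDb(hits, tax)
  expect_equal(refProfile(db, "g1"),
               c(PF00001 = 2L, PF00002 = 1L))
  expect_equal(sum(refProfile(db, "g1")), 3)
  # genome with no hits retained but flagged
  expect_equal(db@zeroDomain, "g3")
  # two tables for one genome -> summed counts (concatenation oracle)
  db2 <- buildReferenceDb(rbind(hits, hits), tax)
  expect_equal(refProfile(db2, "g1"), 2L * refProfile(db, "g1"))
  expect_error(buildReferenceDb(
    data.frame(genome_id = "gX", accession = "PF1"), tax), "gX")
})

test_that("database archive round-trips bit-identically", {
  sim <- simulatePfamProfiles(n_refs = 5, n_domains = 30, n_queries = 2,
                              seed = 3)
  f <- tempfile(fileext = ".json")
  saveReferenceDb(sim$db, f)
  db2 <- loadReferenceDb(f)
  expect_identical(db2@profiles, sim$db@profiles)
  expect_identical(db2@lineage, sim$db@lineage)
  f2 <- tempfile(fileext = ".json")
  saveReferenceDb(db2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("MAG profiles sum member contig hits", {
  hits <- data.frame(seq_id = c("c1", "c2", "c2", "c2"),
                     accession = c("PF1", "PF1", "PF1", "PF2"))
  expect_equal(aggregateMagProfile(hits, c("c1", "c2")),
               c(PF1 = 3L, PF2 = 1L))
  expect_equal(aggregateMagProfile(hits, "c2"), c(PF1 = 2L, PF2 = 1L))
  # hit-less members contribute nothing; a fully hit-less MAG is empty
  expect_equal(length(aggregateMagProfile(hits, "c9")), 0)
  expect_error(aggregateMagProfile(hits, character(0)), "no member")
})

test_that("classification picks the profile with highest union Pearson", {
  db <- new("PfamReferenceDb",
            profiles = list(A = c(PF1 = 10L, PF3 = 5L),
                            B = c(PF2 = 8L, PF3 = 2L)),
            lineage = c(A = "Bacteria;X", B = "Viruses;Y"),
            zeroDomain = character(0))
  q <- c(PF1 = 9L, PF2 = 1L, PF3 = 4L)
  got <- ccpClassify(q, db)
  # brute-force dense oracle over the union vocabulary
  oracle <- oracleCcpBest(q, db@profiles)
  expect_identical(got$best_genome_id, oracle$best)
  expect_identical(got$best_genome_id, "A")
  expect_equal(got$r_best, oracle$r)
  expect_identical(got$lineage, "Bacteria;X")
  # self-match is exact
  self <- ccpClassify(refProfile(db, "B"), db, min_domains = 1)
  expect_identical(self$best_genome_id, "B")
  expect_equal(self$r_best, 1.0)
  # scale invariance of the assignment and the coefficient
  scaled <- ccpClassify(q * 10L, db)
  expect_identical(scaled$best_genome_id, got$best_genome_id)
  expect_equal(scaled$r_best, got$r_best)
})

test_that("union correlation equals dense brute force on random profiles", {
  sim <- simulatePfamProfiles(n_refs = 8, n_domains = 40, n_queries = 20,
                              seed = 17)
  for (q in sim$queries) {
    got <- ccpClassify(q, sim$db, min_domains = 1)
    oracle <- oracleCcpBest(q, sim$db@profiles)
    expect_identical(got$best_genome_id, oracle$best)
    expect_equal(got$r_best, oracle$r)
  }
})

test_that("sparse queries and forced ties follow the documented rules", {
  db <- new("PfamReferenceDb",
            profiles = list(A = c(PF1 = 5L, PF2 = 3L),
                            B = c(PF1 = 5L, PF2 = 3L)),
            lineage = c(A = "Bacteria;X", B = "Bacteria;Y"),
            zeroDomain = character(0))
  # below the domain floor -> unclassified
  few <- ccpClassify(c(PF1 = 2L), db, min_domains = 5)
  expect_identical(few$best_genome_id, "unclassified")
  # identical references tie; lexicographically smaller id wins
  tie <- ccpClassify(c(PF1 = 5L, PF2 = 3L), db, min_domains = 1)
  expect_identical(tie$best_genome_id, "A")
  expect_error(ccpClassify(c(PF1 = 9L),
                           new("PfamReferenceDb", profiles = list(),
                               lineage = character(0),
                               zeroDomain = character(0))),
               "empty")
})

test_that("every reference classifies to itself with r = 1", {
  sim <- simulatePfamProfiles(n_refs = 20, n_domains = 60, n_queries = 2,
                              seed = 23)
  res <- ccpClassifyAll(sim$db@profiles, sim$db)
  expect_identical(res$best_genome_id, refGenomeIds(sim$db))
  expect_true(all(abs(res$r_best - 1) < 1e-12))
})

test_that("binomially thinned queries recover their source genome", {
  sim <- simulatePfamProfiles(n_refs = 25, n_domains = 100,
                              n_queries = 60, retention = 0.5, seed = 31)
  res <- ccpClassifyAll(sim$queries, sim$db)
  expect_gte(mean(res$best_genome_id == sim$truth$genome_id), 0.95)
})

test_that("annotation agreement compares only co-annotated MAGs", {
  ccp <- data.frame(mag_id = c("m1", "m2", "m3", "m4", "m5"),
                    best_genome_id = c("g", "g", "g", "g", "unclassified"),
                    lineage = c("Bacteria;X", "Viruses;Y", "Bacteria;Z",
                                "Archaea;W", "Bacteria;Q"))
  blast <- data.frame(mag_id = c("m1", "m2", "m3", "m4"),
                      lineage = c("Bacteria;P", "Viruses;Y",
                                  "Bacteria;Z", "Eukaryota;V"))
  out <- annotationAgreement(ccp, blast, rank = "superkingdom")
  expect_equal(out$n_compared, 4)   # m5 is CCP-unclassified
  expect_equal(out$agreement, 0.75) # m4 disagrees
  # virus-level mode is a binary comparison
  vir <- annotationAgreement(ccp, blast, rank = "virus")
  expect_equal(vir$agreement, 1.0)
  expect_identical(annotationAgreement(ccp, ccp[1:4, c("mag_id", "lineage")],
                                       rank = "superkingdom")$agreement, 1)
  expect_error(annotationAgreement(ccp[5, ], blast), "no co-annotated")
})

test_that("pfam_scan-style and simplified hit tables parse identically", {
  f1 <- tempfile(); f2 <- tempfile()
  writeLines(c("# pfam_scan.pl output",
               "c1  1 90  1 92 PF00001.21 His_kinase Domain 1 88 90 150.2 1e-40 1",
               "c1 95 180 93 181 PF00072.12 Resp_reg  Domain 1 110 112 99.1 1e-25 1"),
             f1)
  writeLines(c("seq_id\tpfam_accession",
               "c1\tPF00001.21", "c1\tPF00072.12"), f2)
  expect_identical(readPfamHits(f1), readPfamHits(f2))
  expect_identical(readPfamHits(f2)$accession, c("PF00001", "PF00072"))
})
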