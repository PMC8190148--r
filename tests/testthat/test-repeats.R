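test_that("maximal primitive runs are found and canonically labelled", {
  # pure trinucleotide repeat: one run, class {AGT, GTA, TAG} -> AGT
  runs <- findRepeatRuns("TAGTAGTAGTAG")
  expect_equal(nrow(runs), 1)
  expect_identical(runs$unit, "AGT")
  expect_equal(runs$length_bp, 12)
  expect_identical(rotationClass("TAG"), c("AGT", "GTA", "TAG"))

  # the 54-nt CTA-repeat hybridization probe: a single maximal
  # trinucleotide run spanning the whole oligo
  probe <- strrep("CTA", 18)
  expect_equal(nchar(probe), 54)
  pr <- findRepeatRuns(probe)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$unit_length, 3)
  expect_equal(pr$length_bp, 54)

  # TATA is (TA)^2: no primitive unit-4 run, reported once at unit 2
  tata <- findRepeatRuns("TATATATA")
  expect_equal(nrow(tata), 1)
  expect_equal(tata$unit_length, 2)
  expect_equal(tata$length_bp, 8)
  tata4 <- findRepeatRuns("TATATATA", unit_lengths = 4)
  expect_equal(nrow(tata4), 0)

  # partial trailing copy counts in whole bases: (GAT)x3 + "GA"
  part <- findRepeatRuns("GATGATGATGA")
  expect_equal(part$length_bp, 11)
  # N breaks runs
  expect_equal(findRepeatRuns("TAGTAGNTAGTAG")$length_bp, c(6, 6))
  expect_equal(nrow(findRepeatRuns("")), 0)
})

test_that("the >70-of-100 rule is strict and scales with read length", {
  rd <- paste0(strrep("TAG", 33), "A")  # 99 of 100 bases
  cl <- classifyReadRepeat(rd)
  expect_true(cl$is_repeat_read)
  expect_identical(cl$best_unit, "AGT")
  expect_equal(cl$repeat_bases, 99)

  # exactly 70 repeat bases: NOT a repeat read
  seventy <- paste0(strrep("AC", 35), "GTGATCGTAGCTAGGTACCTGATCGAGTCA")
  cl70 <- classifyReadRepeat(seventy)
  expect_equal(cl70$repeat_bases, 70)
  expect_false(cl70$is_repeat_read)

  # 50-bp read with 36 repeat bases: 36 > 35 -> repeat read
  rd50 <- paste0(strrep("AC", 18), "GTGATCGTAGCTAG")
  cl50 <- classifyReadRepeat(rd50)
  expect_equal(cl50$read_length, 50)
  expect_equal(cl50$repeat_bases, 36)
  expect_true(cl50$is_repeat_read)

  # mostly-N reads are skipped but still scanned
  nn <- classifyReadRepeat(paste0(strrep("N", 60), strrep("TAG", 13), "A"))
  expect_true(nn$skipped)
  expect_false(nn$is_repeat_read)
})

test_that("appending unit copies never decreases repeat coverage", {
  base <- strrep("GAT", 10)
  prev <- classifyReadRepeat(base)$repeat_bases
  for (i in 1:5) {
    base <- paste0(base, "GAT")
    cur <- classifyReadRepeat(base)$repeat_bases
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("reverse complement maps classes and preserves the call", {
  sim <- simulateRepeatReads(n_reads = 40, repeat_fraction = 0.4,
                             unit = "TAG", seed = 12)
  for (rd in sim$reads) {
    fwd <- classifyReadRepeat(rd)
    rc <- classifyReadRepeat(
      chartr("ACGT", "TGCA",
             paste(rev(strsplit(rd, "")[[1]]), collapse = "")))
    expect_identical(rc$is_repeat_read, fwd$is_repeat_read)
    if (fwd$is_repeat_read)
      expect_identical(rc$best_unit,
                       canonicalUnit(chartr("ACGT", "TGCA",
                                            paste(rev(strsplit(fwd$best_unit,
                                                               "")[[1]]),
                                                  collapse = ""))))
  }
})

test_that("scanner agrees exactly with the brute-force oracle", {
  # random reads plus planted repeat reads of assorted units
  reads <- randomReadSet(120, 100, seed = 77)
  for (u in c("TA", "TAG", "ACA", "GAAT", "CATGA")) {
    sim <- simulateRepeatReads(n_reads = 10, repeat_fraction = 0.8,
                               unit = u, seed = nchar(u))
    reads <- c(reads, unname(sim$reads))
  }
  for (rd in reads) {
    got <- classifyReadRepeat(rd)
    want <- oracleClassifyRead(rd)
    expect_identical(got$is_repeat_read, want$is_repeat_read)
    expect_equal(got$repeat_bases, want$repeat_bases)
    if (got$repeat_bases > 0) expect_identical(got$best_unit, want$best_unit)
  }
})

test_that("sample summaries rank unit classes by repeat-read fraction", {
  sim <- simulateRepeatReads(n_reads = 200, repeat_fraction = 0.075,
                             unit = "TAG", seed = 4)
  calls <- classifyReads(sim$reads)
  rep_ <- summarizeRepeatSample(calls, "sendai_5_20um")
  expect_equal(rep_$fraction[rep_$unit_class == "AGT"], 0.075)
  expect_equal(rep_$repeat_reads[1], 15)
  expect_identical(rep_$rotations[1], "AGT/GTA/TAG")
  expect_error(summarizeRepeatSample(calls[0, ]), "zero reads")
  none <- summarizeRepeatSample(
    classifyReads(c(a = "ACGTACGATCGATTCGAA")), "s")
  expect_equal(nrow(none), 0)
})
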