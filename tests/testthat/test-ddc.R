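probeFixture <- function() {
  data.frame(
    probe_id = c("p_frac_a", "p_frac_b", "p_dec1", "p_dec2", "p_jun",
                 "p_stn"),
    sequence = c("ACGTACGTACGTACGTACGTA", "TTTTGGGGCCCCAAAATTTTG",
                 "GATTACAGATTACAGATTACA", "CCGGAATTCCGGAATTCCGGA",
                 "TGCATGCATGCATGCATGCAT", "AAACCCGGGTTTAAACCCGGG"),
    label_category = c("filter_fraction", "filter_fraction", "month",
                       "month", "month", "station"),
    label_value = c("0.2-0.8", "5-20", "December", "December", "June",
                    "Sendai"))
}

embed <- function(probe, pad = 30) {
  set.seed(nchar(probe) + utf8ToInt(substr(probe, 1, 1)))
  paste0(paste(sample(c("A", "C", "G", "T"), pad, TRUE), collapse = ""),
         probe,
         paste(sample(c("A", "C", "G", "T"), pad, TRUE), collapse = ""))
}

test_that("hybridization counts containing reads on either strand", {
  probes <- probeFixture()
  reads <- c(embed(probes$sequence[1]), embed(probes$sequence[1]),
             embed(probes$sequence[1]),
             # reverse complement only
             chartr("ACGT", "TGCA",
                    paste(rev(strsplit(embed(probes$sequence[3]), "")[[1]]),
                          collapse = "")))
  chip <- digitalHybridize(reads, probes)
  calls <- as.data.frame(chipCalls(chip))
  expect_equal(calls$hit_count[calls$probe_id == "p_frac_a"], 3)
  expect_true(calls$positive[calls$probe_id == "p_frac_a"])
  # strand-agnostic: probe present only as reverse complement still hits
  expect_equal(calls$hit_count[calls$probe_id == "p_dec1"], 1)
  expect_false(calls$positive[calls$probe_id == "p_jun"])
  # zero reads -> all negative
  none <- digitalHybridize(character(0), probes)
  expect_true(all(!chipCalls(none)$positive))
  expect_error(digitalHybridize(reads, probes[0, ]), "empty probe set")
})

test_that("adding reads never turns a positive probe negative", {
  probes <- probeFixture()
  r1 <- c(embed(probes$sequence[1]), embed(probes$sequence[4]))
  r2 <- c(r1, embed(probes$sequence[2]), embed(probes$sequence[1]))
  h1 <- chipCalls(digitalHybridize(r1, probes))
  h2 <- chipCalls(digitalHybridize(r2, probes))
  expect_true(all(h2$hit_count >= h1$hit_count))
  expect_true(all(h2$positive[h1$positive]))
})

test_that("mismatch tolerance admits near-exact probe copies", {
  probes <- probeFixture()[1, , drop = FALSE]
  mutated <- embed(paste0("ACGTACGTACGTACGTACGTG"))  # last base changed
  exact <- digitalHybridize(mutated, probes, max_mismatches = 0)
  loose <- digitalHybridize(mutated, probes, max_mismatches = 1)
  expect_equal(chipCalls(exact)$hit_count, 0)
  expect_equal(chipCalls(loose)$hit_count, 1)
})

test_that("environment inference is a per-category majority vote", {
  probes <- probeFixture()
  # reads matching: both December probes, one June probe, one fraction
  reads <- c(embed(probes$sequence[3]), embed(probes$sequence[4]),
             embed(probes$sequence[5]), embed(probes$sequence[1]))
  chip <- digitalHybridize(reads, probes)
  env <- inferEnvironment(chip, probes)
  expect_identical(env$month, "December")        # 2 votes vs 1
  expect_identical(env$filter_fraction, "0.2-0.8")
  expect_identical(env$station, "undetermined")  # no positive probes
  # no positives at all -> everything undetermined
  env0 <- inferEnvironment(digitalHybridize("ACGT", probes), probes)
  expect_true(all(unlist(env0) == "undetermined"))
})

test_that("planted single-label reads recover their labels exactly", {
  probes <- probeFixture()
  want <- c(filter_fraction = "5-20", month = "June", station = "Sendai")
  sel <- probes$label_value %in% want
  reads <- vapply(probes$sequence[sel], embed, character(1))
  env <- inferEnvironment(digitalHybridize(reads, probes), probes)
  expect_identical(unlist(env[names(want)]), want)
})

test_that("the chip grid is near-square and renders bit-exactly", {
  # 748 probes lay out on a 28 x 27 grid with blanks
  expect_identical(MetaTide:::chipGrid(748), c(rows = 28L, cols = 27L))
  expect_identical(MetaTide:::chipGrid(6), c(rows = 3L, cols = 2L))

  probes <- probeFixture()
  chip <- digitalHybridize(embed(probes$sequence[1]), probes)
  lines <- renderChip(chip)
  expect_equal(length(lines), 3)
  expect_identical(lines, c("#.", "..", ".."))
  # all-negative chip renders all dots
  lines0 <- renderChip(digitalHybridize("ACGT", probes))
  expect_identical(paste(lines0, collapse = ""), "......")
  # PPM output: P3 header, one red pixel block at the positive cell
  f <- tempfile(fileext = ".ppm")
  renderChip(chip, ppm_file = f, cell_px = 1)
  ppm <- readLines(f)
  expect_identical(ppm[1], "P3")
  expect_identical(ppm[2], "2 3")
  expect_identical(ppm[4], "255 0 0 0 0 0")
})

test_that("probe tables read from TSV and structured FASTA agree", {
  probes <- probeFixture()
  tsv <- tempfile(fileext = ".tsv")
  write.table(probes, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  fa <- tempfile(fileext = ".fa")
  writeLines(as.vector(rbind(
    sprintf(">%s|%s|%s", probes$probe_id, probes$label_category,
            probes$label_value),
    probes$sequence)), fa)
  expect_identical(readProbes(tsv), readProbes(fa))
})
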