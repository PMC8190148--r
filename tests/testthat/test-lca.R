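test_that("bit-score filter is strictly greater-than", {
  hits <- data.frame(query_id = "q", bitscore = c(99, 100, 101),
                     lineage = "Bacteria;X")
  out <- filterHits(hits)
  expect_equal(out$bitscore, 101)
  expect_equal(nrow(filterHits(hits[0, ])), 0)
  high <- hits; high$bitscore <- c(150, 200, 300)
  expect_identical(filterHits(high), high)
})

test_that("LCA is the deepest shared node, down to the synthetic root", {
  one <- lcaAssign(data.frame(bitscore = 200,
                              lineage = "Bacteria;Proteobacteria;X"))
  expect_identical(one$lineage, "Bacteria;Proteobacteria;X")
  expect_identical(one$status, "assigned")

  two <- lcaAssign(data.frame(
    bitscore = c(200, 200),
    lineage = c("Bacteria;Proteobacteria;X", "Bacteria;Proteobacteria;Y")))
  expect_identical(two$lineage, "Bacteria;Proteobacteria")

  cross <- lcaAssign(data.frame(
    bitscore = c(200, 200),
    lineage = c("Bacteria;Proteobacteria;X", "Eukaryota;Opisthokonta;Y")))
  expect_identical(cross$lineage, "root")
  expect_identical(cross$status, "assigned")

  expect_identical(lcaAssign(NULL)$status, "no_hit")
  expect_identical(
    lcaAssign(data.frame(bitscore = 150, lineage = NA_character_))$status,
    "unresolved")
})

test_that("the top-percent window limits which hits participate", {
  hits <- data.frame(
    bitscore = c(500, 480, 200),
    lineage = c("Bacteria;Proteobacteria;X", "Bacteria;Proteobacteria;Y",
                "Eukaryota;Z;W"))
  # 10% window: 200 < 450 is excluded, so the LCA stays inside Bacteria
  expect_identical(lcaAssign(hits, top_percent = 10)$lineage,
                   "Bacteria;Proteobacteria")
  # no window: the eukaryote hit drags the LCA to the root
  expect_identical(lcaAssign(hits, top_percent = NULL)$lineage, "root")
})

test_that("LCA equals prefix-enumeration brute force on random trees", {
  set.seed(42)
  for (rep in 1:25) {
    nHit <- sample(1:6, 1)
    lin <- vapply(seq_len(nHit), function(i) {
      depth <- sample(1:5, 1)
      paste(paste0("n", sample(1:3, depth, TRUE), "_", seq_len(depth)),
            collapse = ";")
    }, character(1))
    got <- lcaAssign(data.frame(bitscore = 200, lineage = lin),
                     top_percent = NULL)
    want <- oracleLca(lin)
    expect_identical(got$lineage,
                     if (length(want)) paste(want, collapse = ";")
                     else "root")
    # monotonicity: adding a hit never deepens the LCA
    more <- lcaAssign(data.frame(bitscore = 200,
                                 lineage = c(lin, "zz;zz")),
                      top_percent = NULL)
    expect_true(startsWith(got$lineage, sub("^root$", "", more$lineage)) ||
                  more$lineage == "root")
  }
})

test_that("MAG annotation adopts the longest contig's assignment only", {
  m <- rbind(c1 = c(1, 2, 3), c2 = c(2, 4, 6), c3 = c(9, 9, 1))
  contigs <- data.frame(contig_id = c("c1", "c2", "c3"),
                        length_bp = c(500, 900, 100))
  mags <- summarizeMAGs(list(M1 = c("c1", "c2"), M2 = "c3"), m, contigs)
  assign <- data.frame(query_id = c("c1", "c2", "c3"),
                       lineage = c("Bacteria;A", NA, "Viruses;B"),
                       status = c("assigned", "no_hit", "assigned"))
  ann <- blastMagAnnotation(mags, assign)
  # longest contig of M1 is c2, which has no hit: M1 is no_hit even
  # though the shorter c1 was assigned
  expect_identical(ann$status[ann$mag_id == "M1"], "no_hit")
  expect_identical(ann$lineage[ann$mag_id == "M2"], "Viruses;B")
  expect_error(blastMagAnnotation(mags, assign[1, ]), "c3")
})

test_that("composition normalization conserves the target exactly", {
  out <- normalizeComposition(c(A = 2, B = 1, no_hit = 7))
  expect_identical(out, c(A = 667L, B = 333L))
  expect_identical(normalizeComposition(c(A = 5), exclude_no_hit = FALSE),
                   c(A = 1000L))
  # conservation property over random inputs
  set.seed(7)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    x <- setNames(sample(0:500, n, TRUE) + c(1, rep(0, n - 1)),
                  paste0("t", seq_len(n)))
    expect_identical(sum(normalizeComposition(x, exclude_no_hit = FALSE)),
                     1000L)
  }
  expect_error(normalizeComposition(c(no_hit = 7)), "no non-zero")
})

test_that("BLAST outfmt-6 reading joins lineages by subject", {
  f <- tempfile(fileext = ".tsv")
  writeLines(paste(c("q1", "sub1", "98.1", "120", "2", "0", "1", "120",
                     "5", "124", "1e-50", "222"), collapse = "\t"), f)
  hits <- readBlastHits(f, lineage = data.frame(
    sseqid = "sub1", lineage = "Bacteria;Proteobacteria"))
  expect_identical(hits$query_id, "q1")
  expect_equal(hits$bitscore, 222)
  expect_identical(hits$lineage, "Bacteria;Proteobacteria")
})
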