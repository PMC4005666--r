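# Column and joint conservation statistics.

test_that("information content hits its analytic anchors", {
  aln <- toyAlignment()
  # invariant column (all G)
  s3 <- columnStats(aln, 3L)
  expect_equal(s3$fG, 1)
  expect_equal(s3$informationContent, 2)
  # even column
  even <- rbind(c("A"), c("C"), c("G"), c("U"))
  expect_equal(columnStats(even, 1L)$informationContent, 0)
  # A, A, G, - from first column of the toy alignment
  s1 <- columnStats(aln, 1L)
  expect_equal(s1$gapFraction, 0.25)
  expect_equal(s1$fA, 2 / 3, tolerance = 1e-12)
  expect_equal(s1$informationContent,
               2 + (2 / 3) * log2(2 / 3) + (1 / 3) * log2(1 / 3),
               tolerance = 1e-12)
})

test_that("ambiguity codes count as gaps and all-gap columns are flagged", {
  aln <- toyAlignment()
  s4 <- columnStats(aln, 4L)          # C, C, C, N
  expect_equal(s4$gapFraction, 0.25)
  expect_equal(s4$fC, 1)
  gapCol <- rbind(c("-"), c("-"))
  sg <- columnStats(gapCol, 1L)
  expect_false(sg$icDefined)
  expect_true(is.na(sg$informationContent))
  expect_equal(sg$gapFraction, 1)
})

test_that("joint frequencies count co-ungapped sequences and keep marginals", {
  aln <- toyAlignment()
  ps <- pairStats(aln, 2L, 3L)        # (A,A,G,A) vs (G,G,G,G)
  expect_equal(ps$nCoUngapped, 4L)
  expect_equal(ps$percent["A", "G"], 75)
  expect_equal(ps$percent["G", "G"], 25)
  # identical columns on an invariant column
  allA <- rbind(c("A", "A"), c("A", "A"))
  psA <- pairStats(allA, 1L, 1L)
  expect_equal(psA$percent["A", "A"], 100)
  # marginal consistency against columnStats on the co-ungapped subset
  ps15 <- pairStats(aln, 1L, 5L)
  ok <- !(aln[, 1L] %in% c("-", "N")) & !(aln[, 5L] %in% c("-", "N"))
  sub <- aln[ok, , drop = FALSE]
  expect_equal(rowSums(ps15$counts)[c("A", "C", "G", "U")] / ps15$nCoUngapped,
               unlist(columnStats(sub, 1L)[c("fA", "fC", "fG", "fU")],
                      use.names = FALSE) |>
                 stats::setNames(c("A", "C", "G", "U")))
  # no co-ungapped sequences
  twoGaps <- rbind(c("A", "-"), c("-", "C"))
  expect_true(pairStats(twoGaps, 1L, 2L)$empty)
})

test_that("duplicating every sequence changes no frequency or content", {
  aln <- toyAlignment()
  dup <- rbind(aln, aln)
  for (j in seq_len(ncol(aln))) {
    a <- columnStats(aln, j); b <- columnStats(dup, j)
    expect_equal(b[c("fA", "fC", "fG", "fU", "gapFraction", "informationContent")],
                 a[c("fA", "fC", "fG", "fU", "gapFraction", "informationContent")])
  }
  expect_equal(pairStats(dup, 2L, 3L)$percent, pairStats(aln, 2L, 3L)$percent)
})

test_that("stockholm and aligned FASTA both load, with T mapped to U", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "GAT-C", ">b", "GAUGC"), fa)
  m <- readAlignment(fa)
  expect_equal(dim(m), c(2L, 5L))
  expect_equal(unname(m["a", 3L]), "U")
  expect_equal(unname(m["a", 4L]), "-")
  sto <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "",
               "seq1   GGCU..AA", "seq2   GGCUUUAA", "//"), sto)
  ms <- readAlignment(sto)
  expect_equal(dim(ms), c(2L, 8L))
  expect_equal(unname(ms["seq1", 5L]), "-")
  # ragged FASTA is rejected
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "GAUC", ">b", "GA"), bad)
  expect_error(readAlignment(bad), class = "kjParseError")
})

test_that("column masks are validated", {
  aln <- toyAlignment()
  mask <- columnMask(c(`1b` = 2L, `1n` = 3L), aln)
  expect_equal(unname(mask["1b"]), 2L)
  expect_error(columnMask(c(`1b` = 2L, `1n` = 2L)), "injective")
  expect_error(columnMask(c(`1b` = 9L), aln), "width")
  expect_error(columnMask(c(2L, 3L)), "named")
})
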