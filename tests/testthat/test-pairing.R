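# Base-pair detection and helix segments.

test_that("an ideal 12-bp duplex yields 12 WC pairs and 11 segments", {
  d <- buildIdealDuplex("GGCGAUCGCGUC")
  p <- detectBasePairs(d)
  expect_equal(nrow(p), 12L)
  expect_true(all(p$kind == "WC"))
  expect_true(all(p$c1c1 >= 9.9 & p$c1c1 <= 10.9))
  # one pair per nucleotide
  expect_false(anyDuplicated(c(p$nt1, p$nt2)) > 0)
  s <- enumerateHelixSegments(p, d)
  expect_length(s, 11L)
  expect_length(enumerateHelixSegments(p, d, orientations = "both"), 22L)
})

test_that("wobble pairs are detected as wobble, with both canonical contacts", {
  w <- buildIdealDuplex(helixSpec("GAGU", complement = "UUCG"))
  p <- detectBasePairs(w)
  expect_equal(nrow(p), 4L)
  expect_setequal(p$kind[p$base1 %in% c("G", "U") & p$base2 %in% c("G", "U") &
                           p$base1 != p$base2 &
                           paste0(p$base1, p$base2) %in% c("GU", "UG")],
                  "wobble")
  wob <- p[p$kind == "wobble", ]
  expect_equal(nrow(wob), 2L)
  expect_true(all(vapply(wob$hbonds, nrow, 0L) == 2L))
  expect_true(all(unlist(lapply(wob$hbonds, `[[`, "distance")) <= 3.5))
})

test_that("an isolated single strand has no pairs", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeStrandPDB(12L, tf)
  m <- filterToRNA(loadStructure(tf), quiet = TRUE)
  expect_equal(nrow(detectBasePairs(m)), 0L)
  expect_length(enumerateHelixSegments(detectBasePairs(m), m), 0L)
})

test_that("sheared purine pairs are not reported as Watson-Crick pairs", {
  kt <- buildSyntheticKTurn()
  p <- detectBasePairs(kt)
  keys <- paste(p$nt1, p$nt2)
  expect_false(any(grepl("A:7|A:8", keys)))   # 1b and 2b are unpaired here
  expect_equal(nrow(p), 6L)                    # 3 C-helix + 3 NC-helix WC pairs
})

test_that("pair detection is invariant to strand order in the file", {
  d <- buildIdealDuplex("GGCGAU")
  a <- atoms(d)
  rev_ <- rbind(a[a$chain == "B", ], a[a$chain == "A", ])
  m2 <- new("RNAStructure", atoms = `rownames<-`(rev_, NULL),
            sourceId = "swapped", modelIndex = 1L)
  p1 <- detectBasePairs(d); p2 <- detectBasePairs(m2)
  key <- function(p) sort(paste(p$nt1, p$nt2, p$kind))
  expect_identical(key(p2), key(p1))
  expect_identical(p2$nt1, p1$nt1)  # canonical member order, not file order
})

test_that("segments never join pairs of well-separated duplexes", {
  sc <- buildTwoHelixScene("GGCGAU", "GCGAUC",
                           rigidTransform(diag(3), c(100, 0, 0)))
  p <- detectBasePairs(sc)
  expect_equal(nrow(p), 12L)
  segs <- enumerateHelixSegments(p, sc)
  helixOf <- function(k) ifelse(substr(k, 1, 1) %in% c("A", "B"), 1L, 2L)
  for (f in segs)
    expect_length(unique(vapply(framePairs(f), helixOf, 0L)), 1L)
})

test_that("consecutive segment frames twist by the construction value", {
  d <- buildIdealDuplex("GGCGAUCGCGUC")
  s <- enumerateHelixSegments(detectBasePairs(d), d)
  tw <- vapply(seq_len(length(s) - 1L), function(i)
    rotationAngle(rotationMatrix(relativeTransform(s[[i]], s[[i + 1L]]))), 0)
  expect_true(all(abs(tw - 32.7) <= 2))
  # axes of a duplex built along z stay within 5 degrees of z
  ang <- vapply(s, function(f)
    acos(min(1, abs(frameTriad(f)[3L, 1L]))) * 180 / pi, 0)
  expect_true(all(ang <= 5))
})
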