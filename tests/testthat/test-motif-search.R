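# Pattern definition, scanning, hit output.

test_that("a pattern extracted from a planted scene recovers the construction transform", {
  tr <- composeTransforms(rigidTransform(rotationAboutAxis(c(1, 2, 0), 115)),
                          rigidTransform(diag(3), c(3, -8, 6)))
  sc <- suppressWarnings(buildTwoHelixScene("GGCGAU", "GCGAUC", tr))
  pat <- patternFromReference(sc, cSelector = c("A", "B"), ncSelector = c("C", "D"))
  devs <- vapply(pat@entries, function(e)
    sqrt(sum((translationVector(e) - translationVector(tr))^2)) +
      rotationAngle(rotationMatrix(e) %*% t(rotationMatrix(tr))), 0)
  expect_lt(min(devs), 1e-6)
  # selectors that resolve nothing are a typed error
  expect_error(patternFromReference(sc, cSelector = "Q", ncSelector = "C"),
               class = "kjSelectionError")
})

test_that("self-comparison of one straight duplex gives pure-twist entries", {
  d <- buildIdealDuplex("GGCGAUCG")
  pat <- patternFromReference(d, cSelector = c("A", "B"), ncSelector = c("A", "B"))
  for (e in pat@entries) {
    # rotation axis nearly parallel to the helix axis (x in frame coordinates):
    # the (1,1) element of the rotation stays ~1 for a pure twist
    expect_gt(rotationMatrix(e)[1L, 1L], 0.99)
  }
})

test_that("a planted scene gives exactly one deduplicated near-zero hit", {
  patT <- kturnReferencePattern()@entries[[1L]]
  pat <- searchPattern(patT, 4, 25)
  sc <- suppressWarnings(buildTwoHelixScene("GGCGAU", "GCGAUC", patT))
  h <- scanStructure(sc, pat)
  expect_equal(nrow(h), 1L)
  expect_lt(h$translationDev[1L], 1e-6)
  expect_lt(h$rotationDev[1L], 1e-5)
})

test_that("a straight duplex is a negative control", {
  d <- buildIdealDuplex("GGCGAUCGCGUC")
  h <- scanStructure(d, kturnReferencePattern())
  expect_equal(nrow(h), 0L)
})

test_that("hits respect the tolerance boundary and are monotone in tolerance", {
  patT <- kturnReferencePattern()@entries[[1L]]
  pat <- searchPattern(patT, 4, 25)
  beyond <- composeTransforms(patT, rigidTransform(rotationAboutAxis(c(0, 1, 0), 35)))
  within <- composeTransforms(patT, rigidTransform(rotationAboutAxis(c(0, 1, 0), 12.5)))
  scBeyond <- suppressWarnings(buildTwoHelixScene("GGCGAU", "GCGAUC", beyond))
  scWithin <- suppressWarnings(buildTwoHelixScene("GGCGAU", "GCGAUC", within))
  expect_equal(nrow(scanStructure(scBeyond, pat)), 0L)
  expect_equal(nrow(scanStructure(scWithin, pat)), 1L)
  # enlarging tolerances never removes a hit
  wide <- searchPattern(patT, 8, 40)
  hNarrow <- scanStructure(scWithin, pat)
  hWide <- scanStructure(scWithin, wide)
  expect_true(all(paste(hNarrow$cPair1, hNarrow$ncPair1) %in%
                    paste(hWide$cPair1, hWide$ncPair1)))
  expect_gte(nrow(hWide), nrow(hNarrow))
})

test_that("scanning is rigid-motion invariant", {
  patT <- kturnReferencePattern()@entries[[1L]]
  pat <- searchPattern(patT, 4, 25)
  sc <- suppressWarnings(buildTwoHelixScene("GGCGAU", "GCGAUC", patT))
  h0 <- scanStructure(sc, pat)
  set.seed(11)
  for (i in 1:5) {
    g <- randomRigidTransform(c(0, 50))
    hg <- scanStructure(transformStructure(sc, g), pat)
    expect_equal(nrow(hg), nrow(h0))
    expect_lt(max(abs(hg$translationDev - h0$translationDev)), 1e-6)
    expect_lt(max(abs(hg$rotationDev - h0$rotationDev)), 1e-6)
  }
})

test_that("scan refuses ineligible models", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeStrandPDB(9L, tf)
  m <- filterToRNA(loadStructure(tf), quiet = TRUE)
  expect_error(scanStructure(m, kturnReferencePattern()),
               class = "kjIneligibleModel")
})

test_that("pseudo-atom output round-trips frame geometry", {
  kt <- buildSyntheticKTurn()
  h <- scanStructure(kt, kturnReferencePattern())
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeHitsPseudoatoms(h, tf)
  m <- loadStructure(tf)
  a <- atoms(m)
  expect_equal(nrow(a), nrow(h) * 2L * 4L)   # 2 residues x 4 pseudo-atoms per hit
  orig <- a[a$elety == "ORIG" & a$resno == 1L, c("x", "y", "z")]
  expect_equal(as.numeric(orig), frameOrigin(h$cFrame[[1L]]), tolerance = 1e-3)
  tip <- a[a$elety == "AXIS" & a$resno == 2L, c("x", "y", "z")]
  expect_equal(as.numeric(tip),
               frameOrigin(h$ncFrame[[1L]]) + 5 * frameTriad(h$ncFrame[[1L]])[, 1L],
               tolerance = 1e-3)
  # zero hits still writes a parseable placeholder file
  tf0 <- withr::local_tempfile(fileext = ".pdb")
  writeHitsPseudoatoms(h[0L, ], tf0)
  expect_true(any(grepl("^REMARK", readLines(tf0))))
})

test_that("patterns survive a JSON round trip", {
  pat <- kturnReferencePattern(translationTol = 3.5, rotationTol = 20)
  tf <- withr::local_tempfile(fileext = ".json")
  writePattern(pat, tf)
  pat2 <- readPattern(tf)
  expect_equal(pat2@translationTol, 3.5)
  expect_equal(pat2@rotationTol, 20)
  expect_lt(max(abs(rotationMatrix(pat2@entries[[1L]]) -
                      rotationMatrix(pat@entries[[1L]]))), 1e-12)
  expect_equal(translationVector(pat2@entries[[1L]]),
               translationVector(pat@entries[[1L]]))
  expect_equal(pat2@provenance$source, pat@provenance$source)
})
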