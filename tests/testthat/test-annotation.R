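# Role assignment, contact measurement, N-class, superposition.

kturnWithHit <- function() {
  kt <- buildSyntheticKTurn()
  h <- scanStructure(kt, kturnReferencePattern())
  list(model = kt, hit = h[1L, , drop = FALSE])
}

test_that("the synthetic k-turn is annotated with its ground-truth roles", {
  x <- kturnWithHit()
  asg <- assignRoles(x$model, x$hit)
  truth <- attr(x$model, "roles")
  expect_true(completeCore(asg))
  expect_identical(roles(asg)[names(truth)], truth)
})

test_that("plain Watson-Crick scenes fail role assignment with a diagnostic", {
  patT <- kturnReferencePattern()@entries[[1L]]
  sc <- suppressWarnings(buildTwoHelixScene("GGCGAU", "GCGAUC", patT))
  h <- scanStructure(sc, searchPattern(patT, 4, 25))
  expect_equal(nrow(h), 1L)
  expect_error(assignRoles(sc, h[1L, , drop = FALSE]), class = "kjAssignmentError")
})

test_that("explicit role overrides win over the heuristic", {
  x <- kturnWithHit()
  asg <- assignRoles(x$model, x$hit, override = c(L3 = "A:6", `5b` = "A:11"))
  expect_equal(unname(roles(asg)["5b"]), "A:11")
  expect_true(any(grepl("override", asg@notes)))
  # an injectivity violation is rejected
  expect_error(assignRoles(x$model, x$hit, override = c(L3 = "A:4")))
})

test_that("contact measurement is symmetric, exact, and errors on absent atoms", {
  x <- kturnWithHit()
  asg <- assignRoles(x$model, x$hit)
  d1 <- measureContact(x$model, asg, c("L1", "O2'"), c("1n", "N1"))
  d2 <- measureContact(x$model, asg, c("1n", "N1"), c("L1", "O2'"))
  expect_equal(d1, d2)
  expect_equal(measureContact(x$model, asg, c("L1", "O2'"), c("L1", "O2'")), 0)
  expect_error(measureContact(x$model, asg, c("L1", "O2'"), c("1n", "ZZ9")),
               class = "kjMissingAtom")
  expect_error(measureContact(x$model, asg, c("5n", "O2'"), c("1n", "N1")),
               class = "kjMissingAtom")
})

test_that("the contact report always carries every standard label", {
  x <- kturnWithHit()
  asg <- assignRoles(x$model, x$hit)
  rep_ <- classifyNClass(x$model, asg)
  tab <- contacts(rep_)
  expect_setequal(tab$label,
                  c("L1 O2'-1n N1", "L1 O2'-1n N3", "-1n O2'-2b N1",
                    "-1n O2'-2b N3", "2b N6-2n N3", "2b N6-2n N7",
                    "-2n O2'-3b O2'", "L3 O2'-L2 proS-OP"))
  expect_true(all(tab$status %in% c("bonded", "borderline", "long", "missing")))
  # the class matches whichever 2b nitrogen the -1n O2' is nearer
  d1 <- tab$distance[tab$label == "-1n O2'-2b N1"]
  d3 <- tab$distance[tab$label == "-1n O2'-2b N3"]
  expect_equal(nClass(rep_), if (d1 < d3) "N1" else "N3")
})

test_that("moving the -1n O2' donor flips the N class", {
  x <- kturnWithHit()
  asg <- assignRoles(x$model, x$hit)
  keyM1n <- roles(asg)["-1n"]; key2b <- roles(asg)["2b"]
  place <- function(target) {
    a <- atoms(x$model)
    k <- sprintf("%s:%d%s", a$chain, a$resno, a$insert)
    i <- which(k == keyM1n & a$elety == "O2'")
    a[i, c("x", "y", "z")] <- target
    new("RNAStructure", atoms = a, sourceId = "moved", modelIndex = 1L)
  }
  n1 <- atoms(x$model); k <- sprintf("%s:%d%s", n1$chain, n1$resno, n1$insert)
  p1 <- as.numeric(n1[k == key2b & n1$elety == "N1", c("x", "y", "z")])
  p3 <- as.numeric(n1[k == key2b & n1$elety == "N3", c("x", "y", "z")])
  u <- (p3 - p1) / sqrt(sum((p3 - p1)^2))
  nearN1 <- classifyNClass(place(p1 + 2.9 * u * 0), asg)   # on N1 itself
  expect_equal(nClass(nearN1), "N1")
  nearN3 <- classifyNClass(place(p3 + 1.0 * u), asg)       # 1 A beyond N3
  expect_equal(nClass(nearN3), "N3")
})

test_that("superposition recovers rigid motions exactly and is symmetric", {
  kt <- buildSyntheticKTurn()
  asg <- new("KTurnAssignment", roles = attr(kt, "roles"),
             completeCore = TRUE, notes = character(0))
  self <- superposeRoles(kt, asg, kt, asg)
  expect_lt(self$rmsd, 1e-9)
  set.seed(21)
  for (i in 1:10) {
    moved <- transformStructure(kt, randomRigidTransform(c(0, 40)))
    expect_lt(superposeRoles(moved, asg, kt, asg)$rmsd, 1e-6)
  }
  # symmetry on a genuinely different pair of structures
  a <- atoms(kt)
  set.seed(22)
  a$x <- a$x + rnorm(nrow(a), 0, 0.5)
  a$y <- a$y + rnorm(nrow(a), 0, 0.5)
  a$z <- a$z + rnorm(nrow(a), 0, 0.5)
  pert <- new("RNAStructure", atoms = a, sourceId = "pert", modelIndex = 1L)
  r1 <- superposeRoles(pert, asg, kt, asg)
  r2 <- superposeRoles(kt, asg, pert, asg)
  expect_equal(r1$rmsd, r2$rmsd, tolerance = 1e-9)
  expect_gt(r1$rmsd, 0.1)
  # agreement with an independent Kabsch oracle
  collect <- function(model) {
    out <- NULL
    for (role in c("-1n", "L1", "2b", "1n", "2n")) {
      cc <- kjunction:::.residueCoords(model, roles(asg)[role])
      out <- rbind(out, cc[intersect(backboneAtomSet("backbone"), rownames(cc)), ])
    }
    out
  }
  expect_equal(r1$rmsd, oracleKabschRMSD(collect(pert), collect(kt)),
               tolerance = 1e-9)
  # the restricted trace set re-optimises over fewer atoms
  rTrace <- superposeRoles(pert, asg, kt, asg, atomSet = backboneAtomSet("trace"))
  expect_lt(rTrace$nAtoms, r1$nAtoms)
  expect_gt(rTrace$rmsd, 0)
  # underdetermined selections error
  expect_error(superposeRoles(kt, asg, kt, asg, roleSet = "L1",
                              atomSet = c("P", "OP1")),
               class = "kjUnderdetermined")
})
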