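# Reading, filtering and writing coordinate models.

test_that("a written duplex reloads with identical residues and coordinates", {
  d <- buildIdealDuplex("GGCGAUCGCGUC")
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeStructurePDB(d, tf)
  d2 <- filterToRNA(loadStructure(tf), quiet = TRUE)
  a1 <- atoms(d); a2 <- atoms(d2)
  expect_equal(nrow(a2), nrow(a1))
  expect_identical(a2$elety, a1$elety)
  expect_identical(a2$resno, a1$resno)
  expect_identical(a2$chain, a1$chain)
  # PDB carries three decimals
  expect_lt(max(abs(a1$x - a2$x), abs(a1$y - a2$y), abs(a1$z - a2$z)), 1e-3)
  nt <- nucleotides(d2)
  expect_equal(nrow(nt), 24L)
  expect_true(all(nt$complete))
  expect_true(eligible(d2))
})

test_that("eligibility flips exactly at ten complete nucleotides", {
  f9 <- withr::local_tempfile(fileext = ".pdb")
  f10 <- withr::local_tempfile(fileext = ".pdb")
  writeStrandPDB(9L, f9)
  writeStrandPDB(10L, f10)
  m9 <- filterToRNA(loadStructure(f9), quiet = TRUE)
  m10 <- filterToRNA(loadStructure(f10), quiet = TRUE)
  expect_equal(sum(nucleotides(m9)$complete), 9L)
  expect_false(eligible(m9))
  expect_true(eligible(m10))
})

test_that("alternate locations resolve to highest occupancy and ions are filtered", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeAltLocPDB(tf)
  m <- loadStructure(tf)
  a <- atoms(m)
  n9 <- a[a$elety == "N9", ]
  expect_equal(nrow(n9), 1L)        # one conformer survives
  expect_equal(n9$x, 2)             # the higher-occupancy B location
  expect_equal(nrow(nucleotides(m)), 2L)  # G plus the MG ion
  mf <- suppressMessages(filterToRNA(m))
  expect_equal(nrow(nucleotides(mf)), 1L)
  expect_false("MG" %in% atoms(mf)$resname)
})

test_that("filterToRNA is idempotent, maps modified residues, drops unknowns", {
  d <- buildIdealDuplex("GGCGAU")
  a <- atoms(d)
  a$resname[a$resno == 2 & a$chain == "A"] <- "PSU"   # pseudouridine-style alias
  odd <- a[a$resno == 1 & a$chain == "A", ][1, ]
  odd$resno <- 99L; odd$resname <- "XYZ"
  m <- new("RNAStructure", atoms = rbind(a, odd), sourceId = "t", modelIndex = 1L)
  expect_warning(f1 <- suppressMessages(filterToRNA(m)), "XYZ")
  nt <- nucleotides(f1)
  expect_false(any(nt$resname == "XYZ"))
  expect_equal(nt$base[nt$chain == "A" & nt$resno == 2], "U")
  f2 <- filterToRNA(f1, quiet = TRUE)
  expect_identical(atoms(f2), atoms(f1))
})

test_that("empty and unreadable inputs raise typed errors", {
  expect_error(loadStructure(file.path(tempdir(), "absent.pdb")), class = "kjIOError")
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK   nothing here", "END"), tf)
  expect_error(loadStructure(tf), class = "kjEmptyModel")
  # a model with zero RNA residues filters to an empty, ineligible model
  tf2 <- withr::local_tempfile(fileext = ".pdb")
  writeAltLocPDB(tf2)
  m <- loadStructure(tf2)
  a <- atoms(m)
  onlyIon <- new("RNAStructure", atoms = `rownames<-`(a[a$resname == " MG" |
                                                          a$resname == "MG", ], NULL),
                 sourceId = "ion", modelIndex = 1L)
  f <- filterToRNA(onlyIon, quiet = TRUE)
  expect_equal(nrow(nucleotides(f)), 0L)
  expect_false(eligible(f))
})

test_that("mmCIF atom sites parse with quoted primed atom names", {
  cif <- c(
    "data_test", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C \"C1'\" . G A 1 1 ? 1.000 2.000 3.000 1.00 0.00 ? 1 G A \"C1'\" 1",
    "ATOM 2 N N9 . G A 1 1 ? 2.000 2.500 3.200 1.00 0.00 ? 1 G A N9 1")
  tf <- withr::local_tempfile(fileext = ".cif")
  writeLines(cif, tf)
  m <- loadStructure(tf)
  expect_setequal(atoms(m)$elety, c("C1'", "N9"))
  expect_equal(atoms(m)$x, c(1, 2))
})
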