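# Reading PDB/mmCIF coordinate files into the uniform RNAStructure model,
# stripping non-RNA content, and writing PDB output. Parsing and PDB writing
# are delegated to bio3d; this module adds alternate-location resolution,
# modified-residue mapping, nucleotide completeness and eligibility.

# Parent-base mapping: the four ribonucleotides plus common modified residues
# seen in ribosomal and riboswitch structures. Unknown residues are dropped by
# filterToRNA with a warning.
.RNA_BASE_MAP <- c(
  A = "A", C = "C", G = "G", U = "U",
  PSU = "U", H2U = "U", `4SU` = "U", OMU = "U", UR3 = "U", `5MU` = "U",
  `5MC` = "C", OMC = "C",
  `1MA` = "A", A2M = "A", MA6 = "A", `2MA` = "A",
  OMG = "G", `2MG` = "G", M2G = "G", `7MG` = "G", `1MG` = "G", YG = "G"
)

.WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")
.ION_NAMES <- c("MG", "NA", "K", "CL", "ZN", "MN", "CA", "SR", "BA", "CO",
                "NI", "CD", "FE", "CU", "BR", "IOD", "CS", "RB", "TL", "OS",
                "IRI", "NH4", "SO4", "PO4")
.AA_NAMES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
               "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
               "TYR", "VAL", "MSE")
.DNA_NAMES <- c("DA", "DC", "DG", "DT", "DU", "DI")

.BACKBONE_ATOMS <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
                     "C3'", "O3'", "C2'", "O2'", "C1'")
.PHOSPHATE_GROUP <- c("P", "OP1", "OP2")

.BASE_ATOMS <- list(
  A = c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6", "N6"),
  G = c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6", "O6", "N2"),
  C = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
  U = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6")
)

.PURINE_RING <- c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6")
.PYRIMIDINE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6")

.ntKey <- function(chain, resno, insert) {
  ins <- ifelse(is.na(insert) | insert == "", "", insert)
  sprintf("%s:%d%s", chain, as.integer(resno), ins)
}

# Normalise atom naming across PDB generations: primes for sugar atoms,
# OP1/OP2 for the phosphate oxygens.
.normAtomName <- function(x) {
  x <- gsub("^\"|\"$", "", trimws(x))  # mmCIF-quoted names like "C1'"
  x <- gsub("\\*", "'", x)
  x[x == "O1P"] <- "OP1"
  x[x == "O2P"] <- "OP2"
  x[x == "O3P"] <- "OP3"
  x
}

# Internal constructor: normalises column types and checks validity.
.rnaStructure <- function(atoms, sourceId = "unnamed", modelIndex = 1L) {
  atoms <- as.data.frame(atoms)[, .ATOM_COLS]
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$insert <- ifelse(is.na(atoms$insert), "", as.character(atoms$insert))
  atoms$resname <- as.character(atoms$resname)
  atoms$base <- as.character(atoms$base)
  atoms$elety <- .normAtomName(atoms$elety)
  atoms$o <- ifelse(is.na(atoms$o), 1, as.numeric(atoms$o))
  rownames(atoms) <- NULL
  new("RNAStructure", atoms = atoms, sourceId = sourceId,
      modelIndex = as.integer(modelIndex))
}

#' Load an RNA coordinate file
#'
#' Reads a PDB or mmCIF file (format guessed from the extension, or sniffed,
#' when `format = "auto"`) into an [RNAStructure-class] model. Only the first
#' model of multi-model files is used. Alternate locations are resolved per
#' atom by highest occupancy, ties broken in favour of label "A". Hydrogens
#' are retained in the atom table but ignored by all geometry operations.
#'
#' @param path path to a coordinate file.
#' @param format one of `"auto"`, `"pdb"`, `"mmcif"`.
#' @param sourceId identifier stored on the model; defaults to the file name.
#' @return an `RNAStructure`. Residues are not yet filtered to RNA; see
#'   [filterToRNA()].
#' @seealso [filterToRNA()], [writeStructurePDB()]
#' @export
loadStructure <- function(path, format = c("auto", "pdb", "mmcif"),
                          sourceId = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(errorCondition(sprintf("file not found: %s", path),
                        class = c("kjIOError", "error", "condition")))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif"
      else if (ext %in% c("pdb", "ent")) "pdb"
      else {
        head <- readLines(path, n = 50L, warn = FALSE)
        if (any(grepl("^(data_|_atom_site)", head))) "mmcif" else "pdb"
      }
  }
  parsed <- tryCatch(
    if (format == "pdb") {
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    },
    error = function(e) {
      stop(errorCondition(
        sprintf("could not parse '%s' as %s: %s", path, format, conditionMessage(e)),
        class = c("kjParseError", "error", "condition")))
    })
  a <- parsed$atom
  if (is.null(a) || nrow(a) == 0L)
    stop(errorCondition(sprintf("no atom records in '%s'", path),
                        class = c("kjEmptyModel", "error", "condition")))
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), "", as.character(a$chain)),
    resno = as.integer(a$resno),
    insert = ifelse(is.na(a$insert), "", as.character(a$insert)),
    resname = trimws(as.character(a$resid)),
    base = NA_character_,
    elety = .normAtomName(a$elety),
    x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, pmin(1, pmax(0, a$o))),
    alt = ifelse(is.na(a$alt), "", as.character(a$alt)),
    stringsAsFactors = FALSE)
  # resolve alternate locations: per (residue, atom name) keep the highest
  # occupancy; ties go to the alphabetically first label (i.e. 'A')
  if (any(nzchar(atoms$alt))) {
    grp <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
    ord <- order(grp, -atoms$o, atoms$alt)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(grp[ord]), , drop = FALSE]
    atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  }
  atoms$alt <- NULL
  m <- .rnaStructure(atoms, sourceId = if (is.null(sourceId)) basename(path) else sourceId)
  n <- nucleotides(m)
  if (nrow(n) == 0L)
    stop(errorCondition(sprintf("zero residues after parsing '%s'", path),
                        class = c("kjEmptyModel", "error", "condition")))
  m
}

#' @rdname nucleotides
#' @export
setMethod("nucleotides", "RNAStructure", function(x) {
  a <- x@atoms
  if (nrow(a) == 0L) {
    return(data.frame(key = character(), chain = character(), resno = integer(),
                      insert = character(), resname = character(),
                      base = character(), complete = logical()))
  }
  key <- .ntKey(a$chain, a$resno, a$insert)
  first <- !duplicated(key)
  nt <- data.frame(key = key[first], chain = a$chain[first],
                   resno = a$resno[first], insert = a$insert[first],
                   resname = a$resname[first], base = a$base[first],
                   complete = FALSE, stringsAsFactors = FALSE)
  # base column may be unset for freshly loaded (unfiltered) models; fall back
  # to the resname mapping so completeness is still meaningful
  unmapped <- is.na(nt$base)
  nt$base[unmapped] <- unname(.RNA_BASE_MAP[nt$resname[unmapped]])
  atomsOf <- split(a$elety, key)
  firstInChain <- !duplicated(nt$chain)
  for (i in seq_len(nrow(nt))) {
    b <- nt$base[i]
    if (is.na(b)) next
    expected <- c(.BACKBONE_ATOMS, .BASE_ATOMS[[b]])
    if (firstInChain[i]) expected <- setdiff(expected, .PHOSPHATE_GROUP)
    nt$complete[i] <- all(expected %in% atomsOf[[nt$key[i]]])
  }
  rownames(nt) <- NULL
  nt
})

#' Restrict a model to RNA residues
#'
#' Removes ligands, ions, waters, protein and unrecognised residues, keeping
#' residues whose name maps to a parent base A/C/G/U (a small lookup handles
#' common modified nucleotides, e.g. PSU -> U). Removal counts are reported
#' via `message()`; unknown residue names additionally raise a warning. The
#' operation is idempotent and an empty result is allowed (the model is then
#' simply ineligible).
#'
#' @param model an `RNAStructure`.
#' @param quiet suppress the removal-count message.
#' @return the filtered `RNAStructure` with the `base` column set.
#' @export
filterToRNA <- function(model, quiet = FALSE) {
  a <- model@atoms
  base <- unname(.RNA_BASE_MAP[a$resname])
  keep <- !is.na(base)
  dropped <- a$resname[!keep]
  if (!quiet && length(dropped) > 0L) {
    key <- .ntKey(a$chain[!keep], a$resno[!keep], a$insert[!keep])
    dn <- dropped[!duplicated(key)]
    cls <- ifelse(dn %in% .WATER_NAMES, "water",
           ifelse(dn %in% .ION_NAMES, "ion",
           ifelse(dn %in% .AA_NAMES, "protein",
           ifelse(dn %in% .DNA_NAMES, "DNA", "other"))))
    tab <- table(cls)
    message(sprintf("filterToRNA: removed %d non-RNA residue(s) (%s)",
                    length(dn),
                    paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
    unknown <- unique(dn[cls == "other"])
    if (length(unknown) > 0L)
      warning(sprintf("dropped unrecognised residue name(s): %s",
                      paste(unknown, collapse = ", ")))
  }
  a <- a[keep, , drop = FALSE]
  a$base <- base[keep]
  # hydrogens and anything outside the heavy-atom dictionary are retained in
  # the table; geometry operations address atoms by name and never see them
  initialize(model, atoms = `rownames<-`(a, NULL))
}

#' Write a structure as PDB
#'
#' @param model an `RNAStructure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStructurePDB <- function(model, path) {
  a <- model@atoms
  if (nrow(a) == 0L) {
    writeLines(c("REMARK   empty model", "END"), path)
    return(invisible(path))
  }
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  isRNA <- !is.na(a$base) | a$resname %in% names(.RNA_BASE_MAP)
  tryCatch(
    bio3d::write.pdb(file = path, xyz = xyz,
                     type = ifelse(isRNA, "ATOM", "HETATM"),
                     resno = a$resno, resid = a$resname, chain = a$chain,
                     insert = ifelse(a$insert == "", NA, a$insert),
                     elety = a$elety, eleno = seq_len(nrow(a)),
                     o = a$o, b = rep(0, nrow(a))),
    error = function(e) {
      stop(errorCondition(sprintf("cannot write PDB '%s': %s", path,
                                  conditionMessage(e)),
                          class = c("kjIOError", "error", "condition")))
    })
  invisible(path)
}

# Coordinates of one named atom of one nucleotide (by key); NULL if absent.
.atomCoord <- function(model, key, atom) {
  a <- model@atoms
  k <- .ntKey(a$chain, a$resno, a$insert)
  i <- which(k == key & a$elety == atom)
  if (length(i) == 0L) return(NULL)
  as.numeric(a[i[1L], c("x", "y", "z")])
}

# All atoms of one nucleotide as a named coordinate matrix.
.residueCoords <- function(model, key) {
  a <- model@atoms
  k <- .ntKey(a$chain, a$resno, a$insert)
  sub <- a[k == key, , drop = FALSE]
  m <- as.matrix(sub[, c("x", "y", "z")])
  rownames(m) <- sub$elety
  m
}
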