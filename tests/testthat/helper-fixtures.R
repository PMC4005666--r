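# Shared test helpers: an independent Kabsch oracle, tiny text fixtures
# written on the fly, and a sampler for cleanly non-matching scenes.

# Independent least-squares superposition oracle (plain SVD Kabsch),
# deliberately separate from the package's superposition path.
oracleKabschRMSD <- function(mobile, fixed) {
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  A <- sweep(mobile, 2, cm); B <- sweep(fixed, 2, cf)
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- A %*% t(R)
  sqrt(mean(rowSums((moved - B)^2)))
}

# Nine-residue and ten-residue single-strand PDBs for the eligibility
# boundary, built from the package's own duplex writer by truncation.
writeStrandPDB <- function(nResidues, path) {
  d <- buildIdealDuplex(strrep("G", 12))
  a <- atoms(d)
  keep <- a$chain == "A" & a$resno <= nResidues
  m <- new("RNAStructure", atoms = `rownames<-`(a[keep, ], NULL),
           sourceId = "strand", modelIndex = 1L)
  writeStructurePDB(m, path)
  path
}

# A PDB with one nucleotide carrying two alternate locations of N9 (the B
# conformer has the higher occupancy) plus a magnesium ion HETATM.
writeAltLocPDB <- function(path) {
  rec <- function(record, serial, name, alt, resn, chain, resno, x, y, z, occ, el) {
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, serial, name, alt, resn, chain, resno, x, y, z, occ, 0, el)
  }
  writeLines(c(
    rec("ATOM", 1L, " C1'", " ", "  G", "A", 1L, 0, 0, 0, 1.00, "C"),
    rec("ATOM", 2L, " N9 ", "A", "  G", "A", 1L, 1, 0, 0, 0.40, "N"),
    rec("ATOM", 3L, " N9 ", "B", "  G", "A", 1L, 2, 0, 0, 0.60, "N"),
    rec("HETATM", 4L, "MG  ", " ", " MG", "A", 2L, 5, 5, 5, 1.00, "MG"),
    "END"), path)
  path
}

# sample a rigid transform that is far from the pattern (>= 2x tolerances)
# AND whose realized two-helix scene contains no segment pair within 2x
# tolerances of the pattern (see countPatternMatches)
sampleNonMatchingScene <- function(pattern) {
  entry <- pattern@entries[[1L]]
  repeat {
    tr <- randomRigidTransform(c(6, 16))
    dev <- c(translation = sqrt(sum((translationVector(tr) -
                                       translationVector(entry))^2)),
             rotation = rotationAngle(rotationMatrix(tr) %*%
                                        t(rotationMatrix(entry))))
    if (dev["translation"] < 2 * pattern@translationTol ||
        dev["rotation"] < 2 * pattern@rotationTol) next
    sc <- suppressWarnings(buildTwoHelixScene("GGCGAU", "GCGAUC", tr))
    if (countPatternMatches(sc, pattern, factor = 2) == 0L) return(sc)
  }
}

toyAlignment <- function() {
  rbind(s1 = c("A", "A", "G", "C", "-"),
        s2 = c("A", "A", "G", "C", "U"),
        s3 = c("G", "G", "G", "C", "U"),
        s4 = c("-", "A", "G", "N", "U"))
}
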