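# K-turn / k-junction annotation: map structural roles onto nucleotides,
# measure the canonical cross-strand contacts, classify N1 vs N3, and
# superpose role-matched atoms between structures.
#
# Role nomenclature: the non-canonical (NC) helix opens with tandem
# purine.purine (typically G.A) pairs 1b.1n and 2b.2n ("b" on the bulged
# strand, "n" on the non-bulged strand); the loop preceding 1b is L1..L3
# (L1.1 when four nucleotides); the canonical (C) helix pairs adjacent to the
# loop are -1b.-1n and -2b.-2n. Roles are assigned by 3D position, not
# sequence: gaps between 1b and 2b are permitted (riboswitch k-junctions
# interpose extra nucleotides there).

# non-WC purine.purine candidate pairs (e.g. trans sugar/Hoogsteen G.A):
# coplanar purines with at least one base-base N/O contact in reach
.purinePairs <- function(model, excludeKeyPairs, config = ktConfig()) {
  g <- .ntGeometry(model)
  n <- length(g$geo)
  out <- list()
  if (n < 2L) return(out)
  baseNO <- function(geo) {
    nm <- intersect(rownames(geo$coords),
                    setdiff(.BASE_ATOMS[[geo$base]], "C1'"))
    nm <- nm[substr(nm, 1L, 1L) %in% c("N", "O")]
    geo$coords[nm, , drop = FALSE]
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      gi <- g$geo[[i]]; gj <- g$geo[[j]]
      if (!(gi$base %in% c("A", "G")) || !(gj$base %in% c("A", "G"))) next
      pk <- paste(sort(c(gi$key, gj$key)), collapse = "|")
      if (pk %in% excludeKeyPairs) next
      d <- .vnorm(gi$c1 - gj$c1)
      if (d < 8.0 || d > 12.0) next
      ang <- .rad2deg(acos(min(1, abs(sum(gi$normal * gj$normal)))))
      if (ang > config$maxNormalAngle) next
      # coplanarity: reject stacked purines (centres offset along the normal)
      sep <- gj$center - gi$center
      if (max(abs(sum(sep * gi$normal)), abs(sum(sep * gj$normal))) > 2.5) next
      ai <- baseNO(gi); aj <- baseNO(gj)
      dm <- sqrt(pmax(0, outer(rowSums(ai^2), rowSums(aj^2), "+") - 2 * ai %*% t(aj)))
      if (min(dm) > config$hbondMax) next
      out[[length(out) + 1L]] <- list(
        key1 = gi$key, key2 = gj$key, base1 = gi$base, base2 = gj$base,
        mid = (gi$c1 + gj$c1) / 2, minContact = min(dm))
    }
  }
  out
}

# sequence neighbours of a nucleotide (same chain, residue number +/- 1,
# no insertion-code bookkeeping beyond exact matches)
.seqNeighbours <- function(nt, key) {
  i <- which(nt$key == key)
  if (length(i) == 0L) return(character(0))
  hits <- nt$chain == nt$chain[i] & abs(nt$resno - nt$resno[i]) == 1L
  nt$key[hits]
}

#' Assign k-turn structural roles to a motif hit
#'
#' Heuristic role assignment: (1) non-WC purine.purine pairs stacked at the
#' NC-segment end facing the C segment become 1b.1n (nearest the C helix)
#' and 2b.2n (stacked on it); the 1n member is recognised by having a
#' sequence neighbour inside the hit's C-segment pairs (the non-bulged
#' strand runs ... -1n, 1n, 2n ...). (2) The loop is the run of nucleotides
#' between the last C-helix pair and 1b on the bulged strand, labelled
#' L1..L3 (L1, L1.1, L2, L3 when four). (3) -1b/-1n is the C-helix pair
#' adjacent to L1, -2b/-2n the next. (4) A further pair stacked outward of
#' 2b.2n supplies 3b/3n when present. An explicit `override` map always
#' wins.
#'
#' @param model the RNA-filtered `RNAStructure` the hit belongs to.
#' @param hit one row of the [scanStructure()] hit table (data.frame of one
#'   row).
#' @param override optional named character vector role -> nucleotide key,
#'   merged over the heuristic result (needed for "out of sequence" complex
#'   topologies).
#' @param config a [ktConfig()].
#' @return a `KTurnAssignment`. When no purine.purine candidate exists a
#'   `kjAssignmentError` is raised listing the candidates considered.
#' @export
assignRoles <- function(model, hit, override = NULL, config = ktConfig()) {
  stopifnot(nrow(hit) == 1L)
  cFrame <- hit$cFrame[[1L]]
  cPairKeys <- framePairs(cFrame)
  nt <- nucleotides(model)
  pairs <- detectBasePairs(model, config)
  wcKeyPairs <- if (nrow(pairs) > 0L)
    vapply(seq_len(nrow(pairs)),
           function(i) paste(sort(c(pairs$nt1[i], pairs$nt2[i])), collapse = "|"),
           "") else character(0)
  cand <- .purinePairs(model, wcKeyPairs, config)
  notes <- character(0)
  if (length(cand) == 0L) {
    stop(errorCondition(
      "no non-Watson-Crick purine.purine pair near the NC segment; cannot anchor 1b.1n",
      class = c("kjAssignmentError", "error", "condition"),
      candidates = character(0)))
  }
  # 1b.1n: the candidate whose member has a sequence neighbour inside the
  # C-segment pairs; fallback: nearest to the C-segment terminal pair
  cTermMid <- {
    c1 <- .atomCoord(model, cFrame@pair2[1L], "C1'")
    c2 <- .atomCoord(model, cFrame@pair2[2L], "C1'")
    (c1 + c2) / 2
  }
  nSide <- vapply(cand, function(p) {
    nb1 <- .seqNeighbours(nt, p$key1); nb2 <- .seqNeighbours(nt, p$key2)
    if (any(nb1 %in% cPairKeys)) 1L else if (any(nb2 %in% cPairKeys)) 2L else 0L
  }, 0L)
  distTerm <- vapply(cand, function(p) .vnorm(p$mid - cTermMid), 0)
  anchored <- which(nSide > 0L)
  p1i <- if (length(anchored) > 0L) anchored[which.min(distTerm[anchored])]
         else {
           notes <- c(notes, "1n anchored by proximity only (no sequence neighbour in C segment)")
           which.min(distTerm)
         }
  p1 <- cand[[p1i]]
  if (nSide[p1i] == 1L) { nt1n <- p1$key1; nt1b <- p1$key2 }
  else if (nSide[p1i] == 2L) { nt1n <- p1$key2; nt1b <- p1$key1 }
  else {
    # geometric fallback: 1n is the member nearer the C-helix non-bulged end
    d1 <- .vnorm(.atomCoord(model, p1$key1, "C1'") - cTermMid)
    d2 <- .vnorm(.atomCoord(model, p1$key2, "C1'") - cTermMid)
    if (d1 <= d2) { nt1n <- p1$key1; nt1b <- p1$key2 }
    else { nt1n <- p1$key2; nt1b <- p1$key1 }
  }
  rolesv <- c(`1b` = nt1b, `1n` = nt1n)
  # 2b.2n: next purine pair stacked on 1b.1n
  restIdx <- setdiff(seq_along(cand), p1i)
  stackD <- vapply(restIdx, function(i) .vnorm(cand[[i]]$mid - p1$mid), 0)
  chainOf <- function(key) nt$chain[nt$key == key]
  if (length(restIdx) > 0L && min(stackD) <= config$stackMaxDist * 1.25) {
    p2 <- cand[[restIdx[which.min(stackD)]]]
    if (identical(chainOf(p2$key1), chainOf(nt1b))) {
      rolesv["2b"] <- p2$key1; rolesv["2n"] <- p2$key2
    } else if (identical(chainOf(p2$key2), chainOf(nt1b))) {
      rolesv["2b"] <- p2$key2; rolesv["2n"] <- p2$key1
    } else {
      d1 <- .vnorm(.atomCoord(model, p2$key1, "C1'") - .atomCoord(model, nt1b, "C1'"))
      d2 <- .vnorm(.atomCoord(model, p2$key2, "C1'") - .atomCoord(model, nt1b, "C1'"))
      if (d1 <= d2) { rolesv["2b"] <- p2$key1; rolesv["2n"] <- p2$key2 }
      else { rolesv["2b"] <- p2$key2; rolesv["2n"] <- p2$key1 }
    }
  } else {
    p2 <- NULL
    notes <- c(notes, "no stacked second purine.purine pair; 2b/2n unassigned")
  }
  # the loop: bulged-strand nucleotides between the C helix and 1b
  i1b <- which(nt$key == nt1b)
  sameChain <- which(nt$chain == nt$chain[i1b])
  below <- sameChain[nt$resno[sameChain] < nt$resno[i1b]]
  below <- below[order(nt$resno[below], decreasing = TRUE)]
  wcPaired <- unique(c(pairs$nt1, pairs$nt2))
  loopIdx <- integer(0); m1bIdx <- NA_integer_
  for (i in below) {
    if (nt$key[i] %in% wcPaired) { m1bIdx <- i; break }
    loopIdx <- c(loopIdx, i)
  }
  loopIdx <- rev(loopIdx)
  if (length(loopIdx) == 3L) {
    rolesv[c("L1", "L2", "L3")] <- nt$key[loopIdx]
  } else if (length(loopIdx) == 4L) {
    rolesv[c("L1", "L1.1", "L2", "L3")] <- nt$key[loopIdx]
  } else if (length(loopIdx) > 0L) {
    notes <- c(notes, sprintf("loop of %d nucleotide(s) not labelled (expected 3 or 4)",
                              length(loopIdx)))
  } else {
    notes <- c(notes, "no unpaired loop found 5' of 1b")
  }
  partnerOf <- function(key) {
    i <- which(pairs$nt1 == key); if (length(i) > 0L) return(pairs$nt2[i[1L]])
    i <- which(pairs$nt2 == key); if (length(i) > 0L) return(pairs$nt1[i[1L]])
    NA_character_
  }
  if (!is.na(m1bIdx)) {
    rolesv["-1b"] <- nt$key[m1bIdx]
    pm1 <- partnerOf(nt$key[m1bIdx])
    if (!is.na(pm1)) rolesv["-1n"] <- pm1
    i2 <- which(nt$chain == nt$chain[m1bIdx] & nt$resno == nt$resno[m1bIdx] - 1L)
    if (length(i2) == 1L && nt$key[i2] %in% wcPaired) {
      rolesv["-2b"] <- nt$key[i2]
      pm2 <- partnerOf(nt$key[i2])
      if (!is.na(pm2)) rolesv["-2n"] <- pm2
    }
  } else {
    notes <- c(notes, "no Watson-Crick pair found 5' of the loop (-1b/-1n unassigned)")
  }
  # 3b.3n: a pair (WC or purine.purine) stacked outward of 2b.2n
  if (!is.null(p2)) {
    p2mid <- cand[[restIdx[which.min(stackD)]]]$mid
    best <- NULL
    if (nrow(pairs) > 0L) {
      for (i in seq_len(nrow(pairs))) {
        m1 <- .atomCoord(model, pairs$nt1[i], "C1'")
        m2 <- .atomCoord(model, pairs$nt2[i], "C1'")
        mid <- (m1 + m2) / 2
        d <- .vnorm(mid - p2mid)
        if (d <= config$stackMaxDist * 1.25 &&
            .vnorm(mid - p1$mid) > d &&
            (is.null(best) || d < best$d)) {
          best <- list(d = d, nt1 = pairs$nt1[i], nt2 = pairs$nt2[i])
        }
      }
    }
    if (!is.null(best)) {
      if (identical(chainOf(best$nt1), chainOf(nt1b))) {
        rolesv["3b"] <- best$nt1; rolesv["3n"] <- best$nt2
      } else {
        rolesv["3b"] <- best$nt2; rolesv["3n"] <- best$nt1
      }
    }
  }
  if (!is.null(override)) {
    if (is.null(names(override)) || any(!nzchar(names(override))))
      stop("override must be a named character vector (role -> nucleotide key)")
    rolesv[names(override)] <- override
    notes <- c(notes, sprintf("override applied to: %s",
                              paste(names(override), collapse = ", ")))
  }
  rolesv <- rolesv[!is.na(rolesv)]
  missing <- setdiff(rolesv, nt$key)
  if (length(missing) > 0L)
    stop(sprintf("role map names nucleotides absent from the model: %s",
                 paste(missing, collapse = ", ")))
  new("KTurnAssignment", roles = rolesv,
      completeCore = all(.KT_CORE %in% names(rolesv)),
      notes = notes)
}

#' Measure a role-to-role atomic distance
#'
#' Euclidean distance between two atoms addressed by (role, atom name).
#' Summaries report such distances to 0.1 A; this returns full precision.
#'
#' @param model an `RNAStructure`.
#' @param assignment a `KTurnAssignment` on that model.
#' @param from,to character(2): `c(role, atomName)`.
#' @return distance in angstroms.
#' @export
measureContact <- function(model, assignment, from, to) {
  getAtom <- function(spec) {
    role <- spec[1L]; atom <- spec[2L]
    key <- roles(assignment)[role]
    if (is.na(key))
      stop(errorCondition(sprintf("role %s is not assigned", role),
                          class = c("kjMissingAtom", "error", "condition")))
    p <- .atomCoord(model, key, atom)
    if (is.null(p))
      stop(errorCondition(
        sprintf("atom %s missing from role %s (nucleotide %s)", atom, role, key),
        class = c("kjMissingAtom", "error", "condition")))
    p
  }
  .vnorm(getAtom(from) - getAtom(to))
}

# the standard k-turn contact set measured by classifyNClass
.STANDARD_CONTACTS <- data.frame(
  label = c("L1 O2'-1n N1", "L1 O2'-1n N3",
            "-1n O2'-2b N1", "-1n O2'-2b N3",
            "2b N6-2n N3", "2b N6-2n N7",
            "-2n O2'-3b O2'", "L3 O2'-L2 proS-OP"),
  fromRole = c("L1", "L1", "-1n", "-1n", "2b", "2b", "-2n", "L3"),
  fromAtom = c("O2'", "O2'", "O2'", "O2'", "N6", "N6", "O2'", "O2'"),
  toRole = c("1n", "1n", "2b", "2b", "2n", "2n", "3b", "L2"),
  toAtom = c("N1", "N3", "N1", "N3", "N3", "N7", "O2'", "OP2"),
  stringsAsFactors = FALSE)

#' Measure the standard contact set and classify N1 vs N3
#'
#' Measures the canonical k-turn contacts (the two conserved cross-strand
#' hydrogen bonds L1 O2' -> A1n and -1n O2' -> A2b among them) and sets the
#' class to whichever of 2b N1 / 2b N3 lies nearer the -1n O2' donor. Every
#' standard label appears in the table; unmeasurable ones are flagged
#' missing rather than silently dropped. Distances up to 3.5 A are labelled
#' "bonded", up to 4.0 A "borderline" (narrative labels, not assertions).
#'
#' @param model an `RNAStructure`.
#' @param assignment a `KTurnAssignment` with a complete core.
#' @param bondedMax,borderlineMax narrative thresholds, angstroms.
#' @return a `ContactReport`.
#' @export
classifyNClass <- function(model, assignment, bondedMax = 3.5,
                           borderlineMax = 4.0) {
  if (!completeCore(assignment))
    warning("assignment core is incomplete; contact table will have gaps")
  tab <- .STANDARD_CONTACTS
  tab$distance <- NA_real_
  tab$status <- "missing"
  for (i in seq_len(nrow(tab))) {
    d <- tryCatch(
      measureContact(model, assignment,
                     c(tab$fromRole[i], tab$fromAtom[i]),
                     c(tab$toRole[i], tab$toAtom[i])),
      kjMissingAtom = function(e) NA_real_)
    if (!is.na(d)) {
      tab$distance[i] <- d
      tab$status[i] <- if (d <= bondedMax) "bonded"
        else if (d <= borderlineMax) "borderline" else "long"
    }
  }
  d1 <- tab$distance[tab$label == "-1n O2'-2b N1"]
  d3 <- tab$distance[tab$label == "-1n O2'-2b N3"]
  cls <- if (is.na(d1) || is.na(d3) || d1 == d3) "undetermined"
    else if (d1 < d3) "N1" else "N3"
  new("ContactReport", contacts = tab, nClass = cls)
}

#' Named backbone atom sets for superposition
#'
#' `"backbone"`: full sugar-phosphate backbone plus the ribose ring
#' (P, OP1, OP2, O5', C5', C4', C3', O3', C2', C1', O4'); `"trace"`:
#' phosphate and sugar trace only (P, O5', C5', C4', C3', O3').
#'
#' @param name `"backbone"` or `"trace"`.
#' @return character vector of atom names.
#' @export
backboneAtomSet <- function(name = c("backbone", "trace")) {
  switch(match.arg(name),
         backbone = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "O3'",
                      "C2'", "C1'", "O4'"),
         trace = c("P", "O5'", "C5'", "C4'", "C3'", "O3'"))
}

#' Superpose role-matched atoms between two structures
#'
#' Least-squares rigid superposition (Kabsch) of the mobile structure onto
#' the reference over the atoms of the requested roles present in both
#' structures. The applied rotation is proper (determinant +1).
#'
#' @param mobile,reference `RNAStructure` models.
#' @param mobileAssignment,referenceAssignment `KTurnAssignment` objects on
#'   the respective models.
#' @param roleSet roles to superpose over (default the core used for k-turn
#'   comparisons: -1n, L1, 2b, 1n, 2n).
#' @param atomSet atom names per role; see [backboneAtomSet()].
#' @return list with `rmsd` (angstroms), `nAtoms`, and `atoms` (the matched
#'   role/atom labels). Fewer than 3 matched atoms raises a
#'   `kjUnderdetermined` error.
#' @export
superposeRoles <- function(mobile, mobileAssignment, reference,
                           referenceAssignment,
                           roleSet = c("-1n", "L1", "2b", "1n", "2n"),
                           atomSet = backboneAtomSet("backbone")) {
  mr <- roles(mobileAssignment); rr <- roles(referenceAssignment)
  xm <- list(); xr <- list(); labels <- character(0)
  for (role in roleSet) {
    if (is.na(mr[role]) || is.na(rr[role]))
      stop(errorCondition(sprintf("role %s missing from an assignment", role),
                          class = c("kjUnderdetermined", "error", "condition")))
    cm <- .residueCoords(mobile, mr[role])
    cr <- .residueCoords(reference, rr[role])
    for (atom in atomSet) {
      if (atom %in% rownames(cm) && atom %in% rownames(cr)) {
        xm[[length(xm) + 1L]] <- cm[atom, ]
        xr[[length(xr) + 1L]] <- cr[atom, ]
        labels <- c(labels, paste(role, atom))
      }
    }
  }
  if (length(labels) < 3L)
    stop(errorCondition("fewer than 3 matched atoms; superposition underdetermined",
                        class = c("kjUnderdetermined", "error", "condition")))
  xm <- do.call(rbind, xm); xr <- do.call(rbind, xr)
  inds <- seq_len(3L * nrow(xr))
  fitted <- matrix(bio3d::fit.xyz(fixed = as.numeric(t(xr)),
                                  mobile = as.numeric(t(xm)),
                                  fixed.inds = inds, mobile.inds = inds),
                   ncol = 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - xr)^2)))
  list(rmsd = rmsd, nAtoms = length(labels), atoms = labels)
}
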