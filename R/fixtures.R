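# Synthetic coordinate generators: idealized A-form duplexes, two-helix
# scenes planted at a prescribed relative transform, and a synthetic k-turn.
# These stand in for downloaded coordinate files so that pair detection,
# framing, scanning and annotation are testable offline. The scenes validate
# the geometric search; they are idealized rigid constructions, not
# energy-minimised RNA (no sugar-pucker variation, no sequence-dependent
# helical parameters).

# Planar base heavy-atom coordinates (angstroms, z = 0) in the standard
# nucleic-acid base reference frame (Olson et al. 2001, J Mol Biol 313:229),
# C1' included. The complementary strand of an ideal Watson-Crick pair is the
# 180 degree rotation about x: (x, -y, -z).
.BASE_XYZ <- local({
  mk <- function(...) {
    v <- c(...)
    nm <- v[seq(1, length(v), by = 3)]
    xy <- matrix(as.numeric(v[-seq(1, length(v), by = 3)]), ncol = 2, byrow = TRUE)
    out <- cbind(xy, 0)
    rownames(out) <- nm
    colnames(out) <- c("x", "y", "z")
    out
  }
  list(
    A = mk("C1'", -2.479, 5.346, "N9", -1.291, 4.498, "C8", 0.024, 4.897,
           "N7", 0.877, 3.902, "C5", 0.071, 2.771, "C6", 0.369, 1.398,
           "N6", 1.611, 0.909, "N1", -0.668, 0.532, "C2", -1.912, 1.023,
           "N3", -2.320, 2.290, "C4", -1.267, 3.124),
    G = mk("C1'", -2.477, 5.399, "N9", -1.289, 4.551, "C8", 0.023, 4.962,
           "N7", 0.870, 3.969, "C5", 0.071, 2.833, "C6", 0.424, 1.460,
           "O6", 1.554, 0.955, "N1", -0.700, 0.641, "C2", -1.999, 1.087,
           "N2", -2.949, 0.139, "N3", -2.342, 2.364, "C4", -1.265, 3.177),
    C = mk("C1'", -2.477, 5.402, "N1", -1.285, 4.542, "C2", -1.472, 3.158,
           "O2", -2.628, 2.709, "N3", -0.391, 2.344, "C4", 0.837, 2.868,
           "N4", 1.875, 2.027, "C5", 1.056, 4.275, "C6", -0.023, 5.068),
    U = mk("C1'", -2.481, 5.354, "N1", -1.284, 4.500, "C2", -1.462, 3.131,
           "O2", -2.563, 2.608, "N3", -0.302, 2.397, "C4", 0.989, 2.884,
           "O4", 1.935, 2.094, "C5", 1.089, 4.311, "C6", -0.024, 5.053)
  )
})

# Sugar-phosphate template for strand I in the same frame (C1' is taken from
# the base table). Bond lengths are plausible; the backbone serves atom
# completeness and steric checks, not conformational realism.
.BACKBONE_XYZ <- local({
  m <- matrix(c(
    -3.514, 5.620,  0.950,   # O4'
    -4.628, 5.000,  0.300,   # C4'
    -5.900, 5.400,  1.000,   # C5'
    -6.000, 4.600,  2.150,   # O5'
    -6.100, 3.300,  2.900,   # P
    -7.400, 3.300,  3.600,   # OP1
    -5.300, 2.200,  3.300,   # OP2
    -4.600, 6.100, -0.900,   # C3'
    -5.500, 7.200, -0.850,   # O3'
    -3.050, 6.250, -1.000,   # C2'
    -2.300, 7.350, -1.350    # O2'
  ), ncol = 3, byrow = TRUE)
  rownames(m) <- c("O4'", "C4'", "C5'", "O5'", "P", "OP1", "OP2",
                   "C3'", "O3'", "C2'", "O2'")
  colnames(m) <- c("x", "y", "z")
  m
})

.WC_PARTNER <- c(A = "U", U = "A", G = "C", C = "G")

# Full heavy-atom template of one residue (strand I orientation).
.residueTemplate <- function(base) {
  rbind(.BASE_XYZ[[base]], .BACKBONE_XYZ)
}

.flipXYZ <- function(m) {
  m[, 2L] <- -m[, 2L]
  m[, 3L] <- -m[, 3L]
  m
}

.applyInPlane <- function(m, theta, dx, dy) {
  c_ <- cos(theta); s_ <- sin(theta)
  out <- m
  out[, 1L] <- c_ * m[, 1L] - s_ * m[, 2L] + dx
  out[, 2L] <- s_ * m[, 1L] + c_ * m[, 2L] + dy
  out
}

.kjFixtureEnv <- new.env(parent = emptyenv())

# In-plane placement of strand-II U against strand-I G forming the wobble
# contacts O6...N3 and N1...O2 at ~2.85 A. Solved once, cached.
.wobbleOffset <- function() {
  if (!is.null(.kjFixtureEnv$wobble)) return(.kjFixtureEnv$wobble)
  G <- .BASE_XYZ$G
  Uf <- .flipXYZ(.BASE_XYZ$U)
  obj <- function(p) {
    m <- .applyInPlane(Uf, p[1L], p[2L], p[3L])
    d1 <- .vnorm(m["N3", ] - G["O6", ])
    d2 <- .vnorm(m["O2", ] - G["N1", ])
    dc <- .vnorm(m["C1'", ] - G["C1'", ])
    (d1 - 2.85)^2 + (d2 - 2.85)^2 + 0.02 * (dc - 10.4)^2
  }
  fit <- stats::optim(c(0, 1.86, 0.5), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  .kjFixtureEnv$wobble <- fit$par
  fit$par
}

# In-plane placement of strand-II A against strand-I G forming the trans
# sugar(G).Hoogsteen(A) contacts G N2...A N7 and G N3...A N6 at ~2.9 A.
.shearedOffset <- function() {
  if (!is.null(.kjFixtureEnv$sheared)) return(.kjFixtureEnv$sheared)
  G <- .BASE_XYZ$G
  Af <- .flipXYZ(.BASE_XYZ$A)
  obj <- function(p) {
    m <- .applyInPlane(Af, p[1L], p[2L], p[3L])
    d1 <- .vnorm(m["N7", ] - G["N2", ])
    d2 <- .vnorm(m["N6", ] - G["N3", ])
    dc <- .vnorm(m["C1'", ] - G["C1'", ])
    # keep the bases apart: penalise any ring-ring approach under 2.7 A
    ring <- as.matrix(stats::dist(rbind(G[-1L, 1:2], m[-1L, 1:2])))
    cl <- ring[seq_len(nrow(G) - 1L), nrow(G) - 1L + seq_len(nrow(m) - 1L)]
    (d1 - 2.9)^2 + (d2 - 2.9)^2 + 0.02 * (dc - 10.0)^2 +
      sum(pmax(0, 2.7 - cl)^2)
  }
  # start from a two-point rigid fit of (N7, N6) onto targets 2.9 A out from
  # (N2, N3) along an outward direction
  u <- .unitv(c(0.10, -0.995, 0))
  t7 <- G["N2", 1:2] + 2.9 * u[1:2]
  t6 <- G["N3", 1:2] + 2.9 * u[1:2]
  cur <- Af[c("N7", "N6"), 1:2]
  va <- cur[2L, ] - cur[1L, ]; vb <- t6 - t7
  th0 <- atan2(vb[2L], vb[1L]) - atan2(va[2L], va[1L])
  c0 <- cos(th0); s0 <- sin(th0)
  p7 <- c(c0 * cur[1L, 1L] - s0 * cur[1L, 2L], s0 * cur[1L, 1L] + c0 * cur[1L, 2L])
  start <- c(th0, t7[1L] - p7[1L], t7[2L] - p7[2L])
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  .kjFixtureEnv$sheared <- fit$par
  fit$par
}

# A base-pair template: named list with strand-I and strand-II residue
# coordinate matrices, recentred so the C1'-C1' midpoint is the origin and
# the pair plane is z = 0 (helix axis through the origin along +z).
.pairTemplate <- function(base1, base2, kind = c("WC", "wobble", "sheared")) {
  kind <- match.arg(kind)
  key <- paste(base1, base2, kind)
  if (!is.null(.kjFixtureEnv[[key]])) return(.kjFixtureEnv[[key]])
  flipped <- FALSE
  if (kind == "WC") {
    if (!identical(.WC_PARTNER[[base1]], base2))
      stop(sprintf("%s-%s is not a Watson-Crick combination", base1, base2))
    if (base1 %in% c("U", "C")) flipped <- TRUE
  } else if (kind == "wobble") {
    if (!(paste0(base1, base2) %in% c("GU", "UG")))
      stop("wobble template requires G and U")
    if (base1 == "U") flipped <- TRUE
  } else {
    if (!(paste0(base1, base2) %in% c("GA", "AG")))
      stop("sheared template requires G and A")
    if (base1 == "A") flipped <- TRUE
  }
  b1 <- if (flipped) base2 else base1
  b2 <- if (flipped) base1 else base2
  s1 <- .residueTemplate(b1)
  s2 <- .flipXYZ(.residueTemplate(b2))
  if (kind == "wobble") {
    p <- .wobbleOffset(); s2 <- .applyInPlane(s2, p[1L], p[2L], p[3L])
  } else if (kind == "sheared") {
    p <- .shearedOffset(); s2 <- .applyInPlane(s2, p[1L], p[2L], p[3L])
  }
  if (flipped) {
    tmp <- .flipXYZ(s2); s2 <- .flipXYZ(s1); s1 <- tmp
  }
  mid <- (s1["C1'", ] + s2["C1'", ]) / 2
  s1 <- sweep(s1, 2L, mid); s2 <- sweep(s2, 2L, mid)
  out <- list(s1 = s1, s2 = s2)
  .kjFixtureEnv[[key]] <- out
  out
}

#' Specify a synthetic helix
#'
#' @param sequence strand-I sequence, 5' to 3', over A/C/G/U.
#' @param complement optional explicit partner bases, aligned with `sequence`
#'   (position i pairs position i); defaults to the Watson-Crick complement.
#'   A G/U combination yields a wobble pair, G/A or A/G a sheared
#'   (trans sugar/Hoogsteen) pair.
#' @param rise helical rise, angstroms per base pair.
#' @param twist helical twist, degrees per base pair.
#' @param pose a `RigidTransform` placing the helix in the scene.
#' @return a `helixSpec` list.
#' @export
helixSpec <- function(sequence, complement = NULL, rise = 2.81, twist = 32.7,
                      pose = identityTransform()) {
  sequence <- toupper(sequence)
  bases <- strsplit(sequence, "")[[1L]]
  if (length(bases) == 0L) stop("empty helix sequence")
  if (!all(bases %in% c("A", "C", "G", "U")))
    stop("sequence must be over A, C, G, U")
  if (rise <= 0) stop("rise must be > 0")
  if (twist <= 0 || twist >= 360) stop("twist must be in (0, 360)")
  comp <- if (is.null(complement)) unname(.WC_PARTNER[bases])
          else strsplit(toupper(complement), "")[[1L]]
  if (length(comp) != length(bases))
    stop("complement must align with sequence")
  kind <- character(length(bases))
  for (i in seq_along(bases)) {
    duo <- paste0(bases[i], comp[i])
    kind[i] <- if (duo %in% c("AU", "UA", "GC", "CG")) "WC"
      else if (duo %in% c("GU", "UG")) "wobble"
      else if (duo %in% c("GA", "AG")) "sheared"
      else stop(sprintf("unsupported base combination %s at position %d", duo, i))
  }
  structure(list(bases = bases, partner = comp, kind = kind,
                 rise = rise, twist = twist, pose = pose),
            class = "helixSpec")
}

# Atom rows for one residue placed at a pose.
.residueRows <- function(coords, chain, resno, base) {
  data.frame(chain = chain, resno = as.integer(resno), insert = "",
             resname = base, base = base, elety = rownames(coords),
             x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
             o = 1, stringsAsFactors = FALSE)
}

#' Build an idealized duplex
#'
#' Stacks base-pair templates with the given rise and twist about the +z
#' axis (pair 1 at the origin, C1'-C1' midpoints on the axis), then applies
#' the spec's pose. Strand I is chain `chains[1]` numbered 5' to 3' along +z;
#' strand II runs antiparallel on `chains[2]`. Every nucleotide carries the
#' full heavy-atom complement.
#'
#' @param spec a [helixSpec()] (a plain sequence string is also accepted).
#' @param chains character(2) chain identifiers.
#' @param startResno integer(2), first residue number of each chain.
#' @param sourceId stored model identifier.
#' @return an `RNAStructure` with attribute `pairTable` (data.frame with
#'   `pair`, `key1`, `key2`, `kind`).
#' @export
buildIdealDuplex <- function(spec, chains = c("A", "B"), startResno = c(1L, 1L),
                             sourceId = "ideal-duplex") {
  if (is.character(spec)) spec <- helixSpec(spec)
  n <- length(spec$bases)
  rows <- vector("list", 2L * n)
  keys1 <- character(n); keys2 <- character(n)
  for (i in seq_len(n)) {
    tpl <- .pairTemplate(spec$bases[i], spec$partner[i], spec$kind[i])
    Rz <- rotationAboutAxis(c(0, 0, 1), (i - 1L) * spec$twist)
    shift <- c(0, 0, (i - 1L) * spec$rise)
    s1 <- sweep(tpl$s1 %*% t(Rz), 2L, -shift)
    s2 <- sweep(tpl$s2 %*% t(Rz), 2L, -shift)
    rownames(s1) <- rownames(tpl$s1); rownames(s2) <- rownames(tpl$s2)
    r1 <- startResno[1L] + i - 1L
    r2 <- startResno[2L] + (n - i)
    rows[[i]] <- .residueRows(s1, chains[1L], r1, spec$bases[i])
    rows[[n + (n - i + 1L)]] <- .residueRows(s2, chains[2L], r2, spec$partner[i])
    keys1[i] <- .ntKey(chains[1L], r1, "")
    keys2[i] <- .ntKey(chains[2L], r2, "")
  }
  atoms <- do.call(rbind, rows)
  model <- .rnaStructure(atoms, sourceId = sourceId)
  model <- transformStructure(model, spec$pose)
  attr(model, "pairTable") <- data.frame(
    pair = seq_len(n), key1 = keys1, key2 = keys2, kind = spec$kind,
    stringsAsFactors = FALSE)
  model
}

#' Helix-segment frame from explicit base-pair keys
#'
#' Builds the (origin, axis, hbond, normal) frame of the segment formed by
#' two base pairs given as nucleotide keys, using their C1' atoms. The origin
#' sits at pair 1 and the axis points toward pair 2.
#'
#' @param model an `RNAStructure`.
#' @param pair1,pair2 character(2): strand-1 and strand-2 nucleotide keys.
#' @return a `HelixFrame`.
#' @export
frameFromPairKeys <- function(model, pair1, pair2) {
  get1 <- function(key) {
    p <- .atomCoord(model, key, "C1'")
    if (is.null(p)) stop(sprintf("nucleotide %s has no C1' atom", key))
    p
  }
  .frameFromC1(get1(pair1[1L]), get1(pair1[2L]),
               get1(pair2[1L]), get1(pair2[2L]),
               pair1 = pair1, pair2 = pair2)
}

# Frame of pair indices (i -> j) of a duplex built by buildIdealDuplex.
.duplexFrame <- function(model, i, j) {
  pt <- attr(model, "pairTable")
  frameFromPairKeys(model,
                    c(pt$key1[pt$pair == i], pt$key2[pt$pair == i]),
                    c(pt$key1[pt$pair == j], pt$key2[pt$pair == j]))
}

#' Build a two-helix scene at a prescribed relative transform
#'
#' Places helix B so that the relative transform from the anchor segment of
#' helix A to the anchor segment of helix B equals `transform` exactly (loop
#' closure holds to numerical precision; re-measuring through pair detection
#' and framing recovers it within 1e-3). Helix A keeps chains A/B, helix B is
#' renamed to chains C/D. Any inter-helix heavy-atom approach below 2 A
#' raises a warning and sets the `clash` attribute.
#'
#' @param specA,specB [helixSpec()] objects (or sequence strings).
#' @param transform a `RigidTransform`: the desired pose of B's anchor frame
#'   in A's anchor-frame coordinates.
#' @param anchorA integer(2) pair indices in helix A defining the reference
#'   segment; defaults to the last two pairs.
#' @param anchorB integer(2) pair indices in helix B; defaults to `c(1, 2)`.
#' @param pose optional global `RigidTransform` applied to the whole scene.
#' @return an `RNAStructure` with attributes `pairTableA`, `pairTableB`,
#'   `anchorA`, `anchorB` (key sets) and `clash` (logical).
#' @export
buildTwoHelixScene <- function(specA, specB, transform,
                               anchorA = NULL, anchorB = c(1L, 2L),
                               pose = identityTransform()) {
  if (is.character(specA)) specA <- helixSpec(specA)
  if (is.character(specB)) specB <- helixSpec(specB)
  A <- buildIdealDuplex(specA, chains = c("A", "B"), sourceId = "sceneA")
  B <- buildIdealDuplex(specB, chains = c("C", "D"), sourceId = "sceneB")
  ptA <- attr(A, "pairTable"); ptB <- attr(B, "pairTable")
  nA <- nrow(ptA)
  if (is.null(anchorA)) anchorA <- c(nA - 1L, nA)
  fA <- .duplexFrame(A, anchorA[1L], anchorA[2L])
  fB0 <- .duplexFrame(B, anchorB[1L], anchorB[2L])
  # desired frame of B's anchor in global coordinates
  triadDes <- fA@triad %*% transform@rotation
  originDes <- fA@origin + as.numeric(fA@triad %*% transform@translation)
  Rm <- triadDes %*% t(fB0@triad)
  tm <- originDes - as.numeric(Rm %*% fB0@origin)
  B <- transformStructure(B, rigidTransform(Rm, tm))
  atoms <- rbind(A@atoms, B@atoms)
  scene <- .rnaStructure(atoms, sourceId = "two-helix-scene")
  scene <- transformStructure(scene, pose)
  # inter-helix steric check
  ia <- scene@atoms$chain %in% c("A", "B")
  xa <- as.matrix(scene@atoms[ia, c("x", "y", "z")])
  xb <- as.matrix(scene@atoms[!ia, c("x", "y", "z")])
  minD <- sqrt(max(0, min(outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb))))
  clash <- is.finite(minD) && minD < 2.0
  if (clash) warning("inter-helix clash: heavy atoms closer than 2.0 A")
  anchorKeysA <- list(pair1 = c(ptA$key1[anchorA[1L]], ptA$key2[anchorA[1L]]),
                      pair2 = c(ptA$key1[anchorA[2L]], ptA$key2[anchorA[2L]]))
  anchorKeysB <- list(pair1 = c(ptB$key1[anchorB[1L]], ptB$key2[anchorB[1L]]),
                      pair2 = c(ptB$key1[anchorB[2L]], ptB$key2[anchorB[2L]]))
  structure(scene, pairTableA = ptA, pairTableB = ptB,
            anchorA = anchorKeysA, anchorB = anchorKeysB, clash = clash)
}

#' Synthetic k-turn reference scene
#'
#' A minimal idealized k-turn: a canonical (C) helix of three Watson-Crick
#' pairs, a three-nucleotide loop, and a non-canonical (NC) helix opening
#' with tandem sheared G.A / A.G pairs followed by three Watson-Crick pairs,
#' the NC helix posed at a tight kink (~130 degrees between outgoing axes)
#' against the C helix. Chain A is the bulged strand (-2b..-1b, L1..L3,
#' 1b..3b and a closing pair), chain B the non-bulged strand. The true role
#' map is attached as attribute `roles`; the construction is deterministic.
#'
#' This scene defines the canonical search geometry used by
#' [kturnReferencePattern()]. It validates the geometric pipeline; it is a
#' synthetic construction, not refined atomic coordinates of any deposited
#' structure.
#'
#' @return an `RNAStructure` with attributes `roles` (named character),
#'   `cPairs`, `ncPairs` (pair tables) and `selectors`.
#' @export
buildSyntheticKTurn <- function() {
  # C helix: pairs 1..3 bottom to top; A:1-3 with B:8-6
  cSpec <- helixSpec("GCG")
  C <- buildIdealDuplex(cSpec, chains = c("A", "B"), startResno = c(1L, 6L),
                        sourceId = "kturnC")
  # NC helix: pairs 1..5 outward from the junction; A:7-11 with B:5-1
  ncSpec <- helixSpec("GACGA", complement = "AGGCU")
  NC <- buildIdealDuplex(ncSpec, chains = c("A", "B"), startResno = c(7L, 1L),
                         sourceId = "kturnNC")
  # pose NC: axis kinked 125 degrees away from +z (tilt about x), spun about
  # its own axis, first pair placed above and beside the C helix top so the
  # two helices pack closely (~2.8 A closest approach) without clashing
  tilt <- rotationAboutAxis(c(1, 0, 0), 125)
  ncAxis <- as.numeric(tilt %*% c(0, 0, 1))
  spin <- rotationAboutAxis(ncAxis, 180)
  NC <- transformStructure(NC, rigidTransform(spin %*% tilt, c(0, -9, 11)))
  # loop residues L1..L3 bridge A:3 (-1b) to A:7 (1b)
  p0 <- .atomCoord(C, "A:3", "C1'")
  p1 <- .atomCoord(NC, "A:7", "C1'")
  loopBases <- c("C", "U", "U")
  loopRows <- vector("list", 3L)
  for (k in 1:3) {
    tfrac <- k / 4
    bump <- 4.5 * sin(pi * tfrac)
    target <- p0 + tfrac * (p1 - p0) + c(0, bump, 1.5 * sin(pi * tfrac))
    tpl <- .residueTemplate(loopBases[k])
    tpl <- tpl %*% t(rotationAboutAxis(c(0, 0, 1), 50 * k))
    rownames(tpl) <- rownames(.residueTemplate(loopBases[k]))
    tpl <- sweep(tpl, 2L, tpl["C1'", ] - target)
    loopRows[[k]] <- .residueRows(tpl, "A", 3L + k, loopBases[k])
  }
  aC <- C@atoms; aNC <- NC@atoms; aL <- do.call(rbind, loopRows)
  # file order: chain A 5'->3' (C strand1, loop, NC strand1), then chain B
  chainA <- rbind(aC[aC$chain == "A", ], aL, aNC[aNC$chain == "A", ])
  chainB <- rbind(aNC[aNC$chain == "B", ], aC[aC$chain == "B", ])
  model <- .rnaStructure(rbind(chainA, chainB), sourceId = "synthetic-kturn")
  roles <- c(`-2b` = "A:2", `-2n` = "B:7", `-1b` = "A:3", `-1n` = "B:6",
             L1 = "A:4", L2 = "A:5", L3 = "A:6",
             `1b` = "A:7", `1n` = "B:5", `2b` = "A:8", `2n` = "B:4",
             `3b` = "A:9", `3n` = "B:3")
  structure(model,
            roles = roles,
            cPairs = attr(C, "pairTable"),
            ncPairs = attr(NC, "pairTable"),
            selectors = list(c = c("A:1-3", "B:6-8"), nc = c("A:9-11", "B:1-3")))
}
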