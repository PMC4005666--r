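# Watson-Crick / wobble base-pair detection and two-pair helix segments.
#
# Pairing criteria (configurable via ktConfig): complementary bases (A-U,
# G-C, and the G.U wobble), C1'-C1' distance within a window, at least two
# base-base donor-acceptor heavy-atom contacts within the hydrogen-bond
# cutoff (the wobble requires exactly its two canonical contacts), and
# near-coplanar base planes. Conflicts are resolved greedily, one pair per
# nucleotide, by summed hydrogen-bond score.

#' Geometric tolerances for pairing, stacking and scanning
#'
#' All tolerances used by the pipeline in one object.
#'
#' @param c1c1Range C1'-C1' distance window for a base pair, angstroms.
#' @param hbondMax maximum donor-acceptor heavy-atom distance, angstroms.
#' @param maxNormalAngle maximum angle between base-plane normals, degrees.
#' @param minContacts minimum number of in-cutoff contacts for a
#'   Watson-Crick pair (the wobble always requires both of its contacts).
#' @param stackMaxDist maximum separation of the C1'-C1' midpoints of two
#'   stacked pairs forming a helix segment, angstroms.
#' @param twistRange admissible inter-pair twist of a segment, degrees.
#' @param translationTol,rotationTol default motif-scan tolerances
#'   (angstroms, degrees).
#' @return a `ktConfig` list.
#' @export
ktConfig <- function(c1c1Range = c(8.9, 11.9), hbondMax = 3.5,
                     maxNormalAngle = 65, minContacts = 2L,
                     stackMaxDist = 5.5, twistRange = c(10, 60),
                     translationTol = 4.0, rotationTol = 25) {
  stopifnot(hbondMax > 0, minContacts >= 1L, stackMaxDist > 0,
            translationTol > 0, rotationTol > 0)
  structure(list(c1c1Range = c1c1Range, hbondMax = hbondMax,
                 maxNormalAngle = maxNormalAngle,
                 minContacts = as.integer(minContacts),
                 stackMaxDist = stackMaxDist, twistRange = twistRange,
                 translationTol = translationTol, rotationTol = rotationTol),
            class = "ktConfig")
}

# canonical donor -> acceptor heavy-atom contacts; first letter of the name
# is the base owning the first atom
.PAIR_CONTACTS <- list(
  AU = list(c("N1", "N3"), c("N6", "O4")),
  GC = list(c("N1", "N3"), c("O6", "N4"), c("N2", "O2")),
  GU = list(c("O6", "N3"), c("N1", "O2"))
)

# donor side of each contact (TRUE = atom on the first-named base donates)
.PAIR_DONOR1 <- list(
  AU = c(FALSE, TRUE),   # U N3 -> A N1 ; A N6 -> U O4
  GC = c(TRUE, FALSE, TRUE),  # G N1 -> C N3 ; C N4 -> G O6 ; G N2 -> C O2
  GU = c(FALSE, TRUE)    # U N3 -> G O6 ; G N1 -> U O2
)

# Per-nucleotide geometry cache: C1' coordinates, base atoms, ring normal.
.ntGeometry <- function(model) {
  nt <- nucleotides(model)
  nt <- nt[!is.na(nt$base), , drop = FALSE]
  geo <- vector("list", nrow(nt))
  keep <- logical(nrow(nt))
  for (i in seq_len(nrow(nt))) {
    m <- .residueCoords(model, nt$key[i])
    ring <- if (nt$base[i] %in% c("A", "G")) .PURINE_RING else .PYRIMIDINE_RING
    if (!("C1'" %in% rownames(m)) || !all(ring %in% rownames(m))) next
    rc <- m[ring, , drop = FALSE]
    ctr <- colMeans(rc)
    sv <- svd(sweep(rc, 2L, ctr))
    geo[[i]] <- list(key = nt$key[i], base = nt$base[i],
                     c1 = m["C1'", ], coords = m,
                     normal = sv$v[, 3L], center = ctr)
    keep[i] <- TRUE
  }
  list(nt = nt[keep, , drop = FALSE], geo = geo[keep])
}

#' Detect Watson-Crick and wobble base pairs
#'
#' @param model an `RNAStructure`, filtered to RNA.
#' @param config a [ktConfig()].
#' @return data.frame with one row per pair: `nt1`, `nt2` (nucleotide keys,
#'   canonical order), `base1`, `base2`, `kind` ("WC" or "wobble"), `c1c1`,
#'   `nContacts`, `score`, and a list-column `hbonds` of per-contact
#'   data.frames (`donor`, `acceptor`, `distance`). Each nucleotide appears
#'   in at most one pair. Empty data.frame when nothing pairs.
#' @export
detectBasePairs <- function(model, config = ktConfig()) {
  g <- .ntGeometry(model)
  n <- length(g$geo)
  empty <- data.frame(nt1 = character(), nt2 = character(),
                      base1 = character(), base2 = character(),
                      kind = character(), c1c1 = numeric(),
                      nContacts = integer(), score = numeric())
  empty$hbonds <- list()
  if (n < 2L) return(empty)
  cand <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      gi <- g$geo[[i]]; gj <- g$geo[[j]]
      duo <- paste0(gi$base, gj$base)
      swap <- FALSE
      key <- switch(duo,
                    AU = "AU", UA = { swap <- TRUE; "AU" },
                    GC = "GC", CG = { swap <- TRUE; "GC" },
                    GU = "GU", UG = { swap <- TRUE; "GU" },
                    NULL)
      if (is.null(key)) next
      d <- .vnorm(gi$c1 - gj$c1)
      if (d < config$c1c1Range[1L] || d > config$c1c1Range[2L]) next
      ang <- .rad2deg(acos(min(1, abs(sum(gi$normal * gj$normal)))))
      if (ang > config$maxNormalAngle) next
      a <- if (swap) gj else gi
      b <- if (swap) gi else gj
      contacts <- .PAIR_CONTACTS[[key]]
      donor1 <- .PAIR_DONOR1[[key]]
      dist <- vapply(contacts, function(ct) {
        if (!(ct[1L] %in% rownames(a$coords)) ||
            !(ct[2L] %in% rownames(b$coords))) return(NA_real_)
        .vnorm(a$coords[ct[1L], ] - b$coords[ct[2L], ])
      }, numeric(1L))
      ok <- !is.na(dist) & dist <= config$hbondMax
      isWobble <- key == "GU"
      if (isWobble) {
        if (!all(ok)) next
      } else if (sum(ok) < config$minContacts) next
      hb <- data.frame(
        donor = ifelse(donor1, paste(a$key, vapply(contacts, `[`, "", 1L)),
                       paste(b$key, vapply(contacts, `[`, "", 2L))),
        acceptor = ifelse(donor1, paste(b$key, vapply(contacts, `[`, "", 2L)),
                          paste(a$key, vapply(contacts, `[`, "", 1L))),
        distance = dist, stringsAsFactors = FALSE)[ok, , drop = FALSE]
      cand[[length(cand) + 1L]] <- list(
        i = i, j = j, kind = if (isWobble) "wobble" else "WC",
        c1c1 = d, nContacts = sum(ok),
        score = sum(config$hbondMax - dist[ok]), hbonds = hb)
    }
  }
  if (length(cand) == 0L) return(empty)
  ord <- order(vapply(cand, `[[`, 0, "score"), decreasing = TRUE)
  used <- logical(n)
  rows <- list()
  for (k in ord) {
    cc <- cand[[k]]
    if (used[cc$i] || used[cc$j]) next
    used[cc$i] <- used[cc$j] <- TRUE
    rows[[length(rows) + 1L]] <- cc
  }
  # canonical member order within a pair: (chain, resno, insert), so the
  # result is invariant to the strand order of the file
  nt <- g$nt
  rank <- order(nt$chain, nt$resno, nt$insert)
  pos <- integer(nrow(nt)); pos[rank] <- seq_len(nrow(nt))
  rows <- lapply(rows, function(r) {
    if (pos[r$j] < pos[r$i]) { tmp <- r$i; r$i <- r$j; r$j <- tmp }
    r
  })
  rows <- rows[order(vapply(rows, function(r) pos[r$i], 0L))]
  out <- data.frame(
    nt1 = vapply(rows, function(r) g$geo[[r$i]]$key, ""),
    nt2 = vapply(rows, function(r) g$geo[[r$j]]$key, ""),
    base1 = vapply(rows, function(r) g$geo[[r$i]]$base, ""),
    base2 = vapply(rows, function(r) g$geo[[r$j]]$base, ""),
    kind = vapply(rows, `[[`, "", "kind"),
    c1c1 = vapply(rows, `[[`, 0, "c1c1"),
    nContacts = vapply(rows, function(r) as.integer(r$nContacts), 0L),
    score = vapply(rows, `[[`, 0, "score"),
    stringsAsFactors = FALSE)
  out$hbonds <- lapply(rows, `[[`, "hbonds")
  out
}

#' Helix-segment frame from two base pairs
#'
#' Computes the four-vector frame of the segment formed by `pair1` and
#' `pair2`: origin at the midpoint of pair 1's C1' atoms, unit axis toward
#' pair 2's midpoint, hydrogen-bond direction (strand 1 C1' toward strand 2
#' C1' of pair 1) projected perpendicular to the axis, and their
#' right-handed normal.
#'
#' @param model an `RNAStructure`.
#' @param pair1,pair2 either single rows of the [detectBasePairs()] table or
#'   character(2) vectors of nucleotide keys.
#' @return a `HelixFrame`. Degenerate geometry (axis < 0.5 A, or hydrogen-
#'   bond vector within 1 degree of the axis) raises a `kjDegenerateFrame`
#'   error.
#' @export
frameFromSegment <- function(model, pair1, pair2) {
  asKeys <- function(p) {
    if (is.character(p)) return(p[1:2])
    c(p$nt1[1L], p$nt2[1L])
  }
  frameFromPairKeys(model, asKeys(pair1), asKeys(pair2))
}

# inter-pair twist: angle between the two pairs' C1'->C1' vectors projected
# perpendicular to the provisional axis joining the pair midpoints
.interPairTwist <- function(c1a, c1b, axis) {
  pa <- c1a - sum(c1a * axis) * axis
  pb <- c1b - sum(c1b * axis) * axis
  na_ <- .vnorm(pa); nb_ <- .vnorm(pb)
  if (na_ < 1e-6 || nb_ < 1e-6) return(NA_real_)
  .rad2deg(acos(min(1, max(-1, sum(pa * pb) / (na_ * nb_)))))
}

#' Enumerate minimal two-pair helix segments
#'
#' Combines detected base pairs into stacked two-pair segments: midpoint
#' separation within `stackMaxDist` and inter-pair twist inside
#' `twistRange`. Pairs need not be sequence-adjacent, so stacking across a
#' strand exchange is representable. With `orientations = "both"` each
#' segment is emitted in both pair orders (the scan uses this so helix
#' polarity need not be guessed); the default canonical order puts the pair
#' whose first nucleotide comes earlier in the file first.
#'
#' @param pairs output of [detectBasePairs()].
#' @param model the `RNAStructure` the pairs belong to.
#' @param config a [ktConfig()].
#' @param orientations `"forward"` (canonical order) or `"both"`.
#' @return list of `HelixFrame` objects.
#' @export
enumerateHelixSegments <- function(pairs, model, config = ktConfig(),
                                   orientations = c("forward", "both")) {
  orientations <- match.arg(orientations)
  np <- nrow(pairs)
  if (is.null(np) || np < 2L) return(list())
  c1a <- lapply(seq_len(np), function(i) .atomCoord(model, pairs$nt1[i], "C1'"))
  c1b <- lapply(seq_len(np), function(i) .atomCoord(model, pairs$nt2[i], "C1'"))
  mids <- lapply(seq_len(np), function(i) (c1a[[i]] + c1b[[i]]) / 2)
  frames <- list()
  for (i in seq_len(np - 1L)) {
    for (j in (i + 1L):np) {
      d <- .vnorm(mids[[j]] - mids[[i]])
      if (d > config$stackMaxDist || d < 1e-6) next
      axis <- (mids[[j]] - mids[[i]]) / d
      tw <- .interPairTwist(c1b[[i]] - c1a[[i]], c1b[[j]] - c1a[[j]], axis)
      if (is.na(tw) || tw < config$twistRange[1L] || tw > config$twistRange[2L]) next
      fwd <- tryCatch(
        frameFromPairKeys(model, c(pairs$nt1[i], pairs$nt2[i]),
                          c(pairs$nt1[j], pairs$nt2[j])),
        kjDegenerateFrame = function(e) NULL)
      if (!is.null(fwd)) frames[[length(frames) + 1L]] <- fwd
      if (orientations == "both") {
        rev_ <- tryCatch(
          frameFromPairKeys(model, c(pairs$nt1[j], pairs$nt2[j]),
                            c(pairs$nt1[i], pairs$nt2[i])),
          kjDegenerateFrame = function(e) NULL)
        if (!is.null(rev_)) frames[[length(frames) + 1L]] <- rev_
      }
    }
  }
  frames
}

#' Tabulate helix segments
#'
#' Flattens a list of `HelixFrame` objects to a data.frame suitable for CSV
#' export (pair keys, origin, triad vectors).
#'
#' @param segments list of `HelixFrame` objects.
#' @return a data.frame.
#' @export
segmentsAsTable <- function(segments) {
  if (length(segments) == 0L) {
    return(data.frame(pair1_nt1 = character(), pair1_nt2 = character(),
                      pair2_nt1 = character(), pair2_nt2 = character()))
  }
  do.call(rbind, lapply(segments, function(f) {
    data.frame(pair1_nt1 = f@pair1[1L], pair1_nt2 = f@pair1[2L],
               pair2_nt1 = f@pair2[1L], pair2_nt2 = f@pair2[2L],
               ox = f@origin[1L], oy = f@origin[2L], oz = f@origin[3L],
               ax = f@triad[1L, 1L], ay = f@triad[2L, 1L], az = f@triad[3L, 1L],
               hx = f@triad[1L, 2L], hy = f@triad[2L, 2L], hz = f@triad[3L, 2L],
               nx = f@triad[1L, 3L], ny = f@triad[2L, 3L], nz = f@triad[3L, 3L],
               stringsAsFactors = FALSE)
  }))
}
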