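# The geometric motif search: reference patterns of relative helix-segment
# transforms, and the scan testing every ordered segment pair of a model
# against the pattern entries.

#' Construct a search pattern
#'
#' @param entries list of `RigidTransform` reference measurements (candidate
#'   NC-helix segment expressed in the C-helix segment frame).
#' @param translationTol translation tolerance, angstroms.
#' @param rotationTol rotation tolerance, degrees.
#' @param provenance optional data.frame describing where each entry came
#'   from.
#' @return a `SearchPattern`.
#' @export
searchPattern <- function(entries, translationTol = 4.0, rotationTol = 25,
                          provenance = data.frame()) {
  if (is(entries, "RigidTransform")) entries <- list(entries)
  new("SearchPattern", entries = entries, translationTol = translationTol,
      rotationTol = rotationTol, provenance = provenance)
}

# Residue-range selectors: "A" (whole chain), "A:3-14", "A:7", or a character
# vector of such; returns the matching nucleotide keys.
.resolveSelector <- function(model, selector) {
  nt <- nucleotides(model)
  keys <- character(0)
  for (s in selector) {
    m <- regmatches(s, regexec("^([^:]+)(?::(-?[0-9]+)(?:-(-?[0-9]+))?)?$", s))[[1L]]
    if (length(m) == 0L || !nzchar(m[1L]))
      stop(errorCondition(sprintf("cannot parse selector '%s'", s),
                          class = c("kjSelectionError", "error", "condition")))
    ch <- m[2L]
    sub <- nt[nt$chain == ch, , drop = FALSE]
    if (nzchar(m[3L])) {
      from <- as.integer(m[3L])
      to <- if (nzchar(m[4L])) as.integer(m[4L]) else from
      sub <- sub[sub$resno >= from & sub$resno <= to, , drop = FALSE]
    }
    keys <- c(keys, sub$key)
  }
  unique(keys)
}

#' Define a search pattern from a reference structure
#'
#' Detects base pairs and helix segments in the reference model, keeps
#' segments falling entirely inside the C-helix and NC-helix selectors, and
#' records the relative transform of every (C segment, NC segment)
#' combination as a pattern entry. Multi-entry patterns are OR-matched by
#' the scan (best entry wins).
#'
#' @param model an RNA-filtered `RNAStructure` containing a known k-turn.
#' @param cSelector,ncSelector residue-range selectors (`"A:3-14"` style
#'   strings, possibly vectors) for the canonical and non-canonical helices.
#' @param translationTol,rotationTol tolerances stored on the pattern.
#' @param config a [ktConfig()].
#' @return a `SearchPattern` with provenance.
#' @export
patternFromReference <- function(model, cSelector, ncSelector,
                                 translationTol = 4.0, rotationTol = 25,
                                 config = ktConfig()) {
  pairs <- detectBasePairs(model, config)
  segs <- enumerateHelixSegments(pairs, model, config, orientations = "forward")
  inSel <- function(f, keys) all(c(f@pair1, f@pair2) %in% keys)
  cKeys <- .resolveSelector(model, cSelector)
  ncKeys <- .resolveSelector(model, ncSelector)
  cSegs <- Filter(function(f) inSel(f, cKeys), segs)
  ncSegs <- Filter(function(f) inSel(f, ncKeys), segs)
  if (length(cSegs) == 0L)
    stop(errorCondition("C-helix selector resolves to no helix segment",
                        class = c("kjSelectionError", "error", "condition")))
  if (length(ncSegs) == 0L)
    stop(errorCondition("NC-helix selector resolves to no helix segment",
                        class = c("kjSelectionError", "error", "condition")))
  entries <- list(); prov <- list()
  for (cs in cSegs) {
    for (ns in ncSegs) {
      if (length(intersect(framePairs(cs), framePairs(ns))) > 0L) next
      entries[[length(entries) + 1L]] <- relativeTransform(cs, ns)
      prov[[length(prov) + 1L]] <- data.frame(
        source = sourceId(model),
        c_pair1 = paste(cs@pair1, collapse = "|"),
        c_pair2 = paste(cs@pair2, collapse = "|"),
        nc_pair1 = paste(ns@pair1, collapse = "|"),
        nc_pair2 = paste(ns@pair2, collapse = "|"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(entries) == 0L)
    stop(errorCondition("selectors resolve to no usable segment combination",
                        class = c("kjSelectionError", "error", "condition")))
  searchPattern(entries, translationTol, rotationTol, do.call(rbind, prov))
}

#' Built-in canonical k-turn pattern
#'
#' The reference relative geometry between the C and NC helices of the
#' synthetic k-turn scene ([buildSyntheticKTurn()]): the NC segment opening
#' past the tandem sheared pairs, expressed in the frame of the C-helix
#' segment adjacent to the loop. Default tolerances (4 A, 25 degrees) are
#' deliberately loose so that natural k-turn variation still matches;
#' patterns built from user-supplied reference coordinates via
#' [patternFromReference()] are interchangeable.
#'
#' @param translationTol,rotationTol tolerances stored on the pattern.
#' @return a single-entry `SearchPattern`.
#' @export
kturnReferencePattern <- function(translationTol = 4.0, rotationTol = 25) {
  kt <- buildSyntheticKTurn()
  fc <- frameFromPairKeys(kt, c("A:2", "B:7"), c("A:3", "B:6"))
  fnc <- frameFromPairKeys(kt, c("A:9", "B:3"), c("A:10", "B:2"))
  searchPattern(relativeTransform(fc, fnc), translationTol, rotationTol,
                provenance = data.frame(source = "synthetic-kturn",
                                        c_pair1 = "A:2|B:7", c_pair2 = "A:3|B:6",
                                        nc_pair1 = "A:9|B:3", nc_pair2 = "A:10|B:2",
                                        stringsAsFactors = FALSE))
}

.emptyHits <- function() {
  h <- data.frame(cPair1 = character(), cPair2 = character(),
                  ncPair1 = character(), ncPair2 = character(),
                  translationDev = numeric(), rotationDev = numeric(),
                  combinedDev = numeric(), matchedEntry = integer())
  h$cFrame <- list(); h$ncFrame <- list(); h$observed <- list()
  h
}

#' Scan a structure for motif hits
#'
#' Detects base pairs, enumerates helix segments in both orientations, and
#' tests every ordered pair of non-overlapping segments against every
#' pattern entry. A segment pair is a hit when its relative transform lies
#' within both tolerances of some entry (the best entry is kept). Hits whose
#' segment pairs overlap (sharing a nucleotide on the C side and on the NC
#' side) are merged, keeping the smallest combined deviation; output is
#' ordered by combined deviation, so results are deterministic.
#'
#' @param model an RNA-filtered, eligible `RNAStructure`.
#' @param pattern a `SearchPattern`.
#' @param config a [ktConfig()]; the pattern's own tolerances are used for
#'   matching.
#' @return a data.frame of hits: nucleotide keys of both segments'
#'   pairs, `translationDev` (A), `rotationDev` (degrees), `combinedDev`
#'   (sum of tolerance-normalised deviations), `matchedEntry`, and
#'   list-columns `cFrame`, `ncFrame` (`HelixFrame`) and `observed`
#'   (`RigidTransform`). Zero rows when nothing matches.
#' @export
scanStructure <- function(model, pattern, config = ktConfig()) {
  if (!eligible(model))
    stop(errorCondition("model is not eligible (needs >= 10 complete nucleotides)",
                        class = c("kjIneligibleModel", "error", "condition")))
  pairs <- detectBasePairs(model, config)
  segs <- enumerateHelixSegments(pairs, model, config, orientations = "both")
  if (length(segs) < 2L) return(.emptyHits())
  ttol <- pattern@translationTol
  rtol <- pattern@rotationTol
  hits <- list()
  for (k in seq_along(segs)) {
    for (l in seq_along(segs)) {
      if (k == l) next
      fk <- segs[[k]]; fl <- segs[[l]]
      if (length(intersect(framePairs(fk), framePairs(fl))) > 0L) next
      obs <- relativeTransform(fk, fl)
      best <- NULL
      for (e in seq_along(pattern@entries)) {
        dev <- .transformDeviation(obs, pattern@entries[[e]])
        if (dev["translation"] > ttol || dev["rotation"] > rtol) next
        comb <- dev["translation"] / ttol + dev["rotation"] / rtol
        if (is.null(best) || comb < best$comb)
          best <- list(e = e, dev = dev, comb = comb)
      }
      if (!is.null(best)) {
        hits[[length(hits) + 1L]] <- list(cFrame = fk, ncFrame = fl, obs = obs,
                                          entry = best$e, dev = best$dev,
                                          comb = unname(best$comb))
      }
    }
  }
  if (length(hits) == 0L) return(.emptyHits())
  # merge overlapping hits (union-find; overlap = shared nucleotide on the C
  # side and on the NC side), keeping the minimal combined deviation
  nh <- length(hits)
  parent <- seq_len(nh)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nh - 1L)) {
    for (j in (i + 1L):nh) {
      ci <- framePairs(hits[[i]]$cFrame); cj <- framePairs(hits[[j]]$cFrame)
      ni <- framePairs(hits[[i]]$ncFrame); nj <- framePairs(hits[[j]]$ncFrame)
      if (length(intersect(ci, cj)) > 0L && length(intersect(ni, nj)) > 0L) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  cluster <- vapply(seq_len(nh), find, 0L)
  keep <- vapply(split(seq_len(nh), cluster), function(idx) {
    idx[which.min(vapply(idx, function(i) hits[[i]]$comb, 0))]
  }, 0L)
  hits <- hits[keep[order(vapply(keep, function(i) hits[[i]]$comb, 0))]]
  out <- data.frame(
    cPair1 = vapply(hits, function(h) paste(h$cFrame@pair1, collapse = "|"), ""),
    cPair2 = vapply(hits, function(h) paste(h$cFrame@pair2, collapse = "|"), ""),
    ncPair1 = vapply(hits, function(h) paste(h$ncFrame@pair1, collapse = "|"), ""),
    ncPair2 = vapply(hits, function(h) paste(h$ncFrame@pair2, collapse = "|"), ""),
    translationDev = vapply(hits, function(h) unname(h$dev["translation"]), 0),
    rotationDev = vapply(hits, function(h) unname(h$dev["rotation"]), 0),
    combinedDev = vapply(hits, function(h) h$comb, 0),
    matchedEntry = vapply(hits, function(h) as.integer(h$entry), 0L),
    stringsAsFactors = FALSE)
  out$cFrame <- lapply(hits, `[[`, "cFrame")
  out$ncFrame <- lapply(hits, `[[`, "ncFrame")
  out$observed <- lapply(hits, `[[`, "obs")
  out
}

#' Count segment pairs within (scaled) pattern tolerances
#'
#' Number of ordered, non-overlapping segment pairs whose relative transform
#' lies within `factor` times the pattern tolerances of some entry, without
#' hit deduplication. Useful as a diagnostic of how close a structure comes
#' to matching (`factor = 1` counts raw matches; a structure is cleanly
#' non-matching when the count at `factor = 2` is zero, since every candidate
#' then deviates by at least twice the tolerance).
#'
#' @param model an RNA-filtered, eligible `RNAStructure`.
#' @param pattern a `SearchPattern`.
#' @param factor tolerance scale factor.
#' @param config a [ktConfig()].
#' @return integer count.
#' @export
countPatternMatches <- function(model, pattern, factor = 1, config = ktConfig()) {
  pairs <- detectBasePairs(model, config)
  segs <- enumerateHelixSegments(pairs, model, config, orientations = "both")
  cnt <- 0L
  for (k in seq_along(segs)) {
    for (l in seq_along(segs)) {
      if (k == l) next
      if (length(intersect(framePairs(segs[[k]]), framePairs(segs[[l]]))) > 0L) next
      obs <- relativeTransform(segs[[k]], segs[[l]])
      for (e in pattern@entries) {
        dev <- .transformDeviation(obs, e)
        if (dev["translation"] <= factor * pattern@translationTol &&
            dev["rotation"] <= factor * pattern@rotationTol) {
          cnt <- cnt + 1L
          break
        }
      }
    }
  }
  cnt
}

#' Write motif hits as pseudo-atom PDB
#'
#' One residue per matched segment (two per hit), with four pseudo-atoms:
#' the frame origin and the tips of the three triad vectors scaled to 5 A
#' (atom names ORIG, AXIS, HBND, NRML; residue name PSD). Residue numbers
#' are 2*hit - 1 (C segment) and 2*hit (NC segment); the chain letter cycles
#' with the hit index. The file parses under [loadStructure()].
#'
#' @param hits data.frame from [scanStructure()].
#' @param path output PDB path.
#' @param scale vector length in angstroms.
#' @return `path`, invisibly.
#' @export
writeHitsPseudoatoms <- function(hits, path, scale = 5) {
  if (nrow(hits) == 0L) {
    writeLines(c("REMARK   kjunction motif scan: no hits", "END"), path)
    return(invisible(path))
  }
  rows <- list()
  for (h in seq_len(nrow(hits))) {
    for (side in 1:2) {
      f <- if (side == 1L) hits$cFrame[[h]] else hits$ncFrame[[h]]
      pts <- rbind(f@origin,
                   f@origin + scale * f@triad[, 1L],
                   f@origin + scale * f@triad[, 2L],
                   f@origin + scale * f@triad[, 3L])
      rows[[length(rows) + 1L]] <- data.frame(
        chain = LETTERS[(h - 1L) %% 26L + 1L],
        resno = 2L * h - 2L + side, insert = "", resname = "PSD",
        base = NA_character_, elety = c("ORIG", "AXIS", "HBND", "NRML"),
        x = pts[, 1L], y = pts[, 2L], z = pts[, 3L], o = 1,
        stringsAsFactors = FALSE)
    }
  }
  writeStructurePDB(.rnaStructure(do.call(rbind, rows), sourceId = "hits"), path)
}

#' Serialize / read a search pattern as JSON
#'
#' @param pattern a `SearchPattern`.
#' @param path JSON file path.
#' @return `writePattern`: `path` invisibly; `readPattern`: a
#'   `SearchPattern`.
#' @export
writePattern <- function(pattern, path) {
  obj <- list(
    translation_tol = pattern@translationTol,
    rotation_tol = pattern@rotationTol,
    entries = lapply(pattern@entries, function(e) {
      list(rotation = unclass(e@rotation), translation = e@translation)
    }),
    provenance = pattern@provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writePattern
#' @export
readPattern <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- lapply(obj$entries, function(e) {
    R <- do.call(rbind, lapply(e$rotation, function(r) as.numeric(unlist(r))))
    rigidTransform(R, as.numeric(unlist(e$translation)))
  })
  prov <- if (length(obj$provenance) > 0L) {
    do.call(rbind, lapply(obj$provenance, function(p)
      as.data.frame(p, stringsAsFactors = FALSE)))
  } else data.frame()
  searchPattern(entries, obj$translation_tol, obj$rotation_tol, prov)
}
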