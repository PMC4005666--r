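# Rigid transforms and helix-segment coordinate frames.
#
# A helix segment (two stacked base pairs) is abstracted to four vectors: an
# origin at the first pair, a unit helix axis toward the second pair, the
# direction of the Watson-Crick hydrogen bonds of the first pair projected
# onto the plane perpendicular to the axis, and the normal completing a
# right-handed orthonormal triad. A RigidTransform expresses one frame in the
# coordinate system of another, which is the quantity the motif scan compares.

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation numeric(3), angstroms.
#' @return a `RigidTransform`.
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = unname(rotation),
      translation = as.numeric(translation))
}

#' Identity transform
#' @return a `RigidTransform` with identity rotation and zero translation.
#' @export
identityTransform <- function() rigidTransform()

#' Compose two rigid transforms
#'
#' `composeTransforms(a, b)` is the transform applying `b` first, then `a`
#' (matrix convention: `R = Ra Rb`, `t = Ra tb + ta`).
#'
#' @param a,b `RigidTransform` objects.
#' @return a `RigidTransform`.
#' @export
composeTransforms <- function(a, b) {
  rigidTransform(a@rotation %*% b@rotation,
                 as.numeric(a@rotation %*% b@translation) + a@translation)
}

#' Invert a rigid transform
#' @param x a `RigidTransform`.
#' @return the inverse `RigidTransform`.
#' @export
invertTransform <- function(x) {
  Rt <- t(x@rotation)
  rigidTransform(Rt, as.numeric(-Rt %*% x@translation))
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz an n x 3 matrix of coordinates.
#' @param transform a `RigidTransform`.
#' @return the transformed n x 3 matrix.
#' @export
transformCoords <- function(xyz, transform) {
  xyz <- rbind(xyz)
  sweep(xyz %*% t(transform@rotation), 2L, -transform@translation)
}

#' Apply a rigid transform to a whole structure
#'
#' Moves every atom; identities, occupancies and ordering are untouched.
#'
#' @param model an `RNAStructure`.
#' @param transform a `RigidTransform`.
#' @return the transformed `RNAStructure`.
#' @export
transformStructure <- function(model, transform) {
  a <- model@atoms
  if (nrow(a) > 0L) {
    xyz <- transformCoords(as.matrix(a[, c("x", "y", "z")]), transform)
    a$x <- xyz[, 1L]; a$y <- xyz[, 2L]; a$z <- xyz[, 3L]
  }
  initialize(model, atoms = a)
}

#' Random rigid transform
#'
#' Uniform random rotation (random unit quaternion) and a translation drawn
#' uniformly from a radial shell. Draws from the current RNG stream, so wrap
#' in `set.seed()`/`withr::with_seed()` for reproducibility.
#'
#' @param translationRange numeric(2), min/max translation length (angstroms).
#' @return a `RigidTransform`.
#' @export
randomRigidTransform <- function(translationRange = c(5, 15)) {
  R <- .randomRotation()
  dir <- .unitv(stats::rnorm(3L))
  len <- stats::runif(1L, translationRange[1L], translationRange[2L])
  rigidTransform(R, dir * len)
}

# Frame construction from the four C1' positions of a two-pair segment.
# a1/a2: strand-1/strand-2 C1' of pair 1; b1/b2: same for pair 2.
.frameFromC1 <- function(a1, a2, b1, b2, pair1 = c(NA_character_, NA_character_),
                         pair2 = c(NA_character_, NA_character_)) {
  origin <- (a1 + a2) / 2
  mid2 <- (b1 + b2) / 2
  ax <- mid2 - origin
  if (.vnorm(ax) < 0.5)
    stop(errorCondition("degenerate helix-segment frame: axis shorter than 0.5 A",
                        class = c("kjDegenerateFrame", "error", "condition")))
  axis <- .unitv(ax)
  hb <- a2 - a1
  hbPerp <- hb - sum(hb * axis) * axis
  if (.vnorm(hbPerp) < .vnorm(hb) * sin(.deg2rad(1)))
    stop(errorCondition("degenerate helix-segment frame: hydrogen-bond vector within 1 degree of the axis",
                        class = c("kjDegenerateFrame", "error", "condition")))
  hbond <- .unitv(hbPerp)
  normal <- .cross3(axis, hbond)
  new("HelixFrame", origin = origin, triad = cbind(axis, hbond, normal),
      pair1 = pair1, pair2 = pair2)
}

#' Relative transform between two helix-segment frames
#'
#' Expresses the candidate frame in the reference frame's coordinate system:
#' the translation is the candidate origin minus the reference origin written
#' in the reference triad's (axis, hbond, normal) coordinates, and the
#' rotation maps the reference triad onto the candidate triad. The result is
#' invariant under any global rigid motion applied to both frames.
#'
#' @param reference,candidate `HelixFrame` objects.
#' @return a `RigidTransform`.
#' @export
relativeTransform <- function(reference, candidate) {
  Rt <- t(reference@triad)
  rigidTransform(Rt %*% candidate@triad,
                 as.numeric(Rt %*% (candidate@origin - reference@origin)))
}

# Deviations between an observed relative transform and a pattern entry:
# translation = Euclidean distance between translation vectors (reference
# frame coordinates); rotation = angle of observed %*% t(entry).
.transformDeviation <- function(observed, entry) {
  c(translation = .vnorm(observed@translation - entry@translation),
    rotation = rotationAngle(observed@rotation %*% t(entry@rotation)))
}
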