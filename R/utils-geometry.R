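# Small 3D linear-algebra helpers shared by the framing, scanning and
# fixture-building code. All angles at the user surface are degrees.

.vnorm <- function(v) sqrt(sum(v * v))

.unitv <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalise a (near-)zero vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about an arbitrary axis
#'
#' @param axis numeric(3); need not be normalised.
#' @param angleDeg rotation angle in degrees (right-handed about `axis`).
#' @return a 3x3 proper rotation matrix.
#' @export
rotationAboutAxis <- function(axis, angleDeg) {
  u <- .unitv(axis)
  th <- .deg2rad(angleDeg)
  c_ <- cos(th); s_ <- sin(th)
  ux <- matrix(c(0, -u[3L], u[2L],
                 u[3L], 0, -u[1L],
                 -u[2L], u[1L], 0), 3L, 3L, byrow = TRUE)
  diag(3L) * c_ + s_ * ux + (1 - c_) * (u %o% u)
}

#' Angle of a rotation matrix
#'
#' Magnitude of the rotation encoded by a proper rotation matrix, in degrees
#' (the bi-invariant geodesic distance from the identity on SO(3)).
#'
#' @param R a 3x3 proper rotation matrix.
#' @return angle in degrees, in `[0, 180]`.
#' @export
rotationAngle <- function(R) {
  # atan2 form: numerically stable near the identity, where acos((tr-1)/2)
  # loses half the working precision
  s <- 0.5 * sqrt((R[3L, 2L] - R[2L, 3L])^2 +
                  (R[1L, 3L] - R[3L, 1L])^2 +
                  (R[2L, 1L] - R[1L, 2L])^2)
  c_ <- (sum(diag(R)) - 1) / 2
  unname(.rad2deg(atan2(s, c_)))
}

# Uniform random rotation (Shoemake, via a random unit quaternion). Consumes
# four uniforms from the current RNG stream.
.randomRotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / .vnorm(q)
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
}
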