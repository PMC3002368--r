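# Low-level 3D geometry used throughout: torsion/bond angles, internal-to-
# Cartesian atom placement (NeRF), and least-squares superposition.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle in degrees into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped into the half-open interval (-180, 180].
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y <= -180] <- y[y <= -180] + 360
  # map exact -180 to +180 so the interval is (-180, 180]
  y[abs(y + 180) < 1e-12] <- 180
  y
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

unitv <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("zero-length vector")
  a / n
}

#' Torsion (dihedral) angle of four points
#'
#' IUPAC sign convention: looking from p2 to p3, the angle is positive when
#' p4 is rotated clockwise from p1.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (coordinates in Angstrom).
#' @return angle in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(rad2deg(atan2(y, x)))
}

#' Bond angle of three points
#'
#' @param p1,p2,p3 numeric 3-vectors; the angle is at `p2`.
#' @return angle in degrees in [0, 180].
#' @export
bond_angle <- function(p1, p2, p3) {
  u <- unitv(p1 - p2)
  v <- unitv(p3 - p2)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Places atom D given the positions of three reference atoms A, B, C such
#' that |C-D| = `len`, the angle B-C-D = `ang` and the torsion A-B-C-D =
#' `tors`.
#'
#' @param a,b,c numeric 3-vectors, positions of the reference atoms.
#' @param len bond length C-D in Angstrom.
#' @param ang bond angle B-C-D in degrees.
#' @param tors torsion angle A-B-C-D in degrees.
#' @return numeric 3-vector, the position of D.
#' @export
place_atom <- function(a, b, c, len, ang, tors) {
  ang <- deg2rad(ang)
  tors <- deg2rad(tors)
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  d_local <- len * c(-cos(ang), sin(ang) * cos(tors),
                     -sin(ang) * sin(tors))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation and translation minimizing the RMSD of `mobile` onto
#' `target`, optionally applying the transform to a second coordinate set.
#'
#' @param mobile,target n x 3 matrices with matching rows.
#' @param apply_to optional m x 3 matrix transformed with the fitted rigid
#'   motion (defaults to `mobile`).
#' @return list with `coords` (transformed `apply_to`), `rotation` (3 x 3),
#'   `translation` (length-3), and `rmsd` (fit RMSD of mobile onto target).
#' @export
superpose_coords <- function(mobile, target, apply_to = mobile) {
  stopifnot(nrow(mobile) == nrow(target), ncol(mobile) == 3)
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  p <- sweep(mobile, 2, cm)
  q <- sweep(target, 2, ct)
  s <- svd(crossprod(p, q))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fit <- p %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fit - q)^2)))
  out <- sweep(sweep(apply_to, 2, cm) %*% t(rot), 2, ct, "+")
  list(coords = out, rotation = rot,
       translation = ct - as.vector(rot %*% cm), rmsd = rmsd)
}

#' In-place RMSD between two coordinate sets
#'
#' No superposition is applied; rows must correspond one-to-one.
#'
#' @param a,b n x 3 coordinate matrices.
#' @return RMSD in Angstrom.
#' @export
rmsd_coords <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}
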