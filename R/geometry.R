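# Low-level 3D geometry: cross products, dihedrals, rigid-body transforms
# and internal-coordinate atom placement. All coordinates are Angstrom,
# all angles degrees unless noted.

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) return(rep(NA_real_, 3L))
  v / n
}

.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180

# wrap an angle in degrees into (-180, 180]
wrap_angle <- function(x) {
  y <- ((x + 180) %% 360) - 180
  ifelse(y == -180, 180, y)
}

#' Torsion (dihedral) angle of four points
#'
#' Computes the dihedral angle defined by four points using the IUPAC sign
#' convention: 180 degrees for the planar anti (trans) arrangement, 0 for
#' syn (cis). The value is invariant under rigid-body transforms and flips
#' sign under mirror reflection.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees in (-180, 180], or `NA` for degenerate
#'   geometry (coincident consecutive points or collinear bond vectors).
#' @export
#' @examples
#' dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0)) # 180
#' dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0))  # 0
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (.vnorm(b1) < 1e-9 || .vnorm(b2) < 1e-9 || .vnorm(b3) < 1e-9) {
    return(NA_real_)
  }
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  if (.vnorm(n1) < 1e-9 || .vnorm(n2) < 1e-9) return(NA_real_)
  m1 <- .cross(.unit(b2), n1)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(.deg(atan2(y, x)))
}

# rotation matrix for angle (degrees) about unit axis n (Rodrigues)
rotation_matrix <- function(axis, angle) {
  n <- .unit(axis)
  a <- .rad(angle)
  K <- matrix(c(0, n[3], -n[2],
                -n[3], 0, n[1],
                n[2], -n[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# apply x -> R (x - origin) + origin + shift to an n x 3 coordinate matrix
transform_coords <- function(xyz, R = diag(3), shift = c(0, 0, 0),
                             origin = c(0, 0, 0)) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3)
  swept <- sweep(xyz, 2, origin)
  out <- swept %*% t(R)
  sweep(out, 2, origin + shift, "+")
}

# random rigid transform, for invariance testing
random_rigid_transform <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ax <- .unit(stats::rnorm(3))
  list(R = rotation_matrix(ax, stats::runif(1, 0, 360)),
       shift = stats::rnorm(3, sd = 20))
}

# Place atom D given atoms A, B, C and internal coordinates:
# bond length |C-D|, bond angle B-C-D (degrees), torsion A-B-C-D (degrees).
# Standard NeRF construction.
place_atom <- function(a, b, c_, length, angle, torsion) {
  bc <- .unit(c_ - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  ang <- .rad(180 - angle)
  tor <- .rad(torsion)
  d2 <- length * c(cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c_ + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Decompose a rigid transform x -> R x + t into a screw motion:
# rotation by `angle` about a line through `point` with direction `axis`,
# plus a translation `pitch` along the axis.
screw_decompose <- function(R, t) {
  tr <- sum(diag(R))
  cang <- max(-1, min(1, (tr - 1) / 2))
  angle <- .deg(acos(cang))
  if (angle < 1e-6) {
    return(list(axis = .unit(t), angle = 0, pitch = .vnorm(t),
                point = c(0, 0, 0)))
  }
  # axis from the skew-symmetric part (robust away from 180 degrees)
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (.vnorm(ax) < 1e-8) {
    # angle near 180: axis from R + I column space
    M <- R + diag(3)
    ax <- M[, which.max(colSums(M^2))]
  }
  n <- .unit(ax)
  pitch <- sum(t * n)
  t_perp <- t - pitch * n
  # solve (I - R) p = t_perp for p in the plane normal to n
  A <- diag(3) - R
  p <- tryCatch(qr.solve(A + tcrossprod(n), t_perp), error = function(e) {
    MASS_ginv <- function(X) {
      s <- svd(X)
      d <- ifelse(s$d > 1e-8, 1 / s$d, 0)
      s$v %*% (d * t(s$u))
    }
    MASS_ginv(A) %*% t_perp
  })
  list(axis = n, angle = angle, pitch = pitch, point = as.numeric(p))
}

# Least-squares superposition (Kabsch): returns R, t such that
# R %*% x + t ~= y. Inputs are n x 3 matrices of paired points.
kabsch_fit <- function(x, y) {
  cx <- colMeans(x)
  cy <- colMeans(y)
  H <- t(sweep(x, 2, cx)) %*% sweep(y, 2, cy)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = as.numeric(cy - R %*% cx))
}
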