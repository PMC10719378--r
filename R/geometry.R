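# Rotation and superposition utilities shared across the package.
# All angles are in degrees, coordinates in Angstrom, frames right-handed.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Elementary rotation matrices
#'
#' Right-handed rotations about the global x, y and z axes, and about an
#' arbitrary axis (Rodrigues formula). Angles in degrees.
#'
#' @param deg rotation angle in degrees.
#' @param axis 3-vector (need not be unit length).
#' @return a 3x3 rotation matrix.
#' @keywords internal
#' @name rotations
NULL

#' @rdname rotations
#' @export
rot_x <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, -s, 0, s, c), 3, 3, byrow = TRUE)
}

#' @rdname rotations
#' @export
rot_y <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(c, 0, s, 0, 1, 0, -s, 0, c), 3, 3, byrow = TRUE)
}

#' @rdname rotations
#' @export
rot_z <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

#' @rdname rotations
#' @export
rot_axis <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  diag(3) * c + s * ux + (1 - c) * (u %o% u)
}

#' Intrinsic Z-Y-Z Euler rotation
#'
#' Builds the rotation `Rz(psi) %*% Ry(theta) %*% Rz(phi)`, the package-wide
#' convention for the subunit orientation degrees of freedom.
#'
#' @param psi,theta,phi Euler angles in degrees.
#' @return a 3x3 rotation matrix.
#' @export
euler_zyz <- function(psi, theta, phi) {
  rot_z(psi) %*% rot_y(theta) %*% rot_z(phi)
}

#' Decompose a rotation into intrinsic Z-Y-Z Euler angles
#'
#' Inverse of [euler_zyz()]. Returns angles in degrees with
#' `theta` in `[0, 180]`. At the gimbal-locked poles (`theta` near 0 or 180)
#' `phi` is set to 0 and the z-rotation is carried entirely by `psi`.
#'
#' @param M a 3x3 rotation matrix.
#' @return named numeric vector `c(psi, theta, phi)` in degrees.
#' @export
matrix_to_euler_zyz <- function(M) {
  ct <- max(-1, min(1, M[3, 3]))
  theta <- acos(ct)
  if (sin(theta) > 1e-9) {
    psi <- atan2(M[2, 3], M[1, 3])
    phi <- atan2(M[3, 2], -M[3, 1])
  } else if (ct > 0) { # theta ~ 0: M = Rz(psi + phi)
    psi <- atan2(M[2, 1], M[1, 1])
    phi <- 0
  } else {             # theta ~ 180: M = Rz(psi - phi) Ry(180)
    psi <- atan2(-M[2, 1], -M[1, 1])
    phi <- 0
  }
  c(psi = rad2deg(psi), theta = rad2deg(theta), phi = rad2deg(phi))
}

#' Rotation axis and angle of a rotation matrix
#'
#' @param M a 3x3 rotation matrix.
#' @return list with `angle` (degrees, in `[0, 180]`) and unit `axis`.
#' @export
axis_angle <- function(M) {
  tr <- max(-1, min(3, sum(diag(M))))
  ang <- acos((tr - 1) / 2)
  if (ang < 1e-9) return(list(angle = 0, axis = c(0, 0, 1)))
  if (pi - ang > 1e-6) {
    ax <- c(M[3, 2] - M[2, 3], M[1, 3] - M[3, 1], M[2, 1] - M[1, 2]) /
      (2 * sin(ang))
  } else {
    # 180-degree rotation: axis from the dominant column of M + I
    B <- (M + diag(3)) / 2
    k <- which.max(diag(B))
    ax <- B[, k] / sqrt(max(B[k, k], 1e-12))
  }
  list(angle = rad2deg(ang), axis = ax / sqrt(sum(ax^2)))
}

#' Optimal rotation between two centered point sets (Kabsch)
#'
#' Finds the proper rotation `R` minimising `||P %*% t(R) - Q||` for point
#' sets given as n x 3 matrices of rows already centered on their centroids.
#'
#' @param P,Q n x 3 coordinate matrices (centered).
#' @return a 3x3 rotation matrix such that `t(R %*% t(P))` matches `Q`.
#' @export
kabsch <- function(P, Q) {
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

#' Superpose one point set onto another
#'
#' Least-squares rigid superposition: returns the rotation, translation and
#' the resulting RMSD so that `t(R %*% t(P)) + t` best matches `Q`.
#'
#' @param P,Q n x 3 coordinate matrices with matching rows.
#' @return list with `R`, `t` and `rmsd`.
#' @export
superpose <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  R <- kabsch(Pc, Qc)
  moved <- Pc %*% t(R)
  list(R = R, t = cq - as.vector(R %*% cp),
       rmsd = sqrt(mean(rowSums((moved - Qc)^2))))
}

#' Root-mean-square deviation of paired coordinates
#'
#' @param P,Q n x 3 coordinate matrices with matching rows.
#' @return RMSD in Angstrom (no superposition is performed).
#' @export
coord_rmsd <- function(P, Q) sqrt(mean(rowSums((P - Q)^2)))

# Z-Y-Z Euler angles of M in the representation (of the double cover
# (psi, theta, phi) ~ (psi + 180, -theta, phi + 180)) closest to `ref`.
euler_zyz_near <- function(M, ref) {
  a <- matrix_to_euler_zyz(M)
  cands <- list(a, c(psi = a[["psi"]] + 180, theta = -a[["theta"]],
                     phi = a[["phi"]] + 180))
  best <- NULL
  for (cand in cands) {
    for (nm in names(cand))
      cand[[nm]] <- ref[[nm]] + wrap_angle(cand[[nm]] - ref[[nm]])
    score <- sum(abs(cand - ref[names(cand)]))
    if (is.null(best) || score < best$score)
      best <- list(angles = cand, score = score)
  }
  best$angles
}

# Wrap an angle in degrees into (-period/2, period/2].
wrap_angle <- function(a, period = 360) {
  w <- a - period * floor(a / period + 0.5)
  if (isTRUE(all.equal(w, -period / 2))) w <- period / 2
  w
}
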