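# Rotation-matrix helpers shared across the package.
#
# Frame convention used throughout: Q denotes a GLOBAL -> LOCAL rotation,
# i.e. v_local = Q %*% v_global.  Its transpose maps local vectors back to
# the global frame.  All rotations are proper (det = +1).

#' Elementary rotation about the z axis
#'
#' Active rotation matrix mapping local coordinates to global coordinates for
#' a frame rotated by `theta` about the common z axis.
#'
#' @param theta Angle in radians.
#' @return A 3x3 rotation matrix.
#' @keywords internal
rot_z <- function(theta) {
  c0 <- cos(theta); s0 <- sin(theta)
  matrix(c(c0, s0, 0, -s0, c0, 0, 0, 0, 1), 3, 3)
}

#' @rdname rot_z
#' @keywords internal
rot_y <- function(theta) {
  c0 <- cos(theta); s0 <- sin(theta)
  matrix(c(c0, 0, -s0, 0, 1, 0, s0, 0, c0), 3, 3)
}

#' @rdname rot_z
#' @keywords internal
rot_x <- function(theta) {
  c0 <- cos(theta); s0 <- sin(theta)
  matrix(c(1, 0, 0, 0, c0, s0, 0, -s0, c0), 3, 3)
}

# Frobenius distance of Q'Q from the identity; 0 for an exact orthonormal Q.
orthonormality_defect <- function(Q) {
  sqrt(sum((crossprod(Q) - diag(3))^2))
}

#' Nearest rotation matrix
#'
#' Projects a near-orthonormal 3x3 matrix onto SO(3) via the SVD polar
#' factor (`U %*% t(V)`, with a sign fix so the determinant is +1).
#'
#' @param Q A 3x3 matrix, approximately orthonormal.
#' @return The closest (Frobenius norm) proper rotation matrix.
#' @keywords internal
nearest_rotation <- function(Q) {
  s <- svd(Q)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    s$u[, 3] <- -s$u[, 3]
    R <- s$u %*% t(s$v)
  }
  R
}

# Matrix exponential of a rotation vector (axis * angle), Rodrigues form.
so3_exp <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-14) return(diag(3) + skew_mat(w))
  K <- skew_mat(w / th)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Rotation vector of a rotation matrix (inverse of so3_exp).
so3_log <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  th <- acos(ct)
  if (th < 1e-12) return(c(0, 0, 0))
  if (abs(pi - th) < 1e-6) {
    # near pi: axis from the symmetric part
    A <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(A), 0))
    i <- which.max(ax)
    v <- A[, i] / ax[i]
    return(th * v / sqrt(sum(v^2)))
  }
  th / (2 * sin(th)) * c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
}

skew_mat <- function(w) {
  matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
}

# Vector of the antisymmetric part of a (near-)skew matrix S = [w]x.
unskew <- function(S) {
  c(S[3, 2] - S[2, 3], S[1, 3] - S[3, 1], S[2, 1] - S[1, 2]) / 2
}

# ---------------------------------------------------------------------------
# Condition helpers: every user-facing error carries a package class so the
# CLI can map error families to distinct exit codes and tests can match them.

imugait_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("imugait_", class), "imugait_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
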