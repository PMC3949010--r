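#' Stiffness matrix of a cubic trilinear hexahedral element
#'
#' Standard 8-node trilinear hexahedron for isotropic linear elasticity on
#' a cube of edge `h`, integrated with 2 x 2 x 2 Gauss quadrature (exact
#' for the constant-Jacobian cube). Local nodes are ordered x-fastest over
#' the cube corners, with three displacement DOFs (ux, uy, uz) per node.
#' The matrix is symmetric positive-semidefinite with a 6-dimensional
#' rigid-body null space, and linear in `E`.
#'
#' @param E elastic modulus (MPa).
#' @param nu Poisson's ratio in \[0, 0.5).
#' @param h element edge length (mm).
#' @return 24 x 24 symmetric matrix (N/mm per unit displacement).
#' @export
hexStiffness <- function(E, nu, h) {
  if (!is.finite(E) || E <= 0) stop("E must be positive")
  if (!is.finite(h) || h <= 0) stop("h must be positive")
  if (nu < 0 || nu >= 0.5) stop("Poisson's ratio must lie in [0, 0.5)")
  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  gp <- 1 / sqrt(3)
  detJ <- (h / 2)^3
  K <- matrix(0, 24, 24)
  for (gx in c(-gp, gp)) for (gy in c(-gp, gp)) for (gz in c(-gp, gp)) {
    dN <- matrix(0, 8, 3)
    for (a in 1:8) {
      s <- corners[a, ]
      dN[a, 1] <- s[1] * (1 + s[2] * gy) * (1 + s[3] * gz) / 8
      dN[a, 2] <- (1 + s[1] * gx) * s[2] * (1 + s[3] * gz) / 8
      dN[a, 3] <- (1 + s[1] * gx) * (1 + s[2] * gy) * s[3] / 8
    }
    dN <- dN * (2 / h)
    B <- matrix(0, 6, 24)
    for (a in 1:8) {
      c0 <- 3L * (a - 1L)
      B[1, c0 + 1] <- dN[a, 1]
      B[2, c0 + 2] <- dN[a, 2]
      B[3, c0 + 3] <- dN[a, 3]
      B[4, c0 + 1] <- dN[a, 2]; B[4, c0 + 2] <- dN[a, 1]
      B[5, c0 + 2] <- dN[a, 3]; B[5, c0 + 3] <- dN[a, 2]
      B[6, c0 + 1] <- dN[a, 3]; B[6, c0 + 3] <- dN[a, 1]
    }
    K <- K + crossprod(B, D %*% B) * detJ
  }
  (K + t(K)) / 2
}
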