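# Quaternion and rotation helpers. Quaternions are unit (w, x, y, z).

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# axis-angle (rotation vector, radians) to matrix
rotvec_to_matrix <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# geodesic angle (degrees) between two rotations
rotation_angle_deg <- function(R1, R2) {
  tr <- sum(diag(t(R1) %*% R2))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

#' Uniformly distributed random rotation matrices
#'
#' Draws unit quaternions from an isotropic Gaussian (Marsaglia's method),
#' giving the Haar-uniform distribution on SO(3).
#'
#' @param n Number of rotations.
#' @return List of 3x3 rotation matrices.
#' @export
random_rotations <- function(n) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  lapply(seq_len(n), function(i) quat_to_matrix(q[i, ]))
}

#' Quasi-uniform grid on SO(3)
#'
#' Super-Fibonacci spiral sampling of unit quaternions: a deterministic,
#' low-discrepancy covering of rotation space used as the coarse search grid
#' for still indexing.
#'
#' @param n Number of grid points.
#' @return n x 4 matrix of unit quaternions (w, x, y, z).
#' @export
so3_grid <- function(n) {
  phi <- sqrt(2)
  psi <- 1.533751168755204288118041
  i <- seq_len(n) - 0.5
  s <- i / n
  r <- sqrt(s); R <- sqrt(1 - s)
  alpha <- 2 * pi * i / phi
  beta <- 2 * pi * i / psi
  cbind(r * sin(alpha), r * cos(alpha), R * sin(beta), R * cos(beta))
}

#' Angular difference between orientations modulo Laue symmetry
#'
#' Minimum geodesic angle between `R1` and `R2 %*% S` over the proper
#' rotations S of the point group: the natural error metric for indexing,
#' where symmetry-equivalent orientations are indistinguishable.
#'
#' When `lattice = TRUE` the minimum is additionally taken over the
#' indexing-ambiguity cosets ([ambiguity_operators()]): position-only still
#' indexing cannot distinguish orientations that map the lattice, but not
#' the structure, onto itself, so recovery against ground truth is assessed
#' modulo the lattice rotations and the coset choice is fixed later, at the
#' merging stage, by intensities.
#'
#' @param R1,R2 3x3 rotation matrices.
#' @param sg A [space_group()].
#' @param cell A [unit_cell()]; needed for `lattice = TRUE`.
#' @param lattice Also minimize over the indexing-ambiguity cosets.
#' @return Angle in degrees.
#' @export
orientation_error <- function(R1, R2, sg, cell = NULL, lattice = FALSE) {
  ops <- Filter(function(m) round(det(m)) == 1, sg$laue_ops)
  if (lattice) {
    if (is.null(cell)) stopf("lattice = TRUE needs the cell")
    amb <- ambiguity_operators(cell, sg)
    ops <- unlist(lapply(amb, function(C) lapply(ops, function(S) S %*% C)),
                  recursive = FALSE)
  }
  min(vapply(ops, function(S) rotation_angle_deg(R1, R2 %*% S), numeric(1)))
}
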