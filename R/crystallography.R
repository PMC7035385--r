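#' Unit cell
#'
#' @param a,b,c Cell edges in Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees.
#' @return Object of class `unit_cell` carrying the reciprocal
#'   orthogonalization matrix `B` (columns are a*, b*, c* in an orthonormal
#'   lab frame, units 1/Angstrom) and the cell volume.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  if (any(c(a, b, c) <= 0)) stopf("cell lengths must be positive")
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180))
    stopf("cell angles must be in (0, 180)")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  sg <- sin(gamma * pi / 180)
  vol_factor <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vol_factor <= 0) stopf("cell metric is not positive definite")
  V <- a * b * c * sqrt(vol_factor)
  # real-space orthogonalization (PDB convention), then B = t(solve(A))
  A <- matrix(c(a, 0, 0,
                b * cg, b * sg, 0,
                c * cb, c * (ca - cb * cg) / sg,
                V / (a * b * sg)), 3, 3)
  B <- t(solve(A))
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
                 volume = V, B = B),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("Unit cell: %.2f %.2f %.2f A, %g %g %g deg (V = %.0f A^3)\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' d-spacing of reflections
#'
#' @param hkl Integer vector `c(h,k,l)` or an n x 3 matrix.
#' @param cell A [unit_cell()].
#' @return d in Angstrom. `(0,0,0)` is rejected.
#' @examples
#' d_spacing(c(1, 1, 0), unit_cell(103.2, 103.2, 103.2))  # 72.97
#' @export
d_spacing <- function(hkl, cell) {
  hkl <- rbind(hkl)
  if (any(rowSums(abs(hkl)) == 0)) stopf("(0,0,0) has no d-spacing")
  g <- hkl %*% t(cell$B)
  1 / sqrt(rowSums(g^2))
}

# ---- space groups ------------------------------------------------------

# rotation parts as 3x3 integer matrices acting on (h,k,l) row vectors
.cyclic_perms <- list(diag(3),
                      matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3, byrow = TRUE),
                      matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3, 3, byrow = TRUE))

.sign_mats <- function(parities) {
  lapply(parities, function(s) diag(s))
}

# proper rotations of point group 23 (order 12): cyclic perms x even sign flips
.ops_23 <- local({
  evens <- .sign_mats(list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)))
  out <- list()
  for (p in .cyclic_perms) for (s in evens) out[[length(out) + 1]] <- s %*% p
  out
})

# proper rotations of point group 422 (order 8)
.ops_422 <- local({
  r4 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE) # 4-fold about z
  r2x <- diag(c(1, -1, -1))
  out <- list(diag(3), r4, r4 %*% r4, r4 %*% r4 %*% r4)
  c(out, lapply(out, function(m) r2x %*% m))
})

.with_inversion <- function(ops) c(ops, lapply(ops, function(m) -m))

#' Space-group symmetry operations
#'
#' Hard-coded support for the groups used in the pipeline: `"I23"` (cubic,
#' Laue class m-3), `"P43212"` (tetragonal, Laue class 4/mmm) and `"P1"`.
#' Arbitrary groups can be supplied as a list with elements `symbol`,
#' `rotations` (list of 3x3 integer matrices), `translations` (list of
#' fractional vectors), `centering` and `laue_symbol`.
#'
#' @param symbol Hermann-Mauguin symbol (spaces ignored) or a full
#'   specification list as described above.
#' @return Object of class `space_group` with rotation/translation parts,
#'   centering, Laue class, and the Laue-group operation list used for
#'   merging (Friedel pairs merged).
#' @export
space_group <- function(symbol) {
  if (is.list(symbol)) {
    sg <- symbol
    sg$laue_ops <- sg$laue_ops %||% .with_inversion(sg$rotations)
    class(sg) <- "space_group"
    return(sg)
  }
  sym <- gsub("[ _]", "", symbol)
  if (toupper(sym) == "I23") {
    rot <- .ops_23
    tra <- rep(list(c(0, 0, 0)), length(rot))
    sg <- list(symbol = "I 2 3", rotations = rot, translations = tra,
               centering = "I", laue_symbol = "m-3",
               laue_ops = .with_inversion(.ops_23))
  } else if (toupper(sym) %in% c("P43212", "P432121")) {
    # generators with translations for the screw axes; only the rotation
    # parts and reflection conditions matter for merging and absences
    rot <- .ops_422
    tra <- list(c(0, 0, 0), c(0.5, 0.5, 0.75), c(0, 0, 0.5), c(0.5, 0.5, 0.25),
                c(0.5, 0.5, 0.25), c(0, 0, 0.5), c(0.5, 0.5, 0.75), c(0, 0, 0))
    sg <- list(symbol = "P 43 21 2", rotations = rot, translations = tra,
               centering = "P", laue_symbol = "4/mmm",
               laue_ops = .with_inversion(.ops_422))
  } else if (toupper(sym) == "P1") {
    sg <- list(symbol = "P 1", rotations = list(diag(3)),
               translations = list(c(0, 0, 0)), centering = "P",
               laue_symbol = "-1", laue_ops = .with_inversion(list(diag(3))))
  } else {
    stopf("space group '%s' not built in; supply an operation list", symbol)
  }
  class(sg) <- "space_group"
  sg
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf("Space group %s (%s centering, Laue %s, %d Laue ops)\n",
              x$symbol, x$centering, x$laue_symbol, length(x$laue_ops)))
  invisible(x)
}

#' Systematic absences
#'
#' Reflection conditions from lattice centering and screw axes:
#' I-centering forbids h+k+l odd; the 4_3 screw of P43212 forbids (0,0,l)
#' with l not a multiple of 4, and its 2_1 axes forbid odd (h,0,0)/(0,k,0).
#'
#' @param hkl `c(h,k,l)` or n x 3 matrix.
#' @param sg A [space_group()].
#' @return Logical vector, `TRUE` where the reflection is forbidden.
#' @export
is_systematically_absent <- function(hkl, sg) {
  hkl <- rbind(hkl)
  h <- hkl[, 1]; k <- hkl[, 2]; l <- hkl[, 3]
  absent <- rep(FALSE, nrow(hkl))
  if (sg$centering == "I") absent <- absent | ((h + k + l) %% 2 != 0)
  if (sg$centering == "F") absent <- absent | !((h %% 2 == k %% 2) & (k %% 2 == l %% 2))
  if (gsub(" ", "", sg$symbol) == "P43212") {
    absent <- absent | (h == 0 & k == 0 & (l %% 4 != 0))
    absent <- absent | (k == 0 & l == 0 & (h %% 2 != 0))
    absent <- absent | (h == 0 & l == 0 & (k %% 2 != 0))
  }
  absent
}

# apply each Laue op to the rows of hkl; returns list of n x 3 matrices
.laue_images <- function(hkl, sg) {
  lapply(sg$laue_ops, function(m) hkl %*% t(m))
}

#' Reduce reflections to a canonical asymmetric-unit representative
#'
#' The canonical representative of a Laue-group orbit (Friedel mates merged)
#' is its lexicographically maximal member, compared on (h, k, l) in order.
#' The map is idempotent and constant on orbits.
#'
#' @param hkl `c(h,k,l)` or n x 3 matrix.
#' @param sg A [space_group()].
#' @return n x 3 integer matrix of canonical indices.
#' @export
asu_reduce <- function(hkl, sg) {
  hkl <- rbind(hkl)
  storage.mode(hkl) <- "double"
  bh <- rep(-Inf, nrow(hkl)); bk <- bh; bl <- bh
  for (img in .laue_images(hkl, sg)) {
    hh <- img[, 1]; kk <- img[, 2]; ll <- img[, 3]
    upd <- (hh > bh) | (hh == bh & kk > bk) | (hh == bh & kk == bk & ll > bl)
    bh[upd] <- hh[upd]; bk[upd] <- kk[upd]; bl[upd] <- ll[upd]
  }
  out <- cbind(h = bh, k = bk, l = bl)
  storage.mode(out) <- "integer"
  out
}

#' Symmetry mates of a reflection under the Laue group
#'
#' @param hkl Single reflection `c(h,k,l)`.
#' @param sg A [space_group()].
#' @return Matrix of distinct mates (including Friedel mates).
#' @export
laue_mates <- function(hkl, sg) {
  m <- do.call(rbind, .laue_images(rbind(hkl), sg))
  unique(m)
}

#' Enumerate symmetry-unique allowed reflections in a resolution range
#'
#' Scans all integer (h,k,l) with `d_min <= d <= d_max` (both bounds
#' inclusive), removes (0,0,0) and systematic absences, reduces to canonical
#' asymmetric-unit representatives under the Laue group (Friedel pairs
#' merged), and deduplicates. The count is the theoretical number of unique
#' reflections used as the completeness denominator.
#'
#' @param cell A [unit_cell()].
#' @param sg A [space_group()].
#' @param d_min,d_max Resolution range in Angstrom.
#' @return List with `hkl` (n x 3 matrix of unique reflections), `d`
#'   (their d-spacings) and `count`.
#' @export
enumerate_unique <- function(cell, sg, d_min, d_max = Inf) {
  if (d_min <= 0) stopf("d_min must be positive")
  if (d_min > d_max) return(list(hkl = matrix(integer(), 0, 3), d = numeric(), count = 0L))
  hmax <- floor(cell$a / d_min)
  kmax <- floor(cell$b / d_min)
  lmax <- floor(cell$c / d_min)
  grid <- as.matrix(expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax))
  g <- grid %*% t(cell$B)
  s2 <- rowSums(g^2)
  keep <- s2 > 0
  d <- rep(Inf, nrow(grid))
  d[keep] <- 1 / sqrt(s2[keep])
  keep <- keep & d >= d_min & d <= d_max & !is_systematically_absent(grid, sg)
  grid <- grid[keep, , drop = FALSE]
  if (!nrow(grid)) return(list(hkl = matrix(integer(), 0, 3), d = numeric(), count = 0L))
  can <- asu_reduce(grid, sg)
  dup <- duplicated(can)
  uni <- can[!dup, , drop = FALSE]
  list(hkl = uni, d = as.numeric(d_spacing(uni, cell)), count = nrow(uni))
}
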