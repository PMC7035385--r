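# ---- known-cell still indexing by orientation search -------------------

# lab-frame reciprocal vectors of peak positions (flat-Ewald inversion)
peaks_to_gvectors <- function(peaks, center, geom, beam) {
  x_um <- (peaks$fs - center[1]) * geom$pixel_size
  y_um <- (peaks$ss - center[2]) * geom$pixel_size
  L_um <- geom$camera_length * 1000
  nrm <- sqrt(x_um^2 + y_um^2 + L_um^2)
  k <- 1 / beam$wavelength
  cbind(x_um / nrm * k, y_um / nrm * k, L_um / nrm * k - k)
}

#' Predict reflection positions for an oriented crystal
#'
#' All allowed reflections with excitation error `|zeta| <= zeta_max` whose
#' flat-Ewald projection lands on the panel. For low-resolution reflections
#' both Friedel mates are simultaneously excited and appear symmetrically
#' about the beam center.
#'
#' @param orientation 3x3 rotation matrix (lab from crystal).
#' @param cell A [unit_cell()].
#' @param sg A [space_group()] (for systematic absences).
#' @param beam,geom Beam and detector descriptions.
#' @param zeta_max Excitation-error cutoff in reciprocal Angstrom.
#' @param d_min High-resolution limit of the prediction, Angstrom.
#' @param center Beam center to project about (fractional pixels).
#' @return Data frame: `h`, `k`, `l`, `fs`, `ss`, `zeta`, `d`.
#' @export
predict_spots <- function(orientation, cell, sg, beam, geom,
                          zeta_max = 0.0045, d_min = 1.55,
                          center = geom$beam_center) {
  hkl <- .allowed_hkl(cell, sg, d_min)
  RB <- orientation %*% cell$B
  G <- hkl %*% t(RB)
  kz <- 1 / beam$wavelength
  zeta <- kz - sqrt(G[, 1]^2 + G[, 2]^2 + (G[, 3] + kz)^2)
  sel <- abs(zeta) <= zeta_max
  G <- G[sel, , drop = FALSE]
  hkl <- hkl[sel, , drop = FALSE]
  zeta <- zeta[sel]
  denom <- G[, 3] + kz
  scale <- geom$camera_length * 1000 / geom$pixel_size
  fs <- center[1] + G[, 1] / denom * scale
  ss <- center[2] + G[, 2] / denom * scale
  on <- fs >= 0 & fs <= geom$n_fast - 1 & ss >= 0 & ss <= geom$n_slow - 1
  d <- 1 / sqrt(rowSums(G[on, , drop = FALSE]^2))
  out <- data.frame(h = hkl[on, 1], k = hkl[on, 2], l = hkl[on, 3],
                    fs = fs[on], ss = ss[on], zeta = zeta[on], d = d)
  rownames(out) <- NULL
  out
}

# cached enumeration of allowed lattice points (both Friedel mates)
.hkl_cache <- new.env(parent = emptyenv())
.allowed_hkl <- function(cell, sg, d_min) {
  key <- paste(signif(c(cell$a, cell$b, cell$c, cell$alpha, cell$beta,
                        cell$gamma), 10), sg$symbol, signif(d_min, 10),
               collapse = "|")
  hit <- .hkl_cache[[key]]
  if (!is.null(hit)) return(hit)
  hmax <- floor(cell$a / d_min); kmax <- floor(cell$b / d_min)
  lmax <- floor(cell$c / d_min)
  grid <- as.matrix(expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax))
  g <- grid %*% t(cell$B)
  s2 <- rowSums(g^2)
  keep <- s2 > 0 & s2 <= 1 / d_min^2 & !is_systematically_absent(grid, sg)
  grid <- grid[keep, , drop = FALSE]
  .hkl_cache[[key]] <- grid
  grid
}

#' Index a still diffraction pattern with a known cell
#'
#' Orientation search against a known unit cell: a quasi-uniform SO(3)
#' quaternion grid is scored by how many observed reciprocal vectors land
#' near integer crystal-frame indices; the top candidates are refined on a
#' shrinking local grid, and the best orientation is polished by least
#' squares on the matched peak-prediction residuals (pixel residuals plus
#' an excitation-error penalty, which is what constrains the out-of-plane
#' rotation on a nearly flat Ewald sphere). The solution is accepted when
#' at least `min_matched` peaks match within `match_tol` pixels.
#'
#' @param peaks A [find_peaks()] result.
#' @param cell,sg Known unit cell and space group.
#' @param beam,geom Beam and detector descriptions.
#' @param center Refined beam center for this pattern.
#' @param grid_step Upper bound on the coarse-search angular step, degrees;
#'   the step is tightened automatically so the innermost scoring peaks
#'   stay within `coarse_tol` fractional indices across one step.
#' @param match_tol Peak-prediction match tolerance, pixels.
#' @param min_matched Minimum matched peaks for an accepted solution.
#' @param zeta_max Excitation-error cutoff for predictions (1/Angstrom).
#' @param zeta_sigma Excitation-error scale of the refinement penalty.
#' @param d_min Prediction resolution limit, Angstrom.
#' @param n_strong Number of strongest peaks used in the coarse scoring.
#' @param n_top Coarse candidates carried into local refinement.
#' @param coarse_tol Fractional-index tolerance of the coarse scoring.
#' @param min_fraction Minimum fraction of observed peaks that must match a
#'   prediction; guards against chance matches on junk patterns, where a
#'   dense prediction set can pick up isolated noise peaks.
#' @return Object of class `indexing_solution`: `orientation`, `n_matched`,
#'   `rms_residual` (px), `predicted`, `success`. On failure `success` is
#'   `FALSE` and the orientation is `NULL`.
#' @export
index_pattern <- function(peaks, cell, sg, beam, geom,
                          center = geom$beam_center, grid_step = 1.5,
                          match_tol = 2, min_matched = 10,
                          zeta_max = 0.0045, zeta_sigma = 0.0015,
                          d_min = 1.55, n_strong = 40, n_top = 10,
                          coarse_tol = 0.2, min_fraction = 0.5) {
  failure <- structure(list(success = FALSE, orientation = NULL,
                            n_matched = 0L, rms_residual = NA_real_,
                            predicted = NULL),
                       class = "indexing_solution")
  if (nrow(peaks) < min_matched) return(failure)
  G_all <- peaks_to_gvectors(peaks, center, geom, beam)
  # score with the innermost peaks: for a cell edge a, an orientation error
  # dtheta moves the fractional index of a peak by up to a * |g| * dtheta,
  # so low-order peaks tolerate the coarsest grid
  inner <- order(peaks$r)[seq_len(min(n_strong, nrow(peaks)))]
  G <- G_all[inner, , drop = FALSE]
  gmax <- sqrt(max(rowSums(G^2)))
  amax <- max(cell$a, cell$b, cell$c)
  step_c <- min(max(coarse_tol / (0.9 * gmax * amax), 0.005), 0.06,
                grid_step * pi / 180)
  laue_order <- sum(vapply(sg$laue_ops, function(m) round(det(m)) == 1,
                           logical(1)))
  n_grid <- min(ceiling(8 * pi^2 / (step_c^3 * laue_order)), 3e6)
  quats <- so3_grid(n_grid)
  binv <- solve(cell$B)
  score <- cpp_score_orientations(quats, binv, G, coarse_tol, zeta_max)[, 2]
  # the low-order score saturates near the optimum, so a generous candidate
  # list is locally optimized on the inner peaks and then re-ranked with a
  # larger peak set at a tight tolerance, which discriminates sharply
  n_re <- min(20 * n_top, length(score))
  pre <- order(-score, seq_along(score))[seq_len(n_re)]
  tols_inner <- vapply(step_c / 2^(1:3), function(st)
    max(0.08, min(coarse_tol, 2 * 0.9 * gmax * amax * st)), numeric(1))
  climb1 <- cpp_hill_climb(quats[pre, , drop = FALSE], binv, G, step_c / 2,
                           tols_inner, 2L, zeta_max)
  ext <- order(peaks$r)[seq_len(min(4 * n_strong, nrow(peaks)))]
  G_ext <- G_all[ext, , drop = FALSE]
  gmax_ext <- sqrt(max(rowSums(G_ext^2)))
  qs1 <- t(apply(climb1[, 1:9, drop = FALSE], 1, function(r)
    .matrix_to_quat(matrix(r, 3, 3, byrow = TRUE))))
  score_ext <- cpp_score_orientations(qs1, binv, G_ext, 0.12, zeta_max)[, 2]
  top <- order(-score_ext, seq_along(score_ext))[seq_len(min(n_top, n_re))]
  tols_ext <- vapply(step_c / 8 / 2^(0:4), function(st)
    max(0.08, min(0.2, 2 * 0.9 * gmax_ext * amax * st)), numeric(1))
  climb2 <- cpp_hill_climb(qs1[top, , drop = FALSE], binv, G_ext, step_c / 8,
                           tols_ext, 3L, zeta_max)
  climbed <- lapply(seq_len(nrow(climb2)), function(i)
    list(R = matrix(climb2[i, 1:9], 3, 3, byrow = TRUE),
         score = climb2[i, 11], count = climb2[i, 10]))
  ord <- order(-vapply(climbed, `[[`, numeric(1), "score"))
  climbed <- climbed[ord]
  if (climbed[[1]]$count < min(min_matched, nrow(G_ext)) * 0.25)
    return(failure)
  # near-coincident lattice sections can produce high-scoring impostor
  # orientations; polish the best few candidates and keep the one that
  # explains the most peaks on the detector
  best <- NULL
  for (cand in climbed) {
    if (!is.null(best) && best$n >= 0.9 * nrow(peaks)) break
    if (cand$score < 0.5 * climbed[[1]]$score) next  # hopeless basin
    R <- .refine_orientation(cand$R, peaks, G_all, cell, sg, beam, geom,
                             center, match_tol, zeta_max, zeta_sigma, d_min)
    pred <- predict_spots(R, cell, sg, beam, geom, zeta_max = zeta_max,
                          d_min = d_min, center = center)
    mm <- .match_peaks(peaks, pred, match_tol)
    rms <- if (nrow(mm)) sqrt(mean(mm$res2)) else NA_real_
    if (is.null(best) || nrow(mm) > best$n ||
        (nrow(mm) == best$n && is.finite(rms) && rms < best$rms))
      best <- list(R = R, pred = pred, mm = mm, n = nrow(mm), rms = rms)
  }
  if (is.null(best) || best$n < min_matched ||
      best$n < min_fraction * nrow(peaks) ||
      !is.finite(best$rms) || best$rms > match_tol)
    return(failure)
  structure(list(success = TRUE, orientation = best$R,
                 n_matched = as.integer(best$n), rms_residual = best$rms,
                 predicted = best$pred, matched = best$mm),
            class = "indexing_solution")
}

.matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q / sqrt(sum(q^2))
}

# nearest-prediction matching within tol px; one prediction per peak
.match_peaks <- function(peaks, pred, tol) {
  if (nrow(pred) == 0 || nrow(peaks) == 0)
    return(data.frame(peak = integer(), pred = integer(), res2 = numeric()))
  m <- cpp_match_points(peaks$fs, peaks$ss, pred$fs, pred$ss, tol)
  ok <- m[, 1] > 0
  data.frame(peak = which(ok), pred = as.integer(m[ok, 1]), res2 = m[ok, 2])
}

# least-squares polish of the orientation: pixel residuals of matched
# peaks plus a zeta/zeta_sigma penalty, re-matching between passes
.refine_orientation <- function(R0, peaks, G_all, cell, sg, beam, geom,
                                center, match_tol, zeta_max, zeta_sigma,
                                d_min) {
  R <- R0
  kz <- 1 / beam$wavelength
  scale <- geom$camera_length * 1000 / geom$pixel_size
  pass_tol <- c(2 * match_tol, match_tol, match_tol)
  for (pass in seq_along(pass_tol)) {
    pred <- predict_spots(R, cell, sg, beam, geom, zeta_max = zeta_max,
                          d_min = d_min, center = center)
    mm <- .match_peaks(peaks, pred, pass_tol[pass])
    if (nrow(mm) < 3) return(R)
    hkl_m <- as.matrix(pred[mm$pred, c("h", "k", "l")])
    obs_fs <- peaks$fs[mm$peak]; obs_ss <- peaks$ss[mm$peak]
    obj <- function(v) {
      Rv <- rotvec_to_matrix(v) %*% R
      G <- hkl_m %*% t(Rv %*% cell$B)
      denom <- G[, 3] + kz
      fs <- center[1] + G[, 1] / denom * scale
      ss <- center[2] + G[, 2] / denom * scale
      zeta <- kz - sqrt(G[, 1]^2 + G[, 2]^2 + (G[, 3] + kz)^2)
      sum((fs - obs_fs)^2 + (ss - obs_ss)^2) / 0.25 +
        sum((zeta / zeta_sigma)^2)
    }
    fit <- stats::optim(c(0, 0, 0), obj, method = "BFGS",
                        control = list(maxit = 100, reltol = 1e-10))
    R <- rotvec_to_matrix(fit$par) %*% R
  }
  R
}

#' @export
print.indexing_solution <- function(x, ...) {
  if (!x$success) cat("Indexing failed\n")
  else cat(sprintf("Indexed: %d peaks matched, rms %.2f px\n",
                   x$n_matched, x$rms_residual))
  invisible(x)
}

#' Indexing rate
#'
#' Fraction of hit patterns that were successfully indexed.
#'
#' @param results List of [index_pattern()] results, or a logical vector.
#' @return Fraction in `[0, 1]`; `NA` for no hits.
#' @export
indexing_rate <- function(results) {
  if (is.list(results))
    results <- vapply(results, function(r) isTRUE(r$success), logical(1))
  if (!length(results)) return(NA_real_)
  mean(results)
}
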