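# ---- crystal mapping on STEM overview images ---------------------------

#' Detect crystals in a STEM overview image
#'
#' Background-subtracted thresholding, 8-connected
#' component labeling, size and shape filters, then intensity-weighted
#' centroids. Features closer than `min_separation` are merged to their
#' joint (intensity-weighted) centroid. Subtracting the image median first
#' makes the detection invariant under constant offsets.
#'
#' @param image Matrix of counts, indexed (x, y), finite values.
#' @param threshold_mode `"robust"` (default: a multiple of the robust
#'   image sigma above the median — the reliable choice for sparse bright
#'   features on a dominant background), `"otsu"` (Otsu's threshold on the
#'   upper intensity tail, floored at 4 robust sigma; classic Otsu on the
#'   full histogram fails when features occupy a tiny area fraction),
#'   `"absolute"` or `"quantile"`.
#' @param threshold Sigma multiplier for `"robust"` (default 3.5), counts
#'   above background for `"absolute"`, probability for `"quantile"`.
#' @param min_area,max_area Component area limits in pixels.
#' @param max_eccentricity Reject features more elongated than this.
#' @param min_separation Merge radius in pixels.
#' @return Data frame of class `crystal_features`: columns `x`, `y`
#'   (0-based fractional pixels), `area`, `eccentricity`, `mean_intensity`.
#' @export
find_crystals <- function(image,
                          threshold_mode = c("robust", "otsu", "absolute",
                                             "quantile"),
                          threshold = NULL, min_area = 5, max_area = 2000,
                          max_eccentricity = 0.97, min_separation = 5) {
  threshold_mode <- match.arg(threshold_mode)
  if (!all(is.finite(image))) stopf("image must be finite")
  empty <- data.frame(x = numeric(), y = numeric(), area = numeric(),
                      eccentricity = numeric(), mean_intensity = numeric())
  class(empty) <- c("crystal_features", "data.frame")
  bg <- stats::median(image)
  img <- image - bg
  rng <- diff(range(img))
  if (rng == 0) return(empty)
  sig <- stats::mad(img)
  thr <- switch(threshold_mode,
    robust = (threshold %||% 3.5) * sig,
    otsu = {
      # Otsu on the full histogram fails when the foreground occupies a
      # tiny fraction of the image (the threshold lands inside the
      # background mode); restrict it to the upper tail and floor it at a
      # robust sigma level so a featureless image yields no detections
      tail_px <- img[img > 2 * sig]
      t_otsu <- if (length(tail_px) > 50) {
        rngt <- range(tail_px)
        norm <- (tail_px - rngt[1]) / max(diff(rngt), 1e-9)
        EBImage::otsu(matrix(norm, ncol = 1), range = c(0, 1)) *
          diff(rngt) + rngt[1]
      } else Inf
      max(t_otsu, 4 * sig)
    },
    absolute = threshold %||% stopf("absolute mode needs a threshold"),
    quantile = stats::quantile(img, threshold %||% 0.999, names = FALSE))
  mask <- img > thr
  if (!any(mask)) return(empty)
  lab <- cpp_label_components(mask)
  ids <- lab[lab > 0L]
  w <- img[lab > 0L]
  idx <- which(lab > 0L)
  xs <- (idx - 1L) %% nrow(img)
  ys <- (idx - 1L) %/% nrow(img)
  w <- pmax(w, 1e-9)
  area <- tabulate(ids)
  sw <- rowsum(w, ids)[, 1]
  cx <- rowsum(w * xs, ids)[, 1] / sw
  cy <- rowsum(w * ys, ids)[, 1] / sw
  # central second moments -> eccentricity of the equivalent ellipse
  mxx <- rowsum(w * xs^2, ids)[, 1] / sw - cx^2
  myy <- rowsum(w * ys^2, ids)[, 1] / sw - cy^2
  mxy <- rowsum(w * xs * ys, ids)[, 1] / sw - cx * cy
  tr <- mxx + myy
  det2 <- sqrt(pmax((mxx - myy)^2 + 4 * mxy^2, 0))
  l1 <- (tr + det2) / 2; l2 <- pmax((tr - det2) / 2, 0)
  ecc <- ifelse(l1 > 0, sqrt(pmax(1 - l2 / l1, 0)), 0)
  mean_int <- rowsum(img[lab > 0L], ids)[, 1] / area
  feat <- data.frame(x = cx, y = cy, area = area, eccentricity = ecc,
                     mean_intensity = mean_int)
  feat <- feat[feat$area >= min_area & feat$area <= max_area &
                 feat$eccentricity <= max_eccentricity, , drop = FALSE]
  feat <- .merge_close_features(feat, min_separation)
  rownames(feat) <- NULL
  class(feat) <- c("crystal_features", "data.frame")
  feat
}

# single-linkage merge of features closer than min_sep, area-weighted centroid
.merge_close_features <- function(feat, min_sep) {
  n <- nrow(feat)
  if (n < 2 || min_sep <= 0) return(feat)
  dmat <- as.matrix(stats::dist(feat[, c("x", "y")]))
  grp <- stats::cutree(stats::hclust(stats::as.dist(dmat), method = "single"),
                       h = min_sep)
  if (max(grp) == n) return(feat)
  out <- do.call(rbind, lapply(split(seq_len(n), grp), function(ii) {
    f <- feat[ii, , drop = FALSE]
    w <- f$area * f$mean_intensity
    data.frame(x = sum(f$x * w) / sum(w), y = sum(f$y * w) / sum(w),
               area = sum(f$area),
               eccentricity = max(f$eccentricity),
               mean_intensity = sum(f$mean_intensity * f$area) / sum(f$area))
  }))
  out
}

#' Ordered diffraction scan-point list from detected crystals
#'
#' Serpentine (boustrophedon) ordering: features are binned into rows of
#' height `row_height` pixels; rows are visited top to bottom with
#' alternating horizontal direction, minimizing deflector travel. Physical
#' coordinates are `pixel * map_field / map_size` micrometres.
#'
#' @param features A [find_crystals()] result.
#' @param map_field Field of view in micrometres.
#' @param map_size Map size in pixels.
#' @param row_height Serpentine row height in pixels.
#' @return Data frame of class `scan_point_list`: `index`, `x_px`, `y_px`,
#'   `x_um`, `y_um`.
#' @export
make_scan_list <- function(features, map_field = 18, map_size = 1024,
                           row_height = 16) {
  if (nrow(features) == 0) {
    out <- data.frame(index = integer(), x_px = numeric(), y_px = numeric(),
                      x_um = numeric(), y_um = numeric())
    class(out) <- c("scan_point_list", "data.frame")
    return(out)
  }
  row <- floor(features$y / row_height)
  xo <- ifelse(row %% 2 == 0, features$x, -features$x)
  ord <- order(row, xo)
  scale <- map_field / map_size
  out <- data.frame(index = seq_along(ord),
                    x_px = features$x[ord], y_px = features$y[ord],
                    x_um = features$x[ord] * scale,
                    y_um = features$y[ord] * scale)
  class(out) <- c("scan_point_list", "data.frame")
  out
}

#' Hit fraction of a scan
#'
#' Fraction of scan points whose diffraction pattern passed the hit filter.
#'
#' @param hits Logical vector (one element per scan point) or hit count.
#' @param n_points Total scan points (when `hits` is a count).
#' @return Fraction in `[0, 1]`; `NA` for an empty scan.
#' @export
hit_fraction <- function(hits, n_points = length(hits)) {
  if (n_points == 0) return(NA_real_)
  if (is.logical(hits)) sum(hits) / n_points else hits / n_points
}

#' Dose delivered by the STEM mapping scan
#'
#' Mapping must stay well below 0.1 electrons per square Angstrom so that
#' crystals are not damaged before diffraction; a warning is emitted above
#' that level.
#'
#' @param beam A [beam_parameters()].
#' @param dwell_time Per-pixel dwell time in ms.
#' @param map_field Field of view in micrometres.
#' @param map_size Map size in pixels.
#' @return Dose in electrons per square Angstrom.
#' @export
map_dose <- function(beam, dwell_time, map_field = 18, map_size = 1024) {
  n_e <- beam$beam_current * 1e-9 * dwell_time * 1e-3 / .e_charge
  area_px <- (map_field * 1e4 / map_size)^2   # um -> Angstrom
  dose <- n_e / area_px
  if (dose > 0.1)
    warning(sprintf("mapping dose %.3g e-/A^2 exceeds 0.1 e-/A^2", dose))
  dose
}
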