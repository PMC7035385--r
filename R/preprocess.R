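# ---- detector corrections, frame summing, pattern centering ------------

#' Apply detector corrections to a movie stack
#'
#' Divides counts by the flat-field gain and attaches a validity mask that
#' excludes dead pixels from all downstream photometry (dead pixels are
#' masked, never interpolated). Idempotent: already-corrected stacks are
#' returned unchanged.
#'
#' @param stack A `movie_stack`.
#' @param maps A [detector_defects()] / correction-maps object.
#' @return Corrected `movie_stack` with numeric frames, `valid_mask`, and
#'   `corrected = TRUE`.
#' @export
apply_corrections <- function(stack, maps) {
  if (isTRUE(stack$corrected)) return(stack)
  dm <- dim(stack$frames[[1]])
  if (!all(dm == dim(maps$flat_field)) || !all(dm == dim(maps$dead_mask)))
    stopf("correction map shape %s does not match frames %s",
          paste(dim(maps$flat_field), collapse = "x"), paste(dm, collapse = "x"))
  if (any(maps$flat_field[!maps$dead_mask] <= 0))
    stopf("flat field must be positive on valid pixels")
  stack$frames <- lapply(stack$frames, function(f) f / maps$flat_field)
  stack$valid_mask <- !maps$dead_mask
  stack$corrected <- TRUE
  stack
}

#' Sum dose-fractionation frames
#'
#' `cumulative = TRUE` returns the sum of frames `1..k` (the image a single
#' `k * frame_time` exposure would have produced); `cumulative = FALSE`
#' returns frame `k` alone. Counts are summed exactly.
#'
#' @param stack A `movie_stack`.
#' @param k Frame count (cumulative) or frame index.
#' @param cumulative Sum frames 1..k or select frame k.
#' @return Matrix of counts.
#' @export
sum_frames <- function(stack, k, cumulative = TRUE) {
  n <- length(stack$frames)
  if (k < 1 || k > n) stopf("k = %s out of range 1..%d", format(k), n)
  if (!cumulative) return(stack$frames[[k]])
  Reduce(`+`, stack$frames[seq_len(k)])
}

#' Refine the beam center of a still pattern
#'
#' Two stages. Stage 1 locates the transmitted beam: the intensity-weighted
#' centroid of pixels above a high quantile within `search_radius` of the
#' nominal center (saturated pixels excluded). Stage 2 refines by Friedel
#' symmetry: peaks at resolutions lower than `friedel_dmin` are paired with
#' their point-symmetric mates (both simultaneously excited on a flat Ewald
#' sphere), and the center minimizing `sum |p_i + p_j - 2c|^2` is the mean
#' of the pair midpoints. If fewer than 2 pairs are found the stage-1
#' center is returned with `flag = "friedel_failed"`.
#'
#' @param image Summed pattern (matrix of counts).
#' @param geom A [detector_geometry()].
#' @param beam A [beam_parameters()].
#' @param search_radius Stage-1 search radius, pixels.
#' @param friedel_dmin Only peaks with d above this (Angstrom) are paired.
#' @param pair_tol Pairing tolerance on the midpoint distance, pixels.
#' @param quantile_thresh Stage-1 intensity quantile.
#' @param saturation Counts above this are excluded from the centroid.
#' @param peaks Optional precomputed [find_peaks()] list; found internally
#'   (around the stage-1 center) when missing.
#' @param peak_params Extra arguments for the internal [find_peaks()] call
#'   (e.g. `snr_min`), so downstream stages can reuse the returned peaks.
#' @param mask Optional validity mask.
#' @return List: `center`, `stage1`, `n_pairs`, `flag` (`"ok"`,
#'   `"friedel_failed"` or `"no_beam"`), and `peaks` (the peak list used
#'   for the Friedel stage, positions relative to the stage-1 center).
#' @export
find_center <- function(image, geom, beam, search_radius = 20,
                        friedel_dmin = 4, pair_tol = 2,
                        quantile_thresh = 0.99, saturation = Inf,
                        peaks = NULL, peak_params = list(), mask = NULL) {
  nominal <- geom$beam_center
  xs <- (seq_len(geom$n_fast) - 1)
  ys <- (seq_len(geom$n_slow) - 1)
  r2 <- outer((xs - nominal[1])^2, (ys - nominal[2])^2, `+`)
  near <- r2 <= search_radius^2
  vals <- image[near]
  thr <- stats::quantile(vals, quantile_thresh, names = FALSE)
  selm <- near & image > thr & image <= saturation
  if (!is.null(mask)) selm <- selm & mask
  if (!any(selm)) {
    return(list(center = nominal, stage1 = nominal, n_pairs = 0L,
                flag = "no_beam", peaks = NULL))
  }
  idx <- which(selm)
  w <- image[idx]
  px <- (idx - 1L) %% geom$n_fast
  py <- (idx - 1L) %/% geom$n_fast
  stage1 <- c(sum(w * px) / sum(w), sum(w * py) / sum(w))
  g1 <- geom
  g1$beam_center <- stage1
  if (is.null(peaks))
    peaks <- do.call(find_peaks, c(list(image, center = stage1, geom = geom,
                                        beam = beam, mask = mask),
                                   peak_params))
  lowres <- peaks[!is.na(peaks$d) & peaks$d > friedel_dmin, , drop = FALSE]
  n <- nrow(lowres)
  if (n >= 2) {
    p <- as.matrix(lowres[, c("fs", "ss")])
    mid_x <- outer(p[, 1], p[, 1], `+`) / 2
    mid_y <- outer(p[, 2], p[, 2], `+`) / 2
    dev <- sqrt((mid_x - stage1[1])^2 + (mid_y - stage1[2])^2)
    diag(dev) <- Inf
    pair <- which(dev < pair_tol, arr.ind = TRUE)
    pair <- pair[pair[, 1] < pair[, 2], , drop = FALSE]
    if (nrow(pair) >= 2) {
      cx <- mean(mid_x[pair]); cy <- mean(mid_y[pair])
      return(list(center = c(cx, cy), stage1 = stage1,
                  n_pairs = nrow(pair), flag = "ok", peaks = peaks))
    }
  }
  list(center = stage1, stage1 = stage1, n_pairs = 0L,
       flag = "friedel_failed", peaks = peaks)
}
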