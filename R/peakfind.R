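# ---- Bragg-spot detection with radial background estimation ------------

# per-pixel ring index for annuli of equal radial width
.ring_index <- function(n_fast, n_slow, center, ring_width) {
  xs <- (seq_len(n_fast) - 1) - center[1]
  ys <- (seq_len(n_slow) - 1) - center[2]
  r <- sqrt(outer(xs^2, ys^2, `+`))
  list(r = r, ring = 1L + as.integer(floor(r / ring_width)))
}

#' Radial background profile
#'
#' Robust background statistics in annuli of equal radial width about the
#' beam center: per-ring median and MAD-based sigma over valid pixels, with
#' iterative exclusion of pixels more than `snr_min` sigma above the median
#' (so Bragg spots do not bias the background). Rings with fewer than 20
#' valid pixels copy the statistics of the nearest populated ring and are
#' flagged.
#'
#' @param image Matrix of counts.
#' @param center Beam center, 0-based fractional pixels.
#' @param ring_width Annulus width in pixels.
#' @param snr_min Outlier exclusion threshold in sigmas.
#' @param n_iter Exclusion iterations.
#' @param mask Optional logical validity mask.
#' @return Data frame: `ring`, `r_mid`, `median`, `sigma`, `n`, `copied`.
#' @export
radial_background <- function(image, center, ring_width = 2, snr_min = 6,
                              n_iter = 2, mask = NULL) {
  ri <- .ring_index(nrow(image), ncol(image), center, ring_width)
  valid <- if (is.null(mask)) rep(TRUE, length(image)) else as.vector(mask)
  ring <- ri$ring
  n_rings <- max(ring)
  med <- sig <- rep(NA_real_, n_rings)
  nv <- integer(n_rings)
  vals <- split(image[valid], ring[valid])
  for (nm in names(vals)) {
    k <- as.integer(nm)
    v <- vals[[nm]]
    for (it in seq_len(n_iter + 1)) {
      m <- stats::median(v)
      s <- stats::mad(v, center = m)
      if (it <= n_iter) v <- v[v <= m + snr_min * max(s, sqrt(max(m, 0)), 1)]
    }
    med[k] <- m; sig[k] <- s; nv[k] <- length(v)
  }
  copied <- nv < 20
  pop <- which(!copied & !is.na(med))
  if (length(pop)) {
    for (k in which(copied | is.na(med))) {
      j <- pop[which.min(abs(pop - k))]
      med[k] <- med[j]; sig[k] <- sig[j]
    }
  } else {
    med[is.na(med)] <- 0; sig[is.na(sig)] <- 0
  }
  data.frame(ring = seq_len(n_rings),
             r_mid = (seq_len(n_rings) - 0.5) * ring_width,
             median = med, sigma = sig, n = nv, copied = copied)
}

#' Find Bragg peaks on a still pattern
#'
#' peakfinder8-style detection: candidate pixels exceed both `adc_thresh`
#' and `ring_median + snr_min * ring_sigma` (with a Poisson floor
#' `sqrt(median)` on the ring sigma, required for photon-counting data
#' where the MAD of a near-empty background collapses to zero); candidates
#' are clustered by 8-connectivity; clusters of `min_pix` to `max_pix`
#' pixels become peaks. Peak position is the background-subtracted
#' intensity-weighted centroid; integrated counts are a background-
#' corrected box sum (half-width `int_radius`) about the centroid, which,
#' unlike a sum over threshold-exceeding pixels only, recovers the full
#' spot flux. The transmitted-beam region (`r < r_exclude`) is ignored.
#'
#' @param image Matrix of counts.
#' @param center Beam center (fractional pixels).
#' @param geom,beam Geometry used to attach d-spacings (optional: `d` is
#'   `NA` when either is missing).
#' @param adc_thresh Absolute count threshold.
#' @param snr_min Signal-to-noise threshold.
#' @param min_pix,max_pix Cluster size limits.
#' @param r_exclude Radius around the beam center to exclude, pixels.
#' @param ring_width Background annulus width, pixels.
#' @param int_radius Box half-width of the photometric sum, pixels.
#' @param mask Optional validity mask.
#' @return Data frame of class `peak_list`: `fs`, `ss`, `intensity`,
#'   `n_pix`, `r`, `d`.
#' @export
find_peaks <- function(image, center, geom = NULL, beam = NULL,
                       adc_thresh = 0, snr_min = 6, min_pix = 2,
                       max_pix = 200, r_exclude = 12, ring_width = 2,
                       int_radius = 3, mask = NULL) {
  bg <- radial_background(image, center, ring_width = ring_width,
                          snr_min = snr_min, mask = mask)
  ri <- .ring_index(nrow(image), ncol(image), center, ring_width)
  med_px <- matrix(bg$median[ri$ring], nrow(image), ncol(image))
  sig_px <- matrix(pmax(bg$sigma[ri$ring],
                        sqrt(pmax(bg$median[ri$ring], 0)), 0.7),
                   nrow(image), ncol(image))
  cand <- image > pmax(adc_thresh, med_px + snr_min * sig_px)
  cand <- cand & (ri$r >= r_exclude)
  if (!is.null(mask)) cand <- cand & mask
  empty <- data.frame(fs = numeric(), ss = numeric(), intensity = numeric(),
                      n_pix = integer(), r = numeric(), d = numeric())
  class(empty) <- c("peak_list", "data.frame")
  if (!any(cand)) return(empty)
  lab <- cpp_label_components(cand)
  idx <- which(lab > 0L)
  ids <- lab[idx]
  size <- tabulate(ids)
  xs <- (idx - 1L) %% nrow(image)
  ys <- (idx - 1L) %/% nrow(image)
  w <- pmax(image[idx] - med_px[idx], 1e-9)
  sw <- rowsum(w, ids)[, 1]
  fs <- rowsum(w * xs, ids)[, 1] / sw
  ss <- rowsum(w * ys, ids)[, 1] / sw
  # photometry: background-corrected box sum about each centroid
  vmask <- if (is.null(mask)) matrix(TRUE, nrow(image), ncol(image)) else mask
  ib <- cpp_integrate_boxes(image, vmask, fs, ss, int_radius,
                            int_radius + 1, int_radius + 4)
  intens <- ib[, 1] - ib[, 2] * ib[, 4]
  keep <- size >= min_pix & size <= max_pix & intens > 0
  pk <- data.frame(fs = fs[keep], ss = ss[keep], intensity = intens[keep],
                   n_pix = size[keep])
  pk$r <- sqrt((pk$fs - center[1])^2 + (pk$ss - center[2])^2)
  pk$d <- if (!is.null(geom) && !is.null(beam))
    radius_to_resolution(pk$r, geom, beam) else rep(NA_real_, nrow(pk))
  pk <- pk[order(-pk$intensity), , drop = FALSE]
  rownames(pk) <- NULL
  class(pk) <- c("peak_list", "data.frame")
  pk
}

#' Hit filter for still patterns
#'
#' A pattern is a hit when strictly more than `min_spots` peaks lie on the
#' chosen side of `d_filter`. The default takes the low-resolution side
#' (`d >= d_filter`): low-order spots are the robust signature of a
#' diffracting crystal even when high-resolution signal has decayed.
#'
#' @param peaks A [find_peaks()] result (with `d` attached).
#' @param min_spots Spot count threshold (strict).
#' @param d_filter Resolution threshold in Angstrom.
#' @param d_side `"low"` counts peaks with `d >= d_filter`; `"high"` counts
#'   `d < d_filter`.
#' @return Logical.
#' @export
hit_filter <- function(peaks, min_spots = 25, d_filter = 2.5,
                       d_side = c("low", "high")) {
  d_side <- match.arg(d_side)
  if (any(is.na(peaks$d))) stopf("peaks need d-spacings for the hit filter")
  n <- if (d_side == "low") sum(peaks$d >= d_filter) else sum(peaks$d < d_filter)
  n > min_spots
}
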