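# ---- background-corrected intensity extraction -------------------------

#' Integrate predicted reflections on a pattern
#'
#' Background-corrected pixel summation: for each prediction, the counts in
#' a `(2 box_radius + 1)^2` box are summed and `n_box` times the local
#' background is subtracted. The background is the outlier-clipped mean of
#' a surrounding square annulus (clipping at 3 robust sigma above the
#' median rejects neighbouring spots; a plain median would be biased low on
#' the near-empty Poisson backgrounds of photon-counting detectors). The
#' variance combines Poisson counting in the box with the background-mean
#' uncertainty. Predictions
#' whose boxes overlap are both discarded (flag `overlap`); boxes losing
#' more than half their pixels to dead pixels or the panel edge are dropped
#' (flag `masked`). Dead pixels never enter box or annulus sums.
#'
#' @param image Pattern (counts; corrected, i.e. gain-divided, if needed).
#' @param predictions Data frame with `fs`, `ss` (and optionally `h,k,l`,
#'   `d`) as from [predict_spots()].
#' @param box_radius Half-width of the integration box, pixels.
#' @param annulus Inner/outer half-widths `c(in, out)` of the background
#'   annulus (Chebyshev rings; `in >= box_radius`).
#' @param mask Optional logical validity mask (TRUE = usable).
#' @param overlap Optional precomputed logical overlap flag per prediction
#'   (computed internally when `NULL`); pass it when integrating the same
#'   prediction list on many frames.
#' @return Data frame of class `observation_list`: prediction columns plus
#'   `I`, `sigma`, `flag` (`"ok"`, `"overlap"`, `"masked"`); discarded rows
#'   are removed, their counts reported in `attr(, "n_discarded")`.
#' @export
integrate_spots <- function(image, predictions, box_radius = 3,
                            annulus = c(5, 8), mask = NULL, overlap = NULL) {
  n <- nrow(predictions)
  if (n == 0) {
    out <- cbind(predictions, I = numeric(0), sigma = numeric(0),
                 flag = character(0))
    class(out) <- c("observation_list", "data.frame")
    return(out)
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  res <- cpp_integrate_boxes(image, mask, predictions$fs, predictions$ss,
                             box_radius, annulus[1], annulus[2])
  sum_box <- res[, 1]; n_box <- res[, 2]; n_masked <- res[, 3]
  bg_mean <- res[, 4]; bg_sigma <- res[, 5]; n_ann <- res[, 6]
  full_box <- (2 * box_radius + 1)^2
  I <- sum_box - n_box * bg_mean
  var_bg <- bg_sigma^2 / pmax(n_ann, 1)
  sigma <- sqrt(pmax(sum_box, 0) + n_box^2 * var_bg + 1)
  # overlap: another prediction center within the box footprint
  ov <- overlap
  if (is.null(ov)) ov <- spot_overlap(predictions, box_radius)
  bad_mask <- n_masked > full_box / 2 | n_ann < 8
  flag <- ifelse(ov, "overlap", ifelse(bad_mask, "masked", "ok"))
  out <- cbind(predictions, I = I, sigma = sigma, flag = flag)
  keep <- flag == "ok"
  n_disc <- c(overlap = sum(flag == "overlap"), masked = sum(flag == "masked"))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_discarded") <- n_disc
  class(out) <- c("observation_list", "data.frame")
  out
}

#' Flag predictions whose integration boxes would overlap
#'
#' @param predictions Data frame with `fs`, `ss`.
#' @param box_radius Box half-width in pixels.
#' @return Logical vector.
#' @export
spot_overlap <- function(predictions, box_radius = 3) {
  n <- nrow(predictions)
  if (n < 2) return(rep(FALSE, n))
  cpp_min_self_dist(predictions$fs, predictions$ss) <= 2 * box_radius + 1
}
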