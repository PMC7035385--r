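# ---- radiation-damage analysis and optimal dose window -----------------

#' Per-shell intensity decay series
#'
#' Mean background-corrected spot intensity per (resolution shell, frame),
#' from per-frame integrations of predicted reflections. Frame mid-times
#' are `(i + 0.5) * frame_time` (i 0-based). Only indexed, predicted spots
#' should enter, to avoid the selection bias of peak finding on late, weak
#' frames. Shells with no observations are omitted.
#'
#' @param frame_obs Data frame with columns `frame` (0-based), `d`, `I`.
#' @param shells A [make_shells()] partition.
#' @param frame_time Frame exposure in ms.
#' @return Data frame of class `decay_series`: `shell`, `d_mid`, `t`,
#'   `mean_I`, `n_obs`.
#' @export
shell_series <- function(frame_obs, shells, frame_time = 2) {
  bin <- shell_of(frame_obs$d, shells)
  ok <- !is.na(bin)
  fo <- frame_obs[ok, , drop = FALSE]
  bin <- bin[ok]
  grp <- interaction(bin, fo$frame, drop = TRUE)
  mi <- tapply(fo$I, grp, mean)
  nn <- tapply(fo$I, grp, length)
  ids <- do.call(rbind, strsplit(names(mi), "\\."))
  out <- data.frame(shell = as.integer(ids[, 1]),
                    frame = as.integer(ids[, 2]),
                    mean_I = as.numeric(mi), n_obs = as.integer(nn))
  out$t <- (out$frame + 0.5) * frame_time
  out$d_mid <- vapply(out$shell, function(s)
    ((0.5 / shells$edges[s]^3 + 0.5 / shells$edges[s + 1]^3))^(-1 / 3),
    numeric(1))
  out <- out[order(out$shell, out$frame), c("shell", "d_mid", "frame", "t",
                                            "mean_I", "n_obs")]
  rownames(out) <- NULL
  class(out) <- c("decay_series", "data.frame")
  out
}

#' Fit an exponential decay to a shell series
#'
#' Weighted log-linear least squares of `I(t) = I0 exp(-t / tau)` with
#' weights proportional to `n_obs * mean_I` (the approximate inverse
#' variance of a log-transformed Poisson-limited mean). The first time
#' point is excluded by default: it carries a shorter effective
#' integration time than the nominal frame. Non-positive means are
#' dropped; fewer than 3 usable points is a failure. A fitted decay slower
#' than the series span with a standard error spanning infinity is
#' reported as "no decay detected".
#'
#' @param series One shell of a [shell_series()] table (columns `t`,
#'   `mean_I`, `n_obs`).
#' @param exclude_first Drop the first time point.
#' @return Object of class `decay_fit`: `tau` (ms), `I0`, `stderr_tau`,
#'   `n_points`, `excluded_first`, `no_decay`.
#' @export
fit_decay <- function(series, exclude_first = TRUE) {
  s <- series[order(series$t), , drop = FALSE]
  if (exclude_first && nrow(s) > 1) s <- s[-1, , drop = FALSE]
  s <- s[is.finite(s$mean_I) & s$mean_I > 0, , drop = FALSE]
  if (nrow(s) < 3) stopf("fewer than 3 usable points for the decay fit")
  w <- s$n_obs * s$mean_I
  fit <- stats::lm(log(s$mean_I) ~ s$t, weights = w)
  slope <- unname(stats::coef(fit)[2])
  se_slope <- sqrt(diag(stats::vcov(fit)))[2]
  tau <- -1 / slope
  stderr_tau <- se_slope / slope^2
  span <- diff(range(s$t))
  no_decay <- !(slope < 0) || (tau > 100 * span) ||
    (is.finite(stderr_tau) && slope + 2 * se_slope >= 0)
  structure(list(tau = tau, I0 = exp(unname(stats::coef(fit)[1])),
                 stderr_tau = unname(stderr_tau),
                 n_points = nrow(s), excluded_first = exclude_first,
                 no_decay = no_decay),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$no_decay) cat("Decay fit: no decay detected\n")
  else cat(sprintf("Decay fit: tau = %.2f(%.0f) ms over %d points\n",
                   x$tau, 100 * x$stderr_tau, x$n_points))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(tau = object$tau, I0 = object$I0)
}

#' @export
predict.decay_fit <- function(object, t, ...) {
  object$I0 * exp(-t / object$tau)
}

#' @export
plot.decay_fit <- function(x, series = NULL, ...) {
  if (!is.null(series)) {
    graphics::plot(series$t, series$mean_I, log = "y", xlab = "delay time (ms)",
                   ylab = "mean intensity", ...)
    tt <- seq(min(series$t), max(series$t), length.out = 50)
    graphics::lines(tt, predict(x, tt), col = 2)
  }
  invisible(x)
}

#' Fit decay times for every shell of a series
#'
#' @param series A [shell_series()] table.
#' @param exclude_first Passed to [fit_decay()].
#' @return Data frame: `shell`, `d_mid`, `tau`, `stderr_tau`, `no_decay`.
#' @export
fit_all_shells <- function(series, exclude_first = TRUE) {
  out <- lapply(split(series, series$shell), function(s) {
    f <- tryCatch(fit_decay(s, exclude_first), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    data.frame(shell = s$shell[1], d_mid = s$d_mid[1], tau = f$tau,
               stderr_tau = f$stderr_tau, no_decay = f$no_decay)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Optimal cumulative-frame window
#'
#' Given merging statistics for each cumulative window `k = 1..n_frames`,
#' picks `k* = argmax` of the highest-resolution-shell CC1/2 (ties to the
#' smaller k): the a-posteriori dose optimum of dose fractionation. Also
#' reports the CC* > 0.5 resolution cutoff and the integrated dose per k.
#'
#' @param window_stats List of [shell_statistics()] tables, one per k.
#' @param beam Optional [beam_parameters()] for the dose column.
#' @param frame_time Frame exposure in ms.
#' @return List: `k_star`, `table` (k, cc_half_high, d_cut, dose).
#' @export
optimal_window <- function(window_stats, beam = NULL,
                           frame_time = if (!is.null(beam)) beam$frame_time else 2) {
  ks <- seq_along(window_stats)
  cc_high <- vapply(window_stats, function(st) {
    cc <- st$cc_half[nrow(st)]
    if (is.na(cc)) -Inf else cc
  }, numeric(1))
  d_cut <- vapply(window_stats, function(st) truncate_resolution(st)$d_cut,
                  numeric(1))
  dose <- if (!is.null(beam)) fluence(beam, ks * frame_time) else NA_real_
  k_star <- ks[which.max(cc_high)]   # which.max takes the first maximum
  list(k_star = k_star,
       table = data.frame(k = ks, cc_half_high = cc_high, d_cut = d_cut,
                          dose = dose))
}
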