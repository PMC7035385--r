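# ---- scaling, Monte-Carlo merging and serial-crystallography statistics

#' Iterative per-pattern linear scaling
#'
#' Alternating least squares: merge all observations, fit one linear scale
#' per pattern minimizing `sum w (I_obs - k_p * Ibar)^2`, rescale, re-merge.
#' Converges when the largest relative scale change drops below `tol` (or
#' after `max_iter` rounds); scales are normalized to mean 1. Patterns that
#' share no reflection with the rest keep unit scale and are flagged.
#'
#' @param obs Data frame with columns `pattern`, `h`, `k`, `l` (ASU-reduced),
#'   `I`, `sigma`.
#' @param tol Relative scale-change convergence threshold.
#' @param max_iter Iteration cap.
#' @return List: `obs` (scaled observations), `scales` (named per pattern),
#'   `n_iter`, `objective` (per-iteration weighted residual sum).
#' @export
scale_patterns <- function(obs, tol = 1e-4, max_iter = 30) {
  if (!nrow(obs)) stopf("no observations to scale")
  key <- paste(obs$h, obs$k, obs$l)
  pat <- factor(obs$pattern)
  w <- 1 / obs$sigma^2
  k_p <- stats::setNames(rep(1, nlevels(pat)), levels(pat))
  objective <- numeric(0)
  for (it in seq_len(max_iter)) {
    I_s <- obs$I / k_p[pat]
    w_s <- w * (as.numeric(k_p[pat]))^2
    ibar <- rowsum(I_s * w_s, key)[, 1] / rowsum(w_s, key)[, 1]
    ref <- ibar[key]
    num <- rowsum(w * obs$I * ref, pat)[, 1]
    den <- rowsum(w * ref^2, pat)[, 1]
    k_new <- ifelse(den > 0, num / den, 1)
    k_new <- k_new / mean(k_new)
    objective <- c(objective, sum(w * (obs$I - k_new[pat] * ref)^2))
    delta <- max(abs(k_new - k_p) / pmax(abs(k_p), 1e-12))
    k_p <- k_new
    if (delta < tol) break
  }
  shared <- tapply(key, pat, function(kk) length(unique(kk)))
  obs$I <- obs$I / k_p[pat]
  obs$sigma <- obs$sigma / k_p[pat]
  list(obs = obs, scales = k_p, n_iter = it, objective = objective)
}

#' Monte-Carlo merge of still observations
#'
#' Straight (unweighted) mean intensity per unique reflection — the
#' Monte-Carlo merging principle for still data, where the dominant
#' observation-to-observation scatter is partiality, not counting noise
#' (inverse-variance weighting would bias the mean toward weakly excited
#' observations) — with two half-set means from a seeded pseudo-random
#' even/odd split of each reflection's observations (the basis of CC1/2
#' and R_split). The split depends only on (reflection, pattern id, seed),
#' so re-merging the same patterns with, say, a different dose window
#' reproduces the same halves. Observations must already be ASU-reduced;
#' pass `sg` to have it done here. The merged sigma is the standard error
#' of the mean (empirical for n >= 2, propagated counting error for
#' singletons).
#'
#' @param obs Data frame with `h`, `k`, `l`, `I`, `sigma` (and `pattern`).
#' @param sg Optional [space_group()]; when given, indices are ASU-reduced.
#' @param cell Optional [unit_cell()] to attach d-spacings.
#' @param seed Seed of the half-set split.
#' @return Data frame of class `merged_set`: `h`, `k`, `l`, `d` (if cell
#'   given), `I`, `sigma`, `n_meas`, `I_half_a`, `I_half_b` (NA where a
#'   half is empty).
#' @export
merge_observations <- function(obs, sg = NULL, cell = NULL, seed = 42) {
  if (!is.null(sg)) {
    red <- asu_reduce(as.matrix(obs[, c("h", "k", "l")]), sg)
    obs$h <- red[, 1]; obs$k <- red[, 2]; obs$l <- red[, 3]
  }
  key <- paste(obs$h, obs$k, obs$l)
  # deterministic pseudo-random order within each reflection
  pat_id <- if (!is.null(obs$pattern)) as.integer(factor(obs$pattern))
            else seq_len(nrow(obs))
  u <- ((pat_id * 2654435761 + .hkl_key(as.matrix(obs[, c("h", "k", "l")])) *
           97 + seed * 13007) %% 1000003) / 1000003
  half <- integer(nrow(obs))
  ord <- order(key, u, obs$I)   # I breaks (pattern, hkl) duplicate ties
  half[ord] <- stats::ave(seq_along(ord), key[ord],
                          FUN = function(ii) seq_along(ii) %% 2)
  agg <- function(sel) {
    si <- rowsum(obs$I[sel], key[sel])
    sn <- rowsum(rep(1, sum(sel)), key[sel])
    stats::setNames(si[, 1] / sn[, 1], rownames(si))
  }
  all_mean <- agg(rep(TRUE, nrow(obs)))
  ka <- agg(half == 0); kb <- agg(half == 1)
  n_meas <- table(key)
  keys <- names(all_mean)
  nvec <- as.integer(n_meas[keys])
  # standard error of the mean: empirical scatter where possible
  ssq <- rowsum(obs$I^2, key)[, 1]
  emp_var <- (ssq[keys] - nvec * all_mean^2) / pmax(nvec - 1, 1)
  prop <- rowsum(obs$sigma^2, key)[, 1][keys] / nvec^2
  sig <- ifelse(nvec >= 2, sqrt(pmax(emp_var, 0) / nvec), sqrt(prop * nvec))
  hkl <- do.call(rbind, strsplit(keys, " "))
  out <- data.frame(h = as.integer(hkl[, 1]), k = as.integer(hkl[, 2]),
                    l = as.integer(hkl[, 3]),
                    I = as.numeric(all_mean),
                    sigma = as.numeric(pmax(sig, 1e-9)),
                    n_meas = nvec,
                    I_half_a = as.numeric(ka[keys]),
                    I_half_b = as.numeric(kb[keys]))
  if (!is.null(cell)) out$d <- as.numeric(d_spacing(as.matrix(out[, 1:3]), cell))
  rownames(out) <- NULL
  class(out) <- c("merged_set", "data.frame")
  out
}

#' @export
print.merged_set <- function(x, ...) {
  cat(sprintf("Merged set: %d unique reflections, multiplicity %.1f\n",
              nrow(x), mean(x$n_meas)))
  invisible(x)
}

#' R_split of two half sets
#'
#' `R_split = 2^(-1/2) * sum|I_A - I_B| / (0.5 * sum(I_A + I_B))`, in
#' percent, over reflections present in both halves. Scale-invariant.
#'
#' @param half_a,half_b Half-set mean intensities on common reflections, or
#'   a `merged_set` as the first argument.
#' @return Percent; `NA` for an empty intersection.
#' @export
rsplit <- function(half_a, half_b = NULL) {
  if (is.data.frame(half_a)) {
    ok <- !is.na(half_a$I_half_a) & !is.na(half_a$I_half_b)
    half_b <- half_a$I_half_b[ok]; half_a <- half_a$I_half_a[ok]
  }
  if (!length(half_a)) return(NA_real_)
  100 * (1 / sqrt(2)) * sum(abs(half_a - half_b)) / (0.5 * sum(half_a + half_b))
}

#' Half-set correlation CC1/2 and CC*
#'
#' CC1/2 is the Pearson correlation of the two half-set means; CC* =
#' `sqrt(2 CC1/2 / (1 + CC1/2))` estimates the correlation of the merged
#' data with the true intensities (0 when CC1/2 < 0). CC* = 0.5
#' corresponds to CC1/2 = 0.143, the conventional resolution cutoff.
#'
#' @inheritParams rsplit
#' @return List with `cc_half` and `cc_star`; `NA` below 3 common pairs.
#' @export
cc_half_and_star <- function(half_a, half_b = NULL) {
  if (is.data.frame(half_a)) {
    ok <- !is.na(half_a$I_half_a) & !is.na(half_a$I_half_b)
    half_b <- half_a$I_half_b[ok]; half_a <- half_a$I_half_a[ok]
  }
  if (length(half_a) < 3 || stats::sd(half_a) == 0 || stats::sd(half_b) == 0)
    return(list(cc_half = NA_real_, cc_star = NA_real_))
  cc <- stats::cor(half_a, half_b)
  list(cc_half = cc, cc_star = cc_star(cc))
}

#' @rdname cc_half_and_star
#' @param cc_half CC1/2 value(s).
#' @export
cc_star <- function(cc_half) {
  ifelse(cc_half < 0, 0, sqrt(2 * cc_half / (1 + cc_half)))
}

#' Completeness of a merged set
#'
#' Observed unique reflections as a fraction of the theoretical unique set
#' in the resolution range, in percent.
#'
#' @param merged A [merge_observations()] result.
#' @param cell,sg Cell and space group.
#' @param d_min,d_max Resolution range in Angstrom.
#' @return Percent.
#' @export
completeness <- function(merged, cell, sg, d_min, d_max = Inf) {
  theo <- enumerate_unique(cell, sg, d_min, d_max)
  if (theo$count == 0) return(NA_real_)
  d_obs <- as.numeric(d_spacing(as.matrix(merged[, c("h", "k", "l")]), cell))
  sel <- d_obs >= d_min & d_obs <= d_max
  obs_keys <- unique(paste(merged$h[sel], merged$k[sel], merged$l[sel]))
  theo_keys <- paste(theo$hkl[, 1], theo$hkl[, 2], theo$hkl[, 3])
  100 * sum(obs_keys %in% theo_keys) / theo$count
}

#' Wilson B-factor from merged intensities
#'
#' Linear regression of `ln <I>` in resolution bins against `1/(2 d^2)`
#' over the `d <= d_fit_max` region; the slope is `-B`. Expected-intensity
#' (epsilon) factors are ignored, a simplification worth < ~1 A^2 for the
#' supported groups.
#'
#' @param merged A `merged_set` with a `d` column (or supply `cell`).
#' @param cell Optional [unit_cell()] to compute `d`.
#' @param d_fit_max Low-resolution end of the fit range, Angstrom.
#' @param n_bins Number of equal reciprocal-volume bins.
#' @return Object of class `wilson_fit`: `B` (A^2), `scale`, `fit_range`,
#'   `bins`; `NA` B when fewer than 3 usable bins.
#' @export
wilson_fit <- function(merged, cell = NULL, d_fit_max = 4.5, n_bins = 20) {
  d <- merged$d
  if (is.null(d)) {
    if (is.null(cell)) stopf("need a d column or a cell")
    d <- as.numeric(d_spacing(as.matrix(merged[, c("h", "k", "l")]), cell))
  }
  sel <- d <= d_fit_max
  if (sum(sel) < 10)
    return(structure(list(B = NA_real_, scale = NA_real_, bins = NULL,
                          fit_range = c(NA, NA)), class = "wilson_fit"))
  d <- d[sel]; I <- merged$I[sel]
  shells <- make_shells(max(d), min(d), n_bins)
  bin <- shell_of(d, shells)
  mi <- tapply(I, bin, mean)
  dm <- tapply(d, bin, function(x) (mean(x^-3))^(-1 / 3))
  ok <- !is.na(mi) & mi > 0
  if (sum(ok) < 3)
    return(structure(list(B = NA_real_, scale = NA_real_, bins = NULL,
                          fit_range = c(NA, NA)), class = "wilson_fit"))
  x <- 1 / (2 * dm[ok]^2)
  fit <- stats::lm(log(mi[ok]) ~ x)
  structure(list(B = -unname(stats::coef(fit)[2]),
                 scale = exp(unname(stats::coef(fit)[1])),
                 fit_range = c(max(d), min(d)),
                 bins = data.frame(d = as.numeric(dm[ok]),
                                   mean_I = as.numeric(mi[ok]))),
            class = "wilson_fit")
}

#' @export
print.wilson_fit <- function(x, ...) {
  cat(sprintf("Wilson fit: B = %.2f A^2 over %.2f-%.2f A\n",
              x$B, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' @export
plot.wilson_fit <- function(x, ...) {
  graphics::plot(1 / (2 * x$bins$d^2), log(x$bins$mean_I),
                 xlab = expression(1 / (2 * d^2)), ylab = "ln <I>",
                 main = sprintf("Wilson plot (B = %.1f)", x$B), ...)
  graphics::abline(log(x$scale), -x$B, col = 2)
  invisible(x)
}

#' Per-shell merging statistics
#'
#' The serial-crystallography statistics block per resolution shell:
#' unique and possible reflections, completeness, multiplicity, mean
#' I/sigma(I), R_split, CC1/2 and CC*. Overall values are attached as
#' `attr(, "overall")`.
#'
#' @param merged A `merged_set` (with `d`, or supply `cell`).
#' @param cell,sg Cell and space group.
#' @param shells A [make_shells()] partition.
#' @return Data frame of class `shell_stats`, one row per shell from low to
#'   high resolution.
#' @export
shell_statistics <- function(merged, cell, sg, shells) {
  if (is.null(merged$d))
    merged$d <- as.numeric(d_spacing(as.matrix(merged[, c("h", "k", "l")]), cell))
  theo <- enumerate_unique(cell, sg, shells$edges[shells$n + 1],
                           shells$edges[1])
  theo_bin <- shell_of(theo$d, shells)
  poss <- tabulate(theo_bin, nbins = shells$n)
  bin <- shell_of(merged$d, shells)
  rows <- lapply(seq_len(shells$n), function(s) {
    m <- merged[!is.na(bin) & bin == s, , drop = FALSE]
    cc <- cc_half_and_star(m)
    data.frame(shell = s, d_max = shells$edges[s], d_min = shells$edges[s + 1],
               n_unique = nrow(m), n_possible = poss[s],
               completeness = if (poss[s] > 0) 100 * nrow(m) / poss[s] else NA_real_,
               multiplicity = if (nrow(m)) mean(m$n_meas) else NA_real_,
               mean_i_sigma = if (nrow(m)) mean(m$I / m$sigma) else NA_real_,
               rsplit = rsplit(m), cc_half = cc$cc_half, cc_star = cc$cc_star)
  })
  out <- do.call(rbind, rows)
  cc_all <- cc_half_and_star(merged)
  attr(out, "overall") <- data.frame(
    n_unique = nrow(merged),
    completeness = 100 * nrow(merged) / max(theo$count, 1),
    multiplicity = mean(merged$n_meas),
    mean_i_sigma = mean(merged$I / merged$sigma),
    rsplit = rsplit(merged), cc_half = cc_all$cc_half,
    cc_star = cc_all$cc_star)
  class(out) <- c("shell_stats", "data.frame")
  out
}

#' @export
plot.shell_stats <- function(x, ...) {
  graphics::plot(1 / x$d_min^2, x$cc_half, type = "b", ylim = c(0, 1),
                 xlab = expression(1 / d^2), ylab = expression(CC[1 / 2]), ...)
  graphics::abline(h = 0.143, lty = 2)
  invisible(x)
}

#' Resolution cutoff from CC*
#'
#' Scanning from low to high resolution, the data are truncated after the
#' last shell with CC* above the threshold: the cutoff is the inner
#' (high-resolution) edge of the last passing shell before the first
#' failure; later shells are excluded even if they fluctuate back above
#' the threshold.
#'
#' @param stats A [shell_statistics()] table.
#' @param cc_star_min CC* threshold (0.5 conventional).
#' @return List: `d_cut` (Angstrom), `n_shells_kept`, `flag` (`"ok"` or
#'   `"none_pass"`).
#' @export
truncate_resolution <- function(stats, cc_star_min = 0.5) {
  pass <- !is.na(stats$cc_star) & stats$cc_star > cc_star_min
  if (!any(pass))
    return(list(d_cut = stats$d_max[1], n_shells_kept = 0L, flag = "none_pass"))
  first_fail <- which(!pass)[1]
  last <- if (is.na(first_fail)) nrow(stats) else first_fail - 1L
  if (last == 0L)
    return(list(d_cut = stats$d_max[1], n_shells_kept = 0L, flag = "none_pass"))
  list(d_cut = stats$d_min[last], n_shells_kept = as.integer(last), flag = "ok")
}
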