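# ---- still-diffraction movie-stack simulation --------------------------

# Flat-Ewald excitation of a crystal in orientation R: reciprocal vectors
# g = R B h; excitation error zeta = 1/lambda - |g + k_in| with the beam
# along +z. Returns the reflections with |zeta| <= cut and their projected
# detector positions (0-based fractional pixels).
excited_reflections <- function(orientation, truth, geom, beam,
                                zeta_cut, center = geom$beam_center) {
  RB <- orientation %*% truth$cell$B
  G <- truth$refl$hkl %*% t(RB)
  kz <- 1 / beam$wavelength
  zeta <- kz - sqrt(G[, 1]^2 + G[, 2]^2 + (G[, 3] + kz)^2)
  sel <- abs(zeta) <= zeta_cut
  G <- G[sel, , drop = FALSE]
  denom <- G[, 3] + kz
  scale <- geom$camera_length * 1000 / geom$pixel_size
  fs <- center[1] + G[, 1] / denom * scale
  ss <- center[2] + G[, 2] / denom * scale
  on <- fs >= 0 & fs <= geom$n_fast - 1 & ss >= 0 & ss <= geom$n_slow - 1
  list(hkl = truth$refl$hkl[sel, , drop = FALSE][on, , drop = FALSE],
       fs = fs[on], ss = ss[on], zeta = zeta[sel][on],
       d = truth$refl$d[sel][on], F2 = truth$refl$F2[sel][on],
       tau = truth$refl$tau[sel][on])
}

# fraction of the initial intensity delivered in frame i (0-based) of
# length dt under exponential decay: exact within-frame integral,
# normalized so that tau = Inf gives 1 per frame.
frame_decay_factor <- function(i, dt, tau) {
  ifelse(is.infinite(tau), 1,
         tau / dt * (exp(-i * dt / tau) - exp(-(i + 1) * dt / tau)))
}

#' Detector defect maps
#'
#' Random dead-pixel mask and flat-field gain map (mean 1) used both to
#' corrupt simulated data and, on the processing side, to correct it.
#'
#' @param geom A [detector_geometry()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Object of class `correction_maps` with `dead_mask` (TRUE = dead)
#'   and `flat_field`.
#' @export
detector_defects <- function(geom, config = sim_config(), seed = 1) {
  set.seed(seed)
  n <- geom$n_fast * geom$n_slow
  dead <- matrix(stats::runif(n) < config$dead_pixel_fraction,
                 geom$n_fast, geom$n_slow)
  gain <- matrix(exp(stats::rnorm(n, 0, config$flat_field_rms)),
                 geom$n_fast, geom$n_slow)
  gain <- gain / mean(gain)
  structure(list(dead_mask = dead, flat_field = gain),
            class = "correction_maps")
}

#' Simulate one dose-fractionated diffraction movie stack
#'
#' Places every sufficiently excited reflection at its flat-Ewald projected
#' detector position with expected counts
#' `intensity_scale * |F|^2 * exp(-zeta^2 / (2 sigma^2)) * decay(frame, d)`,
#' adds diffuse background and the transmitted-beam disk, applies the
#' flat-field gain, draws Poisson counts per pixel per frame, and zeroes
#' dead pixels. All frames share one orientation (no rotation during the
#' exposure); the first frame is attenuated by `first_frame_factor`.
#'
#' @param orientation 3x3 rotation matrix (lab from crystal).
#' @param truth A [make_ground_truth()].
#' @param geom,beam Detector and beam descriptions.
#' @param config A [sim_config()].
#' @param maps Optional [detector_defects()]; `NULL` for a clean detector.
#' @param seed Integer seed.
#' @param center True beam center for this stack (fractional pixels);
#'   default jitters the nominal center by `config$center_jitter`.
#' @param thickness Crystal thickness factor scaling all spot intensities.
#' @return Object of class `movie_stack`: integer count frames plus
#'   metadata (`true_center`, `orientation`, `frame_time`, dose per frame).
#' @export
simulate_pattern_stack <- function(orientation, truth, geom, beam,
                                   config = sim_config(), maps = NULL,
                                   seed = 1, center = NULL, thickness = 1) {
  set.seed(seed)
  if (is.null(center))
    center <- geom$beam_center + stats::rnorm(2, 0, config$center_jitter)
  exc <- excited_reflections(orientation, truth, geom, beam,
                             config$zeta_cut * config$rocking_sigma, center)
  partiality <- exp(-exc$zeta^2 / (2 * config$rocking_sigma^2))
  base <- config$intensity_scale * exc$F2 * partiality * thickness *
    (beam$frame_time / 2)
  n_spots <- length(base)
  sig <- rep(config$spot_sigma, n_spots)
  frames <- vector("list", config$n_frames)
  for (i in seq_len(config$n_frames) - 1L) {
    fac <- frame_decay_factor(i, beam$frame_time, exc$tau)
    if (i == 0L) fac <- fac * config$first_frame_factor
    expected <- cpp_render_spots(geom$n_fast, geom$n_slow, exc$fs, exc$ss,
                                 base * fac, sig, sig, numeric(n_spots),
                                 config$spot_trunc)
    expected <- expected +
      cpp_render_spots(geom$n_fast, geom$n_slow, center[1], center[2],
                       config$beam_counts, config$beam_sigma,
                       config$beam_sigma, 0, 5) +
      config$background_level
    if (!is.null(maps)) expected <- expected * maps$flat_field
    fr <- matrix(stats::rpois(length(expected), expected),
                 geom$n_fast, geom$n_slow)
    if (!is.null(maps)) fr[maps$dead_mask] <- 0L
    frames[[i + 1L]] <- fr
  }
  structure(list(frames = frames, frame_time = beam$frame_time,
                 true_center = center, orientation = orientation,
                 n_spots = n_spots,
                 dose_per_frame = fluence(beam, beam$frame_time),
                 corrected = FALSE),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  cat(sprintf("Movie stack: %d frames of %g ms, %d simulated spots%s\n",
              length(x$frames), x$frame_time, x$n_spots %||% NA_integer_,
              if (isTRUE(x$corrected)) " (corrected)" else ""))
  invisible(x)
}

#' Simulate a full serial-diffraction dataset
#'
#' Ground truth, STEM overview map, detector defect maps and per-crystal
#' movie stacks, all derived from one master seed. Per-crystal seeds come
#' from a counter-based stream, so any subset of stacks can be regenerated
#' reproducibly with [crystal_stack()] without materializing the rest.
#'
#' @param n_crystals Number of crystals.
#' @param geom,beam Detector and beam descriptions.
#' @param config A [sim_config()].
#' @param cell,sg Cell and space group of the ground truth.
#' @param decay A [decay_model()] or `NULL` for no damage.
#' @param wilson_b Wilson B-factor.
#' @param seed Master seed.
#' @param keep_frames If `TRUE`, stacks are materialized in `$stacks`;
#'   otherwise regenerate them on demand with [crystal_stack()] (preferred
#'   for large datasets).
#' @return Object of class `serialed_dataset`.
#' @export
simulate_dataset <- function(n_crystals, geom = detector_geometry(),
                             beam = beam_parameters(), config = sim_config(),
                             cell = unit_cell(103.2, 103.2, 103.2),
                             sg = space_group("I23"), decay = decay_model(),
                             wilson_b = 12.3, seed = 1, keep_frames = TRUE) {
  if (n_crystals < 1) stopf("n_crystals must be >= 1")
  truth <- make_ground_truth(n_crystals, cell, sg, config, decay, wilson_b, seed)
  maps <- detector_defects(geom, config, derive_seed(seed, 2))
  map <- simulate_stem_map(truth, config)
  ds <- structure(list(truth = truth, geom = geom, beam = beam,
                       config = config, maps = maps, map = map,
                       n_crystals = n_crystals, seed = seed, stacks = NULL),
                  class = "serialed_dataset")
  if (keep_frames)
    ds$stacks <- lapply(seq_len(n_crystals), function(i) crystal_stack(ds, i))
  ds
}

#' Regenerate (or fetch) the movie stack of one crystal
#'
#' @param ds A [simulate_dataset()] object.
#' @param i Crystal index (1-based).
#' @return A `movie_stack`.
#' @export
crystal_stack <- function(ds, i) {
  if (!is.null(ds$stacks)) return(ds$stacks[[i]])
  simulate_pattern_stack(ds$truth$orientations[[i]], ds$truth, ds$geom,
                         ds$beam, ds$config, ds$maps,
                         seed = derive_seed(ds$seed, 100 + i),
                         thickness = ds$truth$thickness[i])
}

#' @export
print.serialed_dataset <- function(x, ...) {
  cat(sprintf("SerialED dataset: %d crystals, %s, seed %s (%s)\n",
              x$n_crystals, x$truth$sg$symbol, format(x$seed),
              if (is.null(x$stacks)) "stacks on demand" else "stacks in memory"))
  invisible(x)
}
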