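#' Relativistic electron wavelength
#'
#' Computes the de Broglie wavelength of an electron accelerated through a
#' potential, with the relativistic correction. At 200 kV this gives
#' 0.0251 Angstrom, the regime in which the Ewald sphere is nearly flat and
#' still diffraction patterns sample almost-planar slices of reciprocal space.
#'
#' @param voltage Acceleration voltage in volts (scalar or vector, > 0).
#' @return Wavelength in Angstrom.
#' @examples
#' electron_wavelength(200e3)  # ~0.0251
#' @export
electron_wavelength <- function(voltage) {
  if (any(!is.finite(voltage)) || any(voltage <= 0))
    stopf("voltage must be positive and finite")
  lambda_m <- .h_planck / sqrt(2 * .m_electron * .e_charge * voltage *
                                 (1 + .e_charge * voltage / (2 * .m_electron * .c_light^2)))
  lambda_m * 1e10
}

#' Electron beam description
#'
#' Bundles the electron-optical parameters shared by the simulator and the
#' processing chain. The wavelength is derived from the voltage.
#'
#' @param voltage Acceleration voltage in volts. Default 200 kV.
#' @param beam_diameter Beam diameter on the specimen in nm. Default 110.
#' @param beam_current Beam current in nA. Default 0.1.
#' @param frame_time Exposure time of one movie frame in ms. Default 2.
#' @return Object of class `beam_parameters`.
#' @export
beam_parameters <- function(voltage = 200e3, beam_diameter = 110,
                            beam_current = 0.1, frame_time = 2) {
  if (beam_diameter <= 0) stopf("beam_diameter must be positive")
  structure(list(voltage = voltage,
                 wavelength = electron_wavelength(voltage),
                 beam_diameter = beam_diameter,
                 beam_current = beam_current,
                 frame_time = frame_time),
            class = "beam_parameters")
}

#' @export
print.beam_parameters <- function(x, ...) {
  cat(sprintf("Electron beam: %.0f kV (lambda = %.4f A), %g nm, %g nA, %g ms/frame\n",
              x$voltage / 1e3, x$wavelength, x$beam_diameter, x$beam_current,
              x$frame_time))
  invisible(x)
}

#' Flat-panel detector geometry
#'
#' Single flat panel normal to the beam. Pixel coordinates are 0-based in
#' (fast, slow) order with the origin at the center of pixel (0,0);
#' sub-pixel positions are real-valued.
#'
#' @param n_fast,n_slow Panel size in pixels.
#' @param pixel_size Pixel pitch in micrometres.
#' @param camera_length Sample-to-detector distance in mm.
#' @param beam_center Nominal beam center, fractional pixels (fast, slow).
#' @return Object of class `detector_geometry`.
#' @export
detector_geometry <- function(n_fast = 1024, n_slow = 1024, pixel_size = 55,
                              camera_length = 1740,
                              beam_center = c((n_fast - 1) / 2, (n_slow - 1) / 2)) {
  if (n_fast <= 0 || n_slow <= 0) stopf("panel dimensions must be positive")
  if (camera_length <= 0) stopf("camera_length must be positive")
  if (beam_center[1] < 0 || beam_center[1] > n_fast - 1 ||
      beam_center[2] < 0 || beam_center[2] > n_slow - 1)
    stopf("beam_center outside panel bounds")
  structure(list(n_fast = as.integer(n_fast), n_slow = as.integer(n_slow),
                 pixel_size = pixel_size, camera_length = camera_length,
                 beam_center = as.numeric(beam_center)),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf("Detector: %d x %d px, %g um pixels, L = %g mm, center (%.2f, %.2f)\n",
              x$n_fast, x$n_slow, x$pixel_size, x$camera_length,
              x$beam_center[1], x$beam_center[2]))
  invisible(x)
}

#' Resolution at a detector pixel
#'
#' Small-angle flat-detector geometry: the radial distance r from the beam
#' center subtends a scattering angle 2theta = atan(r * pixel / L), and
#' d = lambda / (2 sin theta). The beam-center pixel maps to d = Inf.
#'
#' @param px Numeric vector `c(fast, slow)` or an n x 2 matrix of positions.
#' @param geom A [detector_geometry()].
#' @param beam A [beam_parameters()].
#' @return d-spacing(s) in Angstrom.
#' @export
pixel_to_resolution <- function(px, geom, beam) {
  px <- rbind(px)
  r <- sqrt((px[, 1] - geom$beam_center[1])^2 + (px[, 2] - geom$beam_center[2])^2)
  unname(radius_to_resolution(r, geom, beam))
}

#' @rdname pixel_to_resolution
#' @param r Radial distance from the beam center in pixels.
#' @export
radius_to_resolution <- function(r, geom, beam) {
  two_theta <- atan(r * geom$pixel_size / (geom$camera_length * 1000))
  d <- beam$wavelength / (2 * sin(two_theta / 2))
  d[r == 0] <- Inf
  d
}

#' @rdname pixel_to_resolution
#' @param d d-spacing in Angstrom.
#' @return `resolution_to_radius`: radius in pixels from the beam center.
#' @export
resolution_to_radius <- function(d, geom, beam) {
  theta <- asin(beam$wavelength / (2 * d))
  tan(2 * theta) * geom$camera_length * 1000 / geom$pixel_size
}

#' Integrated fluence (dose) of an exposure
#'
#' Number of electrons delivered per unit specimen area:
#' `(current * exposure / e) / (pi * (diameter/2)^2)`.
#'
#' @param beam A [beam_parameters()].
#' @param exposure Exposure time in ms (>= 0). Defaults to one frame.
#' @return Dose in electrons per square Angstrom.
#' @examples
#' fluence(beam_parameters(), 2)   # ~1.31 e-/A^2 at 0.1 nA, 110 nm
#' @export
fluence <- function(beam, exposure = beam$frame_time) {
  if (any(exposure < 0)) stopf("exposure must be non-negative")
  n_e <- beam$beam_current * 1e-9 * exposure * 1e-3 / .e_charge
  area_A2 <- pi * (beam$beam_diameter * 10 / 2)^2
  n_e / area_A2
}

#' Resolution shells
#'
#' Partition a resolution range into shells. The default
#' `"volume"` rule gives equal reciprocal-volume shells (equal increments of
#' 1/d^3), the convention used for per-shell merging statistics; `"count"`
#' places edges so that a supplied set of d-spacings splits evenly.
#'
#' @param d_max,d_min Low/high resolution limits in Angstrom (`d_max > d_min`).
#' @param n Number of shells.
#' @param rule `"volume"` or `"count"`.
#' @param d Observed d-spacings, required for `rule = "count"`.
#' @return Object of class `resolution_shells` with an `edges` vector of
#'   length `n + 1`, strictly decreasing from `d_max` to `d_min`.
#' @export
make_shells <- function(d_max, d_min, n, rule = c("volume", "count"), d = NULL) {
  rule <- match.arg(rule)
  if (!(d_max > d_min) || d_min <= 0) stopf("require d_max > d_min > 0")
  if (n < 1) stopf("n must be >= 1")
  if (rule == "volume") {
    v <- seq(1 / d_max^3, 1 / d_min^3, length.out = n + 1)
    edges <- v^(-1 / 3)
  } else {
    if (is.null(d)) stopf("rule = 'count' needs observed d values")
    d <- d[d >= d_min & d <= d_max]
    q <- stats::quantile(1 / d^3, probs = seq(0, 1, length.out = n + 1), names = FALSE)
    q[1] <- 1 / d_max^3; q[n + 1] <- 1 / d_min^3
    edges <- q^(-1 / 3)
  }
  edges[1] <- d_max; edges[n + 1] <- d_min
  structure(list(n = as.integer(n), edges = edges, rule = rule),
            class = "resolution_shells")
}

#' @export
print.resolution_shells <- function(x, ...) {
  cat(sprintf("%d resolution shells (%s rule), %.2f - %.2f A\n", x$n, x$rule,
              x$edges[1], x$edges[x$n + 1]))
  invisible(x)
}

#' Map d-spacings to shell indices
#'
#' Shell 1 is the lowest-resolution (largest d) shell. Interior boundaries
#' belong to the higher-resolution shell; both outer edges are inclusive, so
#' every d in `[d_min, d_max]` maps to exactly one shell.
#'
#' @param d d-spacings in Angstrom.
#' @param shells A [make_shells()] object.
#' @return Integer shell index, `NA` outside the range.
#' @export
shell_of <- function(d, shells) {
  e <- shells$edges
  idx <- findInterval(-d, -e, rightmost.closed = TRUE)
  idx[d > e[1] | d < e[length(e)]] <- NA_integer_
  idx[idx == 0L] <- NA_integer_
  idx
}

#' Read beam and detector geometry from a key-value config file
#'
#' Keys: voltage_kv, camera_length_mm, pixel_size_um, n_fast, n_slow,
#' beam_center_fast, beam_center_slow, beam_diameter_nm, beam_current_na,
#' frame_time_ms.
#'
#' @param path Config file path.
#' @return List with elements `beam` and `geom`.
#' @export
read_beam_geometry <- function(path) {
  cfg <- read_config(path)
  need <- c("voltage_kv", "camera_length_mm", "pixel_size_um", "n_fast",
            "n_slow", "beam_center_fast", "beam_center_slow",
            "beam_diameter_nm", "beam_current_na", "frame_time_ms")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stopf("geometry config missing keys: %s", paste(miss, collapse = ", "))
  list(beam = beam_parameters(voltage = cfg$voltage_kv * 1e3,
                              beam_diameter = cfg$beam_diameter_nm,
                              beam_current = cfg$beam_current_na,
                              frame_time = cfg$frame_time_ms),
       geom = detector_geometry(n_fast = cfg$n_fast, n_slow = cfg$n_slow,
                                pixel_size = cfg$pixel_size_um,
                                camera_length = cfg$camera_length_mm,
                                beam_center = c(cfg$beam_center_fast,
                                                cfg$beam_center_slow)))
}
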