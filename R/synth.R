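# ---- simulation configuration and ground truth -------------------------

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults reproduce the study
#' conditions of the experiment being emulated: 10-frame dose-fractionation
#' stacks of 2 ms frames, a 1024 x 1024 pixel STEM overview of an
#' (18 um)^2 field, and exponential per-shell intensity decay. Detector
#' noise terms (background, dead pixels, flat field) and spot shape are
#' free parameters of the generator, documented here, not claims about any
#' particular instrument.
#'
#' @param n_frames Frames per dose-fractionation stack.
#' @param frame_time Frame exposure in ms.
#' @param rocking_sigma Gaussian excitation-error (partiality) width in
#'   reciprocal Angstrom, combining mosaicity and beam divergence.
#' @param zeta_cut Excitation-error cutoff for simulated spots, in units of
#'   `rocking_sigma`.
#' @param background_level Mean diffuse background, counts/pixel/frame.
#' @param dead_pixel_fraction Fraction of dead pixels.
#' @param flat_field_rms RMS of the multiplicative flat-field (gain) map.
#' @param spot_sigma Detector point-spread of a Bragg spot, pixels.
#' @param spot_trunc Gaussian truncation radius in sigmas.
#' @param intensity_scale Expected counts per frame for a fully excited
#'   reflection of unit |F|^2.
#' @param beam_counts Transmitted-beam counts per frame.
#' @param beam_sigma Transmitted-beam disk width, pixels.
#' @param first_frame_factor Attenuation of frame 0 (residual beam motion
#'   emulation); set 1 to disable.
#' @param center_jitter Per-crystal beam-center scatter, pixels (sd).
#' @param sim_d_min High-resolution limit of simulated reflections, Angstrom.
#' @param map_size STEM overview size, pixels.
#' @param map_field STEM overview field of view, micrometres.
#' @param map_background Mean STEM background, counts/pixel.
#' @param map_feature_counts Integrated counts of a unit-thickness crystal
#'   feature in the overview image.
#' @param zone_axis_fraction Fraction of crystals with a low-index zone axis
#'   along the beam (preferred-orientation emulation).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_frames = 10, frame_time = 2,
                       rocking_sigma = 0.0015, zeta_cut = 3,
                       background_level = 0.2, dead_pixel_fraction = 0.002,
                       flat_field_rms = 0.05, spot_sigma = 1, spot_trunc = 4,
                       intensity_scale = 2000, beam_counts = 3e4,
                       beam_sigma = 2, first_frame_factor = 0.7,
                       center_jitter = 1.0, sim_d_min = 1.55,
                       map_size = 1024, map_field = 18,
                       map_background = 50, map_feature_counts = 5000,
                       zone_axis_fraction = 0) {
  cfg <- as.list(environment())
  if (cfg$n_frames < 1) stopf("n_frames must be >= 1")
  num <- vapply(cfg, is.numeric, logical(1))
  if (any(unlist(cfg[num]) < 0)) stopf("sim_config values must be non-negative")
  class(cfg) <- "sim_config"
  cfg
}

#' Per-shell exponential damage model
#'
#' Step model of the 1/e intensity decay time versus resolution: five shells
#' whose edges are the 1/d^3 midpoints between the anchor resolutions
#' 5.00, 2.33, 1.96, 1.75 and 1.61 Angstrom, with decay times 14.9, 6.8,
#' 5.9, 5.2 and 5.0 ms. d-spacings outside the range are clamped to the
#' nearest shell.
#'
#' @param edges Shell edges in Angstrom, strictly decreasing.
#' @param tau Decay times in ms, one per shell (`length(edges) - 1`).
#' @return Object of class `decay_model`.
#' @export
decay_model <- function(edges = c(72.97, 2.84, 2.11, 1.84, 1.68, 1.55),
                        tau = c(14.9, 6.8, 5.9, 5.2, 5.0)) {
  if (length(tau) != length(edges) - 1) stopf("need one tau per shell")
  if (any(tau <= 0)) stopf("decay times must be positive")
  if (any(diff(edges) >= 0)) stopf("edges must be strictly decreasing")
  structure(list(edges = edges, tau = tau), class = "decay_model")
}

# tau as a function of d (clamped step lookup); Inf tau = no decay
decay_tau <- function(d, decay) {
  if (is.null(decay)) return(rep(Inf, length(d)))
  e <- decay$edges
  d2 <- pmin(pmax(d, e[length(e)]), e[1])
  idx <- findInterval(-d2, -e, rightmost.closed = TRUE)
  decay$tau[idx]
}

#' Ground-truth structure-factor magnitudes with Wilson statistics
#'
#' Draws |F|^2 for every unique allowed reflection from an exponential
#' distribution whose mean follows the Wilson falloff
#' `exp(-wilson_b / (2 d^2))`, so a Wilson-plot regression on the generated
#' set recovers `wilson_b`. Deterministic given the seed.
#'
#' @param cell A [unit_cell()].
#' @param sg A [space_group()].
#' @param d_min High-resolution limit in Angstrom.
#' @param wilson_b Wilson B-factor in square Angstrom.
#' @param seed Integer seed.
#' @return Data frame with columns h, k, l, d, F (magnitudes, arbitrary units).
#' @export
make_structure_factors <- function(cell, sg, d_min, wilson_b = 12.3, seed = 1) {
  uni <- enumerate_unique(cell, sg, d_min)
  set.seed(seed)
  mean_f2 <- exp(-wilson_b / (2 * uni$d^2))
  f2 <- stats::rexp(uni$count, rate = 1) * mean_f2
  data.frame(h = uni$hkl[, 1], k = uni$hkl[, 2], l = uni$hkl[, 3],
             d = uni$d, F = sqrt(f2))
}

# integer key for fast hkl lookup (|index| < 512)
.hkl_key <- function(hkl) {
  (hkl[, 1] + 512) * 1048576 + (hkl[, 2] + 512) * 1024 + (hkl[, 3] + 512)
}

# Expand the unique structure-factor table to every allowed lattice point
# (all symmetry and Friedel mates) with F^2, d and decay tau attached.
.full_reflection_table <- function(cell, sg, sf, decay, d_min) {
  hmax <- floor(cell$a / d_min); kmax <- floor(cell$b / d_min)
  lmax <- floor(cell$c / d_min)
  grid <- as.matrix(expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax))
  g <- grid %*% t(cell$B)
  s2 <- rowSums(g^2)
  keep <- s2 > 0 & s2 <= 1 / d_min^2 & !is_systematically_absent(grid, sg)
  grid <- grid[keep, , drop = FALSE]
  d <- 1 / sqrt(s2[keep])
  can <- asu_reduce(grid, sg)
  idx <- match(.hkl_key(can), .hkl_key(as.matrix(sf[, c("h", "k", "l")])))
  ok <- !is.na(idx)
  grid <- grid[ok, , drop = FALSE]; d <- d[ok]; idx <- idx[ok]
  list(hkl = grid, d = d, F2 = sf$F[idx]^2, tau = decay_tau(d, decay))
}

#' Assemble the ground truth of a synthetic experiment
#'
#' Generates structure factors, crystal positions in the map field, crystal
#' orientations (uniform on SO(3), optionally with a zone-axis-aligned
#' subset), per-crystal thickness factors and the damage model. Everything
#' downstream (map image, diffraction stacks) is derived deterministically
#' from this object.
#'
#' @param n_crystals Number of crystals.
#' @param cell A [unit_cell()]. Default: cubic, a = 103.2 Angstrom.
#' @param sg A [space_group()]. Default I23.
#' @param config A [sim_config()].
#' @param decay A [decay_model()] or `NULL` for no damage.
#' @param wilson_b Wilson B-factor for the structure factors.
#' @param seed Master seed; per-crystal streams are derived from it.
#' @return Object of class `ground_truth`.
#' @export
make_ground_truth <- function(n_crystals,
                              cell = unit_cell(103.2, 103.2, 103.2),
                              sg = space_group("I23"),
                              config = sim_config(),
                              decay = decay_model(),
                              wilson_b = 12.3, seed = 1) {
  sf <- make_structure_factors(cell, sg, config$sim_d_min, wilson_b, seed)
  set.seed(derive_seed(seed, 0))
  margin <- 0.05 * config$map_field
  positions <- cbind(x = stats::runif(n_crystals, margin, config$map_field - margin),
                     y = stats::runif(n_crystals, margin, config$map_field - margin))
  orientations <- random_rotations(n_crystals)
  n_zone <- round(config$zone_axis_fraction * n_crystals)
  if (n_zone > 0) {
    for (i in seq_len(n_zone)) {
      phi <- stats::runif(1, 0, 2 * pi)  # beam along a low-index zone axis
      orientations[[i]] <- rotvec_to_matrix(c(0, 0, phi))
    }
  }
  thickness <- exp(stats::rnorm(n_crystals, 0, 0.3))
  structure(list(cell = cell, sg = sg, sf = sf, wilson_b = wilson_b,
                 decay = decay, positions = positions,
                 orientations = orientations, thickness = thickness,
                 seed = seed,
                 refl = .full_reflection_table(cell, sg, sf, decay,
                                               config$sim_d_min)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d crystals, %s, %d unique |F|, B = %g A^2\n",
              nrow(x$positions), x$sg$symbol, nrow(x$sf), x$wilson_b))
  invisible(x)
}

#' Counter-based derived seed stream
#'
#' Deterministic per-crystal (or per-purpose) seeds derived from one master
#' seed, so any subset of a simulated dataset can be regenerated in
#' isolation. Kept below 2^31.
#'
#' @param master Master seed.
#' @param counter Stream counter (crystal index, stage id, ...).
#' @return Integer-valued seed.
#' @export
derive_seed <- function(master, counter) {
  (as.numeric(master) * 48271 + as.numeric(counter) * 7919) %% 2147483629
}
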