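# ---- STEM overview image simulation ------------------------------------

#' Simulate a STEM overview map with planted crystals
#'
#' Renders one compact bright feature per crystal — an anisotropic 2-D
#' Gaussian of 100-300 nm extent — on a Poisson background, emulating the
#' low-dose STEM mapping image in which crystals appear as bright features.
#' Feature integrated intensity is proportional to the crystal thickness
#' factor. Returns the ground-truth centroids (pixels) for recovery scoring.
#'
#' @param truth A [make_ground_truth()] object.
#' @param config A [sim_config()].
#' @param seed Seed; defaults to a stream derived from the truth's seed.
#' @return List with `image` (map_size x map_size counts, indexed (x, y)),
#'   `positions_px` (n x 2 true centroids, 0-based pixels) and `scale_px_um`.
#' @export
simulate_stem_map <- function(truth, config = sim_config(),
                              seed = derive_seed(truth$seed, 1)) {
  set.seed(seed)
  n <- nrow(truth$positions)
  sz <- config$map_size
  px_per_um <- sz / config$map_field
  pos_px <- truth$positions * px_per_um
  if (n > 0) {
    sx <- stats::runif(n, 1.5, 4.5)    # 100-300 nm at ~17.6 nm/px
    sy <- stats::runif(n, 1.5, 4.5)
    th <- stats::runif(n, 0, pi)
    amp <- config$map_feature_counts * truth$thickness
    expected <- cpp_render_spots(sz, sz, pos_px[, 1], pos_px[, 2],
                                 amp, sx, sy, th, 4)
  } else {
    expected <- matrix(0, sz, sz)
  }
  expected <- expected + config$map_background
  img <- matrix(stats::rpois(sz * sz, expected), sz, sz)
  list(image = img, positions_px = pos_px, scale_px_um = px_per_um)
}
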