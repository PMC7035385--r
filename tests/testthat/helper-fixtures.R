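# Shared fixtures, built lazily so single-file test runs stay fast.
.fix <- new.env(parent = emptyenv())

# granulovirus-like study conditions (default cell/geometry), no damage
default_truth <- function() {
  if (is.null(.fix$default)) {
    cfg <- sim_config()
    .fix$default <- list(
      cell = unit_cell(103.2, 103.2, 103.2), sg = space_group("I23"),
      geom = detector_geometry(), beam = beam_parameters(), cfg = cfg,
      truth = make_ground_truth(8, config = cfg, decay = NULL, seed = 401),
      maps = detector_defects(detector_geometry(), cfg,
                              seed = derive_seed(401, 2)))
  }
  .fix$default
}

# small cubic cell on a small panel: cheap patterns for plumbing tests
tiny_setup <- function(n = 4, seed = 501, decay = NULL) {
  cell <- unit_cell(20, 20, 20)
  sg <- space_group("I23")
  geom <- detector_geometry(512, 512, 55, 870)
  beam <- beam_parameters()
  cfg <- sim_config(sim_d_min = 2.0)
  truth <- make_ground_truth(n, cell = cell, sg = sg, config = cfg,
                             decay = decay, seed = seed)
  list(cell = cell, sg = sg, geom = geom, beam = beam, cfg = cfg,
       truth = truth,
       maps = detector_defects(geom, cfg, seed = derive_seed(seed, 2)))
}

sim_stack_i <- function(s, i, seed_offset = 100) {
  simulate_pattern_stack(s$truth$orientations[[i]], s$truth, s$geom, s$beam,
                         s$cfg, s$maps,
                         seed = derive_seed(s$truth$seed, seed_offset + i),
                         thickness = s$truth$thickness[i])
}

# processed pattern (corrections, sum, center, peaks) for one crystal
processed_pattern <- function(s, i) {
  st <- sim_stack_i(s, i)
  stc <- apply_corrections(st, s$maps)
  img <- sum_frames(stc, min(5, length(stc$frames)))
  ctr <- find_center(img, s$geom, s$beam, mask = stc$valid_mask)
  peaks <- find_peaks(img, ctr$center, s$geom, s$beam, mask = stc$valid_mask)
  list(stack = st, corrected = stc, img = img, ctr = ctr, peaks = peaks)
}
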