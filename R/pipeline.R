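# ---- end-to-end processing driver --------------------------------------

#' Pipeline parameter block
#'
#' Collects the tunable parameters of the processing chain with the package
#' defaults; any element can be overridden.
#'
#' @param ... Name-value overrides of the defaults.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(sum_k = 5, min_spots = 25, d_filter = 2.5, snr_min = 6,
            min_pix = 2, max_pix = 200, r_exclude = 12, grid_step = 1.5,
            match_tol = 2, min_matched = 10, zeta_max = 0.0045,
            zeta_sigma = 0.0015, d_min = 1.55, box_radius = 3,
            annulus = c(5, 8), friedel_dmin = 4, search_radius = 20,
            merge_seed = 42)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stopf("unknown parameters: %s", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  p
}

#' Process one movie stack through the still pipeline
#'
#' Corrections, cumulative frame sum, beam-center refinement, peak finding,
#' hit filtering, indexing, and integration of the predicted reflections on
#' the summed window (plus, optionally, each single frame for damage
#' analysis). ASU reduction is applied to the observation indices.
#'
#' @param stack A `movie_stack`.
#' @param maps [detector_defects()] correction maps (or `NULL`).
#' @param geom,beam,cell,sg Experiment description.
#' @param params A [pipeline_params()] list.
#' @param pattern_id Identifier stored with the observations.
#' @param per_frame Also integrate every single frame (for decay series).
#' @param orientation Optional known orientation; skips indexing (used to
#'   isolate downstream stages from indexing in validation runs).
#' @return List: `center`, `peaks`, `hit`, `solution`, `obs` (window
#'   observations), `frame_obs` (per-frame observations or `NULL`).
#' @export
process_stack <- function(stack, maps, geom, beam, cell, sg,
                          params = pipeline_params(), pattern_id = "pattern",
                          per_frame = FALSE, orientation = NULL) {
  if (!is.null(maps)) stack <- apply_corrections(stack, maps)
  mask <- stack$valid_mask
  img <- sum_frames(stack, min(params$sum_k, length(stack$frames)))
  pk_par <- list(snr_min = params$snr_min, min_pix = params$min_pix,
                 max_pix = params$max_pix, r_exclude = params$r_exclude)
  ctr <- find_center(img, geom, beam, search_radius = params$search_radius,
                     friedel_dmin = params$friedel_dmin, mask = mask,
                     peak_params = pk_par)
  # reuse the peaks found during centering (stage-1 center differs from the
  # refined one by well under a pixel)
  peaks <- ctr$peaks
  if (is.null(peaks))
    peaks <- do.call(find_peaks, c(list(img, ctr$center, geom, beam,
                                        mask = mask), pk_par))
  hit <- nrow(peaks) > 0 && hit_filter(peaks, params$min_spots, params$d_filter)
  sol <- NULL
  if (!is.null(orientation)) {
    sol <- list(success = TRUE, orientation = orientation)
  } else if (hit) {
    sol <- index_pattern(peaks, cell, sg, beam, geom, center = ctr$center,
                         grid_step = params$grid_step,
                         match_tol = params$match_tol,
                         min_matched = params$min_matched,
                         zeta_max = params$zeta_max,
                         zeta_sigma = params$zeta_sigma, d_min = params$d_min)
  }
  obs <- frame_obs <- NULL
  if (!is.null(sol) && isTRUE(sol$success)) {
    pred <- predict_spots(sol$orientation, cell, sg, beam, geom,
                          zeta_max = params$zeta_max, d_min = params$d_min,
                          center = ctr$center)
    ov <- spot_overlap(pred, params$box_radius)
    obs <- integrate_spots(img, pred, params$box_radius, params$annulus, mask,
                           overlap = ov)
    if (nrow(obs)) {
      red <- asu_reduce(as.matrix(obs[, c("h", "k", "l")]), sg)
      obs$h <- red[, 1]; obs$k <- red[, 2]; obs$l <- red[, 3]
      obs$pattern <- pattern_id
    }
    if (per_frame) {
      frame_obs <- do.call(rbind, lapply(seq_along(stack$frames), function(f) {
        o <- integrate_spots(stack$frames[[f]] /
                               if (is.null(maps)) 1 else maps$flat_field,
                             pred, params$box_radius, params$annulus, mask,
                             overlap = ov)
        if (nrow(o)) o$frame <- f - 1L
        o
      }))
      if (!is.null(frame_obs) && nrow(frame_obs))
        frame_obs$pattern <- pattern_id
    }
  }
  list(center = ctr, peaks = peaks, hit = hit, solution = sol, obs = obs,
       frame_obs = frame_obs)
}

#' Process a whole simulated dataset
#'
#' Runs [process_stack()] over every crystal (stacks are regenerated on
#' demand, so memory stays flat), collects observations, and reports the
#' accounting the acquisition log would show: patterns, hits, indexed.
#'
#' @param ds A [simulate_dataset()] dataset.
#' @param params A [pipeline_params()] list.
#' @param per_frame Collect per-frame observations for damage analysis.
#' @param use_truth_orientations Skip indexing and integrate at the
#'   ground-truth orientations.
#' @param progress Print a progress line every 25 crystals.
#' @return List: `results` (per-crystal), `obs` (combined observation data
#'   frame), `frame_obs`, `n_hits`, `n_indexed`, `hit_fraction`,
#'   `indexing_rate`.
#' @export
process_dataset <- function(ds, params = pipeline_params(), per_frame = FALSE,
                            use_truth_orientations = FALSE, progress = FALSE) {
  results <- vector("list", ds$n_crystals)
  for (i in seq_len(ds$n_crystals)) {
    st <- crystal_stack(ds, i)
    results[[i]] <- process_stack(
      st, ds$maps, ds$geom, ds$beam, ds$truth$cell, ds$truth$sg, params,
      pattern_id = sprintf("crystal_%05d", i), per_frame = per_frame,
      orientation = if (use_truth_orientations) ds$truth$orientations[[i]]
                    else NULL)
    if (progress && i %% 25 == 0)
      message(sprintf("  processed %d / %d", i, ds$n_crystals))
  }
  hits <- vapply(results, function(r) isTRUE(r$hit), logical(1))
  indexed <- vapply(results, function(r)
    !is.null(r$solution) && isTRUE(r$solution$success), logical(1))
  obs <- do.call(rbind, lapply(results, `[[`, "obs"))
  frame_obs <- do.call(rbind, lapply(results, `[[`, "frame_obs"))
  list(results = results, obs = obs, frame_obs = frame_obs,
       n_hits = sum(hits), n_indexed = sum(indexed),
       hit_fraction = hit_fraction(hits),
       indexing_rate = indexing_rate(indexed[hits]))
}

#' Merge processed observations and compute the statistics block
#'
#' Scaling, ASU-consistent Monte-Carlo merging and the per-shell statistics
#' table, plus overall completeness and a Wilson fit: the serial-
#' crystallography summary of one processing run.
#'
#' @param obs Observation data frame from [process_dataset()].
#' @param cell,sg Cell and space group.
#' @param shells A [make_shells()] partition for the shell table.
#' @param scale Apply per-pattern scaling first.
#' @param resolve_ambiguity Run [resolve_indexing_ambiguity()] first (no-op
#'   for unambiguous symmetries).
#' @param seed Half-set split seed.
#' @return List: `merged`, `stats` (shell table), `wilson`, `d_cut`.
#' @export
merge_and_stats <- function(obs, cell, sg, shells, scale = TRUE,
                            resolve_ambiguity = TRUE, seed = 42) {
  if (resolve_ambiguity)
    obs <- resolve_indexing_ambiguity(obs, cell, sg)$obs
  if (scale) obs <- scale_patterns(obs)$obs
  merged <- merge_observations(obs, cell = cell, seed = seed)
  st <- shell_statistics(merged, cell, sg, shells)
  wf <- wilson_fit(merged)
  list(merged = merged, stats = st, wilson = wf,
       d_cut = truncate_resolution(st)$d_cut)
}
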