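# ---- on-disk formats: config, hkl, stream, scan lists, datasets --------

#' Read / write flat key-value configuration files
#'
#' One `key = value` pair per line; `#` comments; numeric values are
#' auto-converted.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    kv <- strsplit(lines[i], "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stopf("malformed config line %d: '%s'", i, lines[i])
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' @rdname read_config
#' @param config Named list.
#' @export
write_config <- function(config, path) {
  writeLines(paste(names(config), unlist(lapply(config, format)), sep = " = "),
             path)
  invisible(path)
}

#' Read / write reflection lists in the CrystFEL hkl text dialect
#'
#' Columns `h k l I phase sigma(I) nmeas` between a `Symmetry:` header line
#' and an `End of reflections` footer; phase is written as `-`.
#'
#' @param merged A `merged_set` (or any data frame with h, k, l, I; missing
#'   `sigma`/`n_meas` are written as 0/1).
#' @param path File path.
#' @param symmetry Symmetry string for the header.
#' @export
write_hkl <- function(merged, path, symmetry = "unknown") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("CrystFEL reflection list version 2.0",
               paste("Symmetry:", symmetry),
               "   h    k    l          I    phase   sigma(I)   nmeas"), con)
  sg <- merged$sigma %||% rep(0, nrow(merged))
  nm <- merged$n_meas %||% rep(1L, nrow(merged))
  if (nrow(merged))
    writeLines(sprintf("%4d %4d %4d %10.2f        - %10.2f %7d",
                       merged$h, merged$k, merged$l, merged$I, sg, nm), con)
  writeLines("End of reflections", con)
  invisible(path)
}

#' @rdname write_hkl
#' @export
read_hkl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sym_line <- grep("^Symmetry:", lines)
  if (!length(sym_line)) stopf("%s: missing Symmetry header", path)
  end <- grep("^End of reflections", lines)
  if (!length(end)) stopf("%s: missing 'End of reflections'", path)
  body <- if (end[1] > sym_line + 2)
    lines[(sym_line + 2):(end - 1)] else character(0)
  body <- body[nzchar(trimws(body))]
  if (!length(body)) {
    out <- data.frame(h = integer(), k = integer(), l = integer(),
                      I = numeric(), sigma = numeric(), n_meas = integer())
  } else {
    f <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(f, length, integer(1)) != 7)
    if (length(bad))
      stopf("%s: malformed record at line %d", path, sym_line + 1 + bad[1])
    m <- do.call(rbind, f)
    out <- data.frame(h = as.integer(m[, 1]), k = as.integer(m[, 2]),
                      l = as.integer(m[, 3]), I = as.numeric(m[, 4]),
                      sigma = as.numeric(m[, 6]), n_meas = as.integer(m[, 7]))
  }
  attr(out, "symmetry") <- sub("^Symmetry:\\s*", "", lines[sym_line])
  out
}

#' Write / read a per-pattern observation stream (CrystFEL-style text)
#'
#' Chunked text format: each pattern contributes a chunk delimited by
#' `----- Begin chunk -----` / `----- End chunk -----`, carrying the
#' pattern id, hit/indexed flags, the found-peak block (`fs/px ss/px
#' (1/d)/nm^-1 Intensity`) and, when indexed, the reciprocal-cell rows and
#' the predicted-reflection block. Round-trips all fields it defines.
#'
#' @param results List of per-pattern result lists (fields `id`, `hit`,
#'   `peaks`, `solution`, `obs`).
#' @param path File path.
#' @export
write_stream <- function(results, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("CrystFEL stream format 2.3", con)
  for (res in results) {
    writeLines("----- Begin chunk -----", con)
    writeLines(sprintf("Image filename: %s", res$id), con)
    writeLines(sprintf("hit = %d", as.integer(isTRUE(res$hit))), con)
    idx <- !is.null(res$solution) && isTRUE(res$solution$success)
    writeLines(sprintf("indexed_by = %s", if (idx) "gridsearch" else "none"), con)
    writeLines("Peaks from peak search", con)
    writeLines("  fs/px   ss/px (1/d)/nm^-1   Intensity", con)
    if (!is.null(res$peaks) && nrow(res$peaks))
      writeLines(sprintf("%8.2f %8.2f %12.4f %12.2f", res$peaks$fs,
                         res$peaks$ss, 10 / res$peaks$d, res$peaks$intensity),
                 con)
    writeLines("End of peak list", con)
    if (idx) {
      A <- res$solution$orientation
      for (i in 1:3)
        writeLines(sprintf("%s = %+.7f %+.7f %+.7f", c("astar", "bstar",
                                                       "cstar")[i],
                           A[1, i], A[2, i], A[3, i]), con)
      if (!is.null(res$obs) && nrow(res$obs)) {
        writeLines("Reflections measured after indexing", con)
        writeLines("   h    k    l          I      sigma(I)", con)
        writeLines(sprintf("%4d %4d %4d %12.2f %12.2f", res$obs$h, res$obs$k,
                           res$obs$l, res$obs$I, res$obs$sigma), con)
        writeLines("End of reflections", con)
      }
    }
    writeLines("----- End chunk -----", con)
  }
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^----- Begin chunk -----", lines)
  ends <- grep("^----- End chunk -----", lines)
  if (length(starts) != length(ends)) stopf("%s: unbalanced chunks", path)
  lapply(seq_along(starts), function(ci) {
    chunk <- lines[starts[ci]:ends[ci]]
    id <- sub("^Image filename: ", "", grep("^Image filename:", chunk,
                                            value = TRUE)[1])
    hit <- grepl("hit = 1", grep("^hit =", chunk, value = TRUE)[1])
    p0 <- grep("^Peaks from peak search", chunk)
    p1 <- grep("^End of peak list", chunk)
    peaks <- NULL
    if (length(p0) && p1 > p0 + 2) {
      m <- do.call(rbind, strsplit(trimws(chunk[(p0 + 2):(p1 - 1)]), "\\s+"))
      peaks <- data.frame(fs = as.numeric(m[, 1]), ss = as.numeric(m[, 2]),
                          d = 10 / as.numeric(m[, 3]),
                          intensity = as.numeric(m[, 4]))
    }
    ast <- grep("^astar =", chunk, value = TRUE)
    orientation <- NULL
    if (length(ast)) {
      rows <- lapply(c("astar", "bstar", "cstar"), function(nm) {
        as.numeric(strsplit(sub(paste0("^", nm, " = "), "",
                                grep(paste0("^", nm, " ="), chunk,
                                     value = TRUE)[1]), "\\s+")[[1]])
      })
      orientation <- cbind(rows[[1]], rows[[2]], rows[[3]])
    }
    r0 <- grep("^Reflections measured after indexing", chunk)
    obs <- NULL
    if (length(r0)) {
      r1 <- grep("^End of reflections", chunk)
      if (r1 > r0 + 2) {
        m <- do.call(rbind, strsplit(trimws(chunk[(r0 + 2):(r1 - 1)]), "\\s+"))
        obs <- data.frame(h = as.integer(m[, 1]), k = as.integer(m[, 2]),
                          l = as.integer(m[, 3]), I = as.numeric(m[, 4]),
                          sigma = as.numeric(m[, 5]))
      }
    }
    list(id = id, hit = hit, peaks = peaks, orientation = orientation,
         obs = obs)
  })
}

#' Write / read scan-point lists as tab-separated text
#'
#' @param scan A [make_scan_list()] result.
#' @param path File path.
#' @export
write_scan_list <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scan_list
#' @export
read_scan_list <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t")
  class(out) <- c("scan_point_list", "data.frame")
  out
}

# matrices as TSV (integer or numeric), used by the dataset layout
.write_matrix <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
.read_matrix <- function(path, integer = FALSE) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = if (integer) "integer" else "numeric"))
  dimnames(m) <- NULL
  m
}

#' Persist / load a simulated dataset as a plain-text directory
#'
#' Directory layout mirroring the acquisition structure: `config.txt`
#' (geometry, beam, simulation parameters, seed), `map/image.tsv` and
#' `map/true_positions.tsv`, `truth/` (cell, structure factors,
#' orientations, decay model), `detector/` (dead mask, flat field) and one
#' `stacks/crystal_NNNNN/` directory per crystal with `frame_NN.tsv` count
#' matrices and a `meta.txt`. Everything is text; counts round-trip
#' exactly.
#'
#' @param ds A [simulate_dataset()] result (with stacks in memory or
#'   regenerable).
#' @param dir Target directory.
#' @param n_stacks Number of stacks to write (default all).
#' @export
write_dataset <- function(ds, dir, n_stacks = ds$n_crystals) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("map", "truth", "detector", "stacks"))
    dir.create(file.path(dir, sub), showWarnings = FALSE)
  cfg <- c(list(n_crystals = ds$n_crystals, seed = ds$seed,
                voltage_kv = ds$beam$voltage / 1e3,
                camera_length_mm = ds$geom$camera_length,
                pixel_size_um = ds$geom$pixel_size,
                n_fast = ds$geom$n_fast, n_slow = ds$geom$n_slow,
                beam_center_fast = ds$geom$beam_center[1],
                beam_center_slow = ds$geom$beam_center[2],
                beam_diameter_nm = ds$beam$beam_diameter,
                beam_current_na = ds$beam$beam_current,
                frame_time_ms = ds$beam$frame_time,
                cell_a = ds$truth$cell$a, cell_b = ds$truth$cell$b,
                cell_c = ds$truth$cell$c, cell_alpha = ds$truth$cell$alpha,
                cell_beta = ds$truth$cell$beta,
                cell_gamma = ds$truth$cell$gamma,
                space_group = gsub(" ", "", ds$truth$sg$symbol),
                wilson_b = ds$truth$wilson_b),
           ds$config[vapply(ds$config, length, integer(1)) == 1])
  write_config(cfg, file.path(dir, "config.txt"))
  .write_matrix(ds$map$image, file.path(dir, "map", "image.tsv"))
  .write_matrix(ds$map$positions_px, file.path(dir, "map", "true_positions.tsv"))
  utils::write.table(ds$truth$sf, file.path(dir, "truth", "sf.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  orient <- do.call(rbind, lapply(ds$truth$orientations, as.vector))
  .write_matrix(orient, file.path(dir, "truth", "orientations.tsv"))
  .write_matrix(ds$truth$positions, file.path(dir, "truth", "positions.tsv"))
  .write_matrix(cbind(ds$truth$thickness), file.path(dir, "truth", "thickness.tsv"))
  if (!is.null(ds$truth$decay))
    utils::write.table(data.frame(edge_hi = ds$truth$decay$edges[-length(ds$truth$decay$edges)],
                                  edge_lo = ds$truth$decay$edges[-1],
                                  tau = ds$truth$decay$tau),
                       file.path(dir, "truth", "decay.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  .write_matrix(ds$maps$dead_mask * 1L, file.path(dir, "detector", "dead_mask.tsv"))
  .write_matrix(ds$maps$flat_field, file.path(dir, "detector", "flat_field.tsv"))
  for (i in seq_len(n_stacks)) {
    st <- crystal_stack(ds, i)
    sd <- file.path(dir, "stacks", sprintf("crystal_%05d", i))
    dir.create(sd, showWarnings = FALSE)
    write_config(list(frame_time_ms = st$frame_time,
                      dose_per_frame = st$dose_per_frame,
                      center_fast = st$true_center[1],
                      center_slow = st$true_center[2]),
                 file.path(sd, "meta.txt"))
    for (f in seq_along(st$frames))
      .write_matrix(st$frames[[f]], file.path(sd, sprintf("frame_%02d.tsv", f - 1)))
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  cfgp <- file.path(dir, "config.txt")
  if (!file.exists(cfgp)) stopf("not a dataset directory (no config.txt): %s", dir)
  cfg <- read_config(cfgp)
  geom <- detector_geometry(cfg$n_fast, cfg$n_slow, cfg$pixel_size_um,
                            cfg$camera_length_mm,
                            c(cfg$beam_center_fast, cfg$beam_center_slow))
  beam <- beam_parameters(cfg$voltage_kv * 1e3, cfg$beam_diameter_nm,
                          cfg$beam_current_na, cfg$frame_time_ms)
  sf <- utils::read.table(file.path(dir, "truth", "sf.tsv"), header = TRUE,
                          sep = "\t")
  orient <- .read_matrix(file.path(dir, "truth", "orientations.tsv"))
  decayp <- file.path(dir, "truth", "decay.tsv")
  decay <- NULL
  if (file.exists(decayp)) {
    dt <- utils::read.table(decayp, header = TRUE, sep = "\t")
    decay <- decay_model(c(dt$edge_hi, dt$edge_lo[nrow(dt)]), dt$tau)
  }
  stacks_dirs <- sort(list.dirs(file.path(dir, "stacks"), recursive = FALSE))
  stacks <- lapply(stacks_dirs, function(sd) {
    meta <- read_config(file.path(sd, "meta.txt"))
    fr_files <- sort(list.files(sd, pattern = "^frame_\\d+\\.tsv$",
                                full.names = TRUE))
    structure(list(frames = lapply(fr_files, .read_matrix, integer = TRUE),
                   frame_time = meta$frame_time_ms,
                   true_center = c(meta$center_fast, meta$center_slow),
                   dose_per_frame = meta$dose_per_frame, corrected = FALSE),
              class = "movie_stack")
  })
  maps <- structure(list(
    dead_mask = .read_matrix(file.path(dir, "detector", "dead_mask.tsv"),
                             integer = TRUE) > 0,
    flat_field = .read_matrix(file.path(dir, "detector", "flat_field.tsv"))),
    class = "correction_maps")
  list(config = cfg, geom = geom, beam = beam, sf = sf,
       orientations = lapply(seq_len(nrow(orient)), function(i)
         matrix(orient[i, ], 3, 3)),
       positions_px = .read_matrix(file.path(dir, "map", "true_positions.tsv")),
       map_image = .read_matrix(file.path(dir, "map", "image.tsv"),
                                integer = TRUE),
       decay = decay, maps = maps, stacks = stacks)
}
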