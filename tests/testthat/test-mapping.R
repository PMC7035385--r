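test_that("crystal detection recovers planted features and rejects noise", {
  cfg <- sim_config()
  truth <- make_ground_truth(50, cell = unit_cell(20, 20, 20),
                             sg = space_group("I23"),
                             config = sim_config(sim_d_min = 3), seed = 21)
  m <- simulate_stem_map(truth, cfg)
  feats <- find_crystals(m$image)
  hit <- serialed:::cpp_match_points(m$positions_px[, 1], m$positions_px[, 2],
                                     feats$x, feats$y, 2)
  # recovery scored on features planted at peak SNR >= 5
  set.seed(derive_seed(21, 1))
  n <- 50
  sx <- runif(n, 1.5, 4.5); sy <- runif(n, 1.5, 4.5); runif(n)
  peak_snr <- cfg$map_feature_counts * truth$thickness / (2 * pi * sx * sy) /
    sqrt(cfg$map_background)
  strong <- peak_snr >= 5
  expect_gte(sum(hit[strong, 1] > 0) / sum(strong), 0.95)
  # no spurious features
  expect_identical(nrow(feats) - length(unique(hit[hit[, 1] > 0, 1])), 0L)
  # blank image yields nothing
  set.seed(8)
  blank <- matrix(rpois(512 * 512, 50), 512, 512)
  expect_identical(nrow(find_crystals(blank)), 0L)
  # invariant under a constant offset
  expect_equal(find_crystals(m$image + 777), feats)
})

test_that("close features merge to a joint centroid", {
  img <- serialed:::cpp_render_spots(64, 64, c(30, 31), c(30, 30.5),
                                     c(4000, 4000), c(2, 2), c(2, 2),
                                     c(0, 0), 4)
  img <- img + 10
  f1 <- find_crystals(img, threshold_mode = "absolute", threshold = 30,
                      min_separation = 5)
  expect_identical(nrow(f1), 1L)
  expect_equal(f1$x, 30.5, tolerance = 0.2)
})

test_that("recovery degrades monotonically with background noise", {
  rec <- vapply(c(50, 2000, 50000), function(bg) {
    cfg <- sim_config(map_size = 512, map_field = 9, map_background = bg)
    truth <- make_ground_truth(30, cell = unit_cell(20, 20, 20),
                               sg = space_group("I23"),
                               config = sim_config(sim_d_min = 3), seed = 31)
    m <- simulate_stem_map(truth, cfg)
    f <- find_crystals(m$image)
    if (nrow(f) == 0) return(0)
    hit <- serialed:::cpp_match_points(m$positions_px[, 1],
                                       m$positions_px[, 2], f$x, f$y, 2)
    mean(hit[, 1] > 0)
  }, numeric(1))
  expect_true(all(diff(rec) <= 0))
  expect_gt(rec[1], rec[3])
})

test_that("scan lists are serpentine-ordered with correct physical units", {
  expect_identical(nrow(make_scan_list(find_crystals(matrix(0, 8, 8)))), 0L)
  f <- data.frame(x = c(100, 500, 900), y = c(5, 6, 4), area = 10,
                  eccentricity = 0, mean_intensity = 1)
  sl <- make_scan_list(f, 18, 1024)
  expect_equal(sl$x_px, c(100, 500, 900))   # along the row
  expect_equal(sl$x_um[2], 500 * 18 / 1024)
  f2 <- data.frame(x = c(100, 900, 100, 900), y = c(5, 6, 20, 21), area = 10,
                   eccentricity = 0, mean_intensity = 1)
  sl2 <- make_scan_list(f2, 18, 1024, row_height = 16)
  # second row traversed in reverse
  expect_equal(sl2$x_px, c(100, 900, 900, 100))
  single <- make_scan_list(data.frame(x = 512, y = 512, area = 10,
                                      eccentricity = 0, mean_intensity = 1),
                           18, 1024)
  expect_equal(c(single$x_um, single$y_um), c(9, 9))
})

test_that("hit fraction and mapping dose behave as defined", {
  expect_equal(hit_fraction(rep(TRUE, 10)), 1)
  expect_equal(hit_fraction(69, 100), 0.69)
  expect_true(is.na(hit_fraction(logical(0))))
  expect_lt(map_dose(beam_parameters(beam_current = 0.001), 0.002), 0.1)
  expect_warning(map_dose(beam_parameters(), 10), "exceeds")
})
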