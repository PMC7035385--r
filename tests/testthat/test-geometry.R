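test_that("relativistic electron wavelength matches closed-form values", {
  expect_equal(electron_wavelength(200e3), 0.0251, tolerance = 1e-2)
  expect_equal(round(electron_wavelength(200e3), 4), 0.0251)
  expect_equal(round(electron_wavelength(300e3), 4), 0.0197)
  # non-relativistic limit: correction factor -> 1 as V -> 0
  V <- 10
  nonrel <- 6.62607015e-34 /
    sqrt(2 * 9.1093837015e-31 * 1.602176634e-19 * V) * 1e10
  expect_equal(electron_wavelength(V) / nonrel, 1, tolerance = 1e-5)
  # strictly decreasing in voltage
  v <- seq(50e3, 300e3, length.out = 20)
  expect_true(all(diff(electron_wavelength(v)) < 0))
  expect_error(electron_wavelength(-1), "positive")
})

test_that("pixel <-> resolution conversion round-trips and is monotone", {
  geom <- detector_geometry()
  beam <- beam_parameters()
  expect_identical(pixel_to_resolution(geom$beam_center, geom, beam), Inf)
  # resolution_to_radius is the exact inverse
  expect_equal(radius_to_resolution(resolution_to_radius(2, geom, beam),
                                    geom, beam), 2, tolerance = 1e-9)
  set.seed(1)
  r <- runif(50, 1, 500)
  d <- radius_to_resolution(r, geom, beam)
  expect_equal(resolution_to_radius(d, geom, beam), r, tolerance = 1e-9)
  expect_true(all(diff(radius_to_resolution(sort(r), geom, beam)) < 0))
})

test_that("fluence follows the charge-over-area formula", {
  beam <- beam_parameters()  # 0.1 nA, 110 nm, 2 ms frames
  expect_equal(fluence(beam, 2), 1.313543, tolerance = 1e-5)
  expect_identical(fluence(beam, 0), 0)
  expect_equal(fluence(beam, 4), 2 * fluence(beam, 2))
  # invariant under current * k, exposure / k
  b2 <- beam_parameters(beam_current = 0.5)
  expect_equal(fluence(b2, 2 / 5), fluence(beam, 2))
  expect_error(fluence(beam, -1), "non-negative")
})

test_that("resolution shells partition the range", {
  s1 <- make_shells(10, 2, 1)
  expect_equal(s1$edges, c(10, 2))
  s4 <- make_shells(3.33, 1.55, 4)
  w <- diff(1 / s4$edges^3)
  expect_equal(max(w) - min(w), 0, tolerance = 1e-12)
  expect_equal(sum(w), 1 / 1.55^3 - 1 / 3.33^3)
  expect_error(make_shells(2, 10, 4), "d_max > d_min")
  # every d in range maps to exactly one shell; outside -> NA
  sh <- make_shells(20, 2, 7)
  set.seed(2)
  d <- runif(200, 2, 20)
  idx <- shell_of(d, sh)
  expect_true(all(idx >= 1 & idx <= 7))
  expect_true(all(d <= sh$edges[idx] & d >= sh$edges[idx + 1]))
  expect_identical(shell_of(c(21, 1.9), sh), c(NA_integer_, NA_integer_))
  expect_identical(shell_of(c(20, 2), sh), c(1L, 7L))
})

test_that("beam/geometry config files round-trip", {
  cfg <- list(voltage_kv = 200, camera_length_mm = 1740, pixel_size_um = 55,
              n_fast = 1024, n_slow = 1024, beam_center_fast = 511.5,
              beam_center_slow = 511.5, beam_diameter_nm = 110,
              beam_current_na = 0.1, frame_time_ms = 2)
  f <- withr::local_tempfile(fileext = ".cfg")
  write_config(cfg, f)
  bg <- read_beam_geometry(f)
  expect_equal(bg$beam$wavelength, electron_wavelength(200e3))
  expect_equal(bg$geom$camera_length, 1740)
  expect_error(read_beam_geometry(withr::local_tempfile(fileext = "x")),
               "not found")
})
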