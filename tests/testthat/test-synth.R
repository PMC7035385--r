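test_that("structure factors are deterministic and follow Wilson statistics", {
  cell <- unit_cell(50, 50, 50)
  sg <- space_group("I23")
  sf1 <- make_structure_factors(cell, sg, 1.6, wilson_b = 12.3, seed = 5)
  sf2 <- make_structure_factors(cell, sg, 1.6, wilson_b = 12.3, seed = 5)
  sf3 <- make_structure_factors(cell, sg, 1.6, wilson_b = 12.3, seed = 6)
  expect_identical(sf1, sf2)
  expect_false(all(sf1$F == sf3$F))
  # B = 0: flat Wilson plot (regression slope ~ 0)
  sf0 <- make_structure_factors(cell, sg, 1.6, wilson_b = 0, seed = 5)
  sh <- make_shells(max(sf0$d), min(sf0$d), 15)
  m0 <- tapply(sf0$F^2, shell_of(sf0$d, sh), mean)
  dm <- tapply(sf0$d, shell_of(sf0$d, sh), mean)
  fit0 <- lm(log(m0) ~ I(1 / (2 * dm^2)))
  expect_lt(abs(coef(fit0)[2]), 1)
  # B = 12.3 recovered by Wilson regression on the generated set
  wf <- wilson_fit(data.frame(h = sf1$h, k = sf1$k, l = sf1$l,
                              d = sf1$d, I = sf1$F^2), d_fit_max = 4.5)
  expect_equal(wf$B, 12.3, tolerance = 1 / 12.3)
})

test_that("the damage model assigns shell-wise decay constants", {
  dm <- decay_model()
  expect_equal(serialed:::decay_tau(c(5.00, 2.33, 1.96, 1.75, 1.61), dm),
               c(14.9, 6.8, 5.9, 5.2, 5.0))
  # clamped outside the modeled range
  expect_equal(serialed:::decay_tau(c(100, 1.2), dm), c(14.9, 5.0))
  expect_error(decay_model(tau = c(1, 2)), "one tau per shell")
})

test_that("frame decay factors integrate the exponential exactly", {
  tau <- 5; dt <- 2
  f <- serialed:::frame_decay_factor(0:9, dt, rep(tau, 10))
  # 10 frames of 2 ms sum to the integrated 20 ms exposure
  expect_equal(sum(f), tau / dt * (1 - exp(-20 / tau)), tolerance = 1e-12)
  # no-damage limit: each frame carries the full per-frame intensity
  expect_identical(serialed:::frame_decay_factor(3, dt, Inf), 1)
  # log-linear in frame mid-time: ratios follow exp(-dt/tau) exactly
  expect_equal(f[6] / f[5], exp(-dt / tau), tolerance = 1e-12)
})

test_that("pattern stacks are reproducible and respect the decay model", {
  s <- tiny_setup(n = 2, seed = 502)
  st1 <- sim_stack_i(s, 1)
  st2 <- sim_stack_i(s, 1)
  expect_identical(st1$frames, st2$frames)
  st3 <- sim_stack_i(s, 1, seed_offset = 900)
  expect_false(identical(st1$frames, st3$frames))
  # no-decay stack: late-frame total spot counts match early frames
  # (compare frames 2..5 vs 6..9 integrated over the whole panel after
  # subtracting the expected flat background)
  tot <- vapply(st1$frames, sum, numeric(1))
  early <- mean(tot[2:5]); late <- mean(tot[7:10])
  expect_equal(late / early, 1, tolerance = 0.05)
  # with decay, late frames are dimmer
  sd_ <- tiny_setup(n = 2, seed = 502,
                    decay = decay_model(edges = c(20, 2), tau = 4))
  std <- simulate_pattern_stack(sd_$truth$orientations[[1]], sd_$truth,
                                sd_$geom, sd_$beam, sd_$cfg, NULL, seed = 77,
                                center = sd_$geom$beam_center)
  ex <- serialed:::excited_reflections(sd_$truth$orientations[[1]], sd_$truth,
                                       sd_$geom, sd_$beam,
                                       3 * sd_$cfg$rocking_sigma,
                                       sd_$geom$beam_center)
  expect_gte(length(ex$fs), 5)
  totd <- vapply(std$frames, sum, numeric(1))
  bgc <- sd_$cfg$background_level * length(std$frames[[1]]) +
    sd_$cfg$beam_counts
  expect_lt((totd[10] - bgc), (totd[2] - bgc) * 0.5)
})

test_that("STEM maps plant recoverable features with thickness scaling", {
  cfg <- sim_config(map_size = 512, map_field = 9)
  t0 <- make_ground_truth(0, cell = unit_cell(20, 20, 20),
                          sg = space_group("I23"),
                          config = sim_config(sim_d_min = 3), seed = 1)
  t0$positions <- matrix(numeric(0), 0, 2)
  m0 <- simulate_stem_map(t0, cfg)
  # pure background: counts Poisson around map_background
  expect_equal(mean(m0$image), cfg$map_background, tolerance = 0.02)
  expect_identical(nrow(find_crystals(m0$image)), 0L)
  # integrated feature counts proportional to thickness
  tt <- make_ground_truth(2, cell = unit_cell(20, 20, 20),
                          sg = space_group("I23"),
                          config = sim_config(sim_d_min = 3), seed = 9)
  tt$positions <- matrix(c(2.2, 2.2, 6.8, 6.8), 2, 2, byrow = TRUE)
  tt$thickness <- c(1, 3)
  m <- simulate_stem_map(tt, cfg, seed = 4)
  box <- function(p) {
    xs <- round(p[1]) + (-15:15); ys <- round(p[2]) + (-15:15)
    sum(m$image[xs + 1, ys + 1]) - cfg$map_background * length(xs) * length(ys)
  }
  r <- box(m$positions_px[2, ]) / box(m$positions_px[1, ])
  expect_equal(r, 3, tolerance = 0.2)
})

test_that("simulated datasets are reproducible and stream on demand", {
  s <- tiny_setup(n = 2, seed = 503)
  ds1 <- simulate_dataset(2, s$geom, s$beam, s$cfg, cell = s$cell, sg = s$sg,
                          decay = NULL, seed = 77, keep_frames = TRUE)
  ds2 <- simulate_dataset(2, s$geom, s$beam, s$cfg, cell = s$cell, sg = s$sg,
                          decay = NULL, seed = 77, keep_frames = FALSE)
  expect_identical(ds1$stacks[[2]]$frames, crystal_stack(ds2, 2)$frames)
  expect_error(simulate_dataset(0), "n_crystals")
})
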