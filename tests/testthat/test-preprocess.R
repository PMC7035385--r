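make_stack <- function(frames, frame_time = 2) {
  structure(list(frames = frames, frame_time = frame_time,
                 corrected = FALSE), class = "movie_stack")
}

test_that("detector corrections divide gain and mask dead pixels", {
  fr <- lapply(1:3, function(i) matrix(10L * i, 16, 16))
  ident <- structure(list(dead_mask = matrix(FALSE, 16, 16),
                          flat_field = matrix(1, 16, 16)),
                     class = "correction_maps")
  st <- apply_corrections(make_stack(fr), ident)
  expect_equal(st$frames, lapply(fr, `+`, 0))
  gain <- ident
  gain$flat_field[3, 4] <- 2
  st2 <- apply_corrections(make_stack(fr), gain)
  expect_equal(st2$frames[[1]][3, 4], 5)
  expect_equal(st2$frames[[1]][1, 1], 10)
  # idempotent on already-corrected stacks
  expect_identical(apply_corrections(st2, gain), st2)
  bad <- ident
  bad$flat_field <- matrix(1, 8, 8)
  expect_error(apply_corrections(make_stack(fr), bad), "shape")
  # simulated gain map: post-correction means uniform within counting error
  set.seed(10)
  g <- matrix(exp(rnorm(64 * 64, 0, 0.1)), 64, 64)
  frames <- lapply(1:40, function(i)
    matrix(rpois(64 * 64, 100 * g), 64, 64))
  stc <- apply_corrections(make_stack(frames),
                           structure(list(dead_mask = matrix(FALSE, 64, 64),
                                          flat_field = g),
                                     class = "correction_maps"))
  px_mean <- Reduce(`+`, stc$frames) / 40
  expect_equal(mean(px_mean), 100, tolerance = 0.01)
  expect_lt(sd(px_mean), 2 * sqrt(100 / 40))
})

test_that("frame summing is exact, conservative and associative", {
  set.seed(11)
  fr <- lapply(1:10, function(i) matrix(rpois(100, 5), 10, 10))
  st <- make_stack(fr)
  expect_identical(sum_frames(st, 1), fr[[1]])
  expect_identical(sum_frames(st, 10), Reduce(`+`, fr))
  expect_identical(sum_frames(st, 5), fr[[1]] + fr[[2]] + fr[[3]] +
                     fr[[4]] + fr[[5]])
  expect_identical(sum_frames(st, 5) + Reduce(`+`, fr[6:10]),
                   sum_frames(st, 10))
  expect_identical(sum_frames(st, 3, cumulative = FALSE), fr[[3]])
  expect_error(sum_frames(st, 11), "out of range")
  expect_identical(sum(sum_frames(st, 10)), sum(unlist(fr)))
})

test_that("beam-center refinement recovers injected shifts", {
  s <- tiny_setup(n = 1, seed = 504)
  true_center <- s$geom$beam_center + c(3.4, -2.1)
  st <- simulate_pattern_stack(s$truth$orientations[[1]], s$truth, s$geom,
                               s$beam, s$cfg, s$maps, seed = 61,
                               center = true_center)
  stc <- apply_corrections(st, s$maps)
  img <- sum_frames(stc, 5)
  ctr <- find_center(img, s$geom, s$beam, mask = stc$valid_mask)
  expect_lt(sqrt(sum((ctr$center - true_center)^2)), 0.3)
  expect_identical(ctr$flag, "ok")
})

test_that("a centrosymmetric noise-free pattern centers exactly", {
  n <- 256
  c0 <- c(128, 128)
  ang <- seq(0.3, 2 * pi, length.out = 9)
  r <- seq(30, 90, length.out = 9)
  x <- c0[1] + r * cos(ang); y <- c0[2] + r * sin(ang)
  xs <- c(x, 2 * c0[1] - x); ys <- c(y, 2 * c0[2] - y)
  img <- serialed:::cpp_render_spots(n, n, c(xs, c0[1]), c(ys, c0[2]),
                                     c(rep(2000, 18), 3e4),
                                     rep(c(1, 2), c(18, 1)),
                                     rep(c(1, 2), c(18, 1)),
                                     rep(0, 19), 4)
  geom <- detector_geometry(n, n, 55, 870, beam_center = c0)
  beam <- beam_parameters()
  ctr <- find_center(img, geom, beam, friedel_dmin = 1)
  expect_equal(ctr$center, c0, tolerance = 1e-6)
  expect_gte(ctr$n_pairs, 2)
})

test_that("patterns without peaks fall back to the transmitted-beam center", {
  n <- 128
  img <- serialed:::cpp_render_spots(n, n, 63.5, 63.5, 3e4, 2, 2, 0, 5)
  img <- matrix(rpois(n * n, img + 0.2), n, n)
  geom <- detector_geometry(n, n, 55, 870, beam_center = c(63.5, 63.5))
  ctr <- find_center(img, geom, beam_parameters())
  expect_identical(ctr$flag, "friedel_failed")
  expect_equal(ctr$center, c(63.5, 63.5), tolerance = 0.3)
})

test_that("centering is accurate and unbiased over a synthetic ensemble", {
  s <- tiny_setup(n = 20, seed = 505)
  errs <- t(vapply(1:20, function(i) {
    st <- sim_stack_i(s, i)
    stc <- apply_corrections(st, s$maps)
    ctr <- find_center(sum_frames(stc, 5), s$geom, s$beam,
                       mask = stc$valid_mask)
    ctr$center - st$true_center
  }, numeric(2)))
  expect_lt(median(sqrt(rowSums(errs^2))), 0.5)
  expect_lt(abs(mean(errs[, 1])), 0.1)
  expect_lt(abs(mean(errs[, 2])), 0.1)
})
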