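test_that("spot prediction is symmetric and inverts the simulator", {
  d <- default_truth()
  # identity orientation of a cubic crystal: 4-fold symmetric about center
  pred <- predict_spots(diag(3), d$cell, d$sg, d$beam, d$geom)
  rot <- cbind(d$geom$beam_center[1] - (pred$ss - d$geom$beam_center[2]),
               d$geom$beam_center[2] + (pred$fs - d$geom$beam_center[1]))
  on <- rot[, 1] >= 0 & rot[, 1] <= d$geom$n_fast - 1 &
    rot[, 2] >= 0 & rot[, 2] <= d$geom$n_slow - 1
  mm <- serialed:::cpp_match_points(rot[on, 1], rot[on, 2], pred$fs, pred$ss,
                                    0.1)
  expect_gte(mean(mm[, 1] > 0), 0.99)
  # predictions at the generator's orientation reproduce the planted spots
  R1 <- d$truth$orientations[[1]]
  exc <- serialed:::excited_reflections(R1, d$truth, d$geom, d$beam,
                                        3 * d$cfg$rocking_sigma,
                                        d$geom$beam_center)
  pred1 <- predict_spots(R1, d$cell, d$sg, d$beam, d$geom)
  mm1 <- serialed:::cpp_match_points(exc$fs, exc$ss, pred1$fs, pred1$ss, 0.5)
  expect_gte(mean(mm1[, 1] > 0), 0.99)
  # zeta_max -> 0: generically nothing is exactly excited
  expect_identical(nrow(predict_spots(R1, d$cell, d$sg, d$beam, d$geom,
                                      zeta_max = 1e-9)), 0L)
})

test_that("still patterns index to the true orientation", {
  d <- default_truth()
  errs <- vapply(1:3, function(i) {
    pp <- processed_pattern(d, i)
    sol <- index_pattern(pp$peaks, d$cell, d$sg, d$beam, d$geom,
                         center = pp$ctr$center)
    expect_true(sol$success)
    # self-consistency: stored n_matched equals a fresh re-match
    mm <- serialed:::cpp_match_points(pp$peaks$fs, pp$peaks$ss,
                                      sol$predicted$fs, sol$predicted$ss, 2)
    expect_lte(abs(sum(mm[, 1] > 0) - sol$n_matched), 1)
    orientation_error(sol$orientation, d$truth$orientations[[i]], d$sg,
                      d$cell, lattice = TRUE)
  }, numeric(1))
  expect_lt(median(errs), 0.2)
})

test_that("indexing is equivariant under in-plane rotation", {
  d <- default_truth()
  pp <- processed_pattern(d, 4)
  sol1 <- index_pattern(pp$peaks, d$cell, d$sg, d$beam, d$geom,
                        center = pp$ctr$center)
  pk2 <- pp$peaks
  pk2$fs <- pp$ctr$center[1] - (pp$peaks$ss - pp$ctr$center[2])
  pk2$ss <- pp$ctr$center[2] + (pp$peaks$fs - pp$ctr$center[1])
  sol2 <- index_pattern(pk2, d$cell, d$sg, d$beam, d$geom,
                        center = pp$ctr$center)
  expect_true(sol1$success && sol2$success)
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  expect_lt(orientation_error(sol2$orientation, Rz %*% sol1$orientation,
                              d$sg, d$cell, lattice = TRUE), 0.2)
})

test_that("junk patterns fail to index", {
  d <- default_truth()
  set.seed(14)
  fails <- vapply(1:15, function(i) {
    pk <- data.frame(fs = runif(30, 20, 1000), ss = runif(30, 20, 1000),
                     intensity = runif(30, 50, 500), n_pix = 4)
    pk$r <- sqrt((pk$fs - 511.5)^2 + (pk$ss - 511.5)^2)
    pk$d <- radius_to_resolution(pk$r, d$geom, d$beam)
    sol <- index_pattern(pk, d$cell, d$sg, d$beam, d$geom)
    !sol$success
  }, logical(1))
  expect_gte(mean(fails), 0.95)
  # too few peaks: failure without search
  few <- data.frame(fs = runif(5, 100, 900), ss = runif(5, 100, 900),
                    intensity = 100, n_pix = 4, r = 100, d = 3)
  expect_false(index_pattern(few, d$cell, d$sg, d$beam, d$geom,
                             min_matched = 10)$success)
})

test_that("indexing rate summarizes results", {
  expect_equal(indexing_rate(c(TRUE, TRUE)), 1)
  expect_equal(indexing_rate(c(rep(TRUE, 81), rep(FALSE, 19))), 0.81)
  expect_true(is.na(indexing_rate(logical(0))))
  res <- list(list(success = TRUE), list(success = FALSE))
  expect_equal(indexing_rate(res), 0.5)
})
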