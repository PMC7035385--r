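test_that("merging averages observations per unique reflection", {
  obs <- data.frame(pattern = c("a", "b", "a", "b", "c"),
                    h = c(1, 1, 2, 2, 2), k = 0, l = c(0, 0, 1, 1, 1),
                    I = c(10, 20, 30, 60, 90), sigma = 1)
  m <- merge_observations(obs, sg = space_group("P1"))
  m <- m[order(m$h), ]
  expect_equal(m$I, c(15, 60))
  expect_equal(m$n_meas, c(2L, 3L))
  # singleton: halves undefined, excluded from CC computations
  single <- merge_observations(data.frame(pattern = "a", h = 3, k = 0, l = 0,
                                          I = 5, sigma = 1))
  expect_true(is.na(single$I_half_a) || is.na(single$I_half_b))
  cc <- cc_half_and_star(single)
  expect_true(is.na(cc$cc_half))
  # merged values invariant under row permutation (deterministic split)
  set.seed(18)
  big <- data.frame(pattern = sample(letters[1:8], 400, replace = TRUE),
                    h = sample(1:40, 400, replace = TRUE), k = 1, l = 2,
                    I = rexp(400, 0.01), sigma = 1)
  m1 <- merge_observations(big)
  m2 <- merge_observations(big[sample(400), ])
  m1 <- m1[order(m1$h), ]; m2 <- m2[order(m2$h), ]
  expect_equal(m1$I_half_a, m2$I_half_a)
})

test_that("R_split follows its definition and invariances", {
  expect_equal(rsplit(c(10, 10, 10), c(10, 10, 10)), 0)
  expect_equal(rsplit(10, 20), 100 / sqrt(2) * 10 / 15, tolerance = 1e-12)
  expect_equal(round(rsplit(10, 20), 2), 47.14)
  a <- c(5, 9, 30); b <- c(6, 8, 28)
  expect_equal(rsplit(a, b), rsplit(7 * a, 7 * b))
  expect_true(is.na(rsplit(numeric(0), numeric(0))))
})

test_that("CC1/2 and CC* follow the analytic relation", {
  # the published pairs are rounded from unrounded CC1/2, so agreement is
  # to the printed precision
  expect_lt(abs(cc_star(0.19) - 0.56), 0.01)
  expect_lt(abs(cc_star(0.22) - 0.60), 0.01)
  expect_equal(cc_star(1), 1)
  expect_equal(cc_star(-0.2), 0)
  # CC* = 0.5 at CC1/2 = 0.143
  expect_equal(round(0.25 / 1.75, 3), 0.143)
  expect_equal(cc_star(1 / 7), 0.5, tolerance = 1e-12)
  # CC* >= CC1/2 on (0, 1), equality at the ends
  cc <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(cc_star(cc) > cc))
  expect_lt(cc_half_and_star(c(1, 2, 3), c(1, 2, 3))$cc_half, 1 + 1e-12)
  expect_true(is.na(cc_half_and_star(c(1, 2), c(1, 2))$cc_half))
})

test_that("half-set statistics match analytic expectations (Monte Carlo)", {
  set.seed(19)
  n_hkl <- 1500; mult <- 50
  I_true <- rexp(n_hkl, 1 / 100)
  obs <- data.frame(pattern = rep(sprintf("p%03d", 1:mult), each = n_hkl),
                    h = rep(seq_len(n_hkl), mult), k = 0, l = 0,
                    I = rpois(n_hkl * mult, rep(I_true, mult)),
                    sigma = sqrt(rep(I_true, mult)) + 1)
  m <- merge_observations(obs)
  got <- cc_half_and_star(m)
  # CC1/2 expectation: var(signal) / (var(signal) + var(noise of a half))
  v_sig <- var(I_true)
  v_noise <- mean(I_true) / (mult / 2)
  expect_equal(got$cc_half, v_sig / (v_sig + v_noise), tolerance = 0.1)
  # R_split expectation for Poisson noise: (1/sqrt(2)) E|A-B| / mean, with
  # E|A_i - B_i| = sqrt(2/pi) sd(A_i - B_i) averaged over reflections
  e_absdiff <- sqrt(2 / pi) * sqrt(2 / (mult / 2)) * mean(sqrt(I_true))
  expect_equal(rsplit(m), 100 / sqrt(2) * e_absdiff / mean(I_true),
               tolerance = 0.1)
})

test_that("completeness compares observed to theoretical unique sets", {
  cell <- unit_cell(20, 20, 20); sg <- space_group("I23")
  uni <- enumerate_unique(cell, sg, 2.5)
  full <- data.frame(h = uni$hkl[, 1], k = uni$hkl[, 2], l = uni$hkl[, 3],
                     I = 1, sigma = 1, n_meas = 2)
  expect_equal(completeness(full, cell, sg, 2.5), 100)
  half <- full[seq_len(floor(nrow(full) / 2)), ]
  expect_equal(completeness(half, cell, sg, 2.5),
               100 * nrow(half) / uni$count)
})

test_that("Wilson fits recover the generator B factor", {
  cell <- unit_cell(50, 50, 50)
  sf <- make_structure_factors(cell, space_group("I23"), 1.6,
                               wilson_b = 12.3, seed = 20)
  fake <- data.frame(h = sf$h, k = sf$k, l = sf$l, d = sf$d, I = sf$F^2)
  wf <- wilson_fit(fake)
  expect_equal(wf$B, 12.3, tolerance = 1 / 12.3)
  # scale invariance: doubling intensities changes scale, not B
  fake2 <- fake; fake2$I <- fake2$I * 2
  expect_equal(wilson_fit(fake2)$B, wf$B, tolerance = 1e-9)
  expect_equal(wilson_fit(fake2)$scale, 2 * wf$scale, tolerance = 1e-9)
  # B = 0 generation: flat plot
  sf0 <- make_structure_factors(cell, space_group("I23"), 1.6,
                                wilson_b = 0, seed = 20)
  wf0 <- wilson_fit(data.frame(h = sf0$h, k = sf0$k, l = sf0$l, d = sf0$d,
                               I = sf0$F^2))
  expect_lt(abs(wf0$B), 1)
})

test_that("resolution truncation follows the CC* > 0.5 rule", {
  mk <- function(cc_star_seq) {
    n <- length(cc_star_seq)
    sh <- make_shells(10, 2, n)
    data.frame(shell = 1:n, d_max = sh$edges[1:n], d_min = sh$edges[-1],
               cc_star = cc_star_seq)
  }
  all_pass <- truncate_resolution(mk(c(1, 0.9, 0.8, 0.7)))
  expect_equal(all_pass$d_cut, 2)
  # the spec-table sequence: third shell (CC* = 0.56) is the last kept
  t1 <- truncate_resolution(mk(c(1.0, 0.9, 0.56, 0.3)))
  expect_identical(t1$n_shells_kept, 3L)
  expect_equal(t1$d_cut, mk(c(1, 1, 1, 1))$d_min[3])
  # shells after the first failure stay excluded even if CC* recovers
  t2 <- truncate_resolution(mk(c(1.0, 0.4, 0.9, 0.9)))
  expect_identical(t2$n_shells_kept, 1L)
  t3 <- truncate_resolution(mk(c(0.3, 0.2)))
  expect_identical(t3$flag, "none_pass")
})

test_that("the indexing ambiguity resolver restores a common convention", {
  cell <- unit_cell(20, 20, 20); sg <- space_group("I23")
  ops <- ambiguity_operators(cell, sg)
  expect_identical(length(ops), 2L)
  # no ambiguity for the tetragonal case
  expect_identical(length(ambiguity_operators(unit_cell(79.1, 79.1, 38),
                                              space_group("P43212"))), 1L)
  set.seed(22)
  sf <- make_structure_factors(cell, sg, 2.2, wilson_b = 5, seed = 23)
  flip <- ops[[2]]
  obs <- do.call(rbind, lapply(1:12, function(p) {
    sel <- sample(nrow(sf), min(150, nrow(sf)))
    hkl <- as.matrix(sf[sel, c("h", "k", "l")])
    flipped <- p %% 2 == 0
    if (flipped) hkl <- asu_reduce(hkl %*% t(flip), sg)
    data.frame(pattern = sprintf("p%02d", p), h = hkl[, 1], k = hkl[, 2],
               l = hkl[, 3],
               I = sf$F[sel]^2 * (1 + rnorm(length(sel), 0, 0.05)),
               sigma = 1)
  }))
  res <- resolve_indexing_ambiguity(obs, cell, sg)
  asn <- res$assignment
  # even patterns got one operator, odd the other (global convention free)
  expect_identical(length(unique(asn[c(1, 3, 5, 7, 9, 11)])), 1L)
  expect_identical(length(unique(asn[c(2, 4, 6, 8, 10, 12)])), 1L)
  expect_false(asn[1] == asn[2])
  # after resolution, merged data correlate with the truth near-perfectly
  m <- merge_observations(res$obs)
  idx <- match(paste(m$h, m$k, m$l), paste(sf$h, sf$k, sf$l))
  expect_gt(cor(m$I[!is.na(idx)], sf$F[idx[!is.na(idx)]]^2), 0.99)
})
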