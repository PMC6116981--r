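te18 <- 2.2 + 2.55 * (0:17)

test_that("with unit correction factors M0 is the mean of the first 3 echoes", {
  # flip 90 deg, TR >> T1, huge T2*: all three factors are 1
  pr <- acq_protocol(1e9, 90, te18[1:3])
  dm <- c(2, 2, 2)
  mag <- array(stats::runif(prod(dm) * 3, 50, 100), c(dm, 3))
  trn <- echo_train(mag, pr)
  fit <- correct_m0(trn, array(1e12, dm), array(1, dm), array(1, dm),
                    array(1, dm))
  expect_equal(fit$m0, (mag[, , , 1] + mag[, , , 2] + mag[, , , 3]) / 3,
               tolerance = 1e-9)
  expect_setequal(fit$corrections, c("T2*", "T1B1a", "B1-"))
})

test_that("supplying the true maps inverts the forward model up to scale", {
  ph <- make_brain_phantom(dim = c(16, 16, 16), delta_f_amp = NA)
  pr <- default_protocols()
  low <- simulate_megre(ph, pr$low)
  suppressMessages(
    fit <- correct_m0(low, ph$t2star, ph$t1, ph$b1plus, ph$b1minus))
  sel <- ph$labels > 0
  scale <- fit$m0[sel] / ph$h2o[sel]
  expect_lt(max(abs(scale / mean(scale) - 1)), 1e-6)
})

test_that("degenerate correction factors invalidate the voxel quietly", {
  pr <- acq_protocol(50, 7, te18[1:3])
  dm <- c(2, 1, 1)
  trn <- echo_train(array(60, c(dm, 3)), pr)
  t2s <- array(c(0, 50), dm)
  expect_message(
    fit <- correct_m0(trn, t2s, array(1000, dm), array(1, dm), array(1, dm)),
    "invalid")
  expect_false(fit$valid[1])
  expect_true(fit$valid[2])
  expect_true(is.na(fit$m0[1]))
})

test_that("receive-bias estimator is flat on unbiased piecewise-constant input", {
  ph <- make_brain_phantom(dim = c(24, 24, 24), b1minus_amp = 0,
                           delta_f_amp = NA)
  m0 <- ph$h2o
  m0[!ph$brain_mask] <- NA
  field <- estimate_receive_bias(m0, ph$brain_mask)
  expect_lt(max(abs(field[ph$brain_mask] - 1)), 0.01)
})

test_that("receive-bias estimator recovers a known polynomial field", {
  ph <- make_brain_phantom(dim = c(24, 24, 24), b1minus_amp = 0.2,
                           delta_f_amp = NA)
  biased <- ph$h2o * ph$b1minus
  biased[!ph$brain_mask] <- NA
  field <- estimate_receive_bias(biased, ph$brain_mask)
  truth <- ph$b1minus / mean(ph$b1minus[ph$brain_mask])
  rel <- field[ph$brain_mask] / truth[ph$brain_mask] - 1
  expect_lt(sqrt(mean(rel^2)), 0.02)
})

test_that("receive-bias estimation requires a non-empty mask", {
  expect_error(estimate_receive_bias(array(1, c(4, 4, 4)),
                                     array(FALSE, c(4, 4, 4))),
               "mask")
})

test_that("CSF normalisation mask applies every threshold at its boundary", {
  dm <- c(3, 1, 1)
  rule <- normalization_rule()
  t1 <- array(3000, dm); t2s <- array(600, dm); p <- array(0.995, dm)
  expect_true(all(csf_normalization_mask(p, t1, t2s, rule)))
  # each constraint violated in turn
  t1_lo <- t1; t1_lo[1] <- 2800
  m <- csf_normalization_mask(p, t1_lo, t2s, rule)
  expect_equal(as.vector(m), c(FALSE, TRUE, TRUE))
  t1_edge <- t1; t1_edge[1] <- 2900        # strict inequality
  expect_false(csf_normalization_mask(p, t1_edge, t2s, rule)[1])
  t2_lo <- t2s; t2_lo[1] <- 500
  expect_false(csf_normalization_mask(p, t1, t2_lo, rule)[1])
  p_lo <- p; p_lo[1] <- 0.989
  expect_false(csf_normalization_mask(p, t1, t2s, rule)[1] &&
                 csf_normalization_mask(p_lo, t1, t2s, rule)[1])
  expect_true(csf_normalization_mask(array(0.99, dm), t1, t2s, rule)[1])
  expect_error(csf_normalization_mask(array(0.5, dm), t1, t2s, rule),
               "empty")
})

test_that("the ellipsoid restriction excludes qualifying voxels outside it", {
  dm <- c(11, 11, 11)
  p <- array(1, dm); t1 <- array(3500, dm); t2s <- array(700, dm)
  rule <- normalization_rule(ellipsoid = list(centre = c(5, 5, 5),
                                              semi_axes = c(2, 2, 2)))
  m <- csf_normalization_mask(p, t1, t2s, rule)   # identity affine
  expect_true(m[6, 6, 6])                  # centre (0-based index 5)
  expect_false(m[1, 1, 1])
  expect_false(m[6, 6, 10])
})

test_that("water calibration fixes the mask mean at exactly 100", {
  dm <- c(6, 6, 6)
  m0 <- array(7.3, dm)
  mask <- array(FALSE, dm); mask[2:4, 2:4, 2:4] <- TRUE
  h <- normalize_h2o(m0, mask)
  expect_equal(as.vector(h$h2o), rep(100, prod(dm)))
  m0r <- array(stats::runif(prod(dm), 3, 9), dm)
  hr <- normalize_h2o(m0r, mask)
  expect_equal(mean(hr$h2o[mask]), 100)
  # invariance under global signal scaling
  hs <- normalize_h2o(m0r * 42, mask)
  expect_equal(hs$h2o, hr$h2o, tolerance = 1e-12)
  expect_error(normalize_h2o(m0, array(FALSE, dm)), "empty")
})

test_that("long-TR water mapping recovers truth with full relaxation", {
  ph <- make_tube_phantom(t1_levels = c(300, 400, 500, 600, 700, 800,
                                        1000, 1200))
  pr <- acq_protocol(10000, 90, 3.84 + 4.08 * (0:31))
  trn <- simulate_megre(ph, pr)
  h <- h2o_long_tr(trn, ph$labels == 8)
  for (k in 1:8)
    expect_equal(mean(h$h2o[ph$labels == k]), ph$h2o_levels[k],
                 tolerance = 0.1 / 100)
})

test_that("short TR through the long-TR path shows T1 saturation bias", {
  ph <- make_tube_phantom(t1_levels = c(300, 400, 500, 600, 700, 800,
                                        1000, 1200))
  pr_short <- acq_protocol(50, 90, 3.84 + 4.08 * (0:31))
  trn <- simulate_megre(ph, pr_short)
  expect_warning(h <- h2o_long_tr(trn, ph$labels == 8), "saturation")
  err <- sapply(1:7, function(k)
    abs(mean(h$h2o[ph$labels == k]) - ph$h2o_levels[k]))
  expect_gt(max(err), 5)                   # bias appears without correction
})

test_that("a uniform water phantom maps to 100% everywhere", {
  ph <- make_tube_phantom(h2o_levels = 100, t1_levels = 800,
                          ring_radius = 0, dim = c(24, 24, 8))
  pr <- acq_protocol(10000, 90, 3.84 + 4.08 * (0:31))
  h <- h2o_long_tr(simulate_megre(ph, pr), ph$labels == 1)
  expect_equal(h$h2o[ph$labels == 1],
               rep(100, sum(ph$labels == 1)), tolerance = 1e-6)
})

test_that("T1-bias propagation: zero at zero, monotone, matches finite differences", {
  expect_equal(propagate_t1_error(1000, 0, 7, 50), 0)
  d <- c(10, 50, 100, 200)
  e <- propagate_t1_error(1000, d, 7, 50)
  expect_true(all(diff(e) > 0))
  # central finite-difference oracle on ln C
  lnc <- function(t1) log(spgr_t1_factor(t1, 50, 7))
  h <- 1e-3
  fd <- abs((lnc(1000 + h) - lnc(1000 - h)) / (2 * h))
  expect_equal(propagate_t1_error(1000, 1, 7, 50), fd, tolerance = 1e-6)
})
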