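make_pair <- function(t1, flip, afi = afi_protocol(), m0 = 1) {
  s <- afi_signals(m0, t1, flip, afi)
  n <- length(s$s1)
  afi_pair(array(s$s1, c(n, 1, 1)), array(s$s2, c(n, 1, 1)), afi)
}

test_that("closed-form flip-angle inversion: exact ratio limits", {
  afi <- afi_protocol()     # n = 5
  pair <- afi_pair(array(1, c(2, 1, 1)),
                   array(c(1, 0.2), c(2, 1, 1)), afi)
  fam <- afi_flip_angle(pair)
  expect_equal(fam$alpha_eff[1], 0)        # r = 1 -> cos = 1
  expect_equal(fam$alpha_eff[2], 90)       # r = 1/n -> cos = 0
})

test_that("forward-inverse round trip through the approximation is ~2%", {
  pair <- make_pair(1000, 40)
  fam <- afi_flip_angle(pair)
  expect_equal(fam$alpha_eff[1], 40, tolerance = 0.02)
})

test_that("flip-angle map depends only on the signal ratio", {
  pair <- make_pair(c(800, 1500), c(35, 55))
  scaled <- afi_pair(pair$s1 * 7.3, pair$s2 * 7.3, pair$protocol)
  expect_equal(afi_flip_angle(pair)$alpha_eff,
               afi_flip_angle(scaled)$alpha_eff)
})

test_that("degenerate AFI voxels are flagged invalid, not errors", {
  afi <- afi_protocol()
  pair <- afi_pair(array(c(0, 1, 1), c(3, 1, 1)),
                   array(c(1, 1.2, 0.19), c(3, 1, 1)), afi)
  fam <- afi_flip_angle(pair)
  expect_false(fam$valid[1])               # S1 = 0
  expect_false(fam$valid[2])               # r > 1: argument beyond clamp
  expect_true(fam$valid[3])
})

test_that("iterative refinement recovers the flip angle with the exact model", {
  g <- expand.grid(a = seq(20, 60, 10), t1 = c(500, 1500, 3000, 4500))
  for (tt in unique(g$t1)) {
    idx <- which(g$t1 == tt)
    pair <- make_pair(g$t1[idx], g$a[idx])
    fam <- afi_refine(afi_flip_angle(pair), pair, t1_assumed = tt,
                      tol = 1e-3)
    expect_true(all(fam$converged))
    expect_lt(max(abs(fam$alpha_eff / g$a[idx] - 1)), 1e-3)
  }
})

test_that("refinement is a fixed point when the initial map is exact", {
  afi <- afi_protocol()
  r_exact <- afi_ratio(1000, 40, afi)
  s1 <- array(1, c(1, 1, 1)); s2 <- array(r_exact, c(1, 1, 1))
  pair <- afi_pair(s1, s2, afi)
  fam0 <- afi_flip_angle(pair)
  fam0$alpha_eff[] <- 40                   # already exact
  fam <- afi_refine(fam0, pair, t1_assumed = 1000, tol = 1e-4)
  expect_equal(fam$alpha_eff[1], 40, tolerance = 1e-3)
})

test_that("a mismatched assumed T1 leaves only a small residual error", {
  true_t1 <- 1000
  pair <- make_pair(true_t1, 40)
  fam_true <- afi_refine(afi_flip_angle(pair), pair, t1_assumed = true_t1,
                         tol = 1e-3)
  err_true <- abs(fam_true$alpha_eff[1] / 40 - 1)
  for (t1a in c(500, 1500)) {              # +/- 50%
    fam <- afi_refine(afi_flip_angle(pair), pair, t1_assumed = t1a,
                      tol = 1e-3)
    err <- abs(fam$alpha_eff[1] / 40 - 1)
    # bounded, and clearly worse than with the correct T1
    expect_lt(err, 0.03)
    expect_gt(err, err_true)
  }
})

test_that("B1+ calibration divides by the nominal flip angle", {
  afi <- afi_protocol()
  fam <- structure(list(alpha_eff = array(c(40, 20), c(2, 1, 1)),
                        valid = array(TRUE, c(2, 1, 1)), protocol = afi),
                   class = "flip_angle_map")
  bm <- b1plus_calibrate(fam, flip_nominal = 40)
  expect_equal(as.vector(bm$b1plus), c(1, 0.5))
  fam$alpha_eff <- fam$alpha_eff * 2       # constant scaling stays constant
  expect_warning(bm2 <- b1plus_calibrate(fam, flip_nominal = 40), "B1\\+")
  expect_equal(as.vector(bm2$b1plus), c(2, 1))
})

test_that("median filter: constant maps and isolated outliers", {
  x <- array(1, c(6, 6, 6))
  expect_equal(median_filter3d(x), x)
  x[3, 3, 3] <- 100
  expect_equal(median_filter3d(x)[3, 3, 3], 1)
})

test_that("trilinear resampling: identity, constants and affine functions", {
  src <- array(stats::runif(5 * 6 * 7), c(5, 6, 7))
  aff <- diag(4)
  expect_equal(resample_to_grid(src, aff, dim(src), aff), src,
               ignore_attr = TRUE)
  cst <- array(3.3, c(4, 4, 4))
  out <- resample_to_grid(cst, aff, c(7, 7, 7), diag(c(0.5, 0.5, 0.5, 1)))
  expect_equal(out[attr(out, "valid")],
               rep(3.3, sum(attr(out, "valid"))))
  # a linear ramp is reproduced exactly when upsampled 2x
  dm <- c(8, 8, 8)
  i <- slice.index(array(0, dm), 1); j <- slice.index(array(0, dm), 2)
  ramp <- 2 * i + 0.5 * j
  aff2 <- diag(c(0.5, 0.5, 0.5, 1))
  out2 <- resample_to_grid(ramp, diag(4), c(15, 15, 15), aff2)
  ii <- slice.index(array(0, c(15, 15, 15)), 1)
  jj <- slice.index(array(0, c(15, 15, 15)), 2)
  expected <- 2 * ((ii - 1) / 2 + 1) + 0.5 * ((jj - 1) / 2 + 1)
  v <- attr(out2, "valid")
  expect_equal(out2[v], expected[v], tolerance = 1e-12)
})

test_that("resampling marks voxels outside the source extent invalid", {
  src <- array(1, c(4, 4, 4))
  aff_target <- diag(4); aff_target[1, 4] <- 10   # shifted out of range
  out <- resample_to_grid(src, diag(4), c(4, 4, 4), aff_target)
  expect_true(all(is.na(out)))
})
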