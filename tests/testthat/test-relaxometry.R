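te18 <- 2.2 + 2.55 * (0:17)

sim_pair <- function(t1, b1 = 1, m0 = 70, t2star = 50, n_echoes = 3,
                     sigma = 0, n_reps = length(t1)) {
  pl <- acq_protocol(50, 7, te18[seq_len(n_echoes)])
  ph <- acq_protocol(50, 40, te18[seq_len(n_echoes)])
  s1 <- sapply(seq_len(n_echoes), function(n)
    spgr_signal(m0, t1, t2star, pl$te[n], 50, b1 * 7))
  s2 <- sapply(seq_len(n_echoes), function(n)
    spgr_signal(m0, t1, t2star, ph$te[n], 50, b1 * 40))
  s1 <- matrix(s1, ncol = n_echoes); s2 <- matrix(s2, ncol = n_echoes)
  if (sigma > 0) {
    s1 <- sqrt((s1 + matrix(stats::rnorm(length(s1), sd = sigma), nrow(s1)))^2 +
                 matrix(stats::rnorm(length(s1), sd = sigma), nrow(s1))^2)
    s2 <- sqrt((s2 + matrix(stats::rnorm(length(s2), sd = sigma), nrow(s2)))^2 +
                 matrix(stats::rnorm(length(s2), sd = sigma), nrow(s2))^2)
  }
  nv <- nrow(s1)
  list(low = echo_train(array(s1, c(nv, 1, 1, n_echoes)), pl),
       high = echo_train(array(s2, c(nv, 1, 1, n_echoes)), ph),
       s1 = s1, s2 = s2)
}

test_that("two-point T1 fit recovers noiseless truth to solver tolerance", {
  d <- sim_pair(1000)
  fit <- fit_t1_two_point(d$low, d$high, 1)
  expect_equal(fit$t1[1], 1000, tolerance = 0.1 / 1000)
  expect_false(fit$clipped[1])
})

test_that("two-point T1 fit is exact on noiseless data over (T1, B1+)", {
  withr::with_seed(11, {
    t1 <- stats::runif(60, 200, 5500)
    b1 <- stats::runif(60, 0.7, 1.3)
  })
  d <- sim_pair(t1, b1)
  fit <- fit_t1_two_point(d$low, d$high, array(b1, c(60, 1, 1)))
  expect_lt(max(abs(fit$t1 / t1 - 1)), 1e-3)
})

test_that("estimated T1 is strictly increasing in true T1", {
  t1 <- seq(300, 5200, length.out = 25)
  d <- sim_pair(t1)
  fit <- fit_t1_two_point(d$low, d$high, 1)
  expect_true(all(diff(as.vector(fit$t1)) > 0))
})

test_that("T1 solver equals the exhaustive 0.1 ms grid search on noisy voxels", {
  withr::with_seed(21, {
    t1 <- stats::runif(200, 200, 5500)
    b1 <- stats::runif(200, 0.7, 1.3)
    s_ref <- spgr_signal(70, 1000, 50, 2.2, 50, 7)
    d <- sim_pair(t1, b1, sigma = s_ref / 20)
  })
  fit <- fit_t1_two_point(d$low, d$high, array(b1, c(200, 1, 1)))
  oracle <- grid_search_t1(d$s1, d$s2, b1 * 7 * pi / 180, b1 * 40 * pi / 180,
                           tr = 50)
  expect_lt(max(abs(fit$t1 - oracle)), 0.2)
})

test_that("T1 estimates beyond the bound are clipped and flagged", {
  d <- sim_pair(8000)
  fit <- fit_t1_two_point(d$low, d$high, 1)
  expect_equal(fit$t1[1], 6000)
  expect_true(fit$clipped[1])
})

test_that("mismatched echo times or TR are protocol errors", {
  d <- sim_pair(1000)
  bad <- d$high
  bad$protocol <- acq_protocol(50, 40, d$high$protocol$te + 0.1)
  expect_error(fit_t1_two_point(d$low, bad, 1), "echo times")
  bad2 <- d$high
  bad2$protocol <- acq_protocol(60, 40, d$high$protocol$te)
  expect_error(fit_t1_two_point(d$low, bad2, 1), "TR")
})

test_that("zero-signal voxels are invalid, not numerical garbage", {
  pl <- acq_protocol(50, 7, te18[1:3]); ph <- acq_protocol(50, 40, te18[1:3])
  z <- array(0, c(1, 1, 1, 3))
  fit <- fit_t1_two_point(echo_train(z, pl), echo_train(z, ph), 1)
  expect_false(fit$valid[1])
  expect_true(is.na(fit$t1[1]))
})

test_that("field map: zero phase and uniform off-resonance", {
  pr <- acq_protocol(50, 7, te18)
  zero <- voxel_train(rep(1, 18), pr, phase = rep(0, 18))
  expect_equal(fieldmap_from_phase(zero)$delta_f[1], 0)
  f_true <- 30
  ph <- 2 * pi * f_true * te18 / 1000
  tr <- voxel_train(rep(1, 18), pr, phase = ph)
  expect_equal(fieldmap_from_phase(tr)$delta_f[1], 30, tolerance = 1e-9)
  mag_only <- voxel_train(rep(1, 18), pr)
  expect_error(fieldmap_from_phase(mag_only), "field map")
})

test_that("frequencies beyond the two-echo Nyquist are recovered when later echo spacings differ", {
  # uneven spacing: first gap 2 ms (Nyquist 250 Hz), later gaps 3 ms
  te <- c(2, 4, 7, 10)
  pr <- acq_protocol(50, 7, te)
  f_true <- 350
  ph <- atan2(sin(2 * pi * f_true * te / 1000),
              cos(2 * pi * f_true * te / 1000))
  tr <- voxel_train(rep(1, 4), pr, phase = ph)
  fm <- fieldmap_from_phase(tr)
  expect_equal(fm$delta_f[1], f_true, tolerance = 1e-6)
})

test_that("uniformly spaced echoes keep the principal value", {
  pr <- acq_protocol(50, 7, te18)
  f_true <- 60
  ph <- 2 * pi * f_true * te18 / 1000
  tr <- voxel_train(rep(1, 18), pr, phase = ph)
  expect_equal(fieldmap_from_phase(tr)$delta_f[1], 60, tolerance = 1e-9)
})

test_that("TE_max from the field gradient: zero, finite and extreme cases", {
  dm <- c(8, 8, 8)
  flat <- structure(list(delta_f = array(5, dm), voxel_size = c(1, 1, 1)),
                    class = "field_gradient_map")
  fm <- compute_te_max(flat)
  expect_true(all(is.infinite(fm$te_max)))
  expect_true(all(te18 < fm$te_max[1]))    # all 18 echoes eligible

  # ramp chosen so q / (G d) = 20 ms: 0.5 cycles / 25 Hz across the voxel
  ramp <- array(slice.index(array(0, dm), 1) * 25, dm)
  fm2 <- compute_te_max(structure(list(delta_f = ramp,
                                       voxel_size = c(1, 1, 1)),
                                  class = "field_gradient_map"))
  expect_equal(fm2$te_max[4, 4, 4], 20)
  expect_equal(sum(te18 < fm2$te_max[4, 4, 4]), 7)  # echoes 1..7 remain
})

test_that("T2* fit is exact on noiseless mono-exponential decays", {
  pr <- acq_protocol(50, 7, te18)
  s <- 100 * exp(-te18 / 50)
  fit <- fit_t2star(voxel_train(s, pr))
  expect_equal(fit$t2star[1], 50, tolerance = 1e-9)
  expect_equal(fit$s0[1], 100, tolerance = 1e-9)
  expect_equal(fit$n_echoes_used[1], 18L)
})

test_that("T2* fit equals a nonlinear least-squares oracle on noiseless data", {
  skip_if_not_installed("minpack.lm")
  pr <- acq_protocol(50, 7, te18)
  withr::with_seed(3, {
    for (i in 1:5) {
      s0 <- stats::runif(1, 50, 150); t2 <- stats::runif(1, 20, 300)
      s <- s0 * exp(-te18 / t2)
      fit <- fit_t2star(voxel_train(s, pr))
      nls_fit <- minpack.lm::nlsLM(s ~ a * exp(-te18 / b),
                                   start = list(a = 80, b = 60))
      cf <- stats::coef(nls_fit)
      expect_equal(fit$s0[1], unname(cf["a"]), tolerance = 1e-6)
      expect_equal(fit$t2star[1], unname(cf["b"]), tolerance = 1e-6)
    }
  })
})

test_that("non-decaying voxels clip to the T2* bound with the mask set", {
  pr <- acq_protocol(50, 7, te18)
  fit <- fit_t2star(voxel_train(rep(80, 18), pr))
  expect_equal(fit$t2star[1], 1500)
  expect_true(fit$clipped[1])
  # all-zero voxel is invalid
  fit0 <- fit_t2star(voxel_train(rep(0, 18), pr))
  expect_false(fit0$valid[1])
})

test_that("amplitude weighting beats the unweighted log-linear fit under noise", {
  pr <- acq_protocol(50, 7, te18)
  nv <- 1000
  withr::with_seed(5, {
    s_true <- matrix(rep(100 * exp(-te18 / 45), each = nv), nv)
    noise_r <- matrix(stats::rnorm(nv * 18, sd = 2), nv)
    noise_i <- matrix(stats::rnorm(nv * 18, sd = 2), nv)
    s <- sqrt((s_true + noise_r)^2 + noise_i^2)
  })
  fit <- fit_t2star(echo_train(array(s, c(nv, 1, 1, 18)), pr))
  unw <- unweighted_loglin(s, te18)
  err_w <- fit$t2star - 45
  err_u <- unw$t2star - 45
  expect_lt(stats::var(err_w), stats::var(err_u))
})

test_that("the echo cutoff reduces the dephasing-induced T2* bias", {
  dm <- c(10, 10, 10)
  ramp <- array(slice.index(array(0, dm), 1) * 15, dm)   # 15 Hz per voxel
  ph <- phantom_spec(array(70, dm), array(1000, dm), array(50, dm),
                     delta_f = ramp)
  pr <- acq_protocol(50, 7, te18)
  tr <- simulate_megre(ph, pr, dephasing = TRUE)
  fm <- compute_te_max(fieldmap_from_phase(tr))
  fit_cut <- fit_t2star(tr, te_max = fm)
  fit_all <- fit_t2star(tr)
  core <- array(FALSE, dm); core[3:8, 3:8, 3:8] <- TRUE
  bias_cut <- abs(mean(fit_cut$t2star[core]) - 50)
  bias_all <- abs(mean(fit_all$t2star[core]) - 50)
  expect_lt(bias_cut, bias_all)
  expect_true(all(fit_cut$n_echoes_used[core] < 18))
})

test_that("restricting echoes never hurts on noiseless clean decays", {
  pr <- acq_protocol(50, 7, te18)
  s <- 100 * exp(-te18 / 60)
  dm <- c(2, 1, 1)
  trn <- echo_train(array(rep(s, each = 2), c(dm, 18)), pr)
  tm <- structure(list(te_max = array(c(Inf, 25), dm)),
                  class = "field_gradient_map")
  fit <- fit_t2star(trn, te_max = tm)
  expect_equal(as.vector(fit$t2star), c(60, 60), tolerance = 1e-9)
})

test_that("extreme gradients fall back to the minimum-echo floor", {
  pr <- acq_protocol(50, 7, te18)
  s <- 100 * exp(-te18 / 60)
  trn <- echo_train(array(s, c(1, 1, 1, 18)), pr)
  tm <- structure(list(te_max = array(1, c(1, 1, 1))),  # below TE_1
                  class = "field_gradient_map")
  fit <- fit_t2star(trn, te_max = tm)
  expect_equal(fit$n_echoes_used[1], 3L)
  expect_true(fit$floor_used[1])
  expect_true(fit$valid[1])
})
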