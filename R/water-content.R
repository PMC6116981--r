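#' Fully corrected magnetisation-density map
#'
#' Inverts the three multiplicative factors of the spoiled-GRE signal
#' model on the low-flip-angle acquisition and averages over the first
#' `n_echoes` echoes:
#' \deqn{M_0 = \frac{1}{N}\sum_{n=1}^{N} S(TE_n)\,
#'   C_{T_2^*}^{-1}(TE_n)\, C_{T_1,B_1^+,\alpha}^{-1}\, C_{B_1^-}^{-1},}
#' with \eqn{C_{T_2^*} = e^{-TE_n/T_2^*}}, the T1/B1+/flip saturation
#' factor from [spgr_t1_factor()], and the receive field.  Water content
#' is derived from the low-flip-angle acquisition only; the high flip
#' angle enters solely through the T1 estimate.
#'
#' @param low `echo_train` of the low-flip-angle acquisition.
#' @param t2star A `t2star_map` (or 3-D array, ms).
#' @param t1 A `t1_map` (or 3-D array, ms).
#' @param b1plus A `b1_map` or 3-D array.
#' @param b1minus 3-D receive-field array, or `NULL` to skip the receive
#'   correction (partially corrected map, e.g. as input to
#'   [estimate_receive_bias()]).
#' @param n_echoes Number of leading echoes averaged (default 3).
#'
#' @return Object of class `m0_map`: list with `m0`, logical `valid`
#'   (voxels where any correction factor was zero or undefined are
#'   invalid, never divided through) and `corrections` (character set).
#' @export
correct_m0 <- function(low, t2star, t1, b1plus, b1minus = NULL,
                       n_echoes = 3) {
  stopifnot(inherits(low, "echo_train"))
  dm <- dim(low$magnitude)[1:3]
  t2s <- if (inherits(t2star, "t2star_map")) t2star$t2star else t2star
  t1v <- if (inherits(t1, "t1_map")) t1$t1 else t1
  b1  <- if (inherits(b1plus, "b1_map")) b1plus$b1plus else b1plus
  if (length(b1) == 1L) b1 <- array(b1, dm)
  stopifnot(identical(dim(t2s), dm), identical(dim(t1v), dm),
            identical(dim(b1), dm))
  ne <- min(n_echoes, low$protocol$n_echoes)

  c_t1 <- spgr_t1_factor(t1v, low$protocol$tr,
                         b1 * low$protocol$flip_nominal)
  valid <- is.finite(t2s) & t2s > 0 & is.finite(t1v) & t1v > 0 &
    is.finite(c_t1) & c_t1 > 0
  corrections <- c("T2*", "T1B1a")
  if (!is.null(b1minus)) {
    stopifnot(identical(dim(b1minus), dm))
    valid <- valid & is.finite(b1minus) & b1minus > 0
    corrections <- c(corrections, "B1-")
  }
  n_invalid <- sum(!valid)
  if (n_invalid > 0)
    message(sprintf("correct_m0: %d voxel(s) with degenerate correction factors marked invalid",
                    n_invalid))
  acc <- array(0, dm)
  for (n in seq_len(ne)) {
    c_t2s <- exp(-low$protocol$te[n] / t2s)
    acc <- acc + low$magnitude[, , , n] / (c_t2s * c_t1)
  }
  m0 <- acc / ne
  if (!is.null(b1minus)) m0 <- m0 / b1minus
  m0[!valid] <- NA_real_
  structure(list(m0 = m0, valid = valid, corrections = corrections),
            class = "m0_map")
}

# design matrix of 3-D monomials x^i y^j z^k with i+j+k <= order,
# on coordinates already normalised to [-1, 1]
.poly_design <- function(u, v, w, order) {
  cols <- list()
  for (i in 0:order) for (j in 0:(order - i)) for (k in 0:(order - i - j))
    cols[[length(cols) + 1L]] <- u^i * v^j * w^k
  do.call(cbind, cols)
}

#' Estimate the receive-field bias from a partially corrected M0 map
#'
#' After the T2* and T1/B1+/flip corrections, the remaining smooth
#' multiplicative modulation of the magnetisation-density map inside the
#' brain is attributed to the receive field.  The estimator alternates
#' (i) k-class 1-D intensity clustering of the log-residual image with
#' (ii) a least-squares fit of a low-order 3-D polynomial to the
#' log-residual relative to the class centres, until the field stabilises.
#' The returned field is normalised to mean 1 over the mask.  A
#' user-supplied measured receive field should be passed directly to
#' [correct_m0()] instead.
#'
#' @param m0_partial `m0_map` corrected for T2* and T1/B1+/flip but not
#'   for the receive field.
#' @param brain_mask Logical 3-D array of voxels inside the object.
#' @param k Number of intensity classes (default 3: WM/GM/CSF).
#' @param order Total polynomial order of the field (default 4).
#' @param max_iter,tol Alternation control; if the field has not
#'   stabilised after `max_iter` rounds the best iterate is returned with
#'   a warning.
#' @param sample_max Cap on the number of mask voxels entering the
#'   regression (deterministic even-stride subsample).
#'
#' @return 3-D array: the estimated multiplicative receive field,
#'   mean 1 over the mask.
#' @export
estimate_receive_bias <- function(m0_partial, brain_mask, k = 3, order = 4,
                                  max_iter = 20L, tol = 1e-4,
                                  sample_max = 40000L) {
  m0 <- if (inherits(m0_partial, "m0_map")) m0_partial$m0 else m0_partial
  dm <- dim(m0)
  stopifnot(identical(dim(brain_mask), dm))
  mask <- brain_mask & is.finite(m0) & m0 > 0
  if (!any(mask)) stop("empty brain mask: cannot estimate the receive field")

  idx <- which(mask)
  if (length(idx) > sample_max)
    idx_fit <- idx[seq(1L, length(idx), length.out = sample_max)]
  else idx_fit <- idx

  cc <- .norm_coords(dm)
  X <- .poly_design(cc$u[idx_fit], cc$v[idx_fit], cc$w[idx_fit], order)
  z <- log(m0[idx_fit])
  beta <- rep(0, ncol(X))
  logf <- as.vector(X %*% beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    resid <- z - logf
    centres <- stats::quantile(resid, (seq_len(k) - 0.5) / k, names = FALSE)
    km <- stats::kmeans(resid, centers = matrix(centres, ncol = 1),
                        iter.max = 100L)
    mu <- km$centers[km$cluster]
    beta_new <- qr.coef(qr(X), z - mu)
    beta_new[is.na(beta_new)] <- 0
    delta <- max(abs(as.vector(X %*% (beta_new - beta))))
    beta <- beta_new
    logf <- as.vector(X %*% beta)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("receive-bias estimation did not stabilise; returning last iterate")
  Xall <- .poly_design(cc$u[idx], cc$v[idx], cc$w[idx], order)
  field <- array(1, dm)
  field[idx] <- exp(as.vector(Xall %*% beta))
  field <- field / mean(field[idx])
  field
}

#' Normalisation mask: ventricular CSF voxels
#'
#' Conjunction of the CSF-probability, T1 and T2* thresholds of a
#' [normalization_rule()], optionally intersected with the interior of
#' the rule's ellipsoid (world-mm coordinates through `affine`), which
#' confines the region to the lateral ventricles and excludes
#' subarachnoid CSF.
#'
#' @param csf_prob 3-D CSF probability array in \[0, 1\].
#' @param t1 `t1_map` or array (ms).
#' @param t2star `t2star_map` or array (ms).
#' @param rule A [normalization_rule()].
#' @param affine 4x4 affine (0-based voxel index to world mm), required
#'   when the rule carries an ellipsoid; defaults to identity.
#'
#' @return Logical 3-D array.  Errors if the mask is empty, since
#'   calibration would then be impossible.
#' @export
csf_normalization_mask <- function(csf_prob, t1, t2star,
                                   rule = normalization_rule(),
                                   affine = diag(4)) {
  t1v <- if (inherits(t1, "t1_map")) t1$t1 else t1
  t2s <- if (inherits(t2star, "t2star_map")) t2star$t2star else t2star
  dm <- dim(csf_prob)
  stopifnot(identical(dim(t1v), dm), identical(dim(t2s), dm))
  mask <- csf_prob >= rule$csf_prob_min &
    !is.na(t1v) & t1v > rule$t1_min &
    !is.na(t2s) & t2s > rule$t2star_min
  if (!is.null(rule$ellipsoid)) {
    i <- slice.index(array(0, dm), 1) - 1
    j <- slice.index(array(0, dm), 2) - 1
    k <- slice.index(array(0, dm), 3) - 1
    wx <- affine[1, 1] * i + affine[1, 2] * j + affine[1, 3] * k + affine[1, 4]
    wy <- affine[2, 1] * i + affine[2, 2] * j + affine[2, 3] * k + affine[2, 4]
    wz <- affine[3, 1] * i + affine[3, 2] * j + affine[3, 3] * k + affine[3, 4]
    ell <- rule$ellipsoid
    inside <- ((wx - ell$centre[1]) / ell$semi_axes[1])^2 +
      ((wy - ell$centre[2]) / ell$semi_axes[2])^2 +
      ((wz - ell$centre[3]) / ell$semi_axes[3])^2 <= 1
    mask <- mask & inside
  }
  if (!any(mask))
    stop("empty normalisation mask: no voxel satisfies the CSF rule")
  mask
}

#' Calibrate a corrected M0 map to percent water
#'
#' The mean corrected M0 over the normalisation region (ventricular CSF,
#' approximately 100% MR-visible water) defines the scalar calibration
#' \eqn{C_{norm} = 100 / \overline{M_0}}, and \eqn{H_2O = C_{norm} M_0}.
#' By construction the mean water content over the mask is exactly 100%.
#'
#' @param m0 A fully corrected `m0_map`.
#' @param norm_mask Logical 3-D array (e.g. from
#'   [csf_normalization_mask()], or a reference compartment of a phantom).
#'
#' @return Object of class `h2o_map`: list with `h2o` (%), scalar
#'   `c_norm` and `norm_mask`.
#' @export
normalize_h2o <- function(m0, norm_mask) {
  m0v <- if (inherits(m0, "m0_map")) m0$m0 else m0
  stopifnot(identical(dim(norm_mask), dim(m0v)))
  sel <- norm_mask & is.finite(m0v)
  if (!any(sel)) stop("empty normalisation mask")
  ref <- mean(m0v[sel])
  if (ref <= 0) stop("non-positive mean M0 over the normalisation mask")
  c_norm <- 100 / ref
  structure(list(h2o = c_norm * m0v, c_norm = c_norm, norm_mask = norm_mask),
            class = "h2o_map")
}

#' Water content from a fully relaxed long-TR acquisition
#'
#' Reference (gold standard style) water mapping: with TR much longer
#' than any tissue T1 and a 90-degree excitation, the signal needs no
#' T1 or transmit-field correction.  The TE = 0 amplitude is obtained by
#' T2* extrapolation ([fit_t2star()]), optionally corrected for the
#' receive field, and calibrated exactly as [normalize_h2o()].
#'
#' @param echoes `echo_train` of the long-TR acquisition.
#' @param norm_mask Logical normalisation region.
#' @param b1minus Optional 3-D receive field.
#' @param te_max Optional `field_gradient_map` echo cutoff.
#' @param t1_longest Longest tissue T1 (ms) used for the full-relaxation
#'   check; a warning is issued when `TR < 5 * t1_longest`.
#'
#' @return An `h2o_map`.
#' @export
h2o_long_tr <- function(echoes, norm_mask, b1minus = NULL, te_max = NULL,
                        t1_longest = 2000) {
  stopifnot(inherits(echoes, "echo_train"))
  if (echoes$protocol$tr < 5 * t1_longest)
    warning(sprintf("TR = %g ms is below 5 x %g ms: saturation bias expected",
                    echoes$protocol$tr, t1_longest))
  fit <- fit_t2star(echoes, te_max = te_max)
  m0 <- fit$s0
  m0[!fit$valid] <- NA_real_
  if (!is.null(b1minus)) {
    stopifnot(identical(dim(b1minus), dim(m0)))
    m0 <- m0 / ifelse(b1minus > 0, b1minus, NA_real_)
  }
  normalize_h2o(m0, norm_mask)
}

#' First-order propagation of a T1 bias into water content
#'
#' Water content scales with the inverse of the T1/B1+/flip saturation
#' factor, so a T1 error \eqn{\delta T_1} produces a relative water error
#' \deqn{\frac{\delta H_2O}{H_2O} =
#'   \left| \frac{\partial \ln C_{T_1,\alpha}}{\partial T_1} \right|
#'   \delta T_1
#'   = \left| \left( \frac{\cos\alpha}{1 - E\cos\alpha} -
#'     \frac{1}{1 - E} \right) \frac{TR}{T_1^2} E \right| \delta T_1,}
#' evaluated analytically from the signal model (\eqn{E = e^{-TR/T_1}}).
#'
#' @param t1 True T1 (ms).
#' @param delta_t1 T1 bias (ms).
#' @param flip_eff Effective flip angle (degrees).
#' @param tr Repetition time (ms).
#'
#' @return Relative water-content error as a fraction (vectorised).
#' @export
#' @examples
#' propagate_t1_error(1000, 50, flip_eff = 7, tr = 50)
propagate_t1_error <- function(t1, delta_t1, flip_eff, tr) {
  if (any(t1 <= 0) || any(tr <= 0)) stop("t1 and tr must be positive")
  if (any(delta_t1 < 0)) stop("delta_t1 must be non-negative")
  a <- flip_eff * pi / 180
  e <- exp(-tr / t1)
  dlnc <- (cos(a) / (1 - e * cos(a)) - 1 / (1 - e)) * e * tr / t1^2
  abs(dlnc) * delta_t1
}
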