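# Vectorised objective of the two-point T1 fit.  Because the T1/B1/flip
# correction factor is echo-independent, the summed squared difference
# over the first N echoes collapses to
#   f(T1) = A/C1^2 - 2 B/(C1 C2) + D/C2^2
# with per-voxel echo sums A = sum S1^2, B = sum S1 S2, D = sum S2^2.
.t1_objective <- function(t1, a1_rad, a2_rad, tr, A, B, D) {
  e <- exp(-tr / t1)
  c1 <- sin(a1_rad) * (1 - e) / (1 - e * cos(a1_rad))
  c2 <- sin(a2_rad) * (1 - e) / (1 - e * cos(a2_rad))
  A / c1^2 - 2 * B / (c1 * c2) + D / c2^2
}

#' Two-point T1 map from a pair of flip-angle acquisitions
#'
#' Estimates T1 per voxel by minimising, over T1, the summed squared
#' difference between the two acquisitions after each is divided by its
#' T1/B1+/flip correction factor:
#' \deqn{T_1 = \arg\min_{T_1} \sum_{n=1}^{N}
#'   \left| \frac{S_{\alpha_1}(TE_n)}{C_{T_1,B_1^+,\alpha_1}} -
#'          \frac{S_{\alpha_2}(TE_n)}{C_{T_1,B_1^+,\alpha_2}} \right|^2 .}
#' Both acquisitions must share TR and echo times, so the residual T2*
#' weighting is identical and cancels from the comparison.  Only the
#' first `n_echoes` echoes (default 3) enter the fit: they carry the
#' highest SNR and are least affected by field-inhomogeneity signal loss.
#'
#' The minimisation is a bracketed scalar search on `[t1_range[1],
#' t1_max]`: a coarse log-spaced grid locates the basin, golden-section
#' refines it to `tol` ms.  Estimates at the upper bound are clipped to
#' `t1_max` and flagged.
#'
#' @param low,high `echo_train` objects for the low and high flip angle.
#' @param b1plus A `b1_map`, or a 3-D array of relative transmit field.
#' @param n_echoes Number of leading echoes in the fit.
#' @param t1_range Search interval in ms (upper end = clip bound).
#' @param tol Absolute solver tolerance (ms).
#'
#' @return Object of class `t1_map`: list with `t1` (ms), `residual`
#'   (objective value at the optimum), logical `clipped` and `valid`.
#' @export
fit_t1_two_point <- function(low, high, b1plus, n_echoes = 3,
                             t1_range = c(1, 6000), tol = 0.01) {
  stopifnot(inherits(low, "echo_train"), inherits(high, "echo_train"))
  if (!isTRUE(all.equal(low$protocol$te, high$protocol$te)))
    stop("the two acquisitions must share the same echo times")
  if (!isTRUE(all.equal(low$protocol$tr, high$protocol$tr)))
    stop("the two acquisitions must share the same TR")
  dm <- dim(low$magnitude)[1:3]
  if (!identical(dim(high$magnitude)[1:3], dm))
    stop("acquisition grids differ")
  b1 <- if (inherits(b1plus, "b1_map")) b1plus$b1plus else b1plus
  if (length(b1) == 1L) b1 <- array(b1, dm)
  stopifnot(identical(dim(b1), dm))
  ne <- min(n_echoes, low$protocol$n_echoes)
  tr <- low$protocol$tr
  nv <- prod(dm)

  s1 <- matrix(low$magnitude[, , , seq_len(ne)], nv, ne)
  s2 <- matrix(high$magnitude[, , , seq_len(ne)], nv, ne)
  A <- rowSums(s1^2); B <- rowSums(s1 * s2); D <- rowSums(s2^2)
  a1 <- as.vector(b1) * low$protocol$flip_nominal * pi / 180
  a2 <- as.vector(b1) * high$protocol$flip_nominal * pi / 180
  valid <- (A + D) > 0 & is.finite(A + B + D) & is.finite(a1) & a1 > 0

  t1_lo <- t1_range[1]; t1_hi <- t1_range[2]
  grid <- exp(seq(log(t1_lo), log(t1_hi), length.out = 120L))
  best_val <- rep(Inf, nv); best_idx <- rep(1L, nv)
  for (g in seq_along(grid)) {
    f <- .t1_objective(grid[g], a1, a2, tr, A, B, D)
    better <- !is.na(f) & f < best_val
    best_val[better] <- f[better]
    best_idx[better] <- g
  }
  lo <- grid[pmax(best_idx - 1L, 1L)]
  hi <- grid[pmin(best_idx + 1L, length(grid))]
  gr <- (sqrt(5) - 1) / 2
  n_iter <- ceiling(log(tol / max(hi - lo)) / log(gr))
  for (it in seq_len(max(n_iter, 1L))) {
    x1 <- hi - gr * (hi - lo)
    x2 <- lo + gr * (hi - lo)
    f1 <- .t1_objective(x1, a1, a2, tr, A, B, D)
    f2 <- .t1_objective(x2, a1, a2, tr, A, B, D)
    take_lower <- f1 < f2
    hi <- ifelse(take_lower, x2, hi)
    lo <- ifelse(take_lower, lo, x1)
  }
  t1 <- (lo + hi) / 2
  resid <- .t1_objective(t1, a1, a2, tr, A, B, D)
  t1 <- pmin(t1, t1_hi)
  clipped <- t1 >= t1_hi - 0.5
  t1[!is.na(clipped) & clipped] <- t1_hi
  t1[!valid] <- NA_real_
  resid[!valid] <- NA_real_
  clipped <- clipped & valid
  dim(t1) <- dm; dim(resid) <- dm; dim(clipped) <- dm
  valid_arr <- array(valid, dm)
  structure(list(t1 = t1, residual = resid, clipped = clipped,
                 valid = valid_arr),
            class = "t1_map")
}

.wrap_phase <- function(x) atan2(sin(x), cos(x))

#' Off-resonance field map from multi-echo phase
#'
#' Estimates the local off-resonance frequency per voxel from the echo
#' phase evolution.  The initial estimate is the wrapped phase difference
#' of the first two echoes, \eqn{\Delta f = \Delta\varphi / (2\pi\,
#' \Delta TE)}.  When more echoes are available, integer-cycle ambiguities
#' of that first difference are resolved by scoring candidate wrap counts
#' against the phase increments of all later echoes (effective only when
#' later echo spacings differ from the first; for uniformly spaced echoes
#' all candidates fit equally and the principal value is kept).  The
#' phase train is then temporally unwrapped against the winning candidate
#' and the frequency re-estimated by a least-squares line through all
#' echoes.
#'
#' @param echoes An `echo_train` with phase volumes for at least 2 echoes.
#' @param n_wrap_search Candidate wrap counts `-k..k` to score.
#'
#' @return Object of class `field_gradient_map` with `delta_f` (Hz);
#'   `grad_magnitude` and `te_max` are filled in by [compute_te_max()].
#' @export
fieldmap_from_phase <- function(echoes, n_wrap_search = 2L) {
  stopifnot(inherits(echoes, "echo_train"))
  if (is.null(echoes$phase))
    stop("no phase volumes present; supply an external field map instead")
  te <- echoes$protocol$te
  ne <- length(te)
  if (ne < 2L) stop("at least two echoes are required for a field map")
  dm <- dim(echoes$phase)[1:3]
  nv <- prod(dm)
  ph <- matrix(echoes$phase, nv, ne)
  dte1 <- te[2] - te[1]
  f0 <- .wrap_phase(ph[, 2] - ph[, 1]) / (2 * pi * dte1) * 1000   # Hz

  ks <- -n_wrap_search:n_wrap_search
  if (ne >= 3L && length(ks) > 1L) {
    score <- matrix(0, nv, length(ks))
    for (j in seq_along(ks)) {
      fk <- f0 + ks[j] * 1000 / dte1
      for (n in 2:ne) {
        pred <- 2 * pi * fk * (te[n] - te[n - 1]) / 1000
        score[, j] <- score[, j] +
          .wrap_phase(ph[, n] - ph[, n - 1] - pred)^2
      }
    }
    # ties (uniform spacing) resolve to the smallest |k|, i.e. k = 0
    ord <- order(abs(ks))
    best <- ord[max.col(-score[, ord, drop = FALSE], ties.method = "first")]
    f_best <- f0 + ks[best] * 1000 / dte1
  } else {
    f_best <- f0
  }

  # temporal unwrapping against the current estimate, then LS refit
  unw <- matrix(0, nv, ne)
  unw[, 1] <- ph[, 1]
  for (n in 2:ne) {
    pred <- 2 * pi * f_best * (te[n] - te[n - 1]) / 1000
    unw[, n] <- unw[, n - 1] + pred +
      .wrap_phase(ph[, n] - ph[, n - 1] - pred)
  }
  tec <- te - mean(te)
  slope <- (unw %*% tec) / sum(tec^2)          # rad per ms
  delta_f <- as.vector(slope) * 1000 / (2 * pi)
  dim(delta_f) <- dm
  structure(list(delta_f = delta_f, grad_magnitude = NULL, te_max = NULL,
                 voxel_size = echoes$voxel_size),
            class = "field_gradient_map")
}

#' Voxel-wise echo-time limit from the local field gradient
#'
#' Strong macroscopic field gradients make the late-echo signal deviate
#' from mono-exponential decay.  The decay fit is therefore truncated at
#' the echo time where the accumulated phase dispersion across a voxel
#' reaches `q_threshold` cycles: with per-axis across-voxel frequency
#' differences \eqn{g_i d_i} (Hz) combined in quadrature to \eqn{G},
#' \deqn{TE_{max} = 1000\, q / G \;\mathrm{ms},}
#' infinite where the gradient vanishes.
#'
#' @param field A `field_gradient_map` holding `delta_f`.
#' @param voxel_size Length-3 voxel dimensions (mm); defaults to the
#'   field map's.
#' @param q_threshold Dispersion threshold in cycles (default 0.5, half
#'   the first zero of the sinc attenuation).
#'
#' @return The `field_gradient_map` with `grad_magnitude` (Hz/mm) and
#'   `te_max` (ms) filled in.
#' @export
compute_te_max <- function(field, voxel_size = field$voxel_size,
                           q_threshold = 0.5) {
  stopifnot(inherits(field, "field_gradient_map"), q_threshold > 0,
            length(voxel_size) == 3L)
  g <- .grad_per_voxel(field$delta_f)          # Hz per voxel
  gd2 <- g[[1]]^2 + g[[2]]^2 + g[[3]]^2        # (Hz across voxel)^2
  grad_mm <- sqrt(g[[1]]^2 / voxel_size[1]^2 +
                  g[[2]]^2 / voxel_size[2]^2 +
                  g[[3]]^2 / voxel_size[3]^2)  # Hz/mm
  gd <- sqrt(gd2)
  te_max <- ifelse(gd > 0, 1000 * q_threshold / gd, Inf)
  field$grad_magnitude <- grad_mm
  field$te_max <- te_max
  field
}

#' Weighted log-linear T2* fit with echo-time cutoff
#'
#' Closed-form weighted least squares of `ln S` on TE with weights
#' `|S(TE_n)|`, so early high-SNR echoes dominate and the
#' log-transformation's noise distortion is counteracted.  Per voxel only
#' echoes with `TE_n < TE_max` are eligible; the first `min_echoes`
#' echoes are always included (flagged in `floor_used`) so every voxel
#' retains a fit.  Returns the extrapolated TE = 0 amplitude `s0` and
#' `t2star = -1/slope`; non-decaying voxels and estimates above
#' `t2star_max` are clipped to `t2star_max` and flagged.
#'
#' @param echoes An `echo_train`.
#' @param te_max A `field_gradient_map` with `te_max` filled in, or
#'   `NULL` to use all echoes.
#' @param min_echoes Minimum leading-echo floor.
#' @param t2star_max Clip bound (ms).
#'
#' @return Object of class `t2star_map`: list with `t2star`, `s0`,
#'   `n_echoes_used`, logical `clipped`, `floor_used` and `valid`.
#' @export
fit_t2star <- function(echoes, te_max = NULL, min_echoes = 3,
                       t2star_max = 1500) {
  stopifnot(inherits(echoes, "echo_train"))
  te <- echoes$protocol$te
  ne <- length(te)
  if (ne < 2L) stop("at least two echoes are required")
  min_echoes <- min(min_echoes, ne)
  dm <- dim(echoes$magnitude)[1:3]
  nv <- prod(dm)
  s <- matrix(echoes$magnitude, nv, ne)

  if (!is.null(te_max)) {
    tm <- if (inherits(te_max, "field_gradient_map")) te_max$te_max else te_max
    stopifnot(identical(dim(tm), dm))
    elig <- outer(as.vector(tm), te, `>`)     # TE_n < TE_max
    floor_used <- rowSums(elig[, seq_len(min_echoes), drop = FALSE]) < min_echoes
    elig[, seq_len(min_echoes)] <- TRUE       # minimum-echo floor
  } else {
    elig <- matrix(TRUE, nv, ne)
    floor_used <- rep(FALSE, nv)
  }
  pos <- s > 0
  w <- abs(s) * (elig & pos)
  y <- log(pmax(s, .Machine$double.xmin))

  W   <- rowSums(w)
  Sx  <- w %*% te
  Sy  <- rowSums(w * y)
  Sxx <- w %*% te^2
  Sxy <- rowSums(w * y * rep(te, each = nv))
  den <- W * Sxx - Sx^2
  n_used <- rowSums(w > 0)
  valid <- n_used >= 2 & den > .Machine$double.eps * W^2 * max(te)^2
  slope <- ifelse(valid, (W * Sxy - Sx * Sy) / den, NA_real_)
  icpt  <- ifelse(valid, (Sy - slope * Sx) / W, NA_real_)
  s0 <- exp(icpt)
  t2star <- ifelse(slope < 0, -1 / slope, Inf)
  clipped <- valid & t2star > t2star_max
  t2star[clipped] <- t2star_max
  t2star[!valid] <- NA_real_
  dim(t2star) <- dm; dim(s0) <- dm; dim(clipped) <- dm
  n_used_arr <- array(as.integer(n_used), dm)
  structure(list(t2star = t2star, s0 = array(as.vector(s0), dm),
                 n_echoes_used = n_used_arr,
                 clipped = array(as.vector(clipped), dm),
                 floor_used = array(floor_used, dm),
                 valid = array(valid, dm)),
            class = "t2star_map")
}
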