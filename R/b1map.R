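#' Closed-form flip-angle map from an AFI acquisition
#'
#' Inverts the short-TR approximation of the AFI steady state,
#' \deqn{\alpha_{eff} \approx \arccos\frac{r n - 1}{n - r},}
#' with \eqn{r = S_2/S_1} and \eqn{n = TR_2/TR_1}.  The arccos argument is
#' clamped to \[-1, 1\]; voxels whose argument exceeded the bounds by more
#' than `clamp_tol` (i.e. beyond what noise plausibly explains) or whose
#' `S1` is non-positive are flagged invalid rather than raising an error.
#'
#' @param afi_pair An `afi_pair` (see [simulate_afi()]) or any list with
#'   arrays `s1`, `s2` and an [afi_protocol()] in `protocol`.
#' @param clamp_tol Silent clamping tolerance on the arccos argument.
#'
#' @return Object of class `flip_angle_map`: list with `alpha_eff`
#'   (degrees) and logical `valid`.
#' @export
afi_flip_angle <- function(afi_pair, clamp_tol = 1e-3) {
  s1 <- afi_pair$s1; s2 <- afi_pair$s2
  n <- afi_pair$protocol$n_ratio
  valid <- is.finite(s1) & is.finite(s2) & s1 > 0
  r <- ifelse(valid, s2 / s1, NA_real_)
  arg <- (r * n - 1) / (n - r)
  excess <- pmax(abs(arg) - 1, 0)
  valid <- valid & !is.na(arg) & excess <= clamp_tol
  arg <- pmin(pmax(arg, -1), 1)
  alpha <- acos(arg) * 180 / pi
  alpha[!valid] <- NA_real_
  dim(alpha) <- dim(s1); dim(valid) <- dim(s1)
  structure(list(alpha_eff = alpha, valid = valid,
                 protocol = afi_pair$protocol),
            class = "flip_angle_map")
}

#' Iterative refinement of the AFI flip-angle map
#'
#' The closed-form inversion assumes TR1, TR2 much smaller than T1 and
#' carries a bias of order a few percent at tissue T1.  This refinement
#' solves, per voxel, the exact two-TR steady-state ratio equation
#' `afi_ratio(t1_assumed, alpha) = r_measured` for the flip angle by
#' bisection (the ratio is monotone decreasing in the flip angle),
#' initialised and bracketed around the closed-form map.  A nominal T1
#' must be assumed; the residual error for a mismatched T1 is small
#' because the ratio depends on T1 only weakly.
#'
#' @param alpha0 A `flip_angle_map` from [afi_flip_angle()].
#' @param afi_pair The AFI acquisition the map came from.
#' @param t1_assumed Assumed T1 (ms), default 1000.
#' @param tol Convergence tolerance on the flip angle (degrees).
#' @param max_iter Maximum bisection iterations.
#'
#' @return A `flip_angle_map`; voxels that failed to bracket or converge
#'   keep their closed-form value and are flagged in `converged`.
#' @export
afi_refine <- function(alpha0, afi_pair, t1_assumed = 1000,
                       tol = 0.01, max_iter = 60L) {
  stopifnot(inherits(alpha0, "flip_angle_map"), t1_assumed > 0)
  afi <- afi_pair$protocol
  s1 <- afi_pair$s1; s2 <- afi_pair$s2
  valid <- alpha0$valid & s1 > 0
  r_meas <- s2 / s1
  idx <- which(valid)
  alpha <- alpha0$alpha_eff
  converged <- array(FALSE, dim(alpha))
  if (length(idx)) {
    r <- r_meas[idx]
    lo <- rep(1e-4, length(idx))
    hi <- rep(179.9, length(idx))
    f_lo <- afi_ratio(t1_assumed, lo, afi) - r
    f_hi <- afi_ratio(t1_assumed, hi, afi) - r
    ok <- f_lo >= 0 & f_hi <= 0          # monotone decreasing bracket
    for (it in seq_len(max_iter)) {
      if (max(hi - lo) < tol) break
      mid <- (lo + hi) / 2
      f_mid <- afi_ratio(t1_assumed, mid, afi) - r
      take_upper <- f_mid < 0
      hi <- ifelse(ok & take_upper, mid, hi)
      lo <- ifelse(ok & !take_upper, mid, lo)
    }
    est <- (lo + hi) / 2
    done <- ok & (hi - lo) < tol
    alpha[idx[done]] <- est[done]
    converged[idx[done]] <- TRUE
  }
  structure(list(alpha_eff = alpha, valid = valid, converged = converged,
                 protocol = afi),
            class = "flip_angle_map")
}

#' Calibrate a flip-angle map to the relative transmit field
#'
#' @param alpha A `flip_angle_map`.
#' @param flip_nominal Nominal flip angle (degrees); defaults to the one
#'   stored in the map's protocol.
#'
#' @return Object of class `b1_map`: list with `b1plus` and `valid`.
#'   Warns when valid values fall outside \[0.5, 1.5\], the plausible
#'   transmit-field range for the human head at 3 T.
#' @export
b1plus_calibrate <- function(alpha, flip_nominal = alpha$protocol$flip_nominal) {
  stopifnot(inherits(alpha, "flip_angle_map"), flip_nominal > 0)
  b1 <- alpha$alpha_eff / flip_nominal
  v <- alpha$valid & is.finite(b1) & b1 > 0
  rng <- range(b1[v])
  if (length(rng) == 2 && (rng[1] < 0.5 || rng[2] > 1.5))
    warning(sprintf("B1+ outside [0.5, 1.5] (range %.2f..%.2f)",
                    rng[1], rng[2]))
  structure(list(b1plus = b1, valid = v), class = "b1_map")
}

#' 3-D median filter
#'
#' Box median filter of radius `radius` voxels (window `(2r+1)^3`) with
#' edge replication; `NA` values are ignored within each window.  Used to
#' regularise B1+ maps, which are physically smooth, before resampling.
#'
#' @param x 3-D array.
#' @param radius Window radius in voxels.
#' @return Filtered array of the same shape.
#' @export
median_filter3d <- function(x, radius = 1L) {
  stopifnot(length(dim(x)) == 3L, radius >= 0L)
  if (radius == 0L) return(x)
  dm <- dim(x)
  offs <- expand.grid(dx = -radius:radius, dy = -radius:radius,
                      dz = -radius:radius)
  n_off <- nrow(offs)
  stacked <- matrix(NA_real_, length(x), n_off)
  for (k in seq_len(n_off)) {
    ix <- pmin(pmax(seq_len(dm[1]) + offs$dx[k], 1L), dm[1])
    iy <- pmin(pmax(seq_len(dm[2]) + offs$dy[k], 1L), dm[2])
    iz <- pmin(pmax(seq_len(dm[3]) + offs$dz[k], 1L), dm[3])
    stacked[, k] <- x[ix, iy, iz]
  }
  out <- apply(stacked, 1L, stats::median, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  dim(out) <- dm
  out
}

#' Trilinear resampling onto a target grid
#'
#' Maps each target voxel centre to world coordinates through the target
#' affine, back into source voxel coordinates through the inverse source
#' affine, and interpolates trilinearly.  Target voxels falling outside
#' the source extent are returned as `NA` and flagged in the `valid`
#' attribute.  Affine transforms reproduce affine functions exactly, so a
#' linear ramp survives any up/downsampling unchanged.
#'
#' @param x 3-D source array.
#' @param src_affine 4x4 affine mapping 0-based source indices to world mm.
#' @param target_dim Length-3 target grid shape.
#' @param target_affine 4x4 affine of the target grid.
#'
#' @return 3-D array of shape `target_dim` with attribute `valid`
#'   (logical array marking voxels inside the source extent).
#' @export
resample_to_grid <- function(x, src_affine, target_dim, target_affine) {
  stopifnot(length(dim(x)) == 3L, length(target_dim) == 3L,
            all(dim(src_affine) == c(4, 4)), all(dim(target_affine) == c(4, 4)))
  dm <- dim(x)
  i <- slice.index(array(0, target_dim), 1) - 1
  j <- slice.index(array(0, target_dim), 2) - 1
  k <- slice.index(array(0, target_dim), 3) - 1
  m <- solve(src_affine) %*% target_affine
  sx <- m[1, 1] * i + m[1, 2] * j + m[1, 3] * k + m[1, 4]
  sy <- m[2, 1] * i + m[2, 2] * j + m[2, 3] * k + m[2, 4]
  sz <- m[3, 1] * i + m[3, 2] * j + m[3, 3] * k + m[3, 4]
  inside <- sx >= 0 & sx <= dm[1] - 1 &
            sy >= 0 & sy <= dm[2] - 1 &
            sz >= 0 & sz <= dm[3] - 1
  x0 <- pmin(pmax(floor(sx), 0), dm[1] - 2); fx <- sx - x0
  y0 <- pmin(pmax(floor(sy), 0), dm[2] - 2); fy <- sy - y0
  z0 <- pmin(pmax(floor(sz), 0), dm[3] - 2); fz <- sz - z0
  if (dm[1] < 2 || dm[2] < 2 || dm[3] < 2)
    stop("source grid must have at least 2 voxels per axis")
  at <- function(dx, dy, dz)
    x[cbind(as.vector(x0 + dx + 1), as.vector(y0 + dy + 1),
            as.vector(z0 + dz + 1))]
  out <- (1 - fx) * (1 - fy) * (1 - fz) * at(0, 0, 0) +
         fx * (1 - fy) * (1 - fz) * at(1, 0, 0) +
         (1 - fx) * fy * (1 - fz) * at(0, 1, 0) +
         (1 - fx) * (1 - fy) * fz * at(0, 0, 1) +
         fx * fy * (1 - fz) * at(1, 1, 0) +
         fx * (1 - fy) * fz * at(1, 0, 1) +
         (1 - fx) * fy * fz * at(0, 1, 1) +
         fx * fy * fz * at(1, 1, 1)
  out[!inside] <- NA_real_
  dim(out) <- target_dim
  attr(out, "valid") <- inside
  out
}
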