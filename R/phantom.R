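#' Multi-echo acquisition container
#'
#' Bundles a 4-D magnitude volume (x, y, z, echo), an optional phase
#' volume, the acquisition protocol and the grid geometry.
#'
#' @param magnitude 4-D non-negative array; the echo dimension must match
#'   the protocol's echo count.
#' @param protocol An [acq_protocol()].
#' @param phase Optional 4-D phase array (radians), same shape.
#' @param voxel_size Length-3 voxel dimensions (mm).
#' @param affine 4x4 affine (0-based voxel index to world mm).
#'
#' @return Object of class `echo_train`.
#' @export
echo_train <- function(magnitude, protocol, phase = NULL,
                       voxel_size = c(1, 1, 1), affine = diag(4)) {
  stopifnot(inherits(protocol, "acq_protocol"),
            length(dim(magnitude)) == 4L)
  if (dim(magnitude)[4] != protocol$n_echoes)
    stop("echo dimension does not match the protocol's echo count")
  if (any(magnitude < 0, na.rm = TRUE))
    stop("magnitude must be non-negative")
  if (!is.null(phase)) stopifnot(identical(dim(phase), dim(magnitude)))
  structure(list(magnitude = magnitude, phase = phase, protocol = protocol,
                 voxel_size = voxel_size, affine = affine),
            class = "echo_train")
}

#' AFI acquisition container
#'
#' @param s1,s2 3-D steady-state volumes acquired with TR1 and TR2.
#' @param protocol An [afi_protocol()].
#' @param voxel_size Length-3 voxel dimensions (mm).
#' @param affine 4x4 affine.
#' @return Object of class `afi_pair`.
#' @export
afi_pair <- function(s1, s2, protocol = afi_protocol(),
                     voxel_size = c(1, 1, 1), affine = diag(4)) {
  stopifnot(inherits(protocol, "afi_protocol"),
            identical(dim(s1), dim(s2)), length(dim(s1)) == 3L)
  structure(list(s1 = s1, s2 = s2, protocol = protocol,
                 voxel_size = voxel_size, affine = affine),
            class = "afi_pair")
}

#' Digital phantom specification
#'
#' Per-voxel ground truth for the forward simulator: water content (% of
#' pure water), T1 and T2* (ms), relative transmit (B1+) and receive
#' (B1-) fields, optional off-resonance field (Hz), voxel size, noise
#' level and seed.  Scalar inputs are expanded to the grid.
#'
#' @param h2o Water content array (%), in \[0, 100\]; doubles as the
#'   magnetisation density M0 of the simulator (arbitrary units = %).
#' @param t1,t2star Relaxation time arrays (ms), positive everywhere
#'   (background voxels carry a positive dummy value and zero `h2o`).
#' @param b1plus,b1minus Relative field arrays, positive.
#' @param delta_f Optional off-resonance field (Hz); enables phase
#'   simulation and intravoxel-dephasing attenuation.
#' @param voxel_size Length-3 voxel dimensions (mm).
#' @param noise_sigma Complex-noise standard deviation (signal units).
#' @param seed Integer RNG seed for the simulator.
#' @param labels Optional integer array of compartment labels.
#' @param extra Optional list of additional components (class
#'   probabilities, masks, ellipsoid definitions ...) kept verbatim.
#'
#' @return Object of class `mri_phantom`.
#' @export
phantom_spec <- function(h2o, t1, t2star, b1plus = 1, b1minus = 1,
                         delta_f = NULL, voxel_size = c(1, 1, 1),
                         noise_sigma = 0, seed = NULL, labels = NULL,
                         extra = list()) {
  dm <- dim(h2o)
  if (is.null(dm) || length(dm) != 3L)
    stop("h2o must be a 3-D array")
  expand <- function(x, name) {
    if (length(x) == 1L) x <- array(x, dim = dm)
    if (!identical(dim(x), dm))
      stop(sprintf("%s does not match the phantom grid", name))
    x
  }
  t1 <- expand(t1, "t1"); t2star <- expand(t2star, "t2star")
  b1plus <- expand(b1plus, "b1plus"); b1minus <- expand(b1minus, "b1minus")
  if (!is.null(delta_f)) delta_f <- expand(delta_f, "delta_f")
  if (any(h2o < 0) || any(h2o > 100)) stop("h2o must lie in [0, 100]")
  if (any(t1 <= 0) || any(t2star <= 0)) stop("relaxation times must be positive")
  if (any(b1plus <= 0) || any(b1minus <= 0)) stop("B1 fields must be positive")
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0), noise_sigma >= 0)
  structure(c(list(h2o = h2o, t1 = t1, t2star = t2star, b1plus = b1plus,
                   b1minus = b1minus, delta_f = delta_f,
                   voxel_size = voxel_size, noise_sigma = noise_sigma,
                   seed = seed, labels = labels, dim = dm),
              extra),
            class = "mri_phantom")
}

#' @export
print.mri_phantom <- function(x, ...) {
  cat(sprintf("Digital phantom %s, voxel %s mm, sigma = %g\n",
              paste(x$dim, collapse = "x"),
              paste(x$voxel_size, collapse = "x"), x$noise_sigma))
  invisible(x)
}

#' Affine of a phantom grid (voxel indices to world mm)
#'
#' World coordinates place the centre of the grid at the origin; axes are
#' scaled by the voxel size.
#' @param phantom An `mri_phantom` (or any list with `dim`, `voxel_size`).
#' @return A 4x4 affine matrix mapping 0-based voxel indices to mm.
#' @export
phantom_affine <- function(phantom) {
  aff <- diag(4)
  diag(aff)[1:3] <- phantom$voxel_size
  aff[1:3, 4] <- -phantom$voxel_size * (phantom$dim - 1) / 2
  aff
}

#' Multi-tube water/relaxation phantom
#'
#' Eight (by default) parallel cylindrical tubes on a signal-free
#' background, each with its own water content and T1, emulating a
#' physical H2O/D2O dilution phantom in which one tube holds 100% water
#' for calibration and T1 is shortened to tissue-like values by paramagnetic
#' doping.
#'
#' @param h2o_levels Water content per tube (%); one entry must be 100 if
#'   the phantom is to be used for calibration.
#' @param t1_levels T1 per tube (ms), same length as `h2o_levels`.
#' @param t2star Single T2* value shared by all tubes (ms).
#' @param dim Grid shape (length 3).
#' @param tube_radius Tube radius in voxels.
#' @param ring_radius Radius of the circle on which tube centres sit
#'   (voxels).
#' @param voxel_size Voxel dimensions (mm).
#' @param noise_sigma,seed Passed to [phantom_spec()].
#'
#' @return An `mri_phantom` whose `labels` array holds 0 for background
#'   and `1..n` for the tubes.
#' @export
#' @examples
#' ph <- make_tube_phantom()
#' table(ph$labels)
make_tube_phantom <- function(h2o_levels = c(50, 57, 64, 71, 79, 86, 93, 100),
                              t1_levels = c(400, 600, 800, 1000, 1200,
                                            1400, 1800, 2500),
                              t2star = 50, dim = c(48, 48, 12),
                              tube_radius = 5, ring_radius = 16,
                              voxel_size = c(2, 2, 4),
                              noise_sigma = 0, seed = NULL) {
  n <- length(h2o_levels)
  if (length(t1_levels) != n)
    stop("h2o_levels and t1_levels must have the same length")
  cx <- (dim[1] + 1) / 2; cy <- (dim[2] + 1) / 2
  ang <- 2 * pi * (seq_len(n) - 1) / n
  centres <- cbind(cx + ring_radius * cos(ang), cy + ring_radius * sin(ang))
  # disjointness: centre spacing must exceed one tube diameter
  if (n > 1) {
    dmin <- min(stats::dist(centres))
    if (dmin <= 2 * tube_radius)
      stop("tubes overlap: reduce tube_radius or enlarge ring_radius")
  }
  if (max(centres[, 1]) + tube_radius > dim[1] ||
      min(centres[, 1]) - tube_radius < 1 ||
      max(centres[, 2]) + tube_radius > dim[2] ||
      min(centres[, 2]) - tube_radius < 1)
    stop("tubes exceed the grid: enlarge dim")

  xi <- slice.index(array(0, dim), 1)
  yi <- slice.index(array(0, dim), 2)
  labels <- array(0L, dim)
  for (k in seq_len(n)) {
    inside <- (xi - centres[k, 1])^2 + (yi - centres[k, 2])^2 <= tube_radius^2
    labels[inside] <- k
  }
  h2o <- array(0, dim); t1 <- array(1000, dim); t2s <- array(t2star, dim)
  for (k in seq_len(n)) {
    h2o[labels == k] <- h2o_levels[k]
    t1[labels == k] <- t1_levels[k]
  }
  phantom_spec(h2o, t1, t2s, voxel_size = voxel_size,
               noise_sigma = noise_sigma, seed = seed, labels = labels,
               extra = list(h2o_levels = h2o_levels, t1_levels = t1_levels,
                            tube_radius = tube_radius, centres = centres))
}

# smooth low-order polynomial fields on [-1,1]^3 coordinates
.norm_coords <- function(dim) {
  u <- (slice.index(array(0, dim), 1) - 1) / (dim[1] - 1) * 2 - 1
  v <- (slice.index(array(0, dim), 2) - 1) / (dim[2] - 1) * 2 - 1
  w <- (slice.index(array(0, dim), 3) - 1) / (dim[3] - 1) * 2 - 1
  list(u = u, v = v, w = w)
}

.ellipsoid_mask <- function(dim, centre, semi_axes) {
  xi <- slice.index(array(0, dim), 1)
  yi <- slice.index(array(0, dim), 2)
  zi <- slice.index(array(0, dim), 3)
  ((xi - centre[1]) / semi_axes[1])^2 +
    ((yi - centre[2]) / semi_axes[2])^2 +
    ((zi - centre[3]) / semi_axes[3])^2 <= 1
}

#' Three-class digital brain phantom
#'
#' Piecewise-constant white matter / grey matter / cerebrospinal fluid
#' truth maps on nested ellipsoids: a CSF rim (subarachnoid space), a GM
#' shell, a WM core and two lateral-ventricle ellipsoids of CSF, overlaid
#' with smooth low-order polynomial transmit and receive fields and a
#' smooth off-resonance field.  Default tissue values are typical 3 T
#' brain values (WM H2O 69.9%, T1 988 ms, T2* 52 ms; GM 80.8%, 1580 ms,
#' 57 ms; CSF 100%, 4300 ms, 800 ms).
#'
#' @param dim Grid shape; default 64^3.
#' @param voxel_size Voxel dimensions in mm; default 3 mm isotropic so the
#'   grid spans a head-sized field of view.
#' @param tissue_values Named list `wm`, `gm`, `csf`, each a numeric
#'   vector `c(h2o, t1, t2star)`.
#' @param b1plus_amp Peak-to-centre relative amplitude of the transmit
#'   field (0 gives a constant field of 1).
#' @param b1minus_amp Maximum relative deviation of the receive field
#'   (order-4 polynomial; 0 gives 1).
#' @param delta_f_amp Amplitude of the off-resonance field (Hz); `NA`
#'   omits the field entirely (no phase, no dephasing).
#' @param noise_sigma,seed Passed to [phantom_spec()].
#'
#' @return An `mri_phantom` with extra components: `labels` (0 background,
#'   1 WM, 2 GM, 3 CSF), `class_probs` (list of WM/GM/CSF probability
#'   volumes), `brain_mask`, `ventricle_mask`, and `norm_ellipsoid` (the
#'   ventricle-enclosing ellipsoid as `centre`/`semi_axes` in world mm).
#' @export
make_brain_phantom <- function(dim = c(64, 64, 64), voxel_size = c(3, 3, 3),
                               tissue_values = list(
                                 wm  = c(h2o = 69.9, t1 = 988,  t2star = 52),
                                 gm  = c(h2o = 80.8, t1 = 1580, t2star = 57),
                                 csf = c(h2o = 100,  t1 = 4300, t2star = 800)),
                               b1plus_amp = 0.15, b1minus_amp = 0.2,
                               delta_f_amp = 30, noise_sigma = 0,
                               seed = NULL) {
  stopifnot(length(dim) == 3L, all(dim >= 16))
  for (cls in c("wm", "gm", "csf"))
    if (is.null(tissue_values[[cls]]) || length(tissue_values[[cls]]) != 3L)
      stop("tissue_values must contain wm, gm, csf triples (h2o, t1, t2star)")

  ctr <- (dim + 1) / 2
  head_ax <- 0.45 * dim; gm_ax <- 0.40 * dim; wm_ax <- 0.30 * dim
  head <- .ellipsoid_mask(dim, ctr, head_ax)
  gm_out <- .ellipsoid_mask(dim, ctr, gm_ax)
  wm_out <- .ellipsoid_mask(dim, ctr, wm_ax)
  vent_ax <- c(0.06, 0.14, 0.07) * dim
  voff <- c(0.08 * dim[1], 0, 0)
  vent <- .ellipsoid_mask(dim, ctr - voff, vent_ax) |
          .ellipsoid_mask(dim, ctr + voff, vent_ax)

  labels <- array(0L, dim)
  labels[head] <- 3L            # subarachnoid CSF rim
  labels[gm_out] <- 2L          # grey matter shell
  labels[wm_out] <- 1L          # white matter core
  labels[vent] <- 3L            # lateral ventricles (CSF)

  tv <- rbind(wm = tissue_values$wm, gm = tissue_values$gm,
              csf = tissue_values$csf)
  h2o <- array(0, dim); t1 <- array(1000, dim); t2s <- array(50, dim)
  for (k in 1:3) {
    sel <- labels == k
    h2o[sel] <- tv[k, 1]; t1[sel] <- tv[k, 2]; t2s[sel] <- tv[k, 3]
  }

  cc <- .norm_coords(dim)
  r2 <- (cc$u^2 + cc$v^2 + cc$w^2) / 3
  b1plus <- 1 + b1plus_amp * (1 - 2 * r2)          # peaks at the centre
  braw <- 0.35 * cc$u - 0.25 * cc$v + 0.3 * cc$w + 0.3 * cc$u * cc$v -
    0.25 * cc$w^2 + 0.2 * cc$u^2 * cc$v^2 - 0.15 * cc$v^3
  b1minus <- if (b1minus_amp > 0) 1 + b1minus_amp * braw / max(abs(braw)) else
    array(1, dim)
  delta_f <- if (is.na(delta_f_amp)) NULL else {
    fraw <- cc$u^2 - cc$v + 0.5 * cc$u * cc$w
    delta_f_amp * fraw / max(abs(fraw))
  }

  class_probs <- list(wm = array(as.numeric(labels == 1L), dim),
                      gm = array(as.numeric(labels == 2L), dim),
                      csf = array(as.numeric(labels == 3L), dim))
  aff <- diag(4); diag(aff)[1:3] <- voxel_size
  aff[1:3, 4] <- -voxel_size * (dim - 1) / 2
  # ventricle-enclosing ellipsoid in world coordinates (mm)
  norm_ellipsoid <- list(
    centre = as.numeric(aff %*% c(ctr - 1, 1))[1:3],
    semi_axes = (voff + vent_ax * 1.25) * voxel_size)

  phantom_spec(h2o, t1, t2s, b1plus = b1plus, b1minus = b1minus,
               delta_f = delta_f, voxel_size = voxel_size,
               noise_sigma = noise_sigma, seed = seed, labels = labels,
               extra = list(class_probs = class_probs,
                            brain_mask = labels > 0L,
                            ventricle_mask = vent,
                            norm_ellipsoid = norm_ellipsoid,
                            tissue_values = tissue_values))
}

# per-axis gradient in units of x per voxel: central differences in the
# interior, one-sided at the borders
.grad_per_voxel <- function(x) {
  dm <- dim(x)
  g <- vector("list", 3L)
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    xp <- aperm(x, perm)
    n <- dm[ax]
    idx_p <- pmin(seq_len(n) + 1L, n)
    idx_m <- pmax(seq_len(n) - 1L, 1L)
    # division recycles the span (2 interior, 1 at borders) along dim 1
    d <- (xp[idx_p, , , drop = FALSE] - xp[idx_m, , , drop = FALSE]) /
      (idx_p - idx_m)
    g[[ax]] <- aperm(d, order(perm))
  }
  g
}

#' Simulate a multi-echo gradient-echo acquisition of a phantom
#'
#' Evaluates the spoiled-GRE forward model voxel by voxel for every echo,
#' with effective flip angle `B1+ * flip_nominal` and receive weighting
#' `B1-`.  If the phantom defines an off-resonance field, echo phases
#' encode `2 * pi * delta_f * TE` and the magnitude is attenuated by the
#' intravoxel-dephasing factor `prod_axis |sinc(g_axis * TE)|`, where
#' `g_axis` is the across-voxel frequency difference (Hz) from the local
#' field gradient and sinc is the normalised sinc.  Complex Gaussian noise
#' of standard deviation `noise_sigma` is added before the magnitude is
#' taken (Rician magnitude statistics).
#'
#' @param phantom An `mri_phantom`.
#' @param protocol An [acq_protocol()].
#' @param noise_sigma Noise level; defaults to the phantom's.
#' @param seed RNG seed; defaults to the phantom's.
#' @param dephasing Logical; apply the sinc attenuation (only possible
#'   when the phantom defines `delta_f`).
#'
#' @return An object of class `echo_train`: list with 4-D `magnitude`,
#'   4-D `phase` (when `delta_f` is present), `protocol`, `voxel_size`
#'   and `affine`.
#' @export
simulate_megre <- function(phantom, protocol,
                           noise_sigma = phantom$noise_sigma,
                           seed = phantom$seed,
                           dephasing = !is.null(phantom$delta_f)) {
  stopifnot(inherits(phantom, "mri_phantom"), inherits(protocol, "acq_protocol"))
  dm <- phantom$dim
  ne <- protocol$n_echoes
  if (dephasing && is.null(phantom$delta_f))
    stop("dephasing requested but the phantom defines no delta_f field")
  flip_eff <- phantom$b1plus * protocol$flip_nominal
  mag <- array(0, c(dm, ne))
  has_phase <- !is.null(phantom$delta_f)
  ph <- if (has_phase) array(0, c(dm, ne)) else NULL
  att_g <- if (dephasing) {
    g <- .grad_per_voxel(phantom$delta_f)   # Hz per voxel, per axis
    lapply(g, abs)
  } else NULL
  sinc1 <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  for (n in seq_len(ne)) {
    te <- protocol$te[n]
    s <- spgr_signal(phantom$h2o, phantom$t1, phantom$t2star, te,
                     protocol$tr, flip_eff, phantom$b1minus)
    if (dephasing) {
      for (ax in 1:3) s <- s * abs(sinc1(att_g[[ax]] * te / 1000))
    }
    mag[, , , n] <- s
    if (has_phase) ph[, , , n] <- 2 * pi * phantom$delta_f * te / 1000
  }
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    noisy <- rician_noise(mag, noise_sigma, ph)
    mag <- noisy$magnitude
    if (has_phase) ph <- noisy$phase
  }
  structure(list(magnitude = mag, phase = ph, protocol = protocol,
                 voxel_size = phantom$voxel_size,
                 affine = phantom_affine(phantom)),
            class = "echo_train")
}

#' @export
print.echo_train <- function(x, ...) {
  dm <- dim(x$magnitude)
  cat(sprintf("Echo train %s, %d echoes%s\n",
              paste(dm[1:3], collapse = "x"), dm[4],
              if (is.null(x$phase)) "" else " (+phase)"))
  print(x$protocol)
  invisible(x)
}

#' Simulate an AFI acquisition of a phantom
#'
#' Exact two-TR steady-state signals per voxel (see [afi_signals()]) with
#' optional Rician noise; both volumes share one noise level.
#'
#' @param phantom An `mri_phantom`.
#' @param afi An [afi_protocol()].
#' @param noise_sigma Noise standard deviation (default: phantom's).
#' @param seed RNG seed (default: phantom's, offset so the noise is
#'   independent of a meGRE simulation from the same phantom).
#'
#' @return Object of class `afi_pair`: list with 3-D `s1`, `s2`, the
#'   `protocol`, `voxel_size` and `affine`.
#' @export
simulate_afi <- function(phantom, afi = afi_protocol(),
                         noise_sigma = phantom$noise_sigma,
                         seed = phantom$seed) {
  stopifnot(inherits(phantom, "mri_phantom"), inherits(afi, "afi_protocol"))
  flip_eff <- phantom$b1plus * afi$flip_nominal
  sig <- afi_signals(phantom$h2o, phantom$t1, flip_eff, afi, phantom$b1minus)
  s1 <- sig$s1; s2 <- sig$s2
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed + 1L)
    s1 <- rician_noise(s1, noise_sigma)$magnitude
    s2 <- rician_noise(s2, noise_sigma)$magnitude
  }
  structure(list(s1 = s1, s2 = s2, protocol = afi,
                 voxel_size = phantom$voxel_size,
                 affine = phantom_affine(phantom)),
            class = "afi_pair")
}
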