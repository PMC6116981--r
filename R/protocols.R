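#' Multi-echo gradient-echo acquisition protocol
#'
#' Describes one spoiled multi-echo gradient-recalled-echo (meGRE)
#' acquisition: repetition time, nominal excitation flip angle and the
#' echo-time train.  All times are in milliseconds, angles in degrees.
#'
#' @param tr Repetition time (ms), must be positive.
#' @param flip_nominal Nominal flip angle in degrees, in (0, 180).
#' @param te Numeric vector of echo times (ms), strictly increasing.
#'
#' @return An object of class `acq_protocol` with elements `tr`,
#'   `flip_nominal`, `te` and `n_echoes`.
#' @seealso [afi_protocol()], [default_protocols()]
#' @export
#' @examples
#' acq_protocol(tr = 50, flip_nominal = 7, te = 2.2 + 2.55 * (0:17))
acq_protocol <- function(tr, flip_nominal, te) {
  stopifnot(is.numeric(tr), length(tr) == 1L, tr > 0)
  stopifnot(is.numeric(flip_nominal), length(flip_nominal) == 1L,
            flip_nominal > 0, flip_nominal < 180)
  stopifnot(is.numeric(te), length(te) >= 1L, all(te >= 0))
  if (length(te) > 1L && any(diff(te) <= 0))
    stop("echo times must be strictly increasing")
  structure(list(tr = tr, flip_nominal = flip_nominal,
                 te = te, n_echoes = length(te)),
            class = "acq_protocol")
}

#' @export
print.acq_protocol <- function(x, ...) {
  cat(sprintf("meGRE protocol: TR = %g ms, flip = %g deg, %d echoes (TE %g..%g ms)\n",
              x$tr, x$flip_nominal, x$n_echoes, min(x$te), max(x$te)))
  invisible(x)
}

#' Actual flip angle imaging (AFI) protocol
#'
#' Two interleaved repetition times at a single nominal flip angle.  The
#' ratio of the two steady-state signals encodes the actual flip angle,
#' from which the relative transmit field B1+ is derived.
#'
#' @param tr1,tr2 The two repetition times (ms); `tr2 > tr1 > 0`.
#' @param flip_nominal Nominal flip angle in degrees.
#'
#' @return An object of class `afi_protocol` with elements `tr1`, `tr2`,
#'   `flip_nominal` and the TR ratio `n_ratio = tr2/tr1`.
#' @export
#' @examples
#' afi_protocol()  # TR1 = 125 ms, TR2/TR1 = 5, flip = 40 deg
afi_protocol <- function(tr1 = 125, tr2 = 625, flip_nominal = 40) {
  stopifnot(is.numeric(tr1), is.numeric(tr2), tr1 > 0, tr2 > tr1)
  stopifnot(flip_nominal > 0, flip_nominal < 180)
  structure(list(tr1 = tr1, tr2 = tr2, flip_nominal = flip_nominal,
                 n_ratio = tr2 / tr1),
            class = "afi_protocol")
}

#' @export
print.afi_protocol <- function(x, ...) {
  cat(sprintf("AFI protocol: TR1 = %g ms, TR2 = %g ms (n = %g), flip = %g deg\n",
              x$tr1, x$tr2, x$n_ratio, x$flip_nominal))
  invisible(x)
}

#' Default acquisition protocols of the two-point method
#'
#' The operating point of the method: two meGRE acquisitions at TR = 50 ms
#' with flip angles 7 deg (M0-weighted) and 40 deg (T1-weighted), 18 echoes
#' starting at TE = 2.2 ms with 2.55 ms spacing; an AFI acquisition with
#' TR1 = 125 ms, TR2/TR1 = 5 at 40 deg; and a fully relaxed long-TR
#' single-flip-angle reference (TR = 10 s, 90 deg, 32 echoes).
#'
#' @return A list with elements `low`, `high` (class `acq_protocol`),
#'   `afi` (class `afi_protocol`) and `long_tr` (class `acq_protocol`).
#' @export
default_protocols <- function() {
  te18 <- 2.2 + 2.55 * (0:17)
  list(low     = acq_protocol(tr = 50, flip_nominal = 7, te = te18),
       high    = acq_protocol(tr = 50, flip_nominal = 40, te = te18),
       afi     = afi_protocol(tr1 = 125, tr2 = 625, flip_nominal = 40),
       long_tr = acq_protocol(tr = 10000, flip_nominal = 90,
                              te = 3.84 + 4.08 * (0:31)))
}

#' Fit configuration: every tunable of the mapping pipeline
#'
#' Collects the numeric knobs of the processing chain with the method's
#' default values: number of echoes entering the T1 fit and the M0 average
#' (3), the T1 and T2* clip bounds (6000 ms and 1500 ms), the T1 solver
#' tolerance, the intravoxel-dephasing cutoff threshold (0.5 cycles across
#' a voxel), the minimum echo floor of the T2* fit, B1+ median filtering,
#' and the receive-bias estimator settings.
#'
#' @param n_echoes Echoes used for the T1 fit and the corrected-M0 average.
#' @param t1_max,t2star_max Upper clip bounds for T1 and T2* (ms).
#' @param t1_tol Absolute tolerance of the scalar T1 minimisation (ms).
#' @param q_threshold Through-voxel phase dispersion (cycles) at which the
#'   mono-exponential decay model is no longer trusted; sets `TE_max`.
#' @param min_echoes Minimum number of leading echoes always included in
#'   the T2* fit regardless of `TE_max`.
#' @param b1_median_filter Logical; median-filter the B1+ map (radius 1)
#'   before resampling.
#' @param bias_poly_order Total polynomial order of the receive-bias field.
#' @param bias_k Number of intensity classes of the receive-bias estimator.
#' @param seed Integer seed for stochastic stages (`NULL` = leave RNG alone).
#'
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_echoes = 3, t1_max = 6000, t2star_max = 1500,
                       t1_tol = 0.01, q_threshold = 0.5, min_echoes = 3,
                       b1_median_filter = TRUE, bias_poly_order = 4,
                       bias_k = 3, seed = NULL) {
  stopifnot(n_echoes >= 1, t1_max > 0, t2star_max > 0, t1_tol > 0,
            q_threshold > 0, min_echoes >= 2)
  structure(list(n_echoes = n_echoes, t1_max = t1_max,
                 t2star_max = t2star_max, t1_tol = t1_tol,
                 q_threshold = q_threshold, min_echoes = min_echoes,
                 b1_median_filter = b1_median_filter,
                 bias_poly_order = bias_poly_order, bias_k = bias_k,
                 seed = seed),
            class = "fit_config")
}

#' Normalisation-region rule for the water calibration
#'
#' The calibration region is ventricular cerebrospinal fluid, assumed to be
#' 100% MR-visible water.  A voxel enters the region when its CSF
#' probability is at least `csf_prob_min`, its fitted T1 exceeds `t1_min`
#' and its fitted T2* exceeds `t2star_min`; an optional ellipsoid around
#' the lateral ventricles excludes subarachnoid CSF.
#'
#' @param csf_prob_min Minimum CSF probability (default 0.99).
#' @param t1_min Minimum T1 in ms (default 2900, exclusive).
#' @param t2star_min Minimum T2* in ms (default 500, exclusive).
#' @param ellipsoid `NULL` or a list with `centre` (length-3, world mm) and
#'   `semi_axes` (length-3, mm).
#'
#' @return A list of class `normalization_rule`.
#' @export
normalization_rule <- function(csf_prob_min = 0.99, t1_min = 2900,
                               t2star_min = 500, ellipsoid = NULL) {
  stopifnot(csf_prob_min > 0, csf_prob_min <= 1, t1_min > 0, t2star_min > 0)
  if (!is.null(ellipsoid)) {
    stopifnot(is.list(ellipsoid),
              length(ellipsoid$centre) == 3L,
              length(ellipsoid$semi_axes) == 3L,
              all(ellipsoid$semi_axes > 0))
  }
  structure(list(csf_prob_min = csf_prob_min, t1_min = t1_min,
                 t2star_min = t2star_min, ellipsoid = ellipsoid),
            class = "normalization_rule")
}
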