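#' Spoiled gradient-echo steady-state signal
#'
#' Magnitude signal of an ideally spoiled gradient-echo sequence at echo
#' time `te`,
#' \deqn{S = M_0 \, e^{-TE/T_2^*} \,
#'   \frac{\sin\alpha \,(1 - E)}{1 - E\cos\alpha} \, B_1^-,
#'   \qquad E = e^{-TR/T_1},}
#' where \eqn{\alpha} is the effective flip angle (nominal flip angle
#' scaled by the relative transmit field B1+).  All inputs are recycled to
#' a common shape, so whole parameter maps can be evaluated in one call.
#'
#' @param m0 Magnetisation density (arbitrary units).
#' @param t1 Longitudinal relaxation time (ms), positive.
#' @param t2star Effective transverse relaxation time (ms), positive.
#' @param te Echo time (ms), non-negative.
#' @param tr Repetition time (ms), positive.
#' @param flip_eff Effective flip angle in degrees.
#' @param b1minus Relative receive-field sensitivity (dimensionless).
#'
#' @return Signal values with the common recycled shape of the inputs.
#' @export
#' @examples
#' spgr_signal(1, t1 = 1000, t2star = 50, te = 2.2, tr = 50, flip_eff = 7)
spgr_signal <- function(m0, t1, t2star, te, tr, flip_eff, b1minus = 1) {
  if (any(t1 <= 0)) stop("t1 must be positive")
  if (any(t2star <= 0)) stop("t2star must be positive")
  if (any(tr <= 0)) stop("tr must be positive")
  if (any(te < 0)) stop("te must be non-negative")
  a <- flip_eff * pi / 180
  e1 <- exp(-tr / t1)
  m0 * exp(-te / t2star) * sin(a) * (1 - e1) / (1 - e1 * cos(a)) * b1minus
}

#' T1/B1+/flip correction factor of the spoiled GRE signal
#'
#' The saturation term \eqn{\sin\alpha (1-E)/(1-E\cos\alpha)} of
#' [spgr_signal()], used both to correct measured signals for residual
#' T1 weighting and inside the two-point T1 objective.
#'
#' @inheritParams spgr_signal
#' @return Dimensionless correction factor, recycled shape.
#' @export
spgr_t1_factor <- function(t1, tr, flip_eff) {
  a <- flip_eff * pi / 180
  e1 <- exp(-tr / t1)
  sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Exact AFI steady-state signals
#'
#' Signals of the actual-flip-angle-imaging pulse train, which applies the
#' same flip angle with two alternating repetition times TR1 and TR2.  The
#' returned values are the exact periodic steady state of the two-pulse
#' cycle (perfect spoiling assumed), not the short-TR approximation that
#' underlies the closed-form flip-angle inversion:
#' \deqn{S_1 = M_0 \sin\alpha \frac{1 - E_2 + \cos\alpha\, E_2 (1 - E_1)}
#'   {1 - E_1 E_2 \cos^2\alpha}, \qquad E_i = e^{-TR_i/T_1},}
#' and symmetrically for \eqn{S_2} with \eqn{E_1 \leftrightarrow E_2}.
#'
#' @param m0 Magnetisation density.
#' @param t1 Longitudinal relaxation time (ms).
#' @param flip_eff Effective flip angle (degrees).
#' @param afi An [afi_protocol()].
#' @param b1minus Relative receive sensitivity.
#'
#' @return A list with components `s1` and `s2` (recycled shape).
#' @export
#' @examples
#' afi_signals(1, t1 = 1000, flip_eff = 40, afi = afi_protocol())
afi_signals <- function(m0, t1, flip_eff, afi, b1minus = 1) {
  stopifnot(inherits(afi, "afi_protocol"))
  if (any(t1 <= 0)) stop("t1 must be positive")
  a  <- flip_eff * pi / 180
  ca <- cos(a)
  e1 <- exp(-afi$tr1 / t1)
  e2 <- exp(-afi$tr2 / t1)
  den <- 1 - e1 * e2 * ca^2
  s1 <- m0 * sin(a) * (1 - e2 + ca * e2 * (1 - e1)) / den * b1minus
  s2 <- m0 * sin(a) * (1 - e1 + ca * e1 * (1 - e2)) / den * b1minus
  list(s1 = s1, s2 = s2)
}

#' AFI steady-state signal ratio
#'
#' Ratio \eqn{r = S_2/S_1} of the exact AFI steady state, as a function of
#' the flip angle; monotone decreasing in the flip angle over (0, 180)
#' degrees for any T1, which the iterative flip-angle refinement exploits.
#'
#' @inheritParams afi_signals
#' @return The ratio `s2/s1` (M0 and receive field cancel).
#' @export
afi_ratio <- function(t1, flip_eff, afi) {
  a  <- flip_eff * pi / 180
  ca <- cos(a)
  e1 <- exp(-afi$tr1 / t1)
  e2 <- exp(-afi$tr2 / t1)
  (1 - e1 + ca * e1 * (1 - e2)) / (1 - e2 + ca * e2 * (1 - e1))
}

#' Rician magnitude (and phase) noise
#'
#' Adds zero-mean complex Gaussian noise of standard deviation `sigma` per
#' real channel to a complex signal given by magnitude and phase, and
#' returns the noisy magnitude (Rician distributed) and noisy phase.  For
#' zero true signal the magnitude follows a Rayleigh distribution with
#' mean \eqn{\sigma\sqrt{\pi/2}}.
#'
#' @param magnitude Array of noiseless signal magnitudes.
#' @param sigma Noise standard deviation (per real/imaginary channel).
#' @param phase Optional array of true phases (radians); default 0.
#'
#' @return List with `magnitude` and `phase` arrays of the input shape.
#' @export
rician_noise <- function(magnitude, sigma, phase = NULL) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (is.null(phase)) phase <- 0
  re <- magnitude * cos(phase)
  im <- magnitude * sin(phase)
  if (sigma > 0) {
    re <- re + stats::rnorm(length(magnitude), sd = sigma)
    im <- im + stats::rnorm(length(magnitude), sd = sigma)
  }
  mag <- sqrt(re^2 + im^2)
  ph  <- atan2(im, re)
  dim(mag) <- dim(magnitude)
  dim(ph)  <- dim(magnitude)
  list(magnitude = mag, phase = ph)
}
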