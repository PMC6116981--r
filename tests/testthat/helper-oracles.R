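# Independent oracles used across the suite.  These deliberately avoid the
# closed forms and vectorised solvers inside the package.

# Brute-force AFI pulse-train simulation: apply flip, relax TR1, apply
# flip, relax TR2, repeat until the longitudinal magnetisation reaches a
# fixed point.  Returns the two signals (sin(alpha) * Mz before each
# pulse).
bloch_train_afi <- function(m0, t1, flip_deg, tr1, tr2,
                            tol = 1e-12, max_cycles = 100000L) {
  a <- flip_deg * pi / 180
  e1 <- exp(-tr1 / t1)
  e2 <- exp(-tr2 / t1)
  mz <- m0
  for (cyc in seq_len(max_cycles)) {
    mz_before_1 <- mz
    mz <- m0 * (1 - e1) + mz * cos(a) * e1       # pulse then TR1
    mz_before_2 <- mz
    mz <- m0 * (1 - e2) + mz * cos(a) * e2       # pulse then TR2
    if (abs(mz - mz_before_1) < tol * max(m0, 1)) break
  }
  c(s1 = sin(a) * mz_before_1, s2 = sin(a) * mz_before_2)
}

# Exhaustive grid search for the two-point T1 objective; s1, s2 are
# n_voxel x n_echo matrices, a1/a2 effective flip angles in radians
# (scalar or per-voxel).
grid_search_t1 <- function(s1, s2, a1_rad, a2_rad, tr,
                           t1_min = 1, t1_max = 6000, step = 0.1) {
  nv <- nrow(s1)
  A <- rowSums(s1^2); B <- rowSums(s1 * s2); D <- rowSums(s2^2)
  best_val <- rep(Inf, nv); best_t1 <- rep(NA_real_, nv)
  for (t1 in seq(t1_min, t1_max, by = step)) {
    e <- exp(-tr / t1)
    c1 <- sin(a1_rad) * (1 - e) / (1 - e * cos(a1_rad))
    c2 <- sin(a2_rad) * (1 - e) / (1 - e * cos(a2_rad))
    f <- A / c1^2 - 2 * B / (c1 * c2) + D / c2^2
    better <- f < best_val
    best_val[better] <- f[better]
    best_t1[better] <- t1
  }
  best_t1
}

# Unweighted log-linear decay fit (closed form), per row of a signal
# matrix; returns list(s0, t2star).
unweighted_loglin <- function(s, te) {
  y <- log(s)
  n <- length(te)
  sx <- sum(te); sxx <- sum(te^2)
  sy <- rowSums(y); sxy <- as.vector(y %*% te)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  icpt <- (sy - slope * sx) / n
  list(s0 = exp(icpt), t2star = -1 / slope)
}

# Single-voxel echo train (optionally replicated) as an echo_train object.
voxel_train <- function(signal_by_echo, protocol, n_reps = 1L, phase = NULL) {
  ne <- length(signal_by_echo)
  mag <- array(rep(signal_by_echo, each = n_reps), c(n_reps, 1, 1, ne))
  ph <- if (!is.null(phase))
    array(rep(phase, each = n_reps), c(n_reps, 1, 1, ne)) else NULL
  echo_train(mag, protocol, phase = ph)
}
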