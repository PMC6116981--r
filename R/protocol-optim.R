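#' Flip-angle optimisation grid
#'
#' Study design for the Monte Carlo flip-angle search: candidate flip
#' angle pairs at fixed TR and SNR, number of noise replicates, seed, and
#' the reference tissue voxel (white-matter-like by default: 70% water,
#' T1 = 1000 ms, T2* = 50 ms).  SNR is defined on the first echo of the
#' lower-flip-angle acquisition of each pair.
#'
#' @param alpha1,alpha2 Candidate flip angles (degrees) of the two
#'   acquisitions.
#' @param tr Repetition time (ms).
#' @param snr Signal-to-noise ratio (first echo, low flip).
#' @param n_reps Noise replicates per pair.
#' @param seed Integer seed.
#' @param tissue Named numeric vector `c(h2o, t1, t2star)`.
#' @param te Echo-time train (ms).
#'
#' @return Object of class `optim_grid`.
#' @export
optim_grid <- function(alpha1, alpha2, tr = 50, snr = 20, n_reps = 1000L,
                       seed = 1L,
                       tissue = c(h2o = 70, t1 = 1000, t2star = 50),
                       te = 2.2 + 2.55 * (0:17)) {
  stopifnot(length(alpha1) >= 1, length(alpha2) >= 1, all(alpha1 > 0),
            all(alpha2 > 0), tr > 0, snr > 0, n_reps >= 1)
  stopifnot(all(c("h2o", "t1", "t2star") %in% names(tissue)))
  structure(list(alpha1 = sort(unique(alpha1)), alpha2 = sort(unique(alpha2)),
                 tr = tr, snr = snr, n_reps = as.integer(n_reps),
                 seed = as.integer(seed), tissue = tissue, te = te),
            class = "optim_grid")
}

# single-voxel echo train replicated n times, as a minimal echo_train
.rep_echo_train <- function(signal_by_echo, protocol, n_reps, sigma) {
  ne <- length(signal_by_echo)
  mag <- array(rep(signal_by_echo, each = n_reps), c(n_reps, 1, 1, ne))
  if (sigma > 0) mag <- rician_noise(mag, sigma)$magnitude
  structure(list(magnitude = mag, phase = NULL, protocol = protocol,
                 voxel_size = c(1, 1, 1), affine = diag(4)),
            class = "echo_train")
}

#' Monte Carlo feasibility of flip-angle pairs
#'
#' For every candidate pair, simulates `n_reps` noisy two-flip-angle echo
#' trains of the reference voxel at the stated SNR (Rician magnitude
#' noise, known unit B1 fields), runs the two-point T1 fit, the T2* fit
#' and the M0 correction chain, and records relative bias and standard
#' deviation of the recovered water content and T1 in percent of truth.
#' A pair is feasible when all four metrics stay below `tolerance_pct`.
#' Degenerate pairs (`alpha1 == alpha2`, T1 unidentifiable) get infinite
#' metrics.  Fully deterministic for a fixed grid (seed included).
#'
#' @param grid An [optim_grid()].
#' @param tolerance_pct Feasibility threshold in percent (default 10).
#'
#' @return Object of class `feasibility_result`: matrices `bias_h2o`,
#'   `sd_h2o`, `bias_t1`, `sd_t1` and logical `feasible` indexed by
#'   `(alpha1, alpha2)`, plus the grid.
#' @export
monte_carlo_optimize <- function(grid, tolerance_pct = 10) {
  stopifnot(inherits(grid, "optim_grid"), tolerance_pct > 0)
  n1 <- length(grid$alpha1); n2 <- length(grid$alpha2)
  dims <- c(n1, n2)
  dn <- list(alpha1 = as.character(grid$alpha1),
             alpha2 = as.character(grid$alpha2))
  bias_h2o <- sd_h2o <- bias_t1 <- sd_t1 <-
    matrix(NA_real_, n1, n2, dimnames = dn)
  tis <- grid$tissue
  set.seed(grid$seed)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    a1 <- grid$alpha1[i]; a2 <- grid$alpha2[j]
    if (a1 == a2) {
      bias_h2o[i, j] <- sd_h2o[i, j] <- bias_t1[i, j] <- sd_t1[i, j] <- Inf
      next
    }
    p1 <- acq_protocol(grid$tr, a1, grid$te)
    p2 <- acq_protocol(grid$tr, a2, grid$te)
    s1 <- spgr_signal(tis["h2o"], tis["t1"], tis["t2star"], grid$te,
                      grid$tr, a1)
    s2 <- spgr_signal(tis["h2o"], tis["t1"], tis["t2star"], grid$te,
                      grid$tr, a2)
    a_low <- if (a1 <= a2) a1 else a2
    s_ref <- spgr_signal(tis["h2o"], tis["t1"], tis["t2star"], grid$te[1],
                         grid$tr, a_low)
    sigma <- s_ref / grid$snr
    low  <- .rep_echo_train(s1, p1, grid$n_reps, sigma)
    high <- .rep_echo_train(s2, p2, grid$n_reps, sigma)
    t1fit <- fit_t1_two_point(low, high, b1plus = 1)
    t2fit <- fit_t2star(low)
    m0fit <- correct_m0(low, t2fit, t1fit, b1plus = 1,
                        b1minus = array(1, c(grid$n_reps, 1, 1)))
    h2o_rel <- 100 * m0fit$m0 / tis[["h2o"]]
    t1_rel  <- 100 * t1fit$t1 / tis[["t1"]]
    ok <- is.finite(h2o_rel) & is.finite(t1_rel)
    if (!any(ok)) {
      bias_h2o[i, j] <- sd_h2o[i, j] <- bias_t1[i, j] <- sd_t1[i, j] <- Inf
      next
    }
    bias_h2o[i, j] <- abs(mean(h2o_rel[ok]) - 100)
    sd_h2o[i, j]   <- stats::sd(h2o_rel[ok])
    bias_t1[i, j]  <- abs(mean(t1_rel[ok]) - 100)
    sd_t1[i, j]    <- stats::sd(t1_rel[ok])
  }
  feasible <- bias_h2o < tolerance_pct & sd_h2o < tolerance_pct &
    bias_t1 < tolerance_pct & sd_t1 < tolerance_pct
  structure(list(bias_h2o = bias_h2o, sd_h2o = sd_h2o, bias_t1 = bias_t1,
                 sd_t1 = sd_t1, feasible = feasible,
                 tolerance_pct = tolerance_pct, grid = grid),
            class = "feasibility_result")
}

#' Rank the feasible flip-angle pairs
#'
#' Deterministic table of feasible pairs sorted by combined standard
#' deviation (`sd_h2o + sd_t1`), ties broken by `(alpha1, alpha2)` in
#' lexicographic order.
#'
#' @param result A `feasibility_result`.
#' @return A data frame with columns `alpha1`, `alpha2`, the four metrics
#'   and `combined_sd`; zero rows (with a warning) when no pair is
#'   feasible.
#' @export
summarize_feasible <- function(result) {
  stopifnot(inherits(result, "feasibility_result"))
  idx <- which(result$feasible, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    warning("no feasible flip-angle pair at this SNR/tolerance")
    return(data.frame(alpha1 = numeric(0), alpha2 = numeric(0),
                      bias_h2o = numeric(0), sd_h2o = numeric(0),
                      bias_t1 = numeric(0), sd_t1 = numeric(0),
                      combined_sd = numeric(0)))
  }
  out <- data.frame(
    alpha1 = result$grid$alpha1[idx[, 1]],
    alpha2 = result$grid$alpha2[idx[, 2]],
    bias_h2o = result$bias_h2o[idx],
    sd_h2o = result$sd_h2o[idx],
    bias_t1 = result$bias_t1[idx],
    sd_t1 = result$sd_t1[idx])
  out$combined_sd <- out$sd_h2o + out$sd_t1
  out <- out[order(out$combined_sd, out$alpha1, out$alpha2), , drop = FALSE]
  rownames(out) <- NULL
  out
}
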