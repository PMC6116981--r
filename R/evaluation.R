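#' Tissue mask from a probability volume
#'
#' @param prob 3-D probability array in \[0, 1\].
#' @param threshold Inclusion threshold (default 0.99); a voxel is kept
#'   when `prob >= threshold`.
#' @return Logical array.
#' @export
tissue_mask <- function(prob, threshold = 0.99) {
  if (any(prob < 0 | prob > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  !is.na(prob) & prob >= threshold
}

#' Gaussian fit to a tissue histogram
#'
#' Histograms the map over the mask and fits a single Gaussian to the bin
#' counts by least squares, returning its centre and width as the tissue
#' mean and standard deviation.  When the fit fails to converge or the
#' fitted width exceeds the histogram span — as happens for broad,
#' overlapping distributions — the mode (midpoint of the fullest bin) is
#' used instead and recorded in `method`.
#'
#' @param map 3-D array of values.
#' @param mask Logical array, non-empty.
#' @param bins Number of histogram bins; `NULL` uses the
#'   Freedman-Diaconis rule.
#' @param tissue Label stored in the result.
#'
#' @return Object of class `tissue_stats`: a one-row data frame with
#'   `tissue`, `mu`, `sigma`, `n_voxels`, `method` (`"gaussian_fit"` or
#'   `"mode"`).
#' @export
fit_tissue_histogram <- function(map, mask, bins = NULL, tissue = "") {
  stopifnot(identical(dim(map), dim(mask)))
  vals <- map[mask & is.finite(map)]
  if (length(vals) == 0L) stop("empty mask")
  span <- diff(range(vals))
  if (is.null(bins)) {
    h <- graphics::hist(vals, breaks = "FD", plot = FALSE)
  } else {
    h <- graphics::hist(vals, breaks = seq(min(vals), max(vals),
                                           length.out = bins + 1),
                        plot = FALSE)
  }
  mids <- h$mids; counts <- h$counts
  method <- "gaussian_fit"
  mu <- mean(vals); sigma <- stats::sd(vals)
  fit <- NULL
  if (span > 0 && length(mids) >= 4L && sigma > 0) {
    fit <- tryCatch(
      stats::nls(counts ~ a * exp(-(mids - m)^2 / (2 * s^2)),
                 start = list(a = max(counts), m = mu, s = sigma),
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = FALSE)),
      error = function(e) NULL)
  }
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    if (is.finite(cf[["s"]]) && abs(cf[["s"]]) <= span) {
      mu <- cf[["m"]]; sigma <- abs(cf[["s"]])
    } else fit <- NULL
  }
  if (is.null(fit)) {
    method <- "mode"
    mu <- mids[which.max(counts)]
    sigma <- if (span > 0) stats::sd(vals) else 0
  }
  structure(data.frame(tissue = tissue, mu = mu, sigma = sigma,
                       n_voxels = length(vals), method = method,
                       stringsAsFactors = FALSE),
            class = c("tissue_stats", "data.frame"))
}

#' Recovery metrics of an estimated map against ground truth
#'
#' @param estimate,truth 3-D arrays of equal shape.
#' @param mask Logical array, non-empty.
#' @return Named numeric vector: `bias` (mean error), `rmse`
#'   (root-mean-square error) and `cv` (standard deviation of the error
#'   relative to the mean absolute truth).
#' @export
recovery_metrics <- function(estimate, truth, mask) {
  stopifnot(identical(dim(estimate), dim(truth)),
            identical(dim(estimate), dim(mask)))
  sel <- mask & is.finite(estimate) & is.finite(truth)
  if (!any(sel)) stop("empty mask")
  err <- estimate[sel] - truth[sel]
  mt <- mean(abs(truth[sel]))
  c(bias = mean(err),
    rmse = sqrt(mean(err^2)),
    cv = if (mt > 0) stats::sd(err) / mt else 0)
}
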