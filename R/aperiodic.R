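#' Log-log points for aperiodic fitting
#'
#' Restricts a power spectrum to the aperiodic fit range (1-55 Hz by
#' default) and returns log10-frequency / log10-power pairs.  On this scale
#' a 1/f^chi background is a straight line with slope -chi.
#'
#' @param psd A [paf_psd()].
#' @param fit_range Length-2 numeric, the inclusive frequency range in Hz.
#' @return A data frame with columns `freq_hz`, `log_f`, `log_p`.
#' @export
log_log_points <- function(psd, fit_range = c(1, 55)) {
  stopifnot(inherits(psd, "paf_psd"), length(fit_range) == 2,
            fit_range[1] > 0, fit_range[2] > fit_range[1])
  # tolerant comparison: grids built by seq() carry float error at the edges
  eps <- 1e-9
  keep <- psd$freqs >= fit_range[1] - eps & psd$freqs <= fit_range[2] + eps
  if (!any(keep)) stop("no frequency bins inside the fit range")
  p <- psd$power[keep]
  if (any(p <= 0))
    stop("nonpositive power inside the fit range; log-power undefined")
  data.frame(freq_hz = psd$freqs[keep],
             log_f = log10(psd$freqs[keep]),
             log_p = log10(p))
}

#' Robust 1/f fit by Huber regression
#'
#' Fits `log_p ~ log_f` by iteratively reweighted least squares with the
#' Huber weight function.  Residuals are standardised each iteration by
#' 1.4826 times their median absolute deviation; points whose standardised
#' residual exceeds the tuning constant `M` are downweighted by `M/|r|`.
#' Narrow-band peaks (such as the alpha bump) sit far above the 1/f line
#' and are therefore largely ignored, which is what makes the subsequent
#' flattening unbiased.  Ordinary least squares is the exact solution
#' whenever no residual exceeds the threshold.
#'
#' @param points Data frame from [log_log_points()] (columns `log_f`,
#'   `log_p`), or a `paf_psd` (converted with the default fit range).
#' @param M Huber tuning constant on the standardised residual scale.
#' @param tol Convergence tolerance on the coefficient change.
#' @param max_iter Maximum IRLS iterations.
#' @return An object of class `aperiodic_fit`: a list with `intercept`,
#'   `slope`, `tuning_constant`, `n_points`, `converged`, `iterations`,
#'   `scale` and the fitted `weights`.
#' @examples
#' psd <- synth_psd(spectral_params(peak_amplitude = 0))
#' fit_aperiodic_huber(log_log_points(psd))
#' @export
fit_aperiodic_huber <- function(points, M = 1.35, tol = 1e-8,
                                max_iter = 200) {
  if (inherits(points, "paf_psd")) points <- log_log_points(points)
  stopifnot(is.data.frame(points), all(c("log_f", "log_p") %in% names(points)),
            M > 0)
  if (nrow(points) < 3) stop("need at least 3 points for a robust line fit")
  X <- cbind(1, points$log_f)
  y <- points$log_p
  beta <- qr.solve(X, y)   # OLS start
  converged <- FALSE
  it <- 0L
  s <- NA_real_
  w <- rep(1, length(y))
  while (it < max_iter) {
    it <- it + 1L
    r <- as.numeric(y - X %*% beta)
    s <- mad(r)            # 1.4826 * median(|r - median(r)|)
    if (s < .Machine$double.eps^0.5) { converged <- TRUE; break }
    u <- abs(r / s)
    w <- ifelse(u <= M, 1, M / u)
    beta_new <- qr.solve(X * sqrt(w), y * sqrt(w))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  structure(list(intercept = unname(beta[1]), slope = unname(beta[2]),
                 tuning_constant = M, n_points = nrow(points),
                 converged = converged, iterations = it,
                 scale = s, weights = as.numeric(w)),
            class = "aperiodic_fit")
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf(
    "Aperiodic (1/f) fit: log10 P = %.4f %+.4f log10 f  [Huber M = %.2f, %s, %d points]\n",
    x$intercept, x$slope, x$tuning_constant,
    if (x$converged) sprintf("converged in %d iterations", x$iterations)
    else "NOT converged", x$n_points))
  invisible(x)
}

#' @export
coef.aperiodic_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Flatten a spectrum by its fitted 1/f component
#'
#' Subtracts the fitted aperiodic line in log10 space and exponentiates:
#' `ratio(f) = 10^(log10 P(f) - (intercept + slope * log10 f))`, i.e. the
#' observed power divided by the predicted aperiodic power.  A pure power
#' law flattens to a constant ratio of 1; periodic activity appears as a
#' bump above 1.
#'
#' @param psd A [paf_psd()].
#' @param fit An `aperiodic_fit` from [fit_aperiodic_huber()].
#' @param fit_range Frequency range retained, matching the fit.
#' @return An object of class `flat_spectrum`: list with `freqs` and
#'   strictly positive `ratio`.
#' @export
flatten <- function(psd, fit, fit_range = c(1, 55)) {
  stopifnot(inherits(fit, "aperiodic_fit"))
  if (!fit$converged)
    stop("aperiodic fit did not converge; refusing to flatten")
  pts <- log_log_points(psd, fit_range)
  ratio <- 10^(pts$log_p - (fit$intercept + fit$slope * pts$log_f))
  structure(list(freqs = pts$freq_hz, ratio = ratio),
            class = "flat_spectrum")
}

#' @export
print.flat_spectrum <- function(x, ...) {
  cat(sprintf("Flattened spectrum: %d bins, %.3g-%.3g Hz, max ratio %.3f at %.2f Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              max(x$ratio), x$freqs[which.max(x$ratio)]))
  invisible(x)
}
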