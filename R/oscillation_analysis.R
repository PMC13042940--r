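# Spectral and distributional analysis of spontaneous oscillations.
#
# Conventions: the power spectral density is two-sided (defined over the
# whole frequency line) but stored on f > 0; by symmetry of real signals
# the variance is 2 * integral over f > 0. With this convention the
# closed-form root-mean-square of the double-Lorentzian model,
# X_RMS = sqrt(4 pi A Q / f0), is literally the square root of the
# full-line integral of the fitted density.

#' Segment-averaged power spectrum
#'
#' Splits the trace into non-overlapping segments, removes each segment's
#' mean, and averages the raw periodograms. The returned density is
#' two-sided, stored on positive frequencies: `2 * sum(psd) * df` equals
#' the trace variance (Parseval).
#'
#' @param ts A data frame with columns `t_s` and `X_nm` (uniform sampling),
#'   e.g. from [gen_oscillation_trace()].
#' @param n_segments Number of segments to average (>= 1).
#' @return An object of class `bundle_spectrum`: a data frame with columns
#'   `f_Hz`, `psd_nm2_per_Hz`, plus attributes `df_Hz`, `fs_Hz`,
#'   `variance_nm2` (per-segment-mean-removed trace variance).
#' @export
power_spectrum <- function(ts, n_segments = 5) {
  stopifnot(all(c("t_s", "X_nm") %in% names(ts)))
  dt <- diff(ts$t_s)
  if (diff(range(dt)) > 1e-6 * stats::median(dt)) {
    stop("sampling error: time base is not uniform", call. = FALSE)
  }
  fs <- 1 / stats::median(dt)
  x <- ts$X_nm
  nseg <- max(1L, as.integer(n_segments))
  L <- floor(length(x) / nseg)
  if (L < 8) stop("segments too short; reduce n_segments", call. = FALSE)
  kmax <- floor(L / 2)
  acc <- numeric(kmax)
  vsum <- 0
  for (s in seq_len(nseg)) {
    seg <- x[((s - 1) * L + 1):(s * L)]
    seg <- seg - mean(seg)
    vsum <- vsum + stats::var(seg) * (L - 1) / L
    P <- Mod(stats::fft(seg))^2 / (L * fs)   # two-sided periodogram
    acc <- acc + P[2:(kmax + 1)]
  }
  psd <- acc / nseg
  f <- (1:kmax) * fs / L
  structure(
    data.frame(f_Hz = f, psd_nm2_per_Hz = psd),
    df_Hz = fs / L, fs_Hz = fs, variance_nm2 = vsum / nseg,
    class = c("bundle_spectrum", "data.frame")
  )
}

#' Variance carried by a spectrum
#'
#' `2 * sum(psd) * df`, the discrete full-line integral of the two-sided
#' density (the Nyquist bin is counted once).
#'
#' @param s A [power_spectrum()] result.
#' @return Variance, nm^2.
#' @export
spectrum_variance <- function(s) {
  df <- attr(s, "df_Hz")
  fs <- attr(s, "fs_Hz")
  w <- rep(2, nrow(s))
  w[abs(s$f_Hz - fs / 2) < df / 2] <- 1
  sum(w * s$psd_nm2_per_Hz) * df
}

#' Moving-average smoothing of a spectrum
#'
#' Boxcar average over a fixed frequency window (default 1 Hz), with the
#' window shrinking symmetrically at the edges so that the spectral
#' integral is preserved up to edge effects.
#'
#' @param s A [power_spectrum()] result.
#' @param window_Hz Smoothing window, Hz. A window below the spectral
#'   resolution leaves the spectrum unchanged (with a warning).
#' @return A `bundle_spectrum` on the same frequency grid.
#' @export
smooth_spectrum <- function(s, window_Hz = 1) {
  df <- attr(s, "df_Hz")
  if (window_Hz < df) {
    warning("smoothing window below spectral resolution; returning spectrum unchanged")
    return(s)
  }
  k <- 2 * floor(window_Hz / df / 2) + 1     # odd bin count
  out <- s
  out$psd_nm2_per_Hz <- moving_average(s$psd_nm2_per_Hz, k)
  out
}

#' Fit the double-Lorentzian oscillation spectrum
#'
#' Least-squares fit of
#' `C(f) = A / ((f0/(2Q))^2 + (f - f0)^2) + A / ((f0/(2Q))^2 + (f + f0)^2)`
#' over positive frequencies, initialised from the spectral peak (f0 at the
#' argmax, Q from f0 / FWHM, A from the peak height).
#'
#' @param s A (preferably smoothed) [power_spectrum()] result.
#' @param f_max Optional upper frequency bound for the fit, Hz.
#' @return An object of class `spectrum_fit`: a list with `A_nm2_Hz`,
#'   `f0_Hz`, `Q`, `X_RMS_nm` and the fitted object.
#' @export
fit_double_lorentzian <- function(s, f_max = NULL) {
  f <- s$f_Hz; P <- s$psd_nm2_per_Hz
  if (!is.null(f_max)) { P <- P[f <= f_max]; f <- f[f <= f_max] }
  ipk <- which.max(P)
  pk <- P[ipk]
  above <- which(P >= pk / 2)
  if (length(above) < 5 || ipk == 1 || ipk == length(f)) {
    stop("fit failure: spectrum has no resolved peak (need >= 5 bins above half-max)",
         call. = FALSE)
  }
  f0_0 <- f[ipk]
  fwhm <- diff(range(f[above]))
  Q0 <- max(f0_0 / max(fwhm, diff(f)[1]), 0.26)
  A0 <- pk * (f0_0 / (2 * Q0))^2
  fit <- minpack.lm::nlsLM(
    P ~ A / ((f0 / (2 * Q))^2 + (f - f0)^2) + A / ((f0 / (2 * Q))^2 + (f + f0)^2),
    start = list(A = A0, f0 = f0_0, Q = Q0),
    lower = c(A = 0, f0 = diff(f)[1] / 10, Q = 0.05),
    control = minpack.lm::nls.lm.control(maxiter = 300)
  )
  cf <- stats::coef(fit)
  out <- list(A_nm2_Hz = unname(cf["A"]), f0_Hz = unname(cf["f0"]),
              Q = unname(cf["Q"]), fit = fit)
  out$X_RMS_nm <- x_rms(out)
  class(out) <- "spectrum_fit"
  out
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf("Double-Lorentzian spectrum fit: f0 = %.3g Hz, Q = %.3g, A = %.3g nm^2 Hz\n",
              x$f0_Hz, x$Q, x$A_nm2_Hz))
  cat(sprintf("  X_RMS = %.3g nm\n", x$X_RMS_nm))
  invisible(x)
}

#' Root-mean-square oscillation magnitude from a spectrum fit
#'
#' Closed form of the full-line integral of the double Lorentzian:
#' `X_RMS = sqrt(4 pi A Q / f0)`.
#'
#' @param fit A [fit_double_lorentzian()] result, or a list with elements
#'   `A_nm2_Hz`, `f0_Hz`, `Q`.
#' @return X_RMS, nm.
#' @export
x_rms <- function(fit) {
  sqrt(4 * pi * fit$A_nm2_Hz * fit$Q / fit$f0_Hz)
}

#' Open probability from a bimodal position histogram
#'
#' Fits a two-component Gaussian mixture to a sample of bundle positions
#' (EM via mclust with unequal variances, initialised on a deterministic
#' evenly-spaced order-statistic subset). The steady-state open probability
#' is the weight of the component whose mean lies above the sample mean.
#' The fit is flagged unreliable when the modes are closer than one (larger)
#' component SD or when either weight is below 5%.
#'
#' @param positions Numeric sample of bundle positions, nm (n >= 1000 for a
#'   stable mixture fit).
#' @return An object of class `bimodal_fit`: a list with `P_oSS`, `weights`,
#'   `means_nm`, `sds_nm`, `bimodal` (FALSE when the fit is unreliable; then
#'   `P_oSS` is NA).
#' @importFrom mclust Mclust mclustBIC
#' @export
open_prob_from_bimodal <- function(positions) {
  positions <- positions[is.finite(positions)]
  n <- length(positions)
  if (n < 1000) stop("need >= 1000 positions for a stable mixture fit", call. = FALSE)
  sub <- round(seq(1, n, length.out = min(n, 2000)))
  init <- list(subset = order(positions)[sub])
  fit <- mclust::Mclust(positions, G = 2, modelNames = "V",
                        initialization = init, verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed", call. = FALSE)
  mu <- as.numeric(fit$parameters$mean)
  sdv <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sdv) == 1) sdv <- rep(sdv, 2)
  w <- as.numeric(fit$parameters$pro)
  ord <- order(mu)
  mu <- mu[ord]; sdv <- sdv[ord]; w <- w[ord]
  sep_ok <- (mu[2] - mu[1]) >= max(sdv)
  w_ok <- min(w) >= 0.05
  # the fitted mixture must itself be bimodal: a clear density dip between
  # the component means
  dens <- function(x) w[1] * stats::dnorm(x, mu[1], sdv[1]) +
    w[2] * stats::dnorm(x, mu[2], sdv[2])
  grid <- seq(mu[1], mu[2], length.out = 101)
  dg <- dens(grid)
  dip_ok <- length(grid) > 2 && min(dg) < 0.9 * min(dg[1], dg[length(dg)])
  bimodal <- sep_ok && w_ok && dip_ok
  open_comp <- which(mu > mean(positions))
  P <- if (bimodal && length(open_comp) >= 1) sum(w[open_comp]) else NA_real_
  structure(
    list(P_oSS = P, weights = w, means_nm = mu, sds_nm = sdv, bimodal = bimodal),
    class = "bimodal_fit"
  )
}
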