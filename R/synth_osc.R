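# Surrogate spontaneous-oscillation traces and bimodal position samples.
#
# Spontaneous hair-bundle oscillations have a power spectrum well described
# by a double Lorentzian (one line at +f0, its mirror at -f0). Traces are
# generated as linear spectral surrogates: independent complex-Gaussian
# Fourier coefficients with variance proportional to the target density,
# inverse-transformed to a real trace. This reproduces the second-order
# statistics (spectrum, variance) of an oscillating bundle without
# committing to a mechanistic oscillator model.

# Two-sided double-Lorentzian spectral density, nm^2/Hz.
double_lorentzian <- function(f, A, f0, Q) {
  hw2 <- (f0 / (2 * Q))^2
  A / (hw2 + (f - f0)^2) + A / (hw2 + (f + f0)^2)
}

#' Generate a spontaneous-oscillation surrogate trace
#'
#' Spectral synthesis of a real-valued trace whose expected two-sided power
#' spectral density is the double Lorentzian with amplitude `A`,
#' characteristic frequency `f0` and quality factor `Q`. The expected
#' variance is the full-line integral `4 pi A Q / f0` (minus the small tail
#' beyond the Nyquist frequency).
#'
#' @param A Spectral amplitude, nm^2 Hz.
#' @param f0 Characteristic frequency, Hz.
#' @param Q Quality factor.
#' @param fs Sampling rate, Hz; must exceed `4 * f0`.
#' @param duration Trace duration, s; `duration * f0 >= 100` recommended.
#' @param seed Optional scoped seed.
#' @return A data frame of class `osc_ts` with columns `t_s`, `X_nm` and
#'   attribute `fs_Hz`.
#' @export
gen_oscillation_trace <- function(A, f0, Q, fs = 250, duration = 20, seed = NULL) {
  if (A < 0 || f0 <= 0 || Q <= 0) stop("require A >= 0, f0 > 0, Q > 0", call. = FALSE)
  if (fs <= 4 * f0) {
    stop(sprintf("sampling rate fs = %g Hz too low for f0 = %g Hz (aliasing); need fs > 4 f0",
                 fs, f0), call. = FALSE)
  }
  n <- round(fs * duration)
  run <- function() {
    if (A == 0) {
      x <- numeric(n)
    } else {
      k <- 0:(n - 1)
      f <- k / n * fs
      f[f > fs / 2] <- f[f > fs / 2] - fs          # wrap to (-fs/2, fs/2]
      sd_k <- sqrt(n * fs * double_lorentzian(f, A, f0, Q))
      half <- 2:ceiling(n / 2)                      # k = 1 .. floor((n-1)/2)
      Z <- complex(length.out = n)
      re <- stats::rnorm(length(half)); im <- stats::rnorm(length(half))
      Z[half] <- complex(real = re, imaginary = im) / sqrt(2) * sd_k[half]
      Z[n + 2 - half] <- Conj(Z[half])
      if (n %% 2 == 0) Z[n / 2 + 1] <- stats::rnorm(1) * sd_k[n / 2 + 1]
      Z[1] <- 0                                    # zero-mean trace
      x <- Re(stats::fft(Z, inverse = TRUE)) / n
    }
    structure(data.frame(t_s = (0:(n - 1)) / fs, X_nm = x),
              fs_Hz = fs, class = c("osc_ts", "data.frame"))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Draw positions from a two-Gaussian (closed/open) mixture
#'
#' Emulates the bimodal position histogram of a relaxation-oscillating hair
#' bundle dwelling near a channels-closed and a channels-open position. The
#' component labelled "open" must have the larger mean.
#'
#' @param w Weight of the open mode, in \[0, 1\].
#' @param mu_c,mu_o Means of the closed and open modes, nm (`mu_o > mu_c`).
#' @param sd_c,sd_o Mode standard deviations, nm.
#' @param n Number of draws.
#' @param seed Optional scoped seed.
#' @return Numeric vector of positions, nm.
#' @export
gen_bimodal_positions <- function(w = 0.5, mu_c = -20, mu_o = 30, sd_c = 8,
                                  sd_o = 8, n = 10000, seed = NULL) {
  if (w < 0 || w > 1) stop("open-mode weight w must lie in [0, 1]", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (mu_o <= mu_c) {
    stop("label-order error: open-mode mean mu_o must exceed closed-mode mean mu_c",
         call. = FALSE)
  }
  run <- function() {
    open <- stats::runif(n) < w
    x <- numeric(n)
    x[open] <- stats::rnorm(sum(open), mu_o, sd_o)
    x[!open] <- stats::rnorm(sum(!open), mu_c, sd_c)
    x
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
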