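# Oscillation synthesis and spectral analysis: Parseval, smoothing,
# double-Lorentzian fit, X_RMS, bimodal open probability.

test_that("the surrogate trace variance matches the closed-form spectral integral", {
  # A = 1, Q = 1, f0 = 4*pi gives X_RMS = sqrt(4*pi*A*Q/f0) = 1
  rms <- vapply(1:5, function(s) {
    stats::sd(gen_oscillation_trace(1, 4 * pi, 1, fs = 500, duration = 30,
                                    seed = s)$X_nm)
  }, numeric(1))
  expect_lt(abs(stats::median(rms) - 1), 0.05)
  # zero amplitude: all-zero trace
  expect_true(all(gen_oscillation_trace(0, 8, 2, fs = 250, duration = 2)$X_nm == 0))
  # aliasing guard
  expect_error(gen_oscillation_trace(1, 100, 2, fs = 250, duration = 2), "aliasing")
  # deterministic under a fixed seed
  expect_identical(gen_oscillation_trace(1, 8, 2, seed = 3),
                   gen_oscillation_trace(1, 8, 2, seed = 3))
})

test_that("the averaged periodogram matches the generating density near the peak", {
  A <- 2; f0 <- 8; Q <- 2
  n_seeds <- 30
  acc <- NULL
  for (s in seq_len(n_seeds)) {
    ts <- gen_oscillation_trace(A, f0, Q, fs = 250, duration = 20, seed = 300 + s)
    sp <- power_spectrum(ts, n_segments = 5)
    acc <- if (is.null(acc)) sp$psd_nm2_per_Hz else acc + sp$psd_nm2_per_Hz
  }
  mean_psd <- acc / n_seeds
  f <- power_spectrum(gen_oscillation_trace(A, f0, Q, fs = 250, duration = 20,
                                            seed = 1), n_segments = 5)$f_Hz
  band <- f >= f0 / 4 & f <= 4 * f0
  target <- gatingspring:::double_lorentzian(f[band], A, f0, Q)
  rel <- mean(mean_psd[band] / target)
  expect_lt(abs(rel - 1), 0.05)
})

test_that("Parseval holds for the segment-averaged periodogram", {
  # white noise: flat spectrum integrating to the variance
  set.seed(4)
  wn <- data.frame(t_s = (0:9999) / 1000, X_nm = stats::rnorm(10000, 0, 3))
  s <- power_spectrum(wn, n_segments = 8)
  expect_lt(abs(spectrum_variance(s) / attr(s, "variance_nm2") - 1), 0.01)
  expect_lt(abs(spectrum_variance(s) / 9 - 1), 0.03)
  # a pure sine of amplitude a carries power a^2/2
  t <- (0:7999) / 1000
  sine <- data.frame(t_s = t, X_nm = 5 * sin(2 * pi * 16 * t))
  ss <- power_spectrum(sine, n_segments = 4)
  expect_lt(abs(spectrum_variance(ss) / (25 / 2) - 1), 0.01)
  # an oscillation surrogate
  ts <- gen_oscillation_trace(2, 8, 2, fs = 250, duration = 20, seed = 11)
  so <- power_spectrum(ts, n_segments = 5)
  expect_lt(abs(spectrum_variance(so) / attr(so, "variance_nm2") - 1), 0.01)
  # nonuniform sampling is rejected
  bad <- data.frame(t_s = cumsum(c(0.001, 0.001, 0.003, 0.001)), X_nm = 1:4)
  expect_error(power_spectrum(bad), "uniform")
})

test_that("smoothing is integral-preserving and widens spikes", {
  ts <- gen_oscillation_trace(2, 8, 2, fs = 250, duration = 20, seed = 2)
  s <- power_spectrum(ts, n_segments = 5)
  sm <- smooth_spectrum(s, window_Hz = 1)
  expect_lt(abs(spectrum_variance(sm) / spectrum_variance(s) - 1), 0.005)
  # flat spectrum is unchanged
  flat <- s; flat$psd_nm2_per_Hz <- rep(2, nrow(s))
  smf <- smooth_spectrum(flat, 1)
  expect_equal(smf$psd_nm2_per_Hz, flat$psd_nm2_per_Hz, tolerance = 1e-12)
  # a single-bin spike spreads over the window with conserved integral
  spike <- s; spike$psd_nm2_per_Hz <- rep(0, nrow(s))
  spike$psd_nm2_per_Hz[100] <- 40
  sms <- smooth_spectrum(spike, 1)
  expect_gt(sum(sms$psd_nm2_per_Hz > 0), 2)
  expect_lt(abs(sum(sms$psd_nm2_per_Hz) / 40 - 1), 0.005)
  # sub-resolution window is a no-op with a warning
  expect_warning(smooth_spectrum(s, window_Hz = attr(s, "df_Hz") / 2), "resolution")
})

test_that("the double-Lorentzian fit recovers exact and surrogate spectra", {
  # exact curve round trip
  f <- seq(0.25, 60, by = 0.25)
  P <- gatingspring:::double_lorentzian(f, 1, 8, 2)
  s <- structure(data.frame(f_Hz = f, psd_nm2_per_Hz = P),
                 df_Hz = 0.25, fs_Hz = 120,
                 class = c("bundle_spectrum", "data.frame"))
  fit <- fit_double_lorentzian(s)
  expect_equal(fit$A_nm2_Hz, 1, tolerance = 1e-6)
  expect_equal(fit$f0_Hz, 8, tolerance = 1e-6)
  expect_equal(fit$Q, 2, tolerance = 1e-6)
  # surrogate recovery in the median over seeds
  f0s <- Qs <- numeric(20)
  for (s_i in 1:20) {
    ts <- gen_oscillation_trace(2, 8, 2, fs = 250, duration = 20, seed = 40 + s_i)
    ft <- fit_double_lorentzian(smooth_spectrum(power_spectrum(ts, 5), 1))
    f0s[s_i] <- ft$f0_Hz; Qs[s_i] <- ft$Q
  }
  expect_lt(abs(stats::median(f0s) / 8 - 1), 0.05)
  expect_lt(abs(stats::median(Qs) / 2 - 1), 0.15)
  # peakless spectrum fails loudly
  flat <- structure(data.frame(f_Hz = f, psd_nm2_per_Hz = rep(1, length(f))),
                    df_Hz = 0.25, fs_Hz = 120,
                    class = c("bundle_spectrum", "data.frame"))
  expect_error(fit_double_lorentzian(flat), "peak")
})

test_that("high-Q lines have FWHM close to f0/Q", {
  f <- seq(0.05, 40, by = 0.05)
  P <- gatingspring:::double_lorentzian(f, 1, 10, 20)
  above <- f[P >= max(P) / 2]
  fwhm <- diff(range(above))
  expect_lt(abs(fwhm / (10 / 20) - 1), 0.02)
})

test_that("the closed-form X_RMS equals the quadrature of the spectral model", {
  expect_equal(x_rms(list(A_nm2_Hz = 1, Q = 1, f0_Hz = 4 * pi)), 1, tolerance = 1e-12)
  expect_equal(x_rms(list(A_nm2_Hz = 0, Q = 1, f0_Hz = 8)), 0)
  set.seed(99)
  for (i in 1:50) {
    A <- stats::runif(1, 0.1, 5)
    f0 <- stats::runif(1, 2, 40)
    Q <- stats::runif(1, 0.5, 10)
    quad <- stats::integrate(function(ff) gatingspring:::double_lorentzian(ff, A, f0, Q),
                             -Inf, Inf, rel.tol = 1e-9)$value
    expect_lt(abs(x_rms(list(A_nm2_Hz = A, Q = Q, f0_Hz = f0)) / sqrt(quad) - 1), 0.01)
  }
})

test_that("the full spectral pipeline recovers the sample RMS", {
  for (Q in c(0.5, 2, 5)) {
    devs <- vapply(1:3, function(s) {
      ts <- gen_oscillation_trace(2, 8, Q, fs = 250, duration = 30, seed = 600 + 10 * Q + s)
      ft <- fit_double_lorentzian(smooth_spectrum(power_spectrum(ts, 5), 1))
      ft$X_RMS_nm / stats::sd(ts$X_nm)
    }, numeric(1))
    expect_lt(abs(stats::median(devs) - 1), 0.1)
  }
})

test_that("the bimodal-histogram open probability is the open-mode weight", {
  x <- gen_bimodal_positions(0.7, mu_c = -20, mu_o = 30, sd_c = 8, sd_o = 8,
                             n = 1e5, seed = 5)
  bf <- open_prob_from_bimodal(x)
  expect_true(bf$bimodal)
  expect_lt(abs(bf$P_oSS - 0.7), 0.01)
  # equal symmetric modes: one half
  xs <- gen_bimodal_positions(0.5, -25, 25, 8, 8, n = 5e4, seed = 9)
  expect_lt(abs(open_prob_from_bimodal(xs)$P_oSS - 0.5), 0.02)
  # degenerate unimodal sample is flagged
  x1 <- gen_bimodal_positions(1, -20, 30, 8, 8, n = 5000, seed = 6)
  b1 <- open_prob_from_bimodal(x1)
  expect_false(b1$bimodal); expect_true(is.na(b1$P_oSS))
  # overlapping modes (separation below one SD) are unreliable
  xo <- gen_bimodal_positions(0.5, 0, 6, 8, 8, n = 2e4, seed = 7)
  expect_false(open_prob_from_bimodal(xo)$bimodal)
  # generator guards
  expect_error(gen_bimodal_positions(0.5, mu_c = 10, mu_o = -10), "label-order")
  expect_error(gen_bimodal_positions(1.2), "weight")
  expect_error(open_prob_from_bimodal(rnorm(100)), "1000")
})

test_that("mean of a balanced symmetric mixture sits at the midpoint", {
  x <- gen_bimodal_positions(0.5, -30, 30, 6, 6, n = 4e4, seed = 12)
  se <- 30 / sqrt(4e4) * 3    # generous: 3 x SE of the mean
  expect_lt(abs(mean(x)), se + 1)
})
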