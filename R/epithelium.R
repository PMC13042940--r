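# The transepithelial circuit behaves as a resistor and capacitor in
# parallel: a current step I produces a potential relaxing exponentially to
# U = I R with time constant tau = R C (kOhm x nF = us). The steady-state
# potential converts applied current to endolymphatic potential.

#' Simulate a transepithelial RC step response
#'
#' `U(t) = I R (1 - exp(-t / (R C)))` plus optional Gaussian noise.
#'
#' @param R Transepithelial resistance, kOhm.
#' @param C Transepithelial capacitance, nF.
#' @param I_step Current step amplitude, uA.
#' @param fs Sampling rate, Hz.
#' @param duration Record duration, s.
#' @param noise_sd Measurement noise SD, mV.
#' @param seed Optional scoped seed.
#' @return A data frame of class `rc_ts` with columns `t_s`, `U_mV`.
#' @export
gen_rc_step <- function(R = 10, C = 23, I_step = 1, fs = 2e6, duration = 2e-3,
                        noise_sd = 0, seed = NULL) {
  if (R <= 0 || C <= 0) stop("R and C must be > 0", call. = FALSE)
  t <- seq(0, duration, by = 1 / fs)
  tau_s <- R * C * 1e-6                       # kOhm x nF -> us -> s
  U <- I_step * R * (1 - exp(-t / tau_s))
  run <- function() {
    structure(data.frame(t_s = t, U_mV = U + stats::rnorm(length(t), 0, noise_sd)),
              class = c("rc_ts", "data.frame"))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Fit an exponential approach to steady state
#'
#' Least-squares fit of `U(t) = A (1 - exp(-t/tau))`, equivalently a pure
#' exponential decay of the residual `A - U(t)`; the two parameterizations
#' coincide on the fitted amplitude and time constant.
#'
#' @param ts A data frame with columns `t_s` and `U_mV` (e.g. from
#'   [gen_rc_step()]).
#' @return A list with `A_mV` (steady-state amplitude), `tau_us` (time
#'   constant, microseconds) and `flat` (TRUE when the trace carries no
#'   resolvable relaxation; then `tau_us` is NA).
#' @export
fit_exponential <- function(ts) {
  stopifnot(all(c("t_s", "U_mV") %in% names(ts)))
  t <- ts$t_s - ts$t_s[1]
  U <- ts$U_mV
  n <- length(t)
  tail_mean <- mean(U[t >= 0.9 * max(t)])
  rng <- tail_mean - U[1]
  if (!is.finite(rng) || abs(rng) < 1e-12 || stats::sd(U) < 1e-12) {
    return(list(A_mV = 0, tau_us = NA_real_, flat = TRUE))
  }
  # initial tau from the 63.2% crossing of the total change
  lev <- U[1] + (1 - exp(-1)) * rng
  cross <- if (rng > 0) which(U >= lev)[1] else which(U <= lev)[1]
  tau0 <- if (is.na(cross) || cross < 2) max(t) / 3 else t[cross]
  tau0 <- max(tau0, diff(t)[1])
  fit <- minpack.lm::nlsLM(
    U ~ A * (1 - exp(-t / tau)),
    start = list(A = tail_mean, tau = tau0),
    lower = c(A = -Inf, tau = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  # a smoothed reversal larger than the noise floor signals a non-RC response
  if (n >= 42) {
    Us <- moving_average(U, 21)
    if (min(diff(Us)) * sign(rng) < -1 * stats::sd(stats::resid(fit))) {
      warning("step response is not monotone; exponential fit may be unreliable")
    }
  }
  list(A_mV = unname(cf["A"]), tau_us = unname(cf["tau"]) * 1e6, flat = FALSE)
}

#' Derive R and C from an exponential step fit
#'
#' `R = U_max / I_step` and `C = tau / R` (kOhm, nF, us are unit-consistent).
#'
#' @param A_mV Steady-state potential, mV.
#' @param tau_us Relaxation time constant, us.
#' @param I_step_uA Applied current step, uA (nonzero).
#' @return A list with `R_kOhm`, `C_nF`, `tau_us`.
#' @export
derive_rc <- function(A_mV, tau_us, I_step_uA) {
  if (I_step_uA == 0) stop("I_step must be nonzero", call. = FALSE)
  R <- A_mV / I_step_uA
  list(R_kOhm = R, C_nF = tau_us / R, tau_us = tau_us)
}

#' Convert transepithelial current to endolymphatic potential
#'
#' Ohmic steady state `U = I R`.
#'
#' @param I_uA Transepithelial current, uA.
#' @param R_kOhm Transepithelial resistance, kOhm (default 10, the ensemble
#'   mean).
#' @return Endolymphatic potential, mV.
#' @export
current_to_potential <- function(I_uA, R_kOhm = 10) {
  if (!all(is.finite(c(I_uA, R_kOhm)))) stop("inputs must be finite", call. = FALSE)
  I_uA * R_kOhm
}
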