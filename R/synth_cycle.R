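# Dynamic simulation of a hair bundle under triangular fiber stimulation.
#
# Overdamped bundle dynamics coupled to first-order channel kinetics:
#
#   xi dX/dt   = k_F (Delta(t) - X) - (K X - F_G P_o + F_null)
#   tau_a dP_o/dt = P_inf(X) - P_o
#
# where P_inf is the Boltzmann open probability. In the quasi-static limit
# (tau_a -> 0, slow stimulus) the bundle force collapses onto the
# gating-spring relation; a finite activation time tau_a delays gating
# relative to motion and generates gating friction, i.e. a velocity-odd
# force that widens the force-displacement cycle around the set point.

#' Dynamic bundle parameters
#'
#' @param p A [gating_spring_params()] object.
#' @param xi Effective drag coefficient of bundle plus fiber tip, pN s/nm.
#'   Default 1e-4, a literature-typical order of magnitude.
#' @param tau_a Channel activation time constant, s (>= 0).
#' @param noise_sd Measurement noise SD added to the recorded X (nm) and F
#'   (pN) channels; the dynamics themselves are deterministic.
#' @return An object of class `dynamic_bundle_params`.
#' @export
dynamic_bundle_params <- function(p, xi = 1e-4, tau_a = 1e-3, noise_sd = 0) {
  check_params(p)
  if (!is.finite(xi) || xi <= 0) stop("drag coefficient xi must be > 0", call. = FALSE)
  if (!is.finite(tau_a) || tau_a < 0) stop("activation time tau_a must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(params = p, xi = xi, tau_a = tau_a, noise_sd = noise_sd),
            class = "dynamic_bundle_params")
}

# Symmetric triangle wave, zero-mean, peak-to-peak `pp`, frequency `freq`;
# starts at 0 moving upward.
triangle_wave <- function(t, freq, pp) {
  ph <- (t * freq) %% 1
  pp * (abs(2 * ((ph + 0.75) %% 1) - 1) - 0.5)
}

#' Simulate a triangular-stimulus force-displacement recording
#'
#' Integrates the coupled bundle/channel dynamics under a symmetric
#' triangular fiber-base waveform with an exponential (unconditionally
#' stable) integrator at fixed step `dt`, discards the first cycle as
#' transient, and returns the recording subsampled to `fs_out`.
#'
#' @param dp A [dynamic_bundle_params()] object.
#' @param fiber A [fiber_params()] object.
#' @param freq Stimulus frequency, Hz.
#' @param peak_to_peak Fiber-base peak-to-peak amplitude, nm.
#' @param n_cycles Number of cycles retained after the transient.
#' @param dt Integration step, s. The contract is numerical: halving `dt`
#'   must change the maximal friction force by < 1%.
#' @param fs_out Output sampling rate, Hz (recording emulation).
#' @param seed Optional scoped seed (measurement noise only).
#' @return A data frame of class `cycle_ts` with columns `t_s`, `Delta_nm`,
#'   `X_nm`, `F_pN` and attributes `freq_Hz`, `peak_to_peak_nm`, `n_cycles`.
#' @export
simulate_cycle <- function(dp, fiber = fiber_params(), freq = 40,
                           peak_to_peak = 600, n_cycles = 10, dt = 1e-5,
                           fs_out = 25000, seed = NULL) {
  if (!inherits(dp, "dynamic_bundle_params")) {
    stop("expected a 'dynamic_bundle_params' object", call. = FALSE)
  }
  p <- dp$params
  n_steps <- ceiling((n_cycles + 1) / freq / dt)
  t <- (0:n_steps) * dt
  Delta <- triangle_wave(t, freq, peak_to_peak)
  b <- fiber$k_F + p$K
  decay_x <- exp(-b * dt / dp$xi)
  decay_p <- if (dp$tau_a > 0) exp(-dt / dp$tau_a) else 0
  X <- numeric(n_steps + 1)
  Po <- numeric(n_steps + 1)
  # start from the quasi-static state at Delta = 0
  r0 <- balance_roots(Delta[1], p, fiber)
  cand <- r0$roots[r0$stable]
  X[1] <- cand[which.min(abs(cand))]
  Po[1] <- open_probability(X[1], p$X_0, p$delta)
  guard <- 10 * peak_to_peak
  for (i in seq_len(n_steps)) {
    Dm <- 0.5 * (Delta[i] + Delta[i + 1])  # midpoint drive
    a <- fiber$k_F * Dm + p$F_G * Po[i] - p$F_null
    X[i + 1] <- X[i] * decay_x + (a / b) * (1 - decay_x)
    Pinf <- open_probability(X[i + 1], p$X_0, p$delta)
    Po[i + 1] <- Pinf + (Po[i] - Pinf) * decay_p
    if (abs(X[i + 1]) > guard) {
      stop(sprintf("simulation diverged (|X| > 10x stimulus amplitude); dt = %g s", dt),
           call. = FALSE)
    }
  }
  keep <- t >= 1 / freq - dt / 2            # drop the transient first cycle
  t <- t[keep] - 1 / freq
  Delta <- Delta[keep]; X <- X[keep]
  stride <- max(1L, round(1 / (fs_out * dt)))
  sel <- seq(1L, length(t), by = stride)
  t <- t[sel]; Delta <- Delta[sel]; X <- X[sel]
  emit <- function() {
    X_obs <- X + stats::rnorm(length(X), 0, dp$noise_sd)
    F_obs <- fiber$k_F * (Delta - X) + stats::rnorm(length(X), 0, dp$noise_sd)
    structure(
      data.frame(t_s = t, Delta_nm = Delta, X_nm = X_obs, F_pN = F_obs),
      freq_Hz = freq, peak_to_peak_nm = peak_to_peak, n_cycles = n_cycles,
      class = c("cycle_ts", "data.frame")
    )
  }
  if (is.null(seed)) emit() else withr::with_seed(seed, emit())
}
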