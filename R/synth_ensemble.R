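# Per-cell ensembles with the measured current-dependence structure.
#
# Across cells, the changes of set-point, stiffness, gating force and
# gating swing evoked by a transepithelial current I follow linear
# regressions with known slopes, intercepts and R^2. The generator draws
# each observable from its regression line plus Gaussian residuals whose
# variance is matched to the target R^2, and applies the strong/weak-state
# transition: below a threshold current the gating force (and hence the
# gating swing) drops to undetectable levels.

#' Hysteretic strong/weak gating-state transition model
#'
#' @param F_G0 Control gating force, pN.
#' @param slope_FG Gating-force sensitivity dF_G/dI, pN/uA.
#' @param I_down Transition current on a descending ramp, uA. Default -5,
#'   the critical current below which static force-displacement relations
#'   turn linear.
#' @param hyst Hysteresis shift between ascending and descending
#'   transitions, uA (>= 0). Default 2.3.
#' @param weak_F_G Gating force in the weak state; pinned to 0.
#' @return An object of class `state_transition_model`.
#' @export
state_transition_model <- function(F_G0 = 17, slope_FG = -2.3, I_down = -5,
                                   hyst = 2.3, weak_F_G = 0) {
  if (hyst < 0) stop("hysteresis shift must be >= 0", call. = FALSE)
  if (weak_F_G != 0) stop("the weak state has zero gating force by definition", call. = FALSE)
  structure(list(F_G0 = F_G0, slope_FG = slope_FG, I_down = I_down,
                 hyst = hyst, weak_F_G = 0),
            class = "state_transition_model")
}

# One observable's regression model: value = slope * I + intercept + noise,
# with noise variance slope^2 Var(I) (1 - R^2) / R^2 so that the expected
# ordinary-least-squares R^2 equals `r_squared`.
obs_model <- function(slope, intercept, r_squared) {
  if (!(r_squared > 0 && r_squared <= 1)) {
    stop("config error: R^2 must lie in (0, 1]", call. = FALSE)
  }
  list(slope = slope, intercept = intercept, r_squared = r_squared)
}

#' Ensemble generator configuration
#'
#' Defaults reproduce the measured current-dependence regressions:
#' dX0 \[nm\] = 4.6 I - 9.6 (R^2 = 0.75); dK \[pN/nm\] = -0.01 I + 0.04
#' (R^2 = 0.33); dFG \[pN\] = -2.3 I + 5 (R^2 = 0.74); dd_rel \[%\] =
#' -11 I + 22 (R^2 = 0.78).
#'
#' @param currents Current grid, uA; recycled across cells.
#' @param n_cells Number of cells (>= 3); one condition row per cell plus a
#'   control row at I = 0.
#' @param dX0,dK,dFG,dd_rel Per-observable regression models from
#'   [obs_model()] as `list(slope, intercept, r_squared)`.
#' @param control_mean,control_sd Named vectors (K, F_G, X_0) of the
#'   control-condition population means and between-cell SDs.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(currents = seq(-5, 10, length.out = 34),
                            n_cells = length(currents),
                            dX0 = obs_model(4.6, -9.6, 0.75),
                            dK = obs_model(-0.01, 0.04, 0.33),
                            dFG = obs_model(-2.3, 5, 0.74),
                            dd_rel = obs_model(-11, 22, 0.78),
                            control_mean = c(K = 0.85, F_G = 17, X_0 = -2),
                            control_sd = c(K = 0.2, F_G = 4, X_0 = 7)) {
  if (n_cells < 3) stop("n_cells must be >= 3", call. = FALSE)
  for (m in list(dX0, dK, dFG, dd_rel)) obs_model(m$slope, m$intercept, m$r_squared)
  structure(list(currents = currents, n_cells = n_cells, dX0 = dX0, dK = dK,
                 dFG = dFG, dd_rel = dd_rel, control_mean = control_mean,
                 control_sd = control_sd),
            class = "ensemble_config")
}

draw_obs <- function(m, I) {
  vI <- stats::var(I)
  sd_res <- if (m$r_squared == 1 || vI == 0) 0 else {
    abs(m$slope) * sqrt(vI * (1 - m$r_squared) / m$r_squared)
  }
  m$slope * I + m$intercept + stats::rnorm(length(I), 0, sd_res)
}

#' Generate a per-cell ensemble table
#'
#' Each cell contributes a control row (I = 0) and one condition row at its
#' assigned current. Condition deltas are drawn from the configured
#' regression models with R^2-matched residuals; rows below the state
#' threshold (`I < I_down` on a descending approach, `I < I_down + hyst`
#' ascending) are set to the weak state with zero gating force and swing.
#'
#' @param cfg An [ensemble_config()] object.
#' @param stm A [state_transition_model()] object.
#' @param seed Optional scoped seed.
#' @param direction `"descending"` (default) or `"ascending"` approach to
#'   the condition current, which sets the transition threshold.
#' @param geo A [bundle_geometry()] object for gating-swing conversion.
#' @return A data frame of class `ensemble_table` with columns `cell_id`,
#'   `I_uA`, `K_pN_per_nm`, `F_G_pN`, `X0_nm`, `d_nm`, `state`, and the
#'   condition deltas `dX0_nm`, `dK_pN_per_nm`, `dFG_pN`, `dd_rel_pct`
#'   (NA on control rows by convention of being zero-valued deltas).
#' @export
gen_ensemble <- function(cfg = ensemble_config(), stm = state_transition_model(),
                         seed = NULL, direction = c("descending", "ascending"),
                         geo = bundle_geometry()) {
  direction <- match.arg(direction)
  thr <- if (direction == "descending") stm$I_down else stm$I_down + stm$hyst
  run <- function() {
    n <- cfg$n_cells
    I <- rep_len(cfg$currents, n)
    K0 <- pmax(stats::rnorm(n, cfg$control_mean["K"], cfg$control_sd["K"]),
               geo$K_SP + 0.05)
    FG0 <- pmax(stats::rnorm(n, cfg$control_mean["F_G"], cfg$control_sd["F_G"]), 0.5)
    X00 <- stats::rnorm(n, cfg$control_mean["X_0"], cfg$control_sd["X_0"])
    d0 <- geo$gamma * FG0 / (K0 - geo$K_SP)
    dX0 <- draw_obs(cfg$dX0, I)
    dK <- draw_obs(cfg$dK, I)
    dFG <- draw_obs(cfg$dFG, I)
    dd <- draw_obs(cfg$dd_rel, I)
    weak <- I < thr
    K1 <- pmax(K0 + dK, geo$K_SP + 0.01)
    FG1 <- ifelse(weak, 0, pmax(FG0 + dFG, 0))
    d1 <- ifelse(weak, 0, pmax(d0 * (1 + dd / 100), 0))
    dFG[weak] <- -FG0[weak]
    dd[weak] <- -100
    cell <- sprintf("cell%02d", seq_len(n))
    ctrl <- data.frame(
      cell_id = cell, I_uA = 0, K_pN_per_nm = K0, F_G_pN = FG0, X0_nm = X00,
      d_nm = d0, state = "strong", dX0_nm = 0, dK_pN_per_nm = 0, dFG_pN = 0,
      dd_rel_pct = 0, stringsAsFactors = FALSE
    )
    cond <- data.frame(
      cell_id = cell, I_uA = I, K_pN_per_nm = K1, F_G_pN = FG1,
      X0_nm = X00 + dX0, d_nm = d1, state = ifelse(weak, "weak", "strong"),
      dX0_nm = dX0, dK_pN_per_nm = dK, dFG_pN = dFG, dd_rel_pct = dd,
      stringsAsFactors = FALSE
    )
    out <- rbind(ctrl, cond)
    out <- out[order(out$cell_id, out$I_uA != 0), ]
    rownames(out) <- NULL
    class(out) <- c("ensemble_table", "data.frame")
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate hysteretic friction-vs-current ramp branches
#'
#' Emulates the maximal friction force phi_MAX measured while the
#' transepithelial current is ramped down and back up: a strong-state
#' plateau, a logistic drop to the weak-state level centred at `stm$I_down`
#' on the descending branch and at `stm$I_down + hyst` on the ascending
#' branch, plus measurement noise. The same model serves for a generic
#' control-parameter axis (e.g. iontophoretic current).
#'
#' @param stm A [state_transition_model()] object.
#' @param I_max,I_min Ramp endpoints, uA.
#' @param step Current spacing between successive cycle measurements, uA.
#' @param phi_strong,phi_weak Strong- and weak-state phi_MAX plateaus, pN.
#' @param width Logistic width of the drop, uA.
#' @param noise_sd Measurement noise SD on phi_MAX, pN.
#' @param seed Optional scoped seed.
#' @return A list of two data frames, `descending` and `ascending`, each
#'   with columns `I_uA`, `phi_max_pN`, ordered as traversed.
#' @export
gen_transition_ramp <- function(stm = state_transition_model(I_down = -6.9),
                                I_max = 0, I_min = -9, step = 0.1,
                                phi_strong = 15, phi_weak = 1, width = 0.3,
                                noise_sd = 0, seed = NULL) {
  run <- function() {
    branch <- function(I, mid) {
      phi <- phi_weak + (phi_strong - phi_weak) / (1 + exp(-(I - mid) / width))
      data.frame(I_uA = I, phi_max_pN = phi + stats::rnorm(length(I), 0, noise_sd))
    }
    I_dn <- seq(I_max, I_min, by = -abs(step))
    I_up <- seq(I_min, I_max, by = abs(step))
    list(descending = branch(I_dn, stm$I_down),
         ascending = branch(I_up, stm$I_down + stm$hyst))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate paired step-kinetics traces
#'
#' Exponential relaxations of the cycle-averaged bundle position and of the
#' maximal friction force following the onset and offset of a current step,
#' with independent ON/OFF time constants for the two observables.
#'
#' @param tau_on_X,tau_off_X Position time constants, s.
#' @param tau_on_phi,tau_off_phi Friction time constants, s.
#' @param t_on,t_off Step onset and offset times, s.
#' @param duration Total record duration, s.
#' @param fs Sampling rate of the per-cycle measurements, Hz.
#' @param x_base,x_step Baseline and stepped values of the mean position, nm.
#' @param phi_base,phi_step Baseline and stepped values of phi_MAX, pN.
#' @param noise_sd Measurement noise SD (applied to both channels in their
#'   own units).
#' @param seed Optional scoped seed.
#' @return A data frame of class `kinetics_ts` with columns `t_s`,
#'   `xbar_nm`, `phimax_pN` and attributes recording the generating
#'   constants.
#' @export
gen_step_kinetics <- function(tau_on_X = 0.5, tau_off_X = 0.1,
                              tau_on_phi = 0.18, tau_off_phi = 0.4,
                              t_on = 0.5, t_off = 4, duration = 7.5, fs = 1000,
                              x_base = 0, x_step = -150,
                              phi_base = 15, phi_step = 1,
                              noise_sd = 0, seed = NULL) {
  stopifnot(tau_on_X > 0, tau_off_X > 0, tau_on_phi > 0, tau_off_phi > 0,
            t_on < t_off, t_off < duration)
  t <- seq(0, duration, by = 1 / fs)
  relax <- function(base, plateau, tau_on, tau_off) {
    y <- rep(base, length(t))
    on <- t >= t_on & t < t_off
    y[on] <- plateau + (base - plateau) * exp(-(t[on] - t_on) / tau_on)
    y_off0 <- plateau + (base - plateau) * exp(-(t_off - t_on) / tau_on)
    off <- t >= t_off
    y[off] <- base + (y_off0 - base) * exp(-(t[off] - t_off) / tau_off)
    y
  }
  xbar <- relax(x_base, x_step, tau_on_X, tau_off_X)
  phim <- relax(phi_base, phi_step, tau_on_phi, tau_off_phi)
  run <- function() {
    structure(
      data.frame(t_s = t,
                 xbar_nm = xbar + stats::rnorm(length(t), 0, noise_sd),
                 phimax_pN = phim + stats::rnorm(length(t), 0, noise_sd)),
      t_on_s = t_on, t_off_s = t_off,
      class = c("kinetics_ts", "data.frame")
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
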