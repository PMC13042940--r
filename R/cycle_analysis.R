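# Reduction of triangular-stimulus recordings to averaged
# force-displacement cycles and gating-friction metrics.
#
# The half-height of the cycle at position X, phi(X) = [F+(X) - F-(X)]/2,
# is the average friction force opposing the motion there. Delayed channel
# gating makes phi peak near the set point X_0 (gating friction); the peak
# value phi_MAX reports the magnitude of the gating force, and the shift
# between the positions of maximal bundle speed on the two half-cycles
# gives the channel activation time tau = dX / (2 V_MAX).

moving_average <- function(x, k = 5) {
  if (k <= 1) return(x)
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2)) -> y
  # shrink the window at the edges instead of dropping samples
  h <- (k - 1) %/% 2
  n <- length(x)
  for (i in which(is.na(y))) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    y[i] <- mean(x[lo:hi])
  }
  y
}

#' Average a triangular-stimulus recording into a force-displacement cycle
#'
#' Folds the record onto the stimulus phase, splits samples by the sign of
#' the fiber-base velocity, bins the bundle position onto a common grid
#' (width = stimulus peak-to-peak / 100) and averages the force per bin and
#' half-cycle.
#'
#' @param ts A recording with columns `t_s`, `Delta_nm`, `X_nm`, `F_pN`
#'   (e.g. from [simulate_cycle()]).
#' @param freq Stimulus frequency, Hz; taken from the recording's
#'   `freq_Hz` attribute when `NULL`.
#' @param n_cycles Number of whole cycles to average; `NULL` uses all whole
#'   cycles in the record.
#' @return An object of class `force_cycle`: a data frame with columns
#'   `X_nm`, `F_plus_pN`, `F_minus_pN` on the common grid, plus attributes
#'   `freq_Hz`, `peak_to_peak_nm`, `n_averaged`.
#' @export
average_cycles <- function(ts, freq = NULL, n_cycles = NULL) {
  stopifnot(all(c("t_s", "Delta_nm", "X_nm", "F_pN") %in% names(ts)))
  if (is.null(freq)) freq <- attr(ts, "freq_Hz")
  if (is.null(freq)) stop("stimulus frequency unknown; pass `freq`", call. = FALSE)
  T <- 1 / freq
  total <- max(ts$t_s) - min(ts$t_s)
  avail <- floor(total / T + 1e-9)
  if (is.null(n_cycles)) n_cycles <- avail
  if (n_cycles > avail) {
    stop(sprintf("record holds only %d whole cycles (requested %d)", avail, n_cycles),
         call. = FALSE)
  }
  keep <- ts$t_s - min(ts$t_s) < n_cycles * T + 1e-12
  ts <- ts[keep, ]
  pp <- diff(range(ts$Delta_nm))
  up <- c(diff(ts$Delta_nm) > 0, NA)
  up[length(up)] <- up[length(up) - 1]
  binw <- pp / 100
  grid_breaks <- seq(min(ts$X_nm) - binw, max(ts$X_nm) + binw, by = binw)
  bin <- cut(ts$X_nm, grid_breaks, labels = FALSE)
  # bin-average each half-cycle (denoising), then interpolate the bin means
  # onto shared grid centres so the two branches are compared at identical X
  agg <- function(sel) {
    fm <- tapply(ts$F_pN[sel], bin[sel], mean)
    xm <- tapply(ts$X_nm[sel], bin[sel], mean)
    list(X = as.numeric(xm), F = as.numeric(fm))
  }
  a_up <- agg(which(up)); a_dn <- agg(which(!up))
  lo <- max(min(a_up$X), min(a_dn$X))
  hi <- min(max(a_up$X), max(a_dn$X))
  if (hi <= lo) stop("half-cycles share no displacement support", call. = FALSE)
  centres <- grid_breaks + binw / 2
  centres <- centres[centres >= lo & centres <= hi]
  out <- data.frame(
    X_nm = centres,
    F_plus_pN = stats::approx(a_up$X, a_up$F, centres, ties = mean)$y,
    F_minus_pN = stats::approx(a_dn$X, a_dn$F, centres, ties = mean)$y
  )
  rownames(out) <- NULL
  structure(out, freq_Hz = freq, peak_to_peak_nm = pp, n_averaged = n_cycles,
            class = c("force_cycle", "data.frame"))
}

#' Friction profile of a force-displacement cycle
#'
#' `phi(X) = [F+(X) - F-(X)] / 2` on the common grid. The outermost 5% of
#' the displacement range at each end is excluded from the summary
#' statistics (fiber-reversal artifacts); a profile whose interior relative
#' range is below 5% is flagged flat (pure viscous drag) and its argmax is
#' reported as NA.
#'
#' @param cycle A [average_cycles()] result.
#' @return A list with `X_nm`, `phi_pN` (full grid), `phi_max_pN`,
#'   `X_at_max_nm`, `flat`, and the interior index range used.
#' @export
friction_profile <- function(cycle) {
  stopifnot(inherits(cycle, "force_cycle") ||
              all(c("X_nm", "F_plus_pN", "F_minus_pN") %in% names(cycle)))
  phi <- (cycle$F_plus_pN - cycle$F_minus_pN) / 2
  X <- cycle$X_nm
  rng <- range(X)
  margin <- 0.05 * diff(rng)
  interior <- which(X >= rng[1] + margin & X <= rng[2] - margin)
  if (length(interior) == 0) interior <- seq_along(X)
  phi_i <- phi[interior]
  spread <- diff(range(phi_i))
  flat <- spread < 0.05 * max(abs(phi_i), 1e-12)
  imax <- interior[which.max(phi_i)]
  list(
    X_nm = X, phi_pN = phi,
    phi_max_pN = max(phi_i),
    X_at_max_nm = if (flat) NA_real_ else X[imax],
    flat = flat, interior = interior
  )
}

#' Point of inversion symmetry of a force-displacement cycle
#'
#' The abscissa is the friction-profile argmax (identified with the
#' set-point deflection X_0); the ordinate is the mid-force
#' `F_0 = [F+(X_0) + F-(X_0)] / 2`. A flat profile is flagged and the grid
#' midpoint returned.
#'
#' @param cycle A [average_cycles()] result.
#' @return A list with `X0_nm`, `F0_pN`, `flat`.
#' @export
inversion_point <- function(cycle) {
  fp <- friction_profile(cycle)
  X <- cycle$X_nm
  x0 <- if (fp$flat) mean(range(X)) else fp$X_at_max_nm
  f0 <- (stats::approx(X, cycle$F_plus_pN, x0)$y +
           stats::approx(X, cycle$F_minus_pN, x0)$y) / 2
  list(X0_nm = x0, F0_pN = f0, flat = fp$flat)
}

#' Channel activation time from a triangular-stimulus recording
#'
#' The bundle speed |dX/dt| peaks where the bundle is softest, i.e. in the
#' gating region; a finite activation time displaces that region along the
#' direction of motion, by opposite amounts on the two half-cycles. The
#' estimate is `tau = dX / (2 V_MAX)` with `dX` the shift between the
#' positions of maximal speed and `V_MAX` the maximal speed. Positions and
#' speeds are computed from the phase-averaged trajectory after a 5-sample
#' moving-average smoothing.
#'
#' @param ts A recording with columns `t_s`, `Delta_nm`, `X_nm`.
#' @param freq Stimulus frequency, Hz (attribute `freq_Hz` when `NULL`).
#' @return A list with `tau_s`, `dX_nm`, `V_max_nm_per_s`.
#' @export
activation_time <- function(ts, freq = NULL) {
  if (is.null(freq)) freq <- attr(ts, "freq_Hz")
  if (is.null(freq)) stop("stimulus frequency unknown; pass `freq`", call. = FALSE)
  T <- 1 / freq
  dt <- stats::median(diff(ts$t_s))
  n_per <- round(T / dt)
  n_cyc <- floor(nrow(ts) / n_per)
  if (n_cyc < 1) stop("record shorter than one stimulus cycle", call. = FALSE)
  idx <- seq_len(n_cyc * n_per)
  phase_bin <- ((idx - 1) %% n_per) + 1
  Xm <- as.numeric(tapply(ts$X_nm[idx], phase_bin, mean))
  Dm <- as.numeric(tapply(ts$Delta_nm[idx], phase_bin, mean))
  Xs <- moving_average(Xm, 5)
  # periodic central difference on the phase-averaged trajectory
  v <- (Xs[c(2:n_per, 1)] - Xs[c(n_per, 1:(n_per - 1))]) / (2 * dt)
  dDm <- Dm[c(2:n_per, 1)] - Dm
  up <- dDm > 0
  # exclude the immediate neighbourhood of the turning points
  turn <- c(which.max(Dm), which.min(Dm))
  w <- max(3L, round(0.05 * n_per))
  near_turn <- rep(FALSE, n_per)
  for (tp in turn) near_turn[(abs(((seq_len(n_per) - tp + n_per / 2) %% n_per) - n_per / 2) <= w)] <- TRUE
  cand_up <- which(up & !near_turn)
  cand_dn <- which(!up & !near_turn)
  if (length(cand_up) == 0 || length(cand_dn) == 0) {
    stop("degenerate stimulus: cannot locate half-cycles", call. = FALSE)
  }
  i_up <- cand_up[which.max(v[cand_up])]
  i_dn <- cand_dn[which.max(-v[cand_dn])]
  V_max <- max(v[i_up], -v[i_dn])
  if (V_max <= 0) stop("degenerate stimulus: zero maximal speed", call. = FALSE)
  dX <- Xs[i_up] - Xs[i_dn]
  list(tau_s = max(dX, 0) / (2 * V_max), dX_nm = dX, V_max_nm_per_s = V_max)
}

#' Mean bundle position over whole stimulus cycles
#'
#' @param ts A recording with columns `t_s`, `X_nm`.
#' @param freq Stimulus frequency, Hz (attribute `freq_Hz` when `NULL`).
#' @return Time-averaged position over the whole cycles in the record, nm.
#' @export
mean_position <- function(ts, freq = NULL) {
  if (is.null(freq)) freq <- attr(ts, "freq_Hz")
  if (is.null(freq)) stop("stimulus frequency unknown; pass `freq`", call. = FALSE)
  dt <- stats::median(diff(ts$t_s))
  n_per <- round(1 / freq / dt)
  n_cyc <- floor(nrow(ts) / n_per)
  if (n_cyc < 1) stop("record shorter than one stimulus cycle", call. = FALSE)
  mean(ts$X_nm[seq_len(n_cyc * n_per)])
}

#' Full cycle metrics from a triangular-stimulus recording
#'
#' Convenience wrapper running [average_cycles()], [friction_profile()],
#' [inversion_point()], [activation_time()] and [mean_position()].
#'
#' @inheritParams average_cycles
#' @return A list of class `cycle_metrics` with `phi_max_pN`, `X0_nm`,
#'   `F0_pN`, `xbar_nm`, `tau_act_s`, `flat`, and the underlying
#'   `force_cycle`.
#' @export
cycle_metrics <- function(ts, freq = NULL, n_cycles = NULL) {
  cyc <- average_cycles(ts, freq, n_cycles)
  fp <- friction_profile(cyc)
  ip <- inversion_point(cyc)
  at <- activation_time(ts, if (is.null(freq)) attr(ts, "freq_Hz") else freq)
  structure(
    list(phi_max_pN = fp$phi_max_pN, X0_nm = ip$X0_nm, F0_pN = ip$F0_pN,
         xbar_nm = mean_position(ts, freq), tau_act_s = at$tau_s,
         flat = fp$flat, cycle = cyc),
    class = "cycle_metrics"
  )
}
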