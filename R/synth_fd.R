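# Quasi-static step-protocol synthesis of force-displacement relations.
#
# A flexible fiber of stiffness k_F, whose base is stepped to Delta, exerts
# F = k_F (Delta - X) on the bundle. At steady state this balances the
# bundle's own force-displacement relation; each step therefore corresponds
# to a root of k_F (Delta - X) = F(X). In the negative-stiffness regime the
# balance can have three roots and, without displacement-clamp feedback, the
# bundle lands on the stable root reached by continuation from its previous
# position — which is what produces hysteretic jumps in the measured
# relation.

#' Force-displacement relation container
#'
#' @param X Displacements, nm.
#' @param F Forces, pN.
#' @param I_uA Transepithelial current of the condition, uA (metadata).
#' @param cell_id Cell identifier (metadata).
#' @return A data frame of class `fd_relation` with columns `X_nm`, `F_pN`.
#' @export
fd_relation <- function(X, F, I_uA = NA_real_, cell_id = NA_character_) {
  if (length(X) != length(F)) stop("X and F must have equal length", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(F))) {
    stop("fd_relation requires finite X and F", call. = FALSE)
  }
  structure(
    data.frame(X_nm = as.numeric(X), F_pN = as.numeric(F)),
    I_uA = I_uA, cell_id = cell_id,
    class = c("fd_relation", "data.frame")
  )
}

# All roots of the force balance k_F (Delta - X) = fd_force(X), with their
# stability (stable iff d/dX [k_F (Delta - X) - F(X)] < 0, i.e. the total
# restoring stiffness k_F + F'(X) is positive).
balance_roots <- function(Delta, p, fiber) {
  g <- function(X) fiber$k_F * (Delta - X) - fd_force(X, p)
  # residual is confined between the two asymptotic lines; bracket generously
  lo <- (fiber$k_F * Delta + p$F_G - p$F_null) / (fiber$k_F + p$K)
  hi <- (fiber$k_F * Delta - p$F_null) / (fiber$k_F + p$K)
  span <- abs(hi - lo) + 20 * p$delta + 1
  grid <- seq(min(lo, hi) - span, max(lo, hi) + span, length.out = 4001)
  gv <- g(grid)
  sgn <- sign(gv)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(g, c(grid[i], grid[i + 1]), tol = 1e-12)$root
  }, numeric(1))
  exact <- grid[gv == 0]
  roots <- sort(unique(c(roots, exact)))
  if (length(roots) == 0) {
    stop("numerical failure: no root of the quasi-static force balance", call. = FALSE)
  }
  stable <- fiber$k_F + fd_slope(roots, p) > 0
  list(roots = roots, stable = stable)
}

#' Simulate a step-protocol force-displacement relation
#'
#' For each fiber-base step `Delta` the quasi-static force balance
#' `k_F (Delta - X) = F(X)` is solved for the bundle position; in the
#' bistable (negative-stiffness) regime the stable root nearest the bundle's
#' previous position is taken, emulating continuation without displacement
#' clamp. Adaptation is out of scope, so steady-state roots stand in for the
#' few-ms post-step sampling of a real protocol.
#'
#' @param p A [gating_spring_params()] object.
#' @param fiber A [fiber_params()] object.
#' @param schedule Fiber-base positions Delta, nm, applied in order. The
#'   default emulates 8 growing pairs of opposite steps (30-nm increment).
#' @param noise_sd Gaussian measurement noise SD added to both the recorded
#'   displacement (nm) and force (pN). Default 0.
#' @param seed Optional integer seed (scoped; does not touch the global RNG
#'   stream outside the call).
#' @param X_start Bundle position before the first step, nm.
#' @return An [fd_relation()] with one row per step, plus attributes
#'   `schedule` and `X_true` (noise-free positions).
#' @export
gen_fd_step_protocol <- function(p, fiber = fiber_params(), schedule = step_schedule(),
                                 noise_sd = 0, seed = NULL, X_start = NULL) {
  check_params(p)
  if (length(schedule) == 0) stop("step schedule must be nonempty", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  run <- function() {
    X_prev <- if (is.null(X_start)) {
      r0 <- balance_roots(0, p, fiber)
      cand <- r0$roots[r0$stable]
      cand[which.min(abs(cand))]
    } else X_start
    X <- numeric(length(schedule))
    for (i in seq_along(schedule)) {
      r <- balance_roots(schedule[i], p, fiber)
      cand <- r$roots[r$stable]
      if (length(cand) == 0) cand <- r$roots
      X[i] <- cand[which.min(abs(cand - X_prev))]
      X_prev <- X[i]
    }
    F <- fiber$k_F * (schedule - X)
    X_obs <- X + stats::rnorm(length(X), 0, noise_sd)
    F_obs <- F + stats::rnorm(length(F), 0, noise_sd)
    rel <- fd_relation(X_obs, F_obs)
    attr(rel, "schedule") <- schedule
    attr(rel, "X_true") <- X
    rel
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Growing pairs of opposite fiber steps
#'
#' The standard step protocol: `n_pairs` successive pairs of steps in
#' opposite directions with magnitude growing by a constant increment.
#'
#' @param n_pairs Number of step pairs (7-9 typical).
#' @param increment Magnitude increment per pair, nm (20-40 typical).
#' @return Numeric vector of fiber-base positions, nm.
#' @export
step_schedule <- function(n_pairs = 8, increment = 30) {
  mags <- increment * seq_len(n_pairs)
  as.numeric(rbind(mags, -mags))
}

#' Sample the gating-spring relation directly
#'
#' Noise-free (or noisy) evaluation of [fd_force()] on a displacement grid,
#' bypassing the fiber; the idealised counterpart of a step protocol.
#'
#' @param p A [gating_spring_params()] object.
#' @param X Displacement grid, nm.
#' @param noise_sd Gaussian force noise SD, pN.
#' @param seed Optional scoped seed.
#' @return An [fd_relation()].
#' @export
gen_fd_direct <- function(p, X = seq(-150, 150, length.out = 18),
                          noise_sd = 0, seed = NULL) {
  run <- function() {
    fd_relation(X, fd_force(X, p) + stats::rnorm(length(X), 0, noise_sd))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
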