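# The gating-spring model of mechanoelectrical transduction.
#
# A hair bundle deflected by X experiences an elastic restoring force plus a
# nonlinear contribution from transduction-channel gating. With channels
# obeying a two-state Boltzmann law of width delta about the set point X_0,
# the external force needed to hold the bundle at X is
#
#   F(X) = K X - F_G / (1 + exp(-(X - X_0)/delta)) + F_null
#
# The vertical offset between the two asymptotic linear limbs equals the
# gating force F_G, and the local stiffness dips by F_G/(4 delta) at X_0
# (gating compliance). When F_G > 4 K delta the slope becomes negative over
# a range of displacements and the bundle is mechanically bistable.

check_params <- function(p) {
  if (!inherits(p, "gating_spring_params")) {
    stop("expected a 'gating_spring_params' object", call. = FALSE)
  }
  invisible(p)
}

#' Open probability of the transduction channels
#'
#' Two-state Boltzmann relation: `1/(1 + exp(-(X - X_0)/delta))`. Equals 1/2
#' at the set point and increases strictly with X.
#'
#' @param X Displacement(s), nm.
#' @param X_0 Set-point deflection, nm.
#' @param delta Characteristic displacement, nm (> 0).
#' @return Open probability in (0, 1), same length as `X`.
#' @export
open_probability <- function(X, X_0 = 0, delta = 20) {
  if (!is.numeric(delta) || !is.finite(delta) || delta <= 0) {
    stop("delta must be a positive finite number", call. = FALSE)
  }
  if (!all(is.finite(X)) || !is.finite(X_0)) {
    stop("displacements must be finite", call. = FALSE)
  }
  1 / (1 + exp(-(X - X_0) / delta))
}

#' Gating-spring force-displacement relation
#'
#' Evaluates the force a stimulus must exert to hold the hair bundle at
#' displacement `X`, including the gating-compliance term.
#'
#' @param X Displacement(s), nm.
#' @param p A [gating_spring_params()] object.
#' @return Force(s), pN.
#' @examples
#' p <- gating_spring_params(K = 0.85, F_G = 17, X_0 = 0, delta = 20, F_null = 8.5)
#' fd_force(0, p)   # 0: half the gating force is balanced by F_null
#' @export
fd_force <- function(X, p) {
  check_params(p)
  if (!is.numeric(X) || !all(is.finite(X))) {
    stop("displacement X must be finite numeric", call. = FALSE)
  }
  p$K * X - p$F_G * open_probability(X, p$X_0, p$delta) + p$F_null
}

#' Local stiffness of the force-displacement relation
#'
#' Analytic derivative of [fd_force()]:
#' `K - (F_G/delta) * Po * (1 - Po)`. Its minimum, `K - F_G/(4 delta)`, is
#' attained at the set point and can be negative for strong gating.
#'
#' @inheritParams fd_force
#' @return Local stiffness, pN/nm, same length as `X`.
#' @export
fd_slope <- function(X, p) {
  check_params(p)
  po <- open_probability(X, p$X_0, p$delta)
  p$K - (p$F_G / p$delta) * po * (1 - po)
}

#' Minimal local stiffness
#'
#' @param p A [gating_spring_params()] object.
#' @return `K - F_G/(4 delta)`, pN/nm.
#' @export
fd_min_slope <- function(p) {
  check_params(p)
  p$K - p$F_G / (4 * p$delta)
}

#' Classify the mechanical regime of a hair bundle
#'
#' `"linear"` when the gating force vanishes, `"negative-stiffness"` when
#' gating is strong enough to invert the slope (`F_G > 4 K delta`), and
#' `"gated-monotonic"` in between (gating compliance without bistability).
#'
#' @param p A [gating_spring_params()] object.
#' @return One of `"linear"`, `"gated-monotonic"`, `"negative-stiffness"`.
#' @export
classify_regime <- function(p) {
  check_params(p)
  if (p$F_G == 0) return("linear")
  if (p$F_G > 4 * p$K * p$delta) return("negative-stiffness")
  "gated-monotonic"
}

#' Gating swing from gating force and stiffness
#'
#' The gating force is the product of the combined gating-spring stiffness
#' `K_GS = K - K_SP` and the gating swing `D` along the bundle axis; the
#' swing along the tip-link axis is `d = gamma * D = gamma * F_G / (K - K_SP)`.
#'
#' @param F_G Whole-bundle gating force, pN.
#' @param K Linear bundle stiffness, pN/nm.
#' @param geo A [bundle_geometry()] object.
#' @return A list of class `derived_gating` with elements `K_GS` (pN/nm),
#'   `D` (nm, bundle axis), `d` (nm, tip-link axis).
#' @examples
#' gating_swing(17, 0.85, bundle_geometry())$d  # 3.5 nm
#' @export
gating_swing <- function(F_G, K, geo = bundle_geometry()) {
  if (!inherits(geo, "bundle_geometry")) stop("expected a 'bundle_geometry' object", call. = FALSE)
  if (!all(is.finite(c(F_G, K))) || F_G < 0) {
    stop("F_G must be finite and >= 0; K finite", call. = FALSE)
  }
  K_GS <- K - geo$K_SP
  if (K_GS <= 0) {
    stop("degenerate stiffness: K <= K_SP, gating-spring stiffness nonpositive",
         call. = FALSE)
  }
  D <- F_G / K_GS
  structure(list(K_GS = K_GS, D = D, d = geo$gamma * D), class = "derived_gating")
}

#' Gating force from gating swing (inverse of [gating_swing()])
#'
#' @param d Gating swing along the tip-link axis, nm.
#' @param K Linear bundle stiffness, pN/nm.
#' @param geo A [bundle_geometry()] object.
#' @return Gating force, pN.
#' @export
gating_force <- function(d, K, geo = bundle_geometry()) {
  K_GS <- K - geo$K_SP
  if (K_GS <= 0) stop("degenerate stiffness: K <= K_SP", call. = FALSE)
  d / geo$gamma * K_GS
}
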