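# Parameter containers for the gating-spring description of a hair bundle.
#
# Units follow the conventions used throughout hair-bundle biophysics:
# displacements in nm, forces in pN, stiffnesses in pN/nm, times in s unless
# a suffix says otherwise. Positive X is a deflection toward the taller
# stereociliary row; force is positive in the same direction.

#' Gating-spring model parameters
#'
#' Bundles the five parameters of the gating-spring force-displacement
#' relation: the linear stiffness `K`, the whole-bundle gating force `F_G`,
#' the set-point deflection `X_0` (displacement at which the channels' open
#' probability is 1/2), the characteristic displacement `delta` of the
#' two-state Boltzmann gating curve, and the force offset `F_null` that pins
#' the relation to F = 0 at X = 0.
#'
#' @param K Linear stiffness, pN/nm. Must be > 0.
#' @param F_G Whole-bundle gating force, pN. Must be >= 0.
#' @param X_0 Set-point deflection, nm.
#' @param delta Characteristic displacement of the gating curve, nm. Must be
#'   > 0. The default of 20 nm keeps the model well conditioned; fits treat
#'   `delta` as a free bounded parameter because step-protocol data do not
#'   constrain it tightly.
#' @param F_null Force offset, pN. The default `NULL` chooses the value that
#'   makes F(0) = 0.
#' @return An object of class `gating_spring_params` (a named list).
#' @examples
#' p <- gating_spring_params(K = 0.85, F_G = 17, X_0 = -2)
#' fd_force(0, p)  # exactly 0 by construction of F_null
#' @export
gating_spring_params <- function(K, F_G, X_0 = 0, delta = 20, F_null = NULL) {
  stopifnot(is.numeric(K), is.numeric(F_G), is.numeric(X_0), is.numeric(delta))
  if (!all(is.finite(c(K, F_G, X_0, delta)))) {
    stop("gating-spring parameters must be finite", call. = FALSE)
  }
  if (K <= 0) stop("linear stiffness K must be > 0", call. = FALSE)
  if (F_G < 0) stop("gating force F_G must be >= 0", call. = FALSE)
  if (delta <= 0) stop("characteristic displacement delta must be > 0", call. = FALSE)
  if (is.null(F_null)) {
    # F(0) = -F_G/(1+exp(X_0/delta)) + F_null == 0
    F_null <- F_G / (1 + exp(X_0 / delta))
  }
  if (!is.finite(F_null)) stop("F_null must be finite", call. = FALSE)
  structure(
    list(K = K, F_G = F_G, X_0 = X_0, delta = delta, F_null = F_null),
    class = "gating_spring_params"
  )
}

#' @export
print.gating_spring_params <- function(x, ...) {
  cat("Gating-spring parameters\n")
  cat(sprintf("  K      %8.4g pN/nm\n", x$K))
  cat(sprintf("  F_G    %8.4g pN\n", x$F_G))
  cat(sprintf("  X_0    %8.4g nm\n", x$X_0))
  cat(sprintf("  delta  %8.4g nm\n", x$delta))
  cat(sprintf("  F_null %8.4g pN\n", x$F_null))
  cat(sprintf("  regime: %s\n", classify_regime(x)))
  invisible(x)
}

#' Hair-bundle geometry: tip-link projection and pivot stiffness
#'
#' @param gamma Geometric projection factor of bundle-tip displacement onto
#'   the tip-link axis, dimensionless in (0, 1]. Default 0.14, the standard
#'   value for the frog sacculus.
#' @param K_SP Stereociliary-pivot stiffness measured after tip-link
#'   disruption, pN/nm. Default 0.17.
#' @return An object of class `bundle_geometry`.
#' @export
bundle_geometry <- function(gamma = 0.14, K_SP = 0.17) {
  stopifnot(is.numeric(gamma), is.numeric(K_SP))
  if (!is.finite(gamma) || gamma <= 0 || gamma > 1) {
    stop("projection factor gamma must lie in (0, 1]", call. = FALSE)
  }
  if (!is.finite(K_SP) || K_SP < 0) stop("pivot stiffness K_SP must be >= 0", call. = FALSE)
  structure(list(gamma = gamma, K_SP = K_SP), class = "bundle_geometry")
}

#' Control-condition gating-spring parameters
#'
#' Ensemble-mean parameters of oscillatory hair bundles with no applied
#' transepithelial current: K = 0.85 pN/nm, F_G = 17 pN, X_0 = -2 nm. The
#' characteristic displacement defaults to 20 nm.
#'
#' @param delta Characteristic displacement, nm.
#' @return A `gating_spring_params` object.
#' @export
control_params <- function(delta = 20) {
  gating_spring_params(K = 0.85, F_G = 17, X_0 = -2, delta = delta)
}

#' Stimulus-fiber parameters
#'
#' @param k_F Fiber stiffness, pN/nm. Default 0.5.
#' @return An object of class `fiber_params`.
#' @export
fiber_params <- function(k_F = 0.5) {
  if (!is.numeric(k_F) || !is.finite(k_F) || k_F <= 0) {
    stop("fiber stiffness k_F must be a positive number", call. = FALSE)
  }
  structure(list(k_F = k_F), class = "fiber_params")
}

# Flat JSON representation with unit-suffixed keys (shared with io.R).
params_to_list <- function(p) {
  list(
    K_pN_per_nm = p$K, F_G_pN = p$F_G, X0_nm = p$X_0,
    delta_nm = p$delta, Fnull_pN = p$F_null
  )
}

params_from_list <- function(x) {
  gating_spring_params(
    K = x$K_pN_per_nm, F_G = x$F_G_pN, X_0 = x$X0_nm,
    delta = x$delta_nm, F_null = x$Fnull_pN
  )
}
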