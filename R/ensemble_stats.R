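# Ensemble-level statistics: correlations, regressions, paired tests,
# summaries, strong/weak-state transition detection with hysteresis, and
# 10-90% step kinetics.

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors of equal length (n >= 3, finite).
#' @return A list with `r`, `p`, `n`.
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Ordinary least-squares regression of y on x
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return A list with `slope`, `intercept`, `r_squared`, `p` (slope test),
#'   `n`.
#' @export
regress <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite pairs", call. = FALSE)
  if (stats::sd(x) == 0) stop("rank error: degenerate predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p = sm$coefficients[2, 4],
       n = length(x))
}

#' Two-tailed paired Student's t-test
#'
#' @param a,b Paired numeric vectors of equal length (n >= 2).
#' @return A list with `t`, `p`, `df`, `mean_diff`; for a degenerate pairing
#'   (zero difference variance) `degenerate = TRUE` and the statistics are
#'   NA.
#' @export
compare_paired <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length", call. = FALSE)
  if (length(a) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_diff = unname(tt$estimate), degenerate = FALSE)
}

#' Mean, sample SD and n
#'
#' @param values Numeric vector (n >= 1).
#' @return A list with `mean`, `sd` (n-1 denominator; NA for a single
#'   value), `n`.
#' @export
summarize_values <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 1) stop("need at least one finite value", call. = FALSE)
  list(mean = mean(values),
       sd = if (length(values) > 1) stats::sd(values) else NA_real_,
       n = length(values))
}

branch_crossing <- function(I, phi, level) {
  # first crossing of `level` along the branch in traversal order
  for (i in seq_len(length(I) - 1)) {
    a <- phi[i] - level; b <- phi[i + 1] - level
    if (a == 0) return(I[i])
    if (a * b < 0) {
      return(I[i] + (I[i + 1] - I[i]) * a / (a - b))
    }
  }
  NA_real_
}

#' Detect the strong/weak gating-state transition and its hysteresis
#'
#' On each branch of a current ramp the maximal friction force sits on a
#' strong-state plateau, drops, and settles on a weak-state plateau. The
#' operational levels are plateau medians (samples within `plateau_width`
#' of each current extreme); the transition current is where the branch
#' first crosses the midpoint level (linear interpolation), and the
#' hysteresis shift is the ascending minus the descending crossing.
#'
#' @param descending,ascending Data frames with columns `I_uA`,
#'   `phi_max_pN`, ordered as traversed (descending: from high to low
#'   current).
#' @param plateau_width Current span defining each plateau, uA.
#' @return An object of class `transition_result`: a list with
#'   `I_drop_descending_uA`, `I_drop_ascending_uA`, `hysteresis_shift_uA`,
#'   `phi_pre_pN`, `phi_post_pN`, `transition` (FALSE when no drop crosses
#'   the midpoint; currents are then NA).
#' @export
detect_drop <- function(descending, ascending, plateau_width = 1) {
  for (b in list(descending, ascending)) {
    stopifnot(all(c("I_uA", "phi_max_pN") %in% names(b)))
  }
  all_I <- c(descending$I_uA, ascending$I_uA)
  hi <- max(all_I); lo <- min(all_I)
  pre <- stats::median(c(descending$phi_max_pN[descending$I_uA >= hi - plateau_width],
                         ascending$phi_max_pN[ascending$I_uA >= hi - plateau_width]))
  post <- stats::median(c(descending$phi_max_pN[descending$I_uA <= lo + plateau_width],
                          ascending$phi_max_pN[ascending$I_uA <= lo + plateau_width]))
  mid <- (pre + post) / 2
  # no resolvable drop between the plateaus: no transition to locate
  drop_size <- pre - post
  if (!is.finite(drop_size) || drop_size <= 0.05 * max(abs(pre), abs(post), 1e-12)) {
    return(structure(
      list(I_drop_descending_uA = NA_real_, I_drop_ascending_uA = NA_real_,
           hysteresis_shift_uA = NA_real_, phi_pre_pN = pre, phi_post_pN = post,
           transition = FALSE),
      class = "transition_result"
    ))
  }
  I_dn <- branch_crossing(descending$I_uA, descending$phi_max_pN, mid)
  I_up <- branch_crossing(ascending$I_uA, ascending$phi_max_pN, mid)
  ok <- is.finite(I_dn) && is.finite(I_up)
  structure(
    list(I_drop_descending_uA = I_dn, I_drop_ascending_uA = I_up,
         hysteresis_shift_uA = if (ok) I_up - I_dn else NA_real_,
         phi_pre_pN = pre, phi_post_pN = post, transition = ok),
    class = "transition_result"
  )
}

#' @export
print.transition_result <- function(x, ...) {
  if (x$transition) {
    cat(sprintf("Gating-state transition: descending at %.3g uA, ascending at %.3g uA\n",
                x$I_drop_descending_uA, x$I_drop_ascending_uA))
    cat(sprintf("  hysteresis shift %.3g uA (phi: %.3g -> %.3g pN)\n",
                x$hysteresis_shift_uA, x$phi_pre_pN, x$phi_post_pN))
  } else {
    cat("No gating-state transition detected (phi_MAX never crosses the midpoint)\n")
  }
  invisible(x)
}

#' 10-90% rise or decay time of a step response
#'
#' Baseline and plateau are the medians of the first and last 10% of the
#' window; the result is the time between the (linearly interpolated)
#' crossings of 10% and 90% of the total change. A change smaller than
#' three times the baseline noise SD is flagged undefined.
#'
#' @param t Time base, s.
#' @param y Signal.
#' @return A list with `t10_90_ms` (NA when undefined), `change`,
#'   `defined`.
#' @export
t10_90 <- function(t, y) {
  stopifnot(length(t) == length(y), length(t) >= 10)
  n <- length(t)
  head_idx <- seq_len(max(2, floor(0.1 * n)))
  tail_idx <- seq(n - max(2, floor(0.1 * n)) + 1, n)
  base <- stats::median(y[head_idx])
  plat <- stats::median(y[tail_idx])
  change <- plat - base
  noise <- stats::sd(y[head_idx])
  if (!is.finite(change) || abs(change) < 3 * noise || abs(change) < 1e-12) {
    return(list(t10_90_ms = NA_real_, change = change, defined = FALSE))
  }
  lev10 <- base + 0.1 * change
  lev90 <- base + 0.9 * change
  s <- sign(change)
  cross <- function(level, from = 1) {
    for (i in from:(n - 1)) {
      a <- s * (y[i] - level); b <- s * (y[i + 1] - level)
      if (a < 0 && b >= 0) {
        return(list(t = t[i] + (t[i + 1] - t[i]) * (level - y[i]) / (y[i + 1] - y[i]),
                    i = i))
      }
    }
    list(t = NA_real_, i = NA_integer_)
  }
  c10 <- cross(lev10)
  if (is.na(c10$t)) return(list(t10_90_ms = NA_real_, change = change, defined = FALSE))
  c90 <- cross(lev90, from = c10$i)
  if (is.na(c90$t)) return(list(t10_90_ms = NA_real_, change = change, defined = FALSE))
  list(t10_90_ms = (c90$t - c10$t) * 1000, change = change, defined = TRUE)
}

#' 10-90% kinetics of paired position/friction step traces
#'
#' Applies [t10_90()] to the ON and OFF windows of a paired recording of
#' the cycle-averaged position and the maximal friction force (e.g. from
#' [gen_step_kinetics()]). Each window starts `pre_s` before its edge so
#' that the first 10% of the window measures the pre-edge baseline.
#'
#' @param ts A data frame with columns `t_s`, `xbar_nm`, `phimax_pN` and
#'   attributes `t_on_s`, `t_off_s` (or pass `t_on`/`t_off`).
#' @param t_on,t_off Step edges, s.
#' @param pre_s Baseline margin before each edge, s.
#' @return A list of class `kinetics_result` with `t10_90_ms` (named
#'   matrix: X/phi by ON/OFF) and the ratios `ratio_on` and `ratio_off`
#'   (phi over X).
#' @export
step_kinetics <- function(ts, t_on = NULL, t_off = NULL, pre_s = 0.5) {
  if (is.null(t_on)) t_on <- attr(ts, "t_on_s")
  if (is.null(t_off)) t_off <- attr(ts, "t_off_s")
  if (is.null(t_on) || is.null(t_off)) stop("step edges unknown", call. = FALSE)
  win <- function(from, to) ts$t_s >= from & ts$t_s <= to
  on <- win(t_on - pre_s, t_off)
  off <- win(t_off - pre_s, max(ts$t_s))
  m <- matrix(NA_real_, 2, 2, dimnames = list(c("X", "phi"), c("ON", "OFF")))
  m["X", "ON"] <- t10_90(ts$t_s[on], ts$xbar_nm[on])$t10_90_ms
  m["phi", "ON"] <- t10_90(ts$t_s[on], ts$phimax_pN[on])$t10_90_ms
  m["X", "OFF"] <- t10_90(ts$t_s[off], ts$xbar_nm[off])$t10_90_ms
  m["phi", "OFF"] <- t10_90(ts$t_s[off], ts$phimax_pN[off])$t10_90_ms
  structure(list(t10_90_ms = m,
                 ratio_on = m["phi", "ON"] / m["X", "ON"],
                 ratio_off = m["phi", "OFF"] / m["X", "OFF"]),
            class = "kinetics_result")
}
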