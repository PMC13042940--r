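# Shared fixtures and independent oracles used across test files.

# Dense-scan root oracle for the quasi-static force balance
# k_F (Delta - X) = F(X): every root on [-500, 500] nm at 0.01-nm
# resolution, refined by bisection. Independent of balance_roots().
scan_roots <- function(Delta, p, k_F = 0.5, lim = 500, by = 0.01) {
  g <- function(X) k_F * (Delta - X) - fd_force(X, p)
  xs <- seq(-lim, lim, by = by)
  gv <- g(xs)
  hits <- which(sign(gv[-1]) * sign(gv[-length(gv)]) <= 0)
  roots <- vapply(hits, function(j) {
    if (gv[j] == 0) xs[j]
    else if (gv[j + 1] == 0) xs[j + 1]
    else stats::uniroot(g, c(xs[j], xs[j + 1]), tol = 1e-12)$root
  }, numeric(1))
  unique(roots[!duplicated(round(roots, 8))])
}

# Trapezoid integral.
trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

# Default oscillatory-bundle parameters (control condition).
ctrl <- function(delta = 20) gating_spring_params(0.85, 17, -2, delta)
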