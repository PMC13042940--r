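# Gating-spring fitting: identifiability, equivariance, model selection.

test_that("noiseless gated data are recovered to high relative accuracy", {
  p <- gating_spring_params(0.85, 17, -2, 20)
  rel <- gen_fd_direct(p, X = seq(-150, 150, length.out = 18))
  fit <- fit_gating_spring(rel)
  expect_identical(fit$model, "gated")
  expect_equal(fit$params$K, 0.85, tolerance = 1e-6)
  expect_equal(fit$params$F_G, 17, tolerance = 1e-6)
  expect_equal(fit$params$X_0, -2, tolerance = 1e-5)
  expect_equal(fit$params$delta, 20, tolerance = 1e-5)
  expect_equal(fit$derived$d, 0.14 * 17 / (0.85 - 0.17), tolerance = 1e-5)
  expect_lt(fit$rmse, 1e-8)
})

test_that("identifiability holds across parameter values when data span the limbs", {
  for (tr in list(c(K = 0.6, F_G = 8, X_0 = 15, delta = 12),
                  c(K = 1.2, F_G = 30, X_0 = -30, delta = 35))) {
    p <- gating_spring_params(tr["K"], tr["F_G"], tr["X_0"], tr["delta"])
    span <- abs(tr["X_0"]) + 5 * tr["delta"]
    rel <- gen_fd_direct(p, X = seq(-span, span, length.out = 24))
    fit <- fit_gating_spring(rel)
    expect_equal(fit$params$K, unname(tr["K"]), tolerance = 1e-6)
    expect_equal(fit$params$F_G, unname(tr["F_G"]), tolerance = 1e-6)
    expect_equal(fit$params$delta, unname(tr["delta"]), tolerance = 1e-4)
  }
})

test_that("noiseless linear data select the linear model with exact stiffness", {
  p <- gating_spring_params(0.62, 0, 0, 20, F_null = 3)
  rel <- gen_fd_direct(p, X = seq(-150, 150, length.out = 18))
  fit <- fit_gating_spring(rel)
  expect_identical(fit$model, "linear")
  expect_true(fit$undetectable)
  expect_equal(fit$params$K, 0.62, tolerance = 1e-9)
  expect_identical(fit$params$F_G, 0)
})

test_that("the fit is equivariant under force offsets and displacement shifts", {
  p <- gating_spring_params(0.85, 17, -2, 20)
  X <- seq(-150, 150, length.out = 20)
  base <- fit_gating_spring(fd_relation(X, fd_force(X, p)))
  # force offset: only F_null moves
  offs <- fit_gating_spring(fd_relation(X, fd_force(X, p) + 7))
  expect_equal(offs$params$F_null - base$params$F_null, 7, tolerance = 1e-6)
  expect_equal(offs$params$K, base$params$K, tolerance = 1e-7)
  expect_equal(offs$params$F_G, base$params$F_G, tolerance = 1e-6)
  expect_equal(offs$params$X_0, base$params$X_0, tolerance = 1e-5)
  # displacement shift: only X_0 moves
  shft <- fit_gating_spring(fd_relation(X + 25, fd_force(X, p)))
  expect_equal(shft$params$X_0 - base$params$X_0, 25, tolerance = 1e-5)
  expect_equal(shft$params$K, base$params$K, tolerance = 1e-7)
  expect_equal(shft$params$F_G, base$params$F_G, tolerance = 1e-6)
  expect_equal(shft$params$delta, base$params$delta, tolerance = 1e-4)
})

test_that("noisy fits recover the gating force within 10% in the median", {
  p <- ctrl()
  fits <- vapply(1:50, function(s) {
    rel <- gen_fd_direct(p, X = seq(-150, 150, length.out = 18), noise_sd = 2,
                         seed = 1000 + s)
    fit_gating_spring(rel)$params$F_G
  }, numeric(1))
  expect_lt(abs(stats::median(fits) - 17) / 17, 0.1)
})

test_that("detection power is monotone in the true gating force", {
  # probability of selecting "gated" must not decrease with F_G
  n_rep <- 40
  power <- vapply(c(0, 4, 8, 17), function(fg) {
    p <- gating_spring_params(0.85, fg, -2, 20)
    hits <- vapply(seq_len(n_rep), function(s) {
      rel <- gen_fd_direct(p, X = seq(-150, 150, length.out = 16), noise_sd = 1.5,
                           seed = 20000 + 100 * fg + s)
      fit_gating_spring(rel)$model == "gated"
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(power) >= -0.075))   # nondecreasing up to binomial jitter
  expect_lt(power[1], 0.2)                  # no gating: rarely selected
  expect_gt(power[4], 0.9)                  # strong gating: almost always
})

test_that("condition deltas follow the undetectable-gating convention", {
  p0 <- gating_spring_params(0.85, 17, -2, 20)
  X <- seq(-150, 150, length.out = 18)
  f0 <- fit_gating_spring(fd_relation(X, fd_force(X, p0)))
  # identical fits: all deltas zero
  d0 <- delta_metrics(f0, f0)
  expect_equal(d0$dX0_nm, 0); expect_equal(d0$dFG_pN, 0)
  expect_equal(d0$dd_rel_pct, 0, tolerance = 1e-6)
  # halved gating force
  p1 <- gating_spring_params(0.85, 8.5, -2, 20)
  f1 <- fit_gating_spring(fd_relation(X, fd_force(X, p1)))
  d1 <- delta_metrics(f1, f0)
  expect_equal(d1$dFG_pN, -8.5, tolerance = 1e-5)
  expect_equal(d1$dFG_rel_pct, -50, tolerance = 1e-4)
  # linear condition: dFG = -F_G(0), relative swing change -100%
  p2 <- gating_spring_params(0.95, 0, 0, 20)
  f2 <- fit_gating_spring(fd_relation(X, fd_force(X, p2)))
  d2 <- delta_metrics(f2, f0)
  expect_equal(d2$dFG_pN, -17, tolerance = 1e-5)
  expect_identical(d2$dd_rel_pct, -100)
  expect_true(is.na(d2$dX0_nm))
  # pairing guard
  fa <- f0; fa$cell_id <- "cellA"
  fb <- f0; fb$cell_id <- "cellB"
  expect_error(delta_metrics(fa, fb), "pairing")
})
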