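# Ensemble generation and statistics: regressions, correlations, paired
# tests, transition detection, 10-90% kinetics.

test_that("correlate and regress agree on simple OLS and handle exact lines", {
  x <- seq(-5, 10, length.out = 34)
  y <- 4.6 * x - 9.6
  r <- suppressWarnings(regress(x, y))   # lm flags the perfect fit
  expect_equal(r$slope, 4.6, tolerance = 1e-12)
  expect_equal(r$intercept, -9.6, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(correlate(x, y)$r, 1, tolerance = 1e-12)
  expect_equal(correlate(x, -y)$r, -1, tolerance = 1e-12)
  # r^2 == R^2 for noisy data too
  set.seed(8)
  yn <- y + rnorm(34, 0, 8)
  expect_equal(correlate(x, yn)$r^2, regress(x, yn)$r_squared, tolerance = 1e-12)
  expect_error(correlate(rep(1, 5), 1:5), "zero variance")
  expect_error(regress(rep(1, 5), 1:5), "degenerate")
})

test_that("noise-free ensembles reproduce the configured coefficients exactly", {
  cfg <- ensemble_config(dX0 = list(slope = 4.6, intercept = -9.6, r_squared = 1))
  tbl <- gen_ensemble(cfg, seed = 1)
  cond <- tbl[tbl$I_uA != 0, ]
  r <- suppressWarnings(regress(cond$I_uA, cond$dX0_nm))
  expect_equal(r$slope, 4.6, tolerance = 1e-9)
  expect_equal(r$intercept, -9.6, tolerance = 1e-9)
  # structural invariants: every cell has a control row; weak rows are zeroed
  expect_true(all(table(tbl$cell_id) == 2))
  expect_true(all(tbl$I_uA[seq(1, nrow(tbl), 2)] == 0))
  weak <- tbl$state == "weak"
  expect_true(all(tbl$F_G_pN[weak] == 0))
  expect_true(all(tbl$d_nm[weak] == 0))
  expect_error(ensemble_config(dX0 = list(slope = 1, intercept = 0, r_squared = 1.2)),
               "R\\^2")
})

test_that("R^2-matched residuals give the target correlation and slope on average", {
  slopes <- r2s <- rs <- numeric(80)
  for (s in 1:80) {
    tbl <- gen_ensemble(seed = 9000 + s)
    cond <- tbl[tbl$I_uA != 0, ]
    fitl <- regress(cond$I_uA, cond$dX0_nm)
    slopes[s] <- fitl$slope
    r2s[s] <- fitl$r_squared
    rs[s] <- correlate(cond$I_uA, cond$dX0_nm)$r
  }
  expect_lt(abs(mean(slopes) / 4.6 - 1), 0.05)
  expect_lt(abs(mean(r2s) - 0.75), 0.05)
  expect_lt(abs(mean(rs) - sqrt(0.75)), 0.03)   # r = 0.87 for the generating model
})

test_that("currents below threshold produce the weak state on the chosen branch", {
  cfg <- ensemble_config(currents = seq(-9, 0, length.out = 10), n_cells = 10)
  stm <- state_transition_model(I_down = -5, hyst = 2.3)
  dn <- gen_ensemble(cfg, stm, seed = 2, direction = "descending")
  up <- gen_ensemble(cfg, stm, seed = 2, direction = "ascending")
  cdn <- dn[dn$I_uA != 0, ]; cup <- up[up$I_uA != 0, ]
  expect_true(all((cdn$I_uA < -5) == (cdn$state == "weak")))
  expect_true(all((cup$I_uA < -5 + 2.3) == (cup$state == "weak")))
  expect_true(all(cdn$dd_rel_pct[cdn$state == "weak"] == -100))
})

test_that("paired comparisons behave under shift, identity and permutation", {
  set.seed(3)
  a <- rnorm(8, 10, 1)
  b <- a + 1 + rnorm(8, 0, 0.01)
  res <- compare_paired(b, a)
  expect_lt(res$p, 1e-6)
  # identical vectors are degenerate
  expect_true(compare_paired(a, a)$degenerate)
  # destroying the pairing destroys significance when between-pair scatter
  # dominates the shift
  set.seed(4)
  a2 <- rnorm(8, 10, 10)
  b2 <- a2 + 1 + rnorm(8, 0, 0.01)
  perm <- sample(8)
  expect_lt(compare_paired(b2, a2)$p, 1e-4)
  expect_gt(compare_paired(b2[perm], a2)$p, 0.05)
})

test_that("summaries report mean, n-1 SD and n", {
  s <- summarize_values(c(1, 2, 3))
  expect_equal(s$mean, 2); expect_equal(s$sd, 1); expect_equal(s$n, 3)
  expect_true(is.na(summarize_values(5)$sd))
  set.seed(10)
  v <- rnorm(200, 3, 2)
  s2 <- summarize_values(v)
  expect_equal(s2$sd, sqrt(sum((v - mean(v))^2) / 199), tolerance = 1e-12)
})

test_that("the midpoint-crossing detector reads off constructed drop geometry", {
  logistic_branch <- function(I, mid, w = 0.25, pre = 15, post = 1) {
    data.frame(I_uA = I, phi_max_pN = post + (pre - post) / (1 + exp(-(I - mid) / w)))
  }
  dn <- logistic_branch(seq(0, -9, by = -0.05), mid = -6.9)
  up <- logistic_branch(seq(-9, 0, by = 0.05), mid = -5.2)
  tr <- detect_drop(dn, up)
  expect_true(tr$transition)
  expect_equal(tr$I_drop_descending_uA, -6.9, tolerance = 0.02)
  expect_equal(tr$I_drop_ascending_uA, -5.2, tolerance = 0.02)
  expect_equal(tr$hysteresis_shift_uA, 1.7, tolerance = 0.03)
  # identical branches: zero shift
  tr0 <- detect_drop(dn, dn[rev(seq_len(nrow(dn))), ])
  expect_equal(tr0$hysteresis_shift_uA, 0, tolerance = 1e-9)
  # invariances: vertical scaling and horizontal translation
  sc <- function(b, k) { b$phi_max_pN <- b$phi_max_pN * k; b }
  shft <- function(b, a) { b$I_uA <- b$I_uA + a; b }
  tr_sc <- detect_drop(sc(dn, 3.7), sc(up, 3.7))
  expect_equal(tr_sc$hysteresis_shift_uA, tr$hysteresis_shift_uA, tolerance = 1e-9)
  tr_sh <- detect_drop(shft(dn, -2), shft(up, -2))
  expect_equal(tr_sh$hysteresis_shift_uA, tr$hysteresis_shift_uA, tolerance = 1e-6)
  # no drop: flagged
  flatb <- data.frame(I_uA = seq(0, -9, by = -0.5), phi_max_pN = rep(10, 19))
  trf <- detect_drop(flatb, flatb[rev(seq_len(nrow(flatb))), ])
  expect_false(trf$transition)
})

test_that("the detector recovers the generating hysteresis from noisy ramps", {
  shifts <- vapply(1:100, function(s) {
    br <- gen_transition_ramp(state_transition_model(I_down = -5, hyst = 2.3),
                              noise_sd = 0.3, seed = 7000 + s)
    detect_drop(br$descending, br$ascending)$hysteresis_shift_uA
  }, numeric(1))
  expect_lt(abs(mean(shifts) - 2.3), 0.2)
})

test_that("10-90% times follow the exponential and ramp closed forms", {
  t <- seq(0, 6, by = 1e-3)
  y_exp <- ifelse(t < 0.5, 0, 1 - exp(-(t - 0.5) / 0.5))
  r <- t10_90(t, y_exp)
  expect_true(r$defined)
  expect_equal(r$t10_90_ms, 500 * log(9), tolerance = 0.01)
  # linear ramp of duration T between flats: 0.8 T
  y_ramp <- pmin(pmax((t - 1) / 2, 0), 1)   # ramp over [1, 3], T = 2 s
  expect_equal(t10_90(t, y_ramp)$t10_90_ms, 0.8 * 2000, tolerance = 0.01)
  # change below noise: undefined
  set.seed(5)
  y_noise <- rnorm(length(t), 0, 1) + 0.5 * (t > 3)
  expect_false(t10_90(t, y_noise)$defined)
})

test_that("paired kinetics traces reproduce the generating time-constant ratio", {
  ts <- gen_step_kinetics(tau_on_X = 0.5, tau_on_phi = 0.18)
  kr <- step_kinetics(ts)
  expect_equal(unname(kr$t10_90_ms["X", "ON"]), 500 * log(9), tolerance = 0.01)
  expect_lt(abs(kr$ratio_on / 0.36 - 1), 0.02)
  expect_equal(unname(kr$t10_90_ms["phi", "OFF"]), 400 * log(9), tolerance = 0.01)
  # zero-amplitude step: undefined, flagged
  flat <- gen_step_kinetics(x_base = 0, x_step = 0, noise_sd = 0.01, seed = 2)
  expect_true(is.na(step_kinetics(flat)$t10_90_ms["X", "ON"]))
})
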