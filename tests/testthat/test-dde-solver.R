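test_that("constant history at the fixed point stays put (subcritical tau)", {
  p <- params_sub()
  fp <- resting_fixed_point(p$I_1)
  tr <- integrate_dde(p, stimulus_protocol(sigma = 0), dt = 2e-3,
                      history = fp$r_star)
  expect_lt(max(abs(tr$r_1 - fp$r_star)), 1e-6)
  expect_lt(max(abs(tr$r_2 - fp$r_star)), 1e-6)
  expect_equal(tr$w_1, hill(tr$r_1 * tr$r_2))
})

test_that("sigma = 0 gives machine-precision symmetry in both modes", {
  for (tau in c(1.4, 1.7)) {
    p <- model_params(tau_1 = tau, tau_2 = tau)
    tr <- integrate_dde(p, stimulus_protocol(sigma = 0), dt = 2e-3)
    expect_identical(tr$r_1, tr$r_2)
  }
  # sigma = 0 makes the two injection modes coincide exactly
  p <- params_sub()
  tr_c <- integrate_dde(p, stimulus_protocol(sigma = 0, mode = "clamped_history"),
                        dt = 0.01)
  tr_a <- integrate_dde(p, stimulus_protocol(sigma = 0, mode = "additive_input"),
                        dt = 0.01)
  expect_identical(tr_c$r_1, tr_a$r_1)
  expect_identical(tr_c$r_2, tr_a$r_2)
})

test_that("zero-noise stochastic path equals the deterministic Euler path", {
  p <- params_sub()
  s <- stim_weak("additive_input")
  det <- integrate_dde(p, s, dt = 0.01, method = "euler")
  sto <- integrate_sdde(p, s, b = 0, dt = 0.01, seed = 42)
  expect_identical(det$r_1, sto$r_1)
  expect_identical(det$r_2, sto$r_2)
})

test_that("stochastic trajectories are reproducible under a fixed seed", {
  p <- params_sub()
  s <- stim_weak("additive_input")
  a <- suppressWarnings(integrate_sdde(p, s, b = 0.5, dt = 0.01, seed = 7))
  b <- suppressWarnings(integrate_sdde(p, s, b = 0.5, dt = 0.01, seed = 7))
  cc <- suppressWarnings(integrate_sdde(p, s, b = 0.5, dt = 0.01, seed = 8))
  expect_identical(a$r_1, b$r_1)
  expect_false(identical(a$r_1, cc$r_1))
})

test_that("step refinement converges at first order across the clamp kink", {
  p <- params_sub()
  s <- stim_weak()
  tr1 <- integrate_dde(p, s, dt = 4e-3)
  tr2 <- integrate_dde(p, s, dt = 2e-3)
  tr3 <- integrate_dde(p, s, dt = 1e-3)
  sub <- function(tr, by) tr$r_1[seq(1, length(tr$t), by = by)]
  d1 <- max(abs(sub(tr1, 1) - sub(tr2, 2)))
  d2 <- max(abs(sub(tr2, 1) - sub(tr3, 2)))
  # propagated discontinuities cap the global order at p = 1: ratio ~ 2
  expect_gt(d1 / d2, 1.7)
  expect_lt(d2, 1e-4)
})

test_that("method-of-steps solution matches a dense-history Euler oracle", {
  p <- params_sub()
  tr <- integrate_dde(p, stim_weak(), dt = 1e-3)
  or <- oracle_euler(tau = 1.4, sigma = 0.3, dt = 1e-4)
  idx <- seq(1, length(or$t), by = 10)   # common grid at dt = 1e-3
  expect_lt(max(abs(tr$r_1 - or$r1[idx])), 1e-3)
  expect_lt(max(abs(tr$r_2 - or$r2[idx])), 1e-3)
})

test_that("solutions are continuous: adjacent-point jumps scale with dt", {
  p <- params_super()
  for (dt in c(4e-3, 2e-3)) {
    tr <- integrate_dde(p, stim_weak(), dt = dt)
    max_drift <- max(abs(c(tr$r_1, tr$r_2))) + max(tr$w_1) *
      max(abs(c(tr$r_1, tr$r_2))) + p$I_1 + 0.3
    expect_lt(max(abs(diff(tr$r_1))), 2 * max_drift * dt / p$tau_r)
  }
})

test_that("ensemble mean of weakly noisy paths tracks the deterministic path", {
  p <- params_sub()
  s <- stim_weak("additive_input")
  det <- integrate_dde(p, s, dt = 0.01, method = "euler")
  idx <- vapply(c(2, 5, 7), function(tt) which.min(abs(det$t - tt)), integer(1))
  n <- 200
  m <- matrix(0, n, length(idx))
  for (i in seq_len(n)) {
    tr <- suppressWarnings(integrate_sdde(p, s, b = 0.1, dt = 0.01,
                                          seed = 100 + i))
    m[i, ] <- tr$r_1[idx]
  }
  mu <- colMeans(m)
  se <- apply(m, 2, sd) / sqrt(n)
  expect_true(all(abs(mu - det$r_1[idx]) < 3 * se))
})

test_that("trajectory CSV + sidecar round-trips losslessly", {
  p <- params_sub()
  tr <- integrate_dde(p, stim_weak(), dt = 0.01)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  rel <- abs(back$r_1 - tr$r_1) / pmax(abs(tr$r_1), 1)
  expect_lt(max(rel), 1e-15)
  expect_identical(back$meta$dt, 0.01)
  expect_identical(back$meta$mode, "clamped_history")
})

test_that("solver input validation and negative-rate warnings", {
  p <- params_sub()
  expect_error(integrate_dde(p, stim_weak(), dt = -1), "dt")
  expect_error(integrate_dde(p, stim_weak(), dt = 2), "delay")
  expect_error(integrate_dde(model_params(T = 0.2), stim_weak(), dt = 0.01),
               "horizon")
  expect_error(integrate_sdde(p, stim_weak("additive_input"), b = -1), "b")
  # a long weak additive stimulus at supercritical delay dips below zero
  p17 <- params_super()
  expect_warning(
    integrate_dde(p17, stimulus_protocol(sigma = 0.3, t_max = 1.5,
                                         mode = "additive_input"), dt = 2e-3),
    class = "dwta_negative_rates")
})
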