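test_that("symmetric trajectories give p = 0.5 everywhere and no switches", {
  p <- params_super()
  tr <- integrate_dde(p, stimulus_protocol(sigma = 0), dt = 2e-3)
  ev <- accumulate_evidence(tr)
  expect_identical(max(abs(ev$p_1 - 0.5)), 0)
  expect_identical(max(abs(ev$p_2 - 0.5)), 0)
  expect_identical(ev$n_switches, 0L)   # all-zero difference: no sign changes
  expect_identical(ev$decided, "none")
  expect_identical(ev$leader, "tie")
})

test_that("constant rate difference reproduces the logistic closed form", {
  t <- seq(0, 6, by = 1e-3)
  delta <- 2; beta <- 1
  tr <- synthetic_trajectory(t, r1 = rep(0.4 + delta, length(t)),
                             r2 = rep(0.4, length(t)))
  ev <- accumulate_evidence(tr, beta = beta)
  expect_equal(ev$p_1, plogis(beta * delta * t), tolerance = 1e-12)
  expect_equal(ev$p_1 + ev$p_2, rep(1, length(t)), tolerance = 1e-12)
  expect_equal(ev$p_1[1], 0.5)
  # threshold crossing time from inverting the logistic
  d <- decide(ev, theta = 0.99)
  expect_identical(d$outcome, "population_1")
  expect_equal(d$t_decide, log(0.99 / 0.01) / (beta * delta), tolerance = 1e-5)
  # negative difference decides for population 2
  tr2 <- synthetic_trajectory(t, r1 = rep(0.4, length(t)),
                              r2 = rep(0.4 + delta, length(t)))
  expect_identical(accumulate_evidence(tr2)$decided, "population_2")
})

test_that("beta = 0 flattens the evidence regardless of the trajectory", {
  p <- params_super()
  tr <- integrate_dde(p, stim_weak(), dt = 0.01)
  ev <- accumulate_evidence(tr, beta = 0)
  expect_true(all(ev$p_1 == 0.5))
  expect_identical(ev$decided, "none")
})

test_that("normalization p_1 + p_2 = 1 holds in every regime", {
  cases <- list(
    list(p = params_sub(), s = stim_weak()),
    list(p = params_super(), s = stim_weak()),
    list(p = params_super(), s = stim_strong()))
  for (cs in cases) {
    tr <- suppressWarnings(integrate_dde(cs$p, cs$s, dt = 2e-3))
    ev <- accumulate_evidence(tr)
    expect_lt(max(abs(ev$p_1 + ev$p_2 - 1)), 1e-12)
    expect_true(all(ev$p_1 > 0 & ev$p_1 < 1))
  }
  trs <- suppressWarnings(integrate_sdde(params_sub(),
                                         stim_weak("additive_input"),
                                         b = 0.5, dt = 0.01, seed = 5))
  evs <- accumulate_evidence(trs)
  expect_lt(max(abs(evs$p_1 + evs$p_2 - 1)), 1e-12)
})

test_that("swapping the stimulated population swaps the evidence exactly", {
  p <- params_sub()
  tr1 <- integrate_dde(p, stimulus_protocol(sigma = 0.3, target = 1), dt = 0.01)
  tr2 <- integrate_dde(p, stimulus_protocol(sigma = 0.3, target = 2), dt = 0.01)
  ev1 <- accumulate_evidence(tr1)
  ev2 <- accumulate_evidence(tr2)
  expect_identical(ev1$p_1, ev2$p_2)
  expect_identical(ev1$p_2, ev2$p_1)
})

test_that("certainty vanishes for sigma = 0 or beta = 0 and grows with beta", {
  p <- params_super()
  expect_identical(certainty(0, 1, p, dt = 0.01), 0)
  expect_identical(certainty(0.3, 0, p, dt = 0.01), 0)
  betas <- c(0, 0.5, 1, 2, 4)
  cm <- certainty_surface(0.3, betas, p, dt = 0.01)
  expect_identical(dim(cm$c), c(1L, 5L))
  expect_true(all(diff(cm$c[1, ]) >= 0))
  # 1x1 grid consistency with the scalar call
  expect_equal(certainty_surface(0.3, 1, p, dt = 0.01)$c[1, 1],
               certainty(0.3, 1, p, dt = 0.01))
  expect_error(certainty_surface(numeric(0), 1, p), "nonempty")
  expect_error(certainty_surface(-0.1, 1, p), "nonnegative")
})

test_that("certainty is insensitive to halving the integration step", {
  p <- params_super()
  c1 <- certainty(0.3, 1, p, dt = 2e-3)
  c2 <- certainty(0.3, 1, p, dt = 1e-3)
  expect_lt(abs(c1 - c2), 1e-4)
})

test_that("duration sweep flags, conventions and failure mode", {
  p <- params_super()
  # sigma = 0: identically-zero difference counts as unambiguous
  sw0 <- duration_sweep(0, c(0.2, 0.5), p, dt = 0.01)
  expect_false(any(sw0$table$ambivalent))
  expect_equal(sw0$critical_duration, 0.2)
  # canonical brief stimulus is ambivalent in both injection modes
  for (mode in c("clamped_history", "additive_input")) {
    tr <- integrate_dde(p, stimulus_protocol(sigma = 0.3, mode = mode),
                        dt = 2e-3)
    expect_gte(accumulate_evidence(tr)$n_switches, 1L)
  }
  # clamp-mode oscillation outlasts short grids: critical delay undefined
  expect_error(duration_sweep(0.3, c(0.3, 0.5), p, mode = "clamped_history",
                              dt = 0.01),
               "undefined")
  expect_error(duration_sweep(0.3, c(0.5, 0.3), p), "ascending")
})
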