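test_that("hemodynamic parameter validation", {
  expect_error(hemo_params(kappa = 0), "positive")
  expect_error(hemo_params(alpha = 1.5), "alpha")
  expect_error(hemo_params(E_0 = 1), "E_0")
})

test_that("joint signal sums rates; antiphase components cancel", {
  p <- params_sub()
  fp <- resting_fixed_point(p$I_1)
  tr <- integrate_dde(p, stimulus_protocol(sigma = 0), dt = 0.01,
                      history = fp$r_star)
  js <- joint_signal(tr)
  expect_lt(max(abs(js - 2 * fp$r_star)), 1e-6)
  # pure antiphase oscillation sums to a constant; in-phase doubles
  t <- seq(0, 10, by = 0.01)
  m <- 0.4; A <- 0.2
  anti <- synthetic_trajectory(t, m + A * sin(t), m - A * sin(t))
  expect_lt(max(abs(joint_signal(anti) - 2 * m)), 1e-12)
  inph <- synthetic_trajectory(t, m + A * sin(t), m + A * sin(t))
  expect_equal(max(joint_signal(inph)) - min(joint_signal(inph)), 4 * A,
               tolerance = 1e-4)
})

test_that("balloon model at rest stays at rest", {
  hr <- hemodynamic_response(numeric(3000), dt = 0.01)
  expect_lt(max(abs(hr$bold)), 1e-10)
})

test_that("impulse responses peak several seconds post-impulse in both modes", {
  dt <- 0.01
  x <- c(rep(1, round(0.1 / dt)), rep(0, round(24.9 / dt)))  # brief kick
  for (method in c("balloon", "double_gamma")) {
    hr <- hemodynamic_response(0.1 * x, dt = dt, method = method)
    t_peak <- hr$t[which.max(hr$bold)]
    expect_gt(t_peak, 3)
    expect_lt(t_peak, 8)
    # returns toward baseline by the end of the window
    expect_lt(abs(hr$bold[length(hr$bold)]), 0.2 * max(hr$bold))
  }
})

test_that("balloon response is approximately linear at small amplitude", {
  dt <- 0.01
  x <- c(rep(1, round(0.1 / dt)), rep(0, round(19.9 / dt)))
  eps <- 0.01
  h1 <- hemodynamic_response(eps * x, dt = dt)$bold
  h2 <- hemodynamic_response(2 * eps * x, dt = dt)$bold
  ref <- max(abs(h1))
  expect_lt(max(abs(h2 - 2 * h1)) / (2 * ref), 0.05)
})

test_that("TR sampling validates and subsamples the grid", {
  hr <- hemodynamic_response(numeric(1000), dt = 0.01, TR = 0.5)
  expect_equal(diff(hr$t_sample)[1], 0.5)
  expect_error(hemodynamic_response(numeric(100), dt = 0.01, TR = 0.0251),
               "multiple")
})

test_that("weak-stimulus joint signal varies far less than strong", {
  # the mechanism behind the variance prediction, measured on the rates
  p <- params_super()
  fp <- resting_fixed_point(p$I_1)
  win <- function(tr) {
    js <- joint_signal(tr) - 2 * fp$r_star
    var(js[tr$t >= 0.5])
  }
  v_weak <- win(suppressWarnings(integrate_dde(p, stim_weak(), dt = 2e-3)))
  v_strong <- win(suppressWarnings(integrate_dde(p, stim_strong(), dt = 2e-3)))
  expect_lt(v_weak, 0.5 * v_strong)
})

test_that("condition variances order rest < weak < strong and cross-check", {
  cv <- condition_variances(n_trials = 15, dt = 0.01, seed = 2)
  expect_true(attr(cv, "ordering_weak_lt_strong"))
  v <- setNames(cv$variance, cv$condition)
  expect_lt(v["rest"], v["weak"])
  expect_lt(v["weak"], v["strong"])
  # double-gamma forward model gives the same rank order
  cg <- condition_variances(n_trials = 15, dt = 0.01, seed = 2,
                            method = "double_gamma")
  expect_identical(order(cg$variance), order(cv$variance))
  # identical conditions agree up to sampling jitter
  same <- condition_variances(sigmas = c(a = 0.3, b = 0.3), n_trials = 30,
                              dt = 0.01, seed = 2)
  expect_lt(abs(diff(same$variance)) / mean(same$variance), 0.4)
  # all-rest pooling from the exact fixed point is degenerate
  r_star <- resting_fixed_point(0.4)$r_star
  expect_error(condition_variances(sigmas = c(rest = 0), n_trials = 5,
                                   dt = 0.01, history = r_star),
               "degenerate")
})
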