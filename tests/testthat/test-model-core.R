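test_that("hill transfer function matches its closed form and is even", {
  expect_identical(hill(0), 0)
  expect_equal(hill(1), 0.5)
  expect_equal(hill(3), 0.9)
  x <- seq(-5, 5, by = 0.37)
  expect_equal(hill(x), x^2 / (1 + x^2))
  expect_equal(hill(-x), hill(x))        # rates below zero map like |x|
  set.seed(11)
  y <- rnorm(200, sd = 10)
  expect_true(all(hill(y) >= 0 & hill(y) < 1))
  expect_true(all(diff(hill(seq(0, 10, by = 0.01))) >= 0))
})

test_that("quasi-steady weights are symmetric, equal and in [0, 1)", {
  w <- quasi_steady_weights(0.4, 0.4)
  expect_equal(w$w_1, 0.16^2 / (1 + 0.16^2))
  expect_identical(w$w_1, w$w_2)
  expect_identical(quasi_steady_weights(0, 123)$w_1, 0)
  set.seed(7)
  a <- rnorm(100, sd = 3); b <- rnorm(100, sd = 3)
  wab <- quasi_steady_weights(a, b)
  wba <- quasi_steady_weights(b, a)
  expect_identical(wab$w_1, wba$w_1)
  expect_true(all(wab$w_1 >= 0 & wab$w_1 < 1))
})

test_that("resting fixed point agrees with an independent bisection oracle", {
  expect_equal(resting_fixed_point(0), list(r_star = 0, w_star = 0))
  fp <- resting_fixed_point(0.4)
  expect_equal(fp$r_star, oracle_fixed_point(0.4), tolerance = 1e-12)
  expect_lt(abs(fp$r_star - hill(fp$r_star^2) * fp$r_star - 0.4), 1e-12)
  expect_equal(fp$w_star, hill(fp$r_star^2))
  # bracketing by sign of the residual
  g <- function(r) r - hill(r^2) * r - 0.4
  expect_lt(g(0.40), 0)
  expect_gt(g(0.45), 0)
  expect_true(fp$r_star > 0.40 && fp$r_star < 0.45)
  # quasi-steady weights at the fixed point close the loop
  expect_equal(quasi_steady_weights(fp$r_star, fp$r_star)$w_1, fp$w_star)
  # beyond the fold of r/(1+r^4) no resting state exists
  expect_error(resting_fixed_point(0.6), "no resting state")
})

test_that("rhs vanishes at the fixed point and respects relabeling symmetry", {
  p <- model_params()
  fp <- resting_fixed_point(0.4)
  rr <- c(fp$r_star, fp$r_star)
  expect_equal(wta_rhs(rr, rr, p, 0.4, 0.4), c(0, 0), tolerance = 1e-12)
  expect_identical(wta_rhs(c(0, 0), c(0, 0), p, 0.4, 0.4), c(0.4, 0.4))
  set.seed(3)
  for (i in 1:25) {
    r <- rnorm(2); rd <- rnorm(2); ins <- runif(2)
    lhs <- wta_rhs(rev(r), rev(rd), p, ins[2], ins[1])
    expect_equal(lhs, rev(wta_rhs(r, rd, p, ins[1], ins[2])))
  }
  expect_error(wta_rhs(c(0, 0), c(0, 0, 0), p, 0, 0), "length-2")
})

test_that("parameter and stimulus constructors validate their invariants", {
  expect_error(model_params(tau_r = 0), "tau_r")
  expect_error(model_params(tau_1 = -0.1), "tau_1")
  expect_error(model_params(theta = 0.5), "theta")
  expect_error(model_params(theta = 1), "theta")
  expect_error(model_params(I_1 = -1), "I_1")
  expect_error(model_params(T = 0), "'T'")
  expect_error(stimulus_protocol(sigma = -0.1), "sigma")
  expect_error(stimulus_protocol(t_on = 0.5, mode = "clamped_history"), "t_on")
  expect_silent(stimulus_protocol(t_on = 0.5, mode = "additive_input"))
  expect_error(stimulus_protocol(target = 3), "target")
})

test_that("configuration files round-trip and report missing keys", {
  p <- model_params(tau_1 = 1.7, tau_2 = 1.7, beta = 2)
  s <- stimulus_protocol(sigma = 0.3, t_max = 1.0, mode = "additive_input")
  path <- withr::local_tempfile(fileext = ".json")
  write_config(p, s, path)
  cfg <- read_config(path)
  expect_equal(unclass(cfg$params), unclass(p))
  expect_equal(unclass(cfg$stim), unclass(s))
  # dropping a key is reported by name
  raw <- jsonlite::read_json(path)
  raw$tau_r <- NULL
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(raw, path2, auto_unbox = TRUE)
  expect_error(read_config(path2), "tau_r")
})
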