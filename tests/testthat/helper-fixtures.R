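# Shared fixtures and independent oracles for the test suite.

params_sub <- function(...) model_params(tau_1 = 1.4, tau_2 = 1.4, ...)
params_super <- function(...) model_params(tau_1 = 1.7, tau_2 = 1.7, ...)

stim_weak <- function(mode = "clamped_history")
  stimulus_protocol(sigma = 0.3, mode = mode)
stim_strong <- function(mode = "clamped_history")
  stimulus_protocol(sigma = 1.0, mode = mode)

# Hand-built trajectory on a uniform grid (bypasses the solver) for
# closed-form evidence tests.
synthetic_trajectory <- function(t, r1, r2, t_on = 0, t_max = 0) {
  w <- hill(r1 * r2)
  structure(list(t = t, r_1 = r1, r_2 = r2, w_1 = w, w_2 = w,
                 meta = list(dt = t[2] - t[1], method = "synthetic",
                             mode = "additive_input", seed = NULL, b = 0,
                             params = NULL,
                             stim = stimulus_protocol(sigma = 0, t_on = t_on,
                                                      t_max = t_max,
                                                      mode = "additive_input"))),
            class = "dwta_trajectory")
}

# Independent dense-history Euler integration of the delayed system,
# written without the package's method-of-steps bookkeeping: the whole
# solution (including the prescribed history segment) lives in one array
# indexed directly. Clamped-history injection only, t_on = 0.
oracle_euler <- function(tau, sigma, t_max = 0.5, I = 0.4, tau_r = 1,
                         T = 8, dt = 1e-4, base = 0.4) {
  n <- round(T / dt)
  lag <- tau / dt
  stopifnot(abs(lag - round(lag)) < 1e-9)  # oracle needs commensurate delay
  lag <- round(lag)
  k0 <- round(t_max / dt)
  r1 <- numeric(n + 1); r2 <- numeric(n + 1)
  r1[1:(k0 + 1)] <- base + sigma
  r2[1:(k0 + 1)] <- base
  for (k in (k0 + 1):n) {
    d1 <- if (k - lag <= 0) base else r1[k - lag]
    d2 <- if (k - lag <= 0) base else r2[k - lag]
    # during the clamp the stored values ARE the clamped values
    w <- hill(r1[k] * r2[k])
    r1[k + 1] <- r1[k] + dt * (-d1 + w * r2[k] + I) / tau_r
    r2[k + 1] <- r2[k] + dt * (-d2 + w * r1[k] + I) / tau_r
  }
  list(t = (0:n) * dt, r1 = r1, r2 = r2)
}

# Bisection to tolerance tol on the ascending branch of r/(1+r^4) = I;
# independent of the package's uniroot + Newton path.
oracle_fixed_point <- function(I, tol = 1e-13) {
  lo <- 0; hi <- (1 / 3)^0.25
  g <- function(r) r / (1 + r^4) - I
  stopifnot(g(lo) < 0, g(hi) > 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
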