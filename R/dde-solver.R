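# Method-of-steps integration of the delayed two-population system on a
# uniform grid. Delayed values are read from the stored solution: cubic
# Hermite interpolation (using the stored drift) for the deterministic
# RK4 path, linear interpolation for the Euler / Euler-Maruyama path.
# Before t = 0 the system sits in a constant history; in clamped-history
# mode the stimulus window [0, t_max] is part of the prescribed history
# and free integration starts at t_max.

# Shared lookup of the pair (r1(s1), r2(s2)) with s_i = t - tau_i.
# 'r1', 'r2', 'drift1', 'drift2' are the stored grids up to index k_known
# (1-based, time (k_known-1)*dt). 'hermite' selects cubic interpolation.
.delayed_lookup <- function(s, dt, r, drift, base, clamp, clamp_end, clamped_value,
                            hermite) {
  if (s <= 0) {
    if (clamp && s >= 0) return(clamped_value)
    return(base)
  }
  if (clamp && s <= clamp_end) return(clamped_value)
  u <- s / dt
  j <- floor(u + 1e-9)
  th <- u - j
  if (th < 1e-9) return(r[j + 1L])
  y0 <- r[j + 1L]; y1 <- r[j + 2L]
  if (!hermite) return(y0 * (1 - th) + y1 * th)
  d0 <- drift[j + 1L]; d1 <- drift[j + 2L]
  h00 <- (1 + 2 * th) * (1 - th)^2
  h10 <- th * (1 - th)^2
  h01 <- th^2 * (3 - 2 * th)
  h11 <- th^2 * (th - 1)
  h00 * y0 + h10 * dt * d0 + h01 * y1 + h11 * dt * d1
}

.make_trajectory <- function(t, r1, r2, meta) {
  w <- hill(r1 * r2)
  structure(list(t = t, r_1 = r1, r_2 = r2, w_1 = w, w_2 = w, meta = meta),
            class = "dwta_trajectory")
}

.check_negative_rates <- function(t, r1, r2) {
  neg <- which(r1 < 0 | r2 < 0)
  if (length(neg))
    warning(warningCondition(
      sprintf("negative firing rates from t = %.4g s (rates are not rectified)",
              t[neg[1L]]),
      class = "dwta_negative_rates"))
  invisible(NULL)
}

.check_finite <- function(t, r1, r2) {
  bad <- which(!is.finite(r1) | !is.finite(r2))
  if (length(bad))
    stop("integration diverged: non-finite state first reached at t = ",
         signif(t[bad[1L]], 6), " s", call. = FALSE)
  invisible(NULL)
}

# Resolve the stimulus bookkeeping shared by all integrators.
.stim_setup <- function(params, stim, dt) {
  n <- round(params$T / dt)
  if (abs(n * dt - params$T) > 1e-9 * max(1, params$T))
    n <- ceiling(params$T / dt - 1e-9)
  clamp <- stim$mode == "clamped_history" && stim$sigma > 0
  if (params$T < stim$t_on + stim$t_max)
    stop("horizon T must cover the stimulus window", call. = FALSE)
  list(n = n,
       clamp = clamp,
       k0 = if (clamp) round(stim$t_max / dt) else 0L,
       on_idx = round(stim$t_on / dt),
       off_idx = round((stim$t_on + stim$t_max) / dt))
}

#' Integrate the deterministic delayed system
#'
#' Method-of-steps integration of the delayed winner-take-all model over
#' `[0, T]` on a uniform grid. The history before t = 0 is constant at
#' `history` (both populations); in `clamped_history` mode the rates
#' during the stimulus window are held at the clamped values (stimulated
#' population at `history + sigma`) and the free dynamics starts at the
#' end of the window, while in `additive_input` mode integration starts
#' at t = 0 with `sigma` added to the stimulated population's input
#' during the window.
#'
#' The default stepper is classical RK4 with cubic-Hermite interpolation
#' of the stored solution for delayed lookups; `method = "euler"` uses
#' explicit Euler with linear interpolation (bit-identical to the
#' zero-noise stochastic path of [integrate_sdde()]).
#'
#' @param params A [model_params()] object.
#' @param stim A [stimulus_protocol()] object.
#' @param dt Step size, seconds; must be positive and no larger than any
#'   nonzero delay.
#' @param method `"rk4"` (default) or `"euler"`.
#' @param history Constant history value for both rates before t = 0.
#'   Defaults to `params$I_1` (the resting value used in the original
#'   construction); pass `resting_fixed_point(params$I_1)$r_star` for the
#'   exact coupled fixed point.
#' @return A `dwta_trajectory`: uniform grid `t`, rates `r_1`, `r_2`,
#'   quasi-steady weights `w_1`, `w_2`, and solver metadata in `meta`.
#' @examples
#' p <- model_params(tau_1 = 1.7, tau_2 = 1.7)
#' tr <- integrate_dde(p, stimulus_protocol(sigma = 0.3), dt = 0.01)
#' range(tr$r_1)
#' @export
integrate_dde <- function(params, stim = stimulus_protocol(sigma = 0),
                          dt = 1e-3, method = c("rk4", "euler"),
                          history = params$I_1) {
  method <- match.arg(method)
  stopifnot(inherits(params, "dwta_params"), inherits(stim, "dwta_stimulus"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("integrate_dde: 'dt' must be > 0", call. = FALSE)
  for (tau in c(params$tau_1, params$tau_2))
    if (tau > 0 && tau < dt)
      stop("integrate_dde: 'dt' must not exceed a nonzero delay", call. = FALSE)
  if (method == "euler")
    return(.integrate_euler_core(params, stim, b = 0, dt = dt, seed = NULL,
                                 history = history))

  st <- .stim_setup(params, stim, dt)
  n <- st$n
  t <- (0:n) * dt
  r1 <- numeric(n + 1L); r2 <- numeric(n + 1L)
  f1 <- numeric(n + 1L); f2 <- numeric(n + 1L)  # stored drifts for Hermite
  tau1 <- params$tau_1; tau2 <- params$tau_2; tau_r <- params$tau_r
  I1 <- params$I_1; I2 <- params$I_2
  sig1 <- if (stim$mode == "additive_input" && stim$target == 1L) stim$sigma else 0
  sig2 <- if (stim$mode == "additive_input" && stim$target == 2L) stim$sigma else 0
  base1 <- history; base2 <- history
  clamped <- c(history, history)
  if (st$clamp) clamped[stim$target] <- history + stim$sigma
  clamp_end <- stim$t_max

  k_start <- st$k0 + 1L  # 1-based index of first state we integrate FROM
  if (st$clamp) {
    r1[1:k_start] <- clamped[1L]
    r2[1:k_start] <- clamped[2L]
  } else {
    r1[1L] <- base1; r2[1L] <- base2
  }

  look1 <- function(s)
    .delayed_lookup(s, dt, r1, f1, base1, st$clamp, clamp_end, clamped[1L], TRUE)
  look2 <- function(s)
    .delayed_lookup(s, dt, r2, f2, base2, st$clamp, clamp_end, clamped[2L], TRUE)

  drift <- function(tt, a, b2) {
    d1 <- if (tau1 == 0) a else look1(tt - tau1)
    d2 <- if (tau2 == 0) b2 else look2(tt - tau2)
    w <- hill(a * b2)
    in_stim <- tt >= stim$t_on && tt < stim$t_on + stim$t_max
    c(-d1 + w * b2 + I1 + if (in_stim) sig1 else 0,
      -d2 + w * a + I2 + if (in_stim) sig2 else 0) / tau_r
  }

  if (k_start > 1L)
    for (k in 1:(k_start - 1L)) { f1[k] <- 0; f2[k] <- 0 }  # clamp: rates held

  for (k in k_start:n) {
    tk <- t[k]
    a <- r1[k]; b2 <- r2[k]
    k1 <- drift(tk, a, b2)
    f1[k] <- k1[1L]; f2[k] <- k1[2L]
    k2 <- drift(tk + dt / 2, a + dt / 2 * k1[1L], b2 + dt / 2 * k1[2L])
    k3 <- drift(tk + dt / 2, a + dt / 2 * k2[1L], b2 + dt / 2 * k2[2L])
    k4 <- drift(tk + dt, a + dt * k3[1L], b2 + dt * k3[2L])
    r1[k + 1L] <- a + dt / 6 * (k1[1L] + 2 * k2[1L] + 2 * k3[1L] + k4[1L])
    r2[k + 1L] <- b2 + dt / 6 * (k1[2L] + 2 * k2[2L] + 2 * k3[2L] + k4[2L])
  }
  fin <- drift(t[n + 1L], r1[n + 1L], r2[n + 1L])
  f1[n + 1L] <- fin[1L]; f2[n + 1L] <- fin[2L]

  .check_finite(t, r1, r2)
  .check_negative_rates(t, r1, r2)
  .make_trajectory(t, r1, r2,
                   meta = list(dt = dt, method = "rk4", mode = stim$mode,
                               seed = NULL, b = 0, params = params, stim = stim,
                               history = history))
}

# Explicit Euler / Euler-Maruyama core shared by the deterministic euler
# method and the stochastic integrator. The increment of r_i is
#   drift * dt + (b / tau_r) * sqrt(dt) * z
# with independent standard normals per population and step (the noise
# enters the differential of tau_r * r, hence the 1/tau_r factor).
.integrate_euler_core <- function(params, stim, b, dt, seed, history) {
  st <- .stim_setup(params, stim, dt)
  n <- st$n
  t <- (0:n) * dt
  tau1 <- params$tau_1; tau2 <- params$tau_2; tau_r <- params$tau_r
  I1 <- params$I_1; I2 <- params$I_2
  sig1 <- if (stim$mode == "additive_input" && stim$target == 1L) stim$sigma else 0
  sig2 <- if (stim$mode == "additive_input" && stim$target == 2L) stim$sigma else 0
  clamped <- c(history, history)
  if (st$clamp) clamped[stim$target] <- history + stim$sigma
  clamp_end <- stim$t_max
  k_start <- st$k0 + 1L

  if (!is.null(seed)) set.seed(seed)
  nsteps <- n - k_start + 1L
  if (b > 0) {
    z1 <- stats::rnorm(nsteps); z2 <- stats::rnorm(nsteps)
  } else {
    z1 <- numeric(nsteps); z2 <- numeric(nsteps)
  }
  amp <- b / tau_r * sqrt(dt)

  r1 <- numeric(n + 1L); r2 <- numeric(n + 1L)
  if (st$clamp) {
    r1[1:k_start] <- clamped[1L]; r2[1:k_start] <- clamped[2L]
  } else {
    r1[1L] <- history; r2[1L] <- history
  }

  # delayed index offsets; non-commensurate delays use linear interpolation
  lag1 <- tau1 / dt; lag2 <- tau2 / dt
  getdel <- function(r, k, lag, clamped_v) {
    if (lag == 0) return(r[k])
    s <- (k - 1L) - lag           # fractional grid index of t - tau
    if (s <= 0) {
      if (st$clamp && s >= -1e-9) return(clamped_v)
      return(history)
    }
    if (st$clamp && s <= st$k0 + 1e-9) return(clamped_v)
    j <- floor(s + 1e-9); th <- s - j
    if (th < 1e-9) r[j + 1L] else r[j + 1L] * (1 - th) + r[j + 2L] * th
  }

  stim_on <- stim$t_on; stim_off <- stim$t_on + stim$t_max
  for (k in k_start:n) {
    tk <- t[k]
    a <- r1[k]; bb <- r2[k]
    d1 <- getdel(r1, k, lag1, clamped[1L])
    d2 <- getdel(r2, k, lag2, clamped[2L])
    w <- a * bb; w <- w * w / (1 + w * w)   # hill(r1 r2), inlined
    in_stim <- tk >= stim_on && tk < stim_off
    i <- k - k_start + 1L
    r1[k + 1L] <- a + dt * (-d1 + w * bb + I1 + if (in_stim) sig1 else 0) / tau_r +
      amp * z1[i]
    r2[k + 1L] <- bb + dt * (-d2 + w * a + I2 + if (in_stim) sig2 else 0) / tau_r +
      amp * z2[i]
  }
  .check_finite(t, r1, r2)
  .check_negative_rates(t, r1, r2)
  .make_trajectory(t, r1, r2,
                   meta = list(dt = dt, method = if (b > 0) "euler_maruyama" else "euler",
                               mode = stim$mode, seed = seed, b = b,
                               params = params, stim = stim, history = history))
}

#' Integrate the stochastic delayed system (Euler-Maruyama)
#'
#' Adds independent Wiener increments to both populations: the increment
#' of `r_i` per step is `drift * dt + (b / tau_r) * sqrt(dt) * z` with
#' standard normal `z`. With `b = 0` the trajectory is bit-for-bit equal
#' to the deterministic Euler integration on the same grid. Delayed
#' values are linearly interpolated from the stored path.
#'
#' @inheritParams integrate_dde
#' @param b Noise magnitude (diffusion coefficient), nonnegative.
#' @param seed Integer seed; the trial is fully reproducible given
#'   `(seed, dt, b)`. The seed is set via [set.seed()], so the global RNG
#'   stream is advanced.
#' @return A `dwta_trajectory` (metadata records `b` and `seed`).
#' @examples
#' p <- model_params()
#' s <- stimulus_protocol(sigma = 0.3, mode = "additive_input")
#' tr <- integrate_sdde(p, s, b = 0.1, dt = 0.01, seed = 1)
#' @export
integrate_sdde <- function(params, stim, b, dt = 0.01, seed = 1L,
                           history = params$I_1) {
  stopifnot(inherits(params, "dwta_params"), inherits(stim, "dwta_stimulus"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("integrate_sdde: 'dt' must be > 0", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L || b < 0)
    stop("integrate_sdde: 'b' must be >= 0", call. = FALSE)
  for (tau in c(params$tau_1, params$tau_2))
    if (tau > 0 && tau < dt)
      stop("integrate_sdde: 'dt' must not exceed a nonzero delay", call. = FALSE)
  .integrate_euler_core(params, stim, b = b, dt = dt, seed = seed,
                        history = history)
}

#' @export
print.dwta_trajectory <- function(x, ...) {
  m <- x$meta
  cat(sprintf("dwta_trajectory: %d points on [0, %g] s (dt = %g, %s, mode = %s)\n",
              length(x$t), max(x$t), m$dt, m$method, m$mode))
  cat(sprintf("  r_1 in [%.4g, %.4g], r_2 in [%.4g, %.4g]\n",
              min(x$r_1), max(x$r_1), min(x$r_2), max(x$r_2)))
  invisible(x)
}

#' @export
as.data.frame.dwta_trajectory <- function(x, ...) {
  data.frame(t = x$t, r1 = x$r_1, r2 = x$r_2, w1 = x$w_1, w2 = x$w_2)
}

#' Write / read a trajectory as CSV plus JSON sidecar
#'
#' The CSV has header `t,r1,r2,w1,w2` with full double precision
#' (`%.17g`), so a round trip is lossless to 1e-15 relative. Solver
#' metadata (dt, method, mode, seed, b) goes to `<path>.meta.json`.
#'
#' @param traj A `dwta_trajectory`.
#' @param path Output CSV path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `dwta_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "dwta_trajectory"))
  lines <- c("t,r1,r2,w1,w2",
             sprintf("%.17g,%.17g,%.17g,%.17g,%.17g",
                     traj$t, traj$r_1, traj$r_2, traj$w_1, traj$w_2))
  writeLines(lines, path)
  m <- traj$meta
  jsonlite::write_json(
    list(dt = m$dt, method = m$method, mode = m$mode,
         seed = m$seed, b = m$b, history = m$history),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  structure(list(t = df$t, r_1 = df$r1, r_2 = df$r2,
                 w_1 = df$w1, w_2 = df$w2, meta = meta),
            class = "dwta_trajectory")
}
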