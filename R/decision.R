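# Evidence accumulation and decision readout. The accumulated evidence
# for population 1 is the logistic transform of the time integral of the
# rate difference:
#   p_1(t) = 1 / (1 + exp(-beta * int_0^t (r_1 - r_2) dxi)),  p_2 = 1 - p_1.
# Both probabilities are computed through plogis(+x) / plogis(-x), so
# p_1 + p_2 = 1 holds to machine precision by construction.

# Count strict sign alternations of x restricted to t > t0, with a
# dead-band: |x| <= tol counts as exact zero and is dropped, so an
# identically-zero sequence has 0 sign changes.
.count_sign_changes <- function(x, t, t0, tol = 1e-10) {
  x <- x[t > t0]
  s <- sign(x)
  s[abs(x) <= tol] <- 0
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1L] != s[-length(s)])
}

.cum_trapz <- function(t, y) {
  n <- length(t)
  c(0, cumsum((y[-n] + y[-1L]) / 2 * diff(t)))
}

#' Accumulate decision evidence along a trajectory
#'
#' Computes the cumulative trapezoidal integral of `r_1 - r_2` on the
#' trajectory grid and maps it through the logistic psychometric
#' function with slope `beta`, yielding the per-option probabilities
#' `p_1(t)`, `p_2(t)` (summing to one at every grid point, with
#' `p_1(0) = p_2(0) = 0.5`). The decision rule of [decide()] is applied
#' with threshold `theta`, and sign changes of `p_1 - p_2` after stimulus
#' offset are counted as the operational definition of perceptual
#' ambivalence.
#'
#' @param traj A `dwta_trajectory`.
#' @param beta Psychometric slope; defaults to the value stored in the
#'   trajectory's model parameters.
#' @param theta Decision threshold in (0.5, 1); defaults likewise.
#' @return A `dwta_evidence` object: `t`, `p_1`, `p_2`, the raw integral
#'   `e` of the rate difference, `decided` (`"population_1"`,
#'   `"population_2"` or `"none"`), `t_decide`, `n_switches` (sign
#'   changes of `p_1 - p_2` after stimulus offset) and `leader` (the
#'   population with the larger probability at the horizon, `"tie"` if
#'   equal).
#' @examples
#' p <- model_params()
#' tr <- integrate_dde(p, stimulus_protocol(sigma = 0.3), dt = 0.01)
#' ev <- accumulate_evidence(tr)
#' ev$n_switches
#' @export
accumulate_evidence <- function(traj, beta = NULL, theta = NULL) {
  stopifnot(inherits(traj, "dwta_trajectory"))
  if (length(traj$t) < 2L)
    stop("accumulate_evidence: empty trajectory", call. = FALSE)
  params <- traj$meta$params
  if (is.null(beta)) beta <- if (!is.null(params)) params$beta else 1
  if (is.null(theta)) theta <- if (!is.null(params)) params$theta else 0.99
  e <- .cum_trapz(traj$t, traj$r_1 - traj$r_2)
  p1 <- stats::plogis(beta * e)
  p2 <- stats::plogis(-beta * e)
  stim <- traj$meta$stim
  offset <- if (!is.null(stim)) stim$t_on + stim$t_max else 0
  ns <- .count_sign_changes(p1 - p2, traj$t, offset)
  n <- length(p1)
  leader <- if (p1[n] > p2[n]) "population_1"
            else if (p2[n] > p1[n]) "population_2" else "tie"
  ev <- structure(list(t = traj$t, p_1 = p1, p_2 = p2, e = e,
                       beta = beta, theta = theta, offset = offset,
                       n_switches = ns, leader = leader,
                       decided = NULL, t_decide = NULL),
                  class = "dwta_evidence")
  d <- decide(ev, theta)
  ev$decided <- d$outcome
  ev$t_decide <- d$t_decide
  ev
}

#' Threshold decision rule
#'
#' Returns the first population whose accumulated-evidence probability
#' surpasses `theta`, with the crossing time located by linear
#' interpolation between grid points, or `"none"` if neither probability
#' crosses within the horizon. Note that with the default threshold 0.99
#' and the canonical parameter sets, the probabilities do not reach the
#' threshold within the 8 s horizon; the `leader` field of the evidence
#' trace records which option dominates regardless.
#'
#' @param ev A `dwta_evidence` object.
#' @param theta Threshold in (0.5, 1).
#' @return A list with `outcome` (`"population_1"`, `"population_2"` or
#'   `"none"`) and `t_decide` (`NA_real_` when no crossing).
#' @export
decide <- function(ev, theta = ev$theta) {
  stopifnot(inherits(ev, "dwta_evidence"))
  if (theta <= 0.5 || theta >= 1)
    stop("decide: 'theta' must lie in (0.5, 1)", call. = FALSE)
  cross_time <- function(p) {
    idx <- which(p > theta)
    if (!length(idx)) return(NA_real_)
    k <- idx[1L]
    if (k == 1L) return(ev$t[1L])
    # linear interpolation of the crossing within [t[k-1], t[k]]
    ev$t[k - 1L] + (theta - p[k - 1L]) / (p[k] - p[k - 1L]) *
      (ev$t[k] - ev$t[k - 1L])
  }
  t1 <- cross_time(ev$p_1)
  t2 <- cross_time(ev$p_2)
  if (is.na(t1) && is.na(t2)) return(list(outcome = "none", t_decide = NA_real_))
  if (is.na(t2) || (!is.na(t1) && t1 <= t2))
    list(outcome = "population_1", t_decide = t1)
  else
    list(outcome = "population_2", t_decide = t2)
}

#' @export
print.dwta_evidence <- function(x, ...) {
  n <- length(x$t)
  cat(sprintf("dwta_evidence: p_1(T) = %.4f, p_2(T) = %.4f (beta = %g)\n",
              x$p_1[n], x$p_2[n], x$beta))
  cat(sprintf("  decision: %s%s; switches after offset: %d; leader: %s\n",
              x$decided,
              if (!is.na(x$t_decide)) sprintf(" at t = %.3f s", x$t_decide) else "",
              x$n_switches, x$leader))
  invisible(x)
}

#' Decision certainty for one stimulus condition
#'
#' Certainty is the maximum absolute difference of the two accumulated
#' evidence probabilities over the analysis window `[0, T]`:
#' `c(sigma, beta) = max_t |p_1(t) - p_2(t)|`. The maximum is taken over
#' the discrete grid; halving `dt` moves the value by far less than the
#' comparisons it feeds (see the package tests). The window is
#' deliberately capped at the horizon because the un-rectified rate model
#' can reach negative rates at large times.
#'
#' @param sigma Stimulus magnitude, 1/s.
#' @param beta Psychometric slope.
#' @param params A [model_params()] object (`T` is the analysis horizon).
#' @param stim_template A [stimulus_protocol()] whose `sigma` is replaced
#'   by the `sigma` argument; controls duration, mode and target.
#' @param dt Solver step.
#' @return A single certainty value in `[0, 1)`.
#' @examples
#' certainty(0.3, 1, model_params(tau_1 = 1.7, tau_2 = 1.7), dt = 0.01)
#' @export
certainty <- function(sigma, beta, params = model_params(),
                      stim_template = stimulus_protocol(sigma = 0),
                      dt = 1e-3) {
  stim <- stim_template
  stim$sigma <- sigma
  traj <- integrate_dde(params, stim, dt = dt)
  ev <- accumulate_evidence(traj, beta = beta)
  max(abs(ev$p_1 - ev$p_2))
}

#' Certainty surface over stimulus magnitude and slope
#'
#' Evaluates [certainty()] on the tensor grid `sigma_grid` x
#' `beta_grid`. The underlying trajectory depends only on `sigma`, so it
#' is integrated once per `sigma` and reused across all slopes.
#'
#' @param sigma_grid,beta_grid Nonempty, nonnegative numeric grids.
#' @inheritParams certainty
#' @return A `dwta_certainty_map`: list with `sigma_grid`, `beta_grid`
#'   and the certainty matrix `c` (rows = sigma, columns = beta).
#' @export
certainty_surface <- function(sigma_grid, beta_grid, params = model_params(),
                              stim_template = stimulus_protocol(sigma = 0),
                              dt = 1e-3) {
  if (!length(sigma_grid) || !length(beta_grid))
    stop("certainty_surface: grids must be nonempty", call. = FALSE)
  if (any(sigma_grid < 0) || any(beta_grid < 0))
    stop("certainty_surface: grids must be nonnegative", call. = FALSE)
  cmat <- matrix(NA_real_, length(sigma_grid), length(beta_grid),
                 dimnames = list(sigma = format(sigma_grid, trim = TRUE),
                                 beta = format(beta_grid, trim = TRUE)))
  for (i in seq_along(sigma_grid)) {
    stim <- stim_template
    stim$sigma <- sigma_grid[i]
    traj <- integrate_dde(params, stim, dt = dt)
    for (j in seq_along(beta_grid)) {
      ev <- accumulate_evidence(traj, beta = beta_grid[j])
      cmat[i, j] <- max(abs(ev$p_1 - ev$p_2))
    }
  }
  structure(list(sigma_grid = sigma_grid, beta_grid = beta_grid, c = cmat),
            class = "dwta_certainty_map")
}

#' @export
print.dwta_certainty_map <- function(x, ...) {
  cat("dwta_certainty_map: certainty over",
      length(x$sigma_grid), "sigma x", length(x$beta_grid), "beta values\n")
  print(round(x$c, 4))
  invisible(x)
}

#' Write a certainty map as CSV
#'
#' Matrix layout: first column `sigma`, remaining columns one per `beta`
#' value (header `beta_<value>`).
#'
#' @param cm A `dwta_certainty_map`.
#' @param path Output path.
#' @export
write_certainty_map <- function(cm, path) {
  stopifnot(inherits(cm, "dwta_certainty_map"))
  df <- data.frame(sigma = cm$sigma_grid, cm$c, check.names = FALSE)
  names(df) <- c("sigma", paste0("beta_", format(cm$beta_grid, trim = TRUE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Stimulus-duration sweep
#'
#' Integrates the model for each stimulus duration in `durations` (at
#' fixed magnitude `sigma`) and flags each run as *ambivalent* when
#' `p_1 - p_2` changes sign at least once after stimulus offset. The
#' critical duration is the smallest tested duration from which the flag
#' is false for all larger tested durations.
#'
#' The default injection mode is `additive_input`: under the
#' clamped-history construction with the canonical supercritical
#' parameters the oscillation outlasts every duration on the tested grid
#' within the 8 s horizon, so the critical duration would be undefined
#' (see the methods vignette).
#'
#' @param sigma Stimulus magnitude, 1/s.
#' @param durations Ascending vector of stimulus durations, seconds.
#' @param params A [model_params()] object.
#' @param mode Stimulus injection mode.
#' @param dt Solver step.
#' @return A `dwta_duration_sweep`: `table` (data frame `t_max`,
#'   `n_switches`, `ambivalent`) and `critical_duration`.
#' @examples
#' p <- model_params(tau_1 = 1.7, tau_2 = 1.7)
#' sw <- duration_sweep(0.3, c(0.5, 1.5, 2.0), p, dt = 0.01)
#' sw$critical_duration
#' @export
duration_sweep <- function(sigma, durations, params = model_params(),
                           mode = "additive_input", dt = 1e-3) {
  if (is.unsorted(durations, strictly = TRUE))
    stop("duration_sweep: 'durations' must be strictly ascending", call. = FALSE)
  ns <- integer(length(durations))
  for (i in seq_along(durations)) {
    stim <- stimulus_protocol(sigma = sigma, t_max = durations[i], mode = mode)
    traj <- integrate_dde(params, stim, dt = dt)
    ev <- accumulate_evidence(traj)
    ns[i] <- ev$n_switches
  }
  amb <- ns >= 1L
  tab <- data.frame(t_max = durations, n_switches = ns, ambivalent = amb)
  # smallest tested duration unambiguous from there on
  ok <- rev(cumprod(rev(!amb))) == 1
  if (!any(ok))
    stop("duration_sweep: no tested duration is unambiguous; ",
         "critical duration undefined on this grid", call. = FALSE)
  structure(list(table = tab,
                 critical_duration = durations[which(ok)[1L]]),
            class = "dwta_duration_sweep")
}

#' @export
print.dwta_duration_sweep <- function(x, ...) {
  print(x$table)
  cat(sprintf("critical duration: %g s\n", x$critical_duration))
  invisible(x)
}

#' Write a duration sweep as CSV (`t_max,n_switches,ambivalent`)
#'
#' @param sw A `dwta_duration_sweep`.
#' @param path Output path.
#' @export
write_duration_sweep <- function(sw, path) {
  stopifnot(inherits(sw, "dwta_duration_sweep"))
  utils::write.csv(sw$table, path, row.names = FALSE)
  invisible(path)
}
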