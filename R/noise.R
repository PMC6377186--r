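# Stochastic success-rate experiment: many Euler-Maruyama trials of the
# delayed system with an additive weak stimulus to population 1, each
# read out at a random time in a late window. A trial is successful when
# the accumulated evidence favors the stimulated population at readout.
# Success is defined by the sign of p_1 - p_2 (not the 0.99 threshold):
# it is the only definition under which every trial yields a decision
# and the chance level is exactly 0.5.

#' Run a single stochastic decision trial
#'
#' Integrates the stochastic system on `[0, T]` with noise magnitude `b`
#' and scores the trial: a readout time is drawn uniformly from
#' `readout_window`, and the trial succeeds iff `p_1 > p_2` there
#' (linear interpolation of the evidence integral between grid points).
#' An exact tie is resolved by a fair coin from the same generator. The
#' trial's RNG stream is fully determined by `seed`: the seed is set,
#' the readout time is drawn first, then the noise increments.
#'
#' @inheritParams integrate_sdde
#' @param readout_window Two-element window, seconds, within `[0, T]`.
#' @return Logical success flag, with attributes `t_read` and `p_1_read`.
#' @examples
#' p <- model_params()
#' s <- stimulus_protocol(sigma = 0.3, mode = "additive_input")
#' single_trial(p, s, b = 0.5, dt = 0.01, seed = 7)
#' @export
single_trial <- function(params, stim, b, dt = 0.01, seed = 1L,
                         readout_window = c(5, 7)) {
  stopifnot(inherits(params, "dwta_params"), inherits(stim, "dwta_stimulus"))
  if (readout_window[1L] < 0 || readout_window[2L] > params$T ||
      readout_window[1L] >= readout_window[2L])
    stop("single_trial: readout window must be increasing and within [0, T]",
         call. = FALSE)
  set.seed(seed)
  t_read <- stats::runif(1L, readout_window[1L], readout_window[2L])
  traj <- .integrate_euler_core(params, stim, b = b, dt = dt, seed = NULL,
                                history = params$I_1)
  e <- .cum_trapz(traj$t, traj$r_1 - traj$r_2)
  e_read <- stats::approx(traj$t, e, t_read)$y
  correct_sign <- if (stim$target == 1L) e_read > 0 else e_read < 0
  success <- if (e_read == 0) stats::runif(1L) < 0.5 else correct_sign
  structure(success, t_read = t_read,
            p_1_read = stats::plogis(params$beta * e_read))
}

#' Success rate as a function of noise magnitude
#'
#' For each noise magnitude in `b_values`, runs `n_iter` independent
#' trials of [single_trial()] with seeds `seed + 0 .. seed + n_iter - 1`
#' (the same seed set across magnitudes, so curves are reproducible and
#' trials embarrassingly parallel) and reports the mean success flag
#' with its binomial Monte-Carlo standard error
#' `sqrt(p (1 - p) / n_iter)`.
#'
#' @param b_values Noise magnitudes, nonnegative.
#' @param n_iter Trials per magnitude, at least 1.
#' @param params A [model_params()] object (`T` = 8 and `tau = 1.4` by
#'   default, the canonical noise-experiment setting).
#' @param stim A [stimulus_protocol()]; must target population 1 for the
#'   "correct decision" reading. Defaults to the additive weak stimulus
#'   `sigma = 0.3` on `[0, 0.5]` s.
#' @inheritParams single_trial
#' @param seed Base seed.
#' @return A `dwta_success_curve` data frame: `b`, `success_rate`,
#'   `stderr`, `n_iter`, `seed`.
#' @examples
#' success_rate(c(0, 1), n_iter = 20, seed = 1)
#' @export
success_rate <- function(b_values, n_iter = 2000L,
                         params = model_params(),
                         stim = stimulus_protocol(sigma = 0.3,
                                                  mode = "additive_input"),
                         dt = 0.01, seed = 1L, readout_window = c(5, 7)) {
  if (n_iter < 1L) stop("success_rate: 'n_iter' must be >= 1", call. = FALSE)
  if (any(b_values < 0)) stop("success_rate: 'b_values' must be >= 0", call. = FALSE)
  rate <- numeric(length(b_values))
  for (i in seq_along(b_values)) {
    # negative-rate excursions are routine under strong noise; the
    # per-trial warnings are suppressed here
    flags <- suppressWarnings(vapply(seq_len(n_iter) - 1L, function(j)
      as.logical(single_trial(params, stim, b = b_values[i], dt = dt,
                              seed = seed + j,
                              readout_window = readout_window)),
      logical(1L)))
    rate[i] <- mean(flags)
  }
  out <- data.frame(b = b_values, success_rate = rate,
                    stderr = sqrt(rate * (1 - rate) / n_iter),
                    n_iter = n_iter, seed = seed)
  class(out) <- c("dwta_success_curve", "data.frame")
  out
}

#' Write a success curve as CSV (`b,success_rate,stderr,n_iter,seed`)
#'
#' @param curve A `dwta_success_curve`.
#' @param path Output path.
#' @export
write_success_curve <- function(curve, path) {
  stopifnot(inherits(curve, "dwta_success_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
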