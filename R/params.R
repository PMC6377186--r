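#' Model parameters for the delayed winner-take-all system
#'
#' Bundles all fixed constants of the two-population rate model: the
#' firing-rate time scale, the two self-inhibition delays, the constant
#' background inputs, the psychometric slope, the decision threshold and
#' the simulation horizon.
#'
#' The synaptic-weight time scale has no field on purpose: the weights are
#' assumed to equilibrate instantaneously (quasi-steady approximation), so
#' they are always the algebraic function [quasi_steady_weights()] of the
#' current rates and never carry their own dynamics here.
#'
#' @param tau_r Firing-rate time scale, seconds. Must be positive. The
#'   default 1.0 places the critical delay of the pure delayed-feedback
#'   limit at pi/2, which is bracketed by the subcritical (1.4 s) and
#'   supercritical (1.7 s) delays used throughout.
#' @param tau_1,tau_2 Self-inhibition delays of populations 1 and 2,
#'   seconds, nonnegative. All standard experiments use a common delay;
#'   the fields stay distinct for generality.
#' @param I_1,I_2 Constant background inputs, 1/s, nonnegative. Equal
#'   inputs make the resting system perfectly symmetric.
#' @param beta Psychometric slope of the evidence-accumulation logistic
#'   (dimensionless, nonnegative).
#' @param theta Decision threshold on the accumulated-evidence
#'   probability; must lie in (0.5, 1).
#' @param T Simulation horizon, seconds, positive.
#'
#' @return An object of class `dwta_params` (a validated list).
#' @seealso [stimulus_protocol()], [integrate_dde()]
#' @examples
#' p <- model_params(tau_1 = 1.7, tau_2 = 1.7)
#' p$tau_1
#' @export
model_params <- function(tau_r = 1.0, tau_1 = 1.4, tau_2 = 1.4,
                         I_1 = 0.4, I_2 = 0.4,
                         beta = 1.0, theta = 0.99, T = 8.0) {
  p <- list(tau_r = tau_r, tau_1 = tau_1, tau_2 = tau_2,
            I_1 = I_1, I_2 = I_2, beta = beta, theta = theta, T = T)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("model_params: '", nm, "' must be a single finite number", call. = FALSE)
  }
  if (p$tau_r <= 0) stop("model_params: 'tau_r' must be > 0", call. = FALSE)
  if (p$tau_1 < 0 || p$tau_2 < 0)
    stop("model_params: delays 'tau_1', 'tau_2' must be >= 0", call. = FALSE)
  if (p$I_1 < 0 || p$I_2 < 0)
    stop("model_params: inputs 'I_1', 'I_2' must be >= 0", call. = FALSE)
  if (p$beta < 0) stop("model_params: 'beta' must be >= 0", call. = FALSE)
  if (p$theta <= 0.5 || p$theta >= 1)
    stop("model_params: 'theta' must lie in (0.5, 1)", call. = FALSE)
  if (p$T <= 0) stop("model_params: 'T' must be > 0", call. = FALSE)
  structure(p, class = "dwta_params")
}

#' @export
print.dwta_params <- function(x, ...) {
  cat("Delayed WTA model parameters\n")
  cat(sprintf("  tau_r = %g s, delays tau_1 = %g s, tau_2 = %g s\n",
              x$tau_r, x$tau_1, x$tau_2))
  cat(sprintf("  inputs I_1 = %g, I_2 = %g [1/s]; beta = %g; theta = %g\n",
              x$I_1, x$I_2, x$beta, x$theta))
  cat(sprintf("  horizon T = %g s\n", x$T))
  invisible(x)
}

#' Stimulus protocol
#'
#' Describes the rectangular stimulus pulse applied to one population and
#' how it is injected into the system. Two conventions are supported:
#'
#' * `"clamped_history"`: the firing rates are *set* during the stimulus
#'   window (stimulated population at its resting value plus `sigma`, the
#'   other at its resting value) and free integration starts at the end of
#'   the window. This is the construction used for the deterministic
#'   figures and is the default.
#' * `"additive_input"`: `sigma` is added to the background input of the
#'   stimulated population during the window and integration starts at
#'   t = 0. This is the reading used for the stochastic experiments, where
#'   clamping would suppress the noise increments during the window.
#'
#' With `sigma = 0` the two modes produce identical dynamics.
#'
#' @param sigma Stimulus magnitude, 1/s, nonnegative.
#' @param t_on Stimulus onset, seconds, nonnegative. Clamped-history mode
#'   requires `t_on = 0` (the clamp replaces the initial segment).
#' @param t_max Stimulus duration, seconds, nonnegative.
#' @param mode `"clamped_history"` or `"additive_input"`.
#' @param target Stimulated population, 1 or 2.
#'
#' @return An object of class `dwta_stimulus`.
#' @examples
#' stimulus_protocol(sigma = 0.3)
#' @export
stimulus_protocol <- function(sigma = 0.3, t_on = 0, t_max = 0.5,
                              mode = c("clamped_history", "additive_input"),
                              target = 1L) {
  mode <- match.arg(mode)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop("stimulus_protocol: 'sigma' must be a single number >= 0", call. = FALSE)
  if (!is.numeric(t_on) || t_on < 0)
    stop("stimulus_protocol: 't_on' must be >= 0", call. = FALSE)
  if (!is.numeric(t_max) || t_max < 0)
    stop("stimulus_protocol: 't_max' must be >= 0", call. = FALSE)
  if (!target %in% c(1L, 2L))
    stop("stimulus_protocol: 'target' must be 1 or 2", call. = FALSE)
  if (mode == "clamped_history" && t_on != 0)
    stop("stimulus_protocol: clamped_history mode requires t_on = 0", call. = FALSE)
  structure(list(sigma = sigma, t_on = t_on, t_max = t_max,
                 mode = mode, target = as.integer(target)),
            class = "dwta_stimulus")
}

#' @export
print.dwta_stimulus <- function(x, ...) {
  cat(sprintf("Stimulus: sigma = %g [1/s] on [%g, %g] s, mode = %s, target = population %d\n",
              x$sigma, x$t_on, x$t_on + x$t_max, x$mode, x$target))
  invisible(x)
}

#' Read and write model configurations
#'
#' A configuration file is a flat JSON object holding the model-parameter
#' keys (`tau_r`, `tau_1`, `tau_2`, `I_1`, `I_2`, `beta`, `theta`, `T`)
#' and the stimulus keys (`sigma`, `t_on`, `t_max`, `mode`, `target`).
#' All model-parameter keys are required when present as a group; a
#' missing key is reported by name.
#'
#' @param params A `dwta_params` object.
#' @param stim A `dwta_stimulus` object.
#' @param path File path of the JSON configuration.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   `list(params = , stim = )`.
#' @export
write_config <- function(params, stim, path) {
  stopifnot(inherits(params, "dwta_params"), inherits(stim, "dwta_stimulus"))
  cfg <- c(unclass(params), unclass(stim))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  pkeys <- c("tau_r", "tau_1", "tau_2", "I_1", "I_2", "beta", "theta", "T")
  skeys <- c("sigma", "t_on", "t_max", "mode", "target")
  missing_p <- setdiff(pkeys, names(cfg))
  if (length(missing_p))
    stop("read_config: missing required key(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  missing_s <- setdiff(skeys, names(cfg))
  if (length(missing_s))
    stop("read_config: missing required key(s): ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  params <- do.call(model_params, cfg[pkeys])
  stim <- do.call(stimulus_protocol, cfg[skeys])
  list(params = params, stim = stim)
}
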