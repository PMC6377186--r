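# Hemodynamic forward model. The two decision populations are too close
# in space to be resolved by fMRI, so the measurable neural drive is the
# joint signal r_1 + r_2. The Balloon-Windkessel model maps a neural
# drive (deviation from baseline) through four hemodynamic states --
# vasodilatory signal s, inflow f, venous volume v, deoxyhemoglobin q --
# to a percent BOLD signal change:
#   s' = x - kappa s - gamma (f - 1)
#   f' = s
#   tau_0 v' = f - v^(1/alpha)
#   tau_0 q' = f E(f)/E_0 - v^(1/alpha) q / v,  E(f) = 1 - (1-E_0)^(1/f)
#   BOLD = 100 V_0 (k1 (1-q) + k2 (1 - q/v) + k3 (1 - v)),
#   k1 = 7 E_0, k2 = 2, k3 = 2 E_0 - 0.2.

#' Balloon-Windkessel hemodynamic parameters
#'
#' Standard constants of the Balloon-Windkessel family: signal decay
#' `kappa` (1/s), flow feedback `gamma` (1/s), mean transit time `tau_0`
#' (s), vessel stiffness exponent `alpha`, resting oxygen extraction
#' `E_0` and resting venous volume fraction `V_0`.
#'
#' @param kappa,gamma,tau_0 Strictly positive rates/times.
#' @param alpha Stiffness exponent in (0, 1].
#' @param E_0 Resting oxygen extraction fraction in (0, 1).
#' @param V_0 Resting venous blood volume fraction, positive.
#' @return An object of class `dwta_hemo`.
#' @export
hemo_params <- function(kappa = 0.65, gamma = 0.41, tau_0 = 0.98,
                        alpha = 0.32, E_0 = 0.34, V_0 = 0.02) {
  vals <- c(kappa = kappa, gamma = gamma, tau_0 = tau_0,
            alpha = alpha, E_0 = E_0, V_0 = V_0)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("hemo_params: all parameters must be strictly positive", call. = FALSE)
  if (alpha > 1) stop("hemo_params: 'alpha' must lie in (0, 1]", call. = FALSE)
  if (E_0 >= 1) stop("hemo_params: 'E_0' must lie in (0, 1)", call. = FALSE)
  structure(as.list(vals), class = "dwta_hemo")
}

#' Joint population signal
#'
#' The summed firing rate `r_1(t) + r_2(t)` on the trajectory grid: the
#' quantity a macroscopic recording sees when the two populations cannot
#' be spatially resolved. Antiphase oscillations partially cancel in this
#' sum, the mechanism behind the low-variance prediction for weak
#' (ambiguous) stimuli.
#'
#' @param traj A `dwta_trajectory`.
#' @return Numeric vector on `traj$t`.
#' @export
joint_signal <- function(traj) {
  stopifnot(inherits(traj, "dwta_trajectory"))
  traj$r_1 + traj$r_2
}

# Canonical double-gamma impulse response (unit-sum discretized kernel
# is NOT applied: the kernel is in 1/s units and convolved by dt).
.double_gamma <- function(t, peak = 6, under = 16, ratio = 1 / 6) {
  stats::dgamma(t, shape = peak, rate = 1) -
    ratio * stats::dgamma(t, shape = under, rate = 1)
}

#' Hemodynamic response to a neural drive
#'
#' Integrates the Balloon-Windkessel system driven by a neural time
#' series (deviation from baseline, uniform grid) with an explicit Euler
#' scheme on the same grid, then samples the percent-signal-change BOLD
#' series at the repetition time `TR`. A linear double-gamma convolution
#' mode is available as a cross-check (`method = "double_gamma"`).
#'
#' @param neural Numeric vector: neural drive on a uniform grid,
#'   baseline-subtracted so that rest maps to zero BOLD.
#' @param dt Grid step of `neural`, seconds.
#' @param hemo A [hemo_params()] object.
#' @param TR Sampling interval, seconds; must be (a numerical multiple
#'   of) `dt`. `NULL` returns only the full-grid series.
#' @param method `"balloon"` (default) or `"double_gamma"`.
#' @return A `dwta_bold` list: full-grid `t` and `bold`, plus `t_sample`
#'   and `bold_sample` when `TR` is given.
#' @examples
#' x <- c(rep(1, 50), rep(0, 950)) * 0.1
#' b <- hemodynamic_response(x, dt = 0.01, TR = 1)
#' @export
hemodynamic_response <- function(neural, dt, hemo = hemo_params(), TR = NULL,
                                 method = c("balloon", "double_gamma")) {
  method <- match.arg(method)
  if (!is.numeric(neural) || !length(neural))
    stop("hemodynamic_response: empty neural series", call. = FALSE)
  n <- length(neural)
  t <- (seq_len(n) - 1L) * dt
  if (method == "balloon") {
    kap <- hemo$kappa; gam <- hemo$gamma; tau0 <- hemo$tau_0
    alpha <- hemo$alpha; E0 <- hemo$E_0; V0 <- hemo$V_0
    k1 <- 7 * E0; k2 <- 2; k3 <- 2 * E0 - 0.2
    s <- 0; f <- 1; v <- 1; q <- 1
    bold <- numeric(n)
    ia <- 1 / alpha
    for (k in seq_len(n)) {
      bold[k] <- 100 * V0 * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
      Ef <- 1 - (1 - E0)^(1 / f)
      fv <- v^ia
      ds <- neural[k] - kap * s - gam * (f - 1)
      dfl <- s
      dv <- (f - fv) / tau0
      dq <- (f * Ef / E0 - fv * q / v) / tau0
      s <- s + dt * ds; f <- f + dt * dfl
      v <- v + dt * dv; q <- q + dt * dq
      if (!is.finite(s) || !is.finite(f) || !is.finite(v) || !is.finite(q) ||
          v <= 0 || f <= 0)
        stop("hemodynamic_response: non-finite or non-physical hemodynamic ",
             "state at t = ", signif(t[k], 6), " s", call. = FALSE)
    }
  } else {
    kern <- .double_gamma(t)
    conv <- stats::convolve(neural, rev(kern), type = "open")[seq_len(n)] * dt
    # scaled to percent change comparable with the balloon output
    bold <- 100 * hemo$V_0 * conv
  }
  out <- list(t = t, bold = bold, TR = TR, method = method)
  if (!is.null(TR)) {
    if (TR <= 0) stop("hemodynamic_response: 'TR' must be > 0", call. = FALSE)
    step <- round(TR / dt)
    if (abs(step * dt - TR) > 1e-6)
      stop("hemodynamic_response: 'TR' must be a multiple of dt", call. = FALSE)
    idx <- seq(1L, n, by = step)
    out$t_sample <- t[idx]
    out$bold_sample <- bold[idx]
  }
  structure(out, class = "dwta_bold")
}

#' @export
print.dwta_bold <- function(x, ...) {
  cat(sprintf("dwta_bold (%s): %d grid points, bold in [%.4g, %.4g] %%\n",
              x$method, length(x$t), min(x$bold), max(x$bold)))
  invisible(x)
}

#' Condition-wise BOLD variance of the joint signal
#'
#' Emulates the variance comparison of the fMRI validation: for each
#' stimulus condition (rest `sigma = 0`, weak `sigma = 0.3`, strong
#' `sigma = 1.0` by default, all at the supercritical delay), the
#' deterministic system is integrated, the joint signal deviation from
#' the resting baseline `2 r*` drives the hemodynamic model, and
#' post-stimulus BOLD samples are pooled over `n_trials` trials whose
#' inter-stimulus intervals are jittered uniformly in `isi`: each trial
#' contributes samples at multiples of `TR` between stimulus offset and
#' offset + ISI. Pooled samples are standardized jointly across all
#' conditions (zero mean, unit variance overall), and the per-condition
#' variance of the standardized samples is reported, mirroring the
#' within-subject normalization of the experiment.
#'
#' @param params A [model_params()] object; its delays are overridden by
#'   `tau` for both populations.
#' @param tau Common self-inhibition delay, seconds (supercritical 1.7
#'   by default).
#' @param sigmas Named vector of condition stimulus magnitudes.
#' @param stim_template Stimulus protocol whose `sigma` is replaced per
#'   condition.
#' @param n_trials Trials per condition (ISI jitter draws).
#' @param TR Sampling interval, seconds (scanner repetition time).
#' @param isi Two-element jitter window for the inter-stimulus interval.
#' @param hemo A [hemo_params()] object.
#' @param method Forward model passed to [hemodynamic_response()].
#' @param dt Solver step.
#' @param seed Seed for the ISI jitter.
#' @param history Constant pre-stimulus history passed to
#'   [integrate_dde()]; defaults to `params$I_1`.
#' @return A `dwta_condition_variances`: data frame `condition`,
#'   `n_samples`, `variance`, with attribute `ordering_weak_lt_strong`.
#' @examples
#' cv <- condition_variances(n_trials = 10, dt = 0.01, seed = 1)
#' cv
#' @export
condition_variances <- function(params = model_params(), tau = 1.7,
                                sigmas = c(rest = 0, weak = 0.3, strong = 1.0),
                                stim_template = stimulus_protocol(sigma = 0),
                                n_trials = 40L, TR = 1.76, isi = c(5, 7),
                                hemo = hemo_params(),
                                method = c("balloon", "double_gamma"),
                                dt = 1e-3, seed = 1L, history = NULL) {
  method <- match.arg(method)
  p <- model_params(tau_r = params$tau_r, tau_1 = tau, tau_2 = tau,
                    I_1 = params$I_1, I_2 = params$I_2,
                    beta = params$beta, theta = params$theta, T = params$T)
  baseline <- 2 * resting_fixed_point(p$I_1)$r_star
  offset <- stim_template$t_on + stim_template$t_max
  set.seed(seed)
  samples <- vector("list", length(sigmas))
  names(samples) <- names(sigmas)
  for (cond in names(sigmas)) {
    stim <- stim_template
    stim$sigma <- sigmas[[cond]]
    traj <- suppressWarnings(integrate_dde(p, stim, dt = dt,
                                           history = if (is.null(history))
                                             p$I_1 else history))
    drive <- joint_signal(traj) - baseline
    hr <- hemodynamic_response(drive, dt = dt, hemo = hemo, method = method)
    smp <- c()
    for (i in seq_len(n_trials)) {
      u <- stats::runif(1L, isi[1L], isi[2L])
      tt <- seq(offset + TR, offset + u, by = TR)
      tt <- tt[tt <= max(hr$t)]
      if (length(tt))
        smp <- c(smp, stats::approx(hr$t, hr$bold, tt)$y)
    }
    samples[[cond]] <- smp
  }
  pooled <- unlist(samples, use.names = FALSE)
  if (stats::sd(pooled) < 1e-12)
    stop("condition_variances: degenerate (zero-variance) pooled samples",
         call. = FALSE)
  mu <- mean(pooled); sdev <- stats::sd(pooled)
  out <- data.frame(
    condition = names(sigmas),
    sigma = as.numeric(sigmas),
    n_samples = vapply(samples, length, integer(1L)),
    variance = vapply(samples, function(x) stats::var((x - mu) / sdev),
                      numeric(1L)),
    row.names = NULL)
  ord <- if (all(c("weak", "strong") %in% out$condition))
    out$variance[out$condition == "weak"] <
      out$variance[out$condition == "strong"] else NA
  structure(out, ordering_weak_lt_strong = ord,
            class = c("dwta_condition_variances", "data.frame"))
}
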