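#' Hill transfer function
#'
#' The sigmoidal plasticity transfer function `f(x) = x^2 / (1 + x^2)`.
#' It is monotone nondecreasing on `x >= 0` and bounded in `[0, 1)`.
#' The formula is even in `x`, so negative arguments (which can arise
#' because the rate model does not rectify negative firing rates) map to
#' the same value as their absolute value.
#'
#' @param x Numeric vector.
#' @return `x^2 / (1 + x^2)`, elementwise.
#' @examples
#' hill(c(0, 1, 3))  # 0, 0.5, 0.9
#' @export
hill <- function(x) {
  x2 <- x * x
  x2 / (1 + x2)
}

#' Quasi-steady synaptic weights
#'
#' Under the quasi-steady approximation the two plastic weights relax
#' instantaneously to the same value, the Hill function of the product of
#' the two firing rates: `w_1 = w_2 = hill(r_1 * r_2)`. The result is
#' symmetric in its arguments and lies in `[0, 1)`.
#'
#' @param r_1,r_2 Firing rates (numeric, vectorized).
#' @return A list with components `w_1` and `w_2` (equal by construction).
#' @examples
#' quasi_steady_weights(0.4, 0.4)
#' @export
quasi_steady_weights <- function(r_1, r_2) {
  w <- hill(r_1 * r_2)
  list(w_1 = w, w_2 = w)
}

#' Right-hand side of the delayed two-population system
#'
#' Deterministic drift of the delayed winner-take-all model:
#' `tau_r * dr_1/dt = -r_1(t - tau_1) + w_2 * r_2(t) + input_1` and
#' symmetrically for population 2. The weights must already be the
#' quasi-steady weights of the *current* rates; `input_1`/`input_2`
#' include the stimulus when one is active.
#'
#' @param r Numeric length-2 vector of current rates `c(r_1, r_2)`.
#' @param r_delayed Numeric length-2 vector `c(r_1(t - tau_1), r_2(t - tau_2))`.
#' @param params A [model_params()] object (only `tau_r` is used).
#' @param input_1,input_2 Total instantaneous inputs to each population
#'   (background plus any active stimulus), 1/s.
#' @return Numeric length-2 vector of rate derivatives.
#' @examples
#' p <- model_params()
#' wta_rhs(c(0, 0), c(0, 0), p, 0.4, 0.4)  # c(0.4, 0.4)
#' @export
wta_rhs <- function(r, r_delayed, params, input_1, input_2) {
  if (!is.numeric(r) || length(r) != 2L || !is.numeric(r_delayed) ||
      length(r_delayed) != 2L)
    stop("wta_rhs: 'r' and 'r_delayed' must be numeric length-2 vectors",
         call. = FALSE)
  if (params$tau_r <= 0) stop("wta_rhs: tau_r must be > 0", call. = FALSE)
  w <- hill(r[1L] * r[2L])
  c(-r_delayed[1L] + w * r[2L] + input_1,
    -r_delayed[2L] + w * r[1L] + input_2) / params$tau_r
}

#' Symmetric resting fixed point
#'
#' On the symmetric manifold `r_1 = r_2 = r` with no stimulus and equal
#' inputs `I`, the resting state solves `r = hill(r^2) * r + I`,
#' equivalently `r / (1 + r^4) = I`. The left side increases from 0 to
#' its maximum at `r = (1/3)^(1/4)` and decreases thereafter, so for
#' `I` below that maximum there is a unique *lower* root, the
#' continuation of `r = I` from the uncoupled system; this is the resting
#' state used everywhere. The root is located by bracketing on
#' `[0, (1/3)^(1/4)]` and polished by Newton steps to a residual below
#' `1e-12`.
#'
#' @param I Background input, 1/s, nonnegative.
#' @return A list with `r_star` (resting rate) and `w_star`
#'   (`hill(r_star^2)`).
#' @examples
#' resting_fixed_point(0.4)
#' @export
resting_fixed_point <- function(I) {
  if (!is.numeric(I) || length(I) != 1L || !is.finite(I) || I < 0)
    stop("resting_fixed_point: 'I' must be a single number >= 0", call. = FALSE)
  if (I == 0) return(list(r_star = 0, w_star = 0))
  upper <- (1 / 3)^0.25          # argmax of r / (1 + r^4)
  g <- function(r) r / (1 + r^4) - I
  if (g(upper) < 0)
    stop("resting_fixed_point: no resting state exists for I = ", I,
         " (exceeds the fold at I = ", signif(upper / (1 + upper^4), 6), ")",
         call. = FALSE)
  r <- stats::uniroot(g, c(0, upper), tol = 1e-14)$root
  # Newton polish on the fixed-point residual r - hill(r^2) r - I
  for (i in 1:8) {
    res <- r - hill(r^2) * r - I  # equals r/(1+r^4) - I analytically
    dres <- (1 - 3 * r^4) / (1 + r^4)^2
    step <- res / dres
    r <- r - step
    if (abs(step) < 1e-15) break
  }
  if (abs(r - hill(r^2) * r - I) >= 1e-12)
    stop("resting_fixed_point: root finder did not converge", call. = FALSE)
  list(r_star = r, w_star = hill(r^2))
}
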