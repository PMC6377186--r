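---
title: "A delayed winner-take-all model of perceptual decision making"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A delayed winner-take-all model of perceptual decision making}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwta)
```

## The model

Two neuronal populations with firing rates $r_1(t)$, $r_2(t)$ excite each
other through plastic synapses and each inhibits itself with a
transmission delay. The rate dynamics is

$$
\tau_r \dot r_1(t) = -r_1(t-\tau_1) + w_2(t)\, r_2(t) + I_1(t) + \sigma(t),
\qquad
\tau_r \dot r_2(t) = -r_2(t-\tau_2) + w_1(t)\, r_1(t) + I_2(t),
$$

where $I_1 = I_2 = I$ is a constant background input, $\sigma(t)$ is a
rectangular stimulus pulse to population 1, and the synaptic weights relax
toward a Hill function of the product of the rates,
$\tau_w \dot w_i = -w_i + f(r_1 r_2)$ with $f(x) = x^2/(1+x^2)$. Because
$\tau_w \ll 1$, the weights are treated as instantaneously equilibrated
(quasi-steady approximation), $w_1 = w_2 = f(r_1 r_2)$; they therefore have
no state of their own anywhere in this package, and `model_params()`
deliberately has no weight-time-scale field.

Decisions are read from accumulated evidence,

$$
p_1(t) = \frac{1}{1 + e^{-\beta \int_0^t (r_1 - r_2)\,d\xi}},
\qquad p_2(t) = 1 - p_1(t),
$$

with a decision declared when either probability surpasses a threshold
$\theta = 0.99$. Decision *certainty* for a stimulus magnitude $\sigma$ and
slope $\beta$ is $c(\sigma,\beta) = \max_{t \in [0,T]} |p_1(t) - p_2(t)|$.

## Parameters, units and defaults

| parameter | meaning | unit | default | why |
|---|---|---|---|---|
| `tau_r` | rate relaxation time | s | 1.0 | see below |
| `tau_1`, `tau_2` | self-inhibition delays | s | 1.4 | subcritical reference; 1.7 is the supercritical reference |
| `I_1`, `I_2` | background input | 1/s | 0.4 | canonical resting drive |
| `beta` | psychometric slope | – | 1 | canonical value |
| `theta` | decision threshold | – | 0.99 | canonical value |
| `T` | horizon | s | 8 | analysis window; rates can turn negative later |
| `sigma` | stimulus magnitude | 1/s | 0.3 weak / 1.0 strong | canonical values |
| `t_max` | stimulus duration | s | 0.5 | typical visual-cue duration |

`tau_r` is nowhere given a number in the source material. We fix
`tau_r = 1.0` s: the pure delayed-feedback limit $x'(t) = -x(t-\tau)$ then
destabilizes at $\tau = \pi/2 \approx 1.571$ s, which is bracketed by the
stated subcritical (1.4 s) and supercritical (1.7 s) delays. This single
choice is made once and reused everywhere.

## Stimulus injection: two conventions

The stimulus can be injected two ways, and the distinction matters:

* **clamped history** (default for the deterministic figures): the rates
  are *prescribed* on $[0, t_{max}]$ — stimulated population at
  $I + \sigma$, the other at $I$ — and free integration starts at
  $t_{max}$. This is the literal construction used for the reference
  simulations.
* **additive input**: $\sigma$ is added to $I_1$ during the window and
  integration starts at $t=0$. This is the only convention compatible with
  noise increments during the window, so the stochastic experiment uses it.

With $\sigma = 0$ the two coincide exactly (a tested invariant).

The pre-stimulus history is constant at $I$ (0.4), the resting value used
by the original construction, although the true coupled fixed point is
slightly higher ($r^* \approx 0.41147$, the root of $r/(1+r^4) = I$ on the
ascending branch). Both are supported via the `history` argument; defaults
follow the literal construction.

## Numerical scheme

The deterministic integrator is classical RK4 under the method of steps:
delayed values are read from the already-computed solution through cubic
Hermite interpolation (using the stored drift), and from the constant (or
clamped) history before the free segment begins. Because the clamp and
stimulus edges propagate kinks through the solution, the *global* observed
order on the canonical scenarios is one (the step-halving ratio is ≈ 2, a
tested property); RK4 still buys a much smaller error constant than Euler
at the same step. Defaults: `dt = 1e-3` s deterministic (≥ 1400 points per
delay interval), `dt = 1e-2` s stochastic, matched to the readout
precision needed in the [5, 7] s window. The certainty maximum is taken
over the discrete grid; halving `dt` moves $c(0.3, 1)$ by less than
$10^{-4}$ (tested).

The stochastic path is Euler–Maruyama with linear delayed interpolation:
the increment of $r_i$ is $\text{drift}\cdot dt + (b/\tau_r)\sqrt{dt}\,z$,
because the noise enters the differential of $\tau_r r$. With `b = 0` the
stochastic path reproduces the deterministic Euler path bit-for-bit (a
tested invariant). Each trial seeds its own generator (`seed + trial`), so
trial sets are reproducible and embarrassingly parallel. The ensemble mean
of weakly noisy paths is only *approximately* the deterministic path (the
nonlinearity rectifies noise), which is why that check is run at small
`b = 0.1` where the $O(b^2)$ drift is inside the Monte-Carlo envelope.

Negative firing rates are never rectified — the model genuinely produces
them for some parameter/time combinations, which is also why all maxima
and readouts are restricted to $[0, 8]$ s. Integrators emit a classed
warning (`dwta_negative_rates`) when an excursion occurs;
`success_rate()` suppresses these per-trial warnings because they are
routine under strong noise.

## Stability analysis

About the symmetric fixed point, perturbations split into a symmetric mode
$u = \delta r_1 + \delta r_2$ and an antisymmetric mode
$v = \delta r_1 - \delta r_2$, each obeying
$\tau_r x'(t) = -x(t-\tau) + a_\pm x(t)$ with

$$
a_+ = w^* + 2 f'(x^*)\,x^*, \qquad a_- = -w^*, \qquad x^* = r^{*2},
$$

under the quasi-steady linearization (the plasticity chain-rule terms
cancel exactly in the antisymmetric mode). A frozen-weight variant
($a_\pm = \pm w^*$) is also exposed; with $w^* \approx 0.028$ the variants
differ little and both place the smallest critical delay strictly inside
(1.4, 1.7) s. The Hopf crossing of each scalar mode solves
$a = \cos\omega\tau$, $\tau_r\omega = \sin\omega\tau$; the implementation
scans $\omega \in (0, 4\pi/\tau_r]$ and refines with a bracketing root
finder to a characteristic residual below $10^{-10}$, while the tests
check it against the closed form
$\omega_c = \sqrt{1-a^2}/\tau_r$, $\tau_c = \arccos(a)/\omega_c$.

Numbers at the defaults: $r^* = 0.41147$, $w^* = 0.02787$,
$\tau_c^{sym} = 1.448$ s, $\tau_c^{anti} = 1.599$ s. "Supercritical" in
this package (and its sources) means *above the critical delay*, not the
bifurcation-theoretic criticality type, which is not computed.

The dynamic cross-check perturbs the fixed point antisymmetrically by
$10^{-3}$ and compares $|r_1 - r_2|$ amplitudes between an early and a
late window of a 30 s run; because that probe excites the antisymmetric
mode, its verdict is compared against that mode's own threshold. For the
canonical delays (0.5, 1.0, 1.4, 1.7, 2.0 s) both modes agree, so the
analytic min-mode verdict and the dynamic verdict coincide there (tested).

## What the experiments establish — and what they do not

**Regimes.** With the clamped 0.5 s stimulus: no ambivalence at
$\sigma=0.3, \tau=1.4$; at least one evidence crossing at
$\sigma=0.3, \tau=1.7$; no crossing and dominance of choice 1 at
$\sigma=1.0, \tau=1.7$. Ambivalence is operationalized as ≥ 1 strict sign
change of $p_1 - p_2$ after stimulus offset with a $10^{-10}$ dead-band
(an identically-zero difference has zero sign changes by convention).

**The threshold is unreachable within the horizon.** With $\beta = 1$ the
evidence integral reaches ≈ 1.07 by 8 s even for the strong stimulus, far
below $\ln(0.99/0.01) \approx 4.6$, so `decide()` returns `"none"` for
every canonical scenario; the strong-stimulus claim is about *dominance*
($p_1 > p_2$ throughout), which is what the acceptance test asserts. The
threshold rule itself is exercised on closed-form traces.

**Duration sweep.** The sweep defaults to additive injection: under the
clamped construction the supercritical oscillation outlasts every duration
on the 0.1–2.0 s grid within the 8 s horizon and the critical duration
would be undefined. Under additive injection ambivalence disappears from
1.6 s on (convergence-checked in `dt`), consistent with the qualitative
statement that only brief stimuli produce ambivalence, though not with the
printed 1.0–1.5 s boundary. We regard the exact boundary as sensitive to
unstated details (the value of $\tau_r$, injection convention, horizon).

**Noise experiment.** Success is the correct *sign* of $p_1 - p_2$ at a
readout time uniform in [5, 7] s — not the $\theta$ rule, under which most
noisy trials would never decide and chance would not be 0.5. Exact ties
(possible only when the integral is exactly zero) fall to a fair coin. At
$b = 1.0$, 2000 trials give a success rate statistically compatible with
the reference value 0.519 from 20 000 trials; the scheme and step of the
reference implementation are unknown, so agreement is asserted within
Monte-Carlo error, never bit-exactly.

**BOLD forward model.** The joint signal $r_1 + r_2$, minus its resting
baseline $2r^*$, drives a Balloon–Windkessel model (standard constants
$\kappa=0.65$, $\gamma=0.41$, $\tau_0=0.98$, $\alpha=0.32$, $E_0=0.34$,
$V_0=0.02$, all exposed via `hemo_params()`). Samples at TR = 1.76 s
between stimulus offset and a jittered 5–7 s ISI are pooled across trials,
standardized jointly across conditions, and compared: the weak-stimulus
variance is below the strong-stimulus variance, for the balloon model and
the double-gamma cross-check alike. The empirical variances reported from
real fMRI data (0.9148 / 0.9720) are *not* reproduced here — they require
the real recordings, which this package does not ingest.

**Antiphase cancellation is only partial.** The low-variance prediction is
often narrated as "antiphase oscillations cancel in the sum". In this
model at $\tau = 1.7$ the *symmetric* (in-phase) mode is itself unstable —
its critical delay (1.448 s) is smaller than the antisymmetric one's
(1.599 s) — so the joint signal oscillates too: over the final cycle of
the weak-stimulus scenario its variance is comparable to that of $r_1$
alone, not < 1% of it. The prediction that survives, and the one the tests
assert, is relative: the weak-stimulus joint signal varies far less than
the strong-stimulus one, before and after hemodynamic filtering.

## Degenerate inputs and edge conventions

* `sigma = 0` makes both injection modes identical and all evidence flat
  at 0.5; `beta = 0` flattens evidence regardless of the trajectory.
* `resting_fixed_point()` brackets on the ascending branch
  $[0, (1/3)^{1/4}]$ only: the residual $r/(1+r^4) - I$ has two roots
  below 2 for $I = 0.4$, so a naive wide bracket is ill-posed; above the
  fold ($I \gtrsim 0.57$) no resting state exists and an error is raised.
* `dt` must not exceed a nonzero delay (method of steps reads strictly
  past values); `tau = 0` falls back to the ODE limit.
* Decision crossing times are located by linear interpolation between
  grid points.

## Known limitations

* Pure-R integrators: a full 20 000-trial noise curve takes minutes, so
  shipped defaults are scaled down (2000 trials for the acceptance run);
  the trial-seed scheme makes larger runs embarrassingly parallel.
* No adaptive stepping, no distributed delays, no asymmetric-delay
  stability analysis, no Hopf normal form.
* The four-dimensional system with dynamic weights (finite $\tau_w$) is
  out of scope; all statements assume the quasi-steady limit.
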