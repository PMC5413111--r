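---
title: "Robust information propagation through noisy neural circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust information propagation through noisy neural circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popinfo)
```

## The model

A population of $n$ sensory neurons encodes a circular stimulus $s \in [0, 2\pi)$
through the tuning-curve-plus-noise model

$$\mathbf{x} = \mathbf{f}(s) + \boldsymbol{\xi}, \qquad
  \operatorname{Cov}[\boldsymbol{\xi}] = \Sigma_\xi(s),$$

and relays it through a feedforward layer

$$\mathbf{y} = g(W \mathbf{x} + \boldsymbol{\zeta}) + \boldsymbol{\eta},$$

with weights $W$, a pointwise gain $g$, noise $\boldsymbol{\zeta}$ inside the
nonlinearity and noise $\boldsymbol{\eta}$ outside it. Stimulus information is
quantified by the **linear Fisher information** — the inverse mean-squared
error of the locally optimal linear estimator:

$$I_x(s) = \mathbf{f}'(s)^\top \Sigma_\xi^{-1} \mathbf{f}'(s), \qquad
  I_y(s) = \mathbf{f}'(s)^\top \left[\Sigma_\xi +
  (W_{\mathrm{eff}}^\top \Sigma_{\mathrm{eff},\eta}^{-1}
  W_{\mathrm{eff}})^{-1}\right]^{-1} \mathbf{f}'(s),$$

in units of radian$^{-2}$. The package's central question is how the
*structure* of $\Sigma_\xi$, at fixed $I_x$, determines how much information
survives the relay — i.e. how robust the code is.

The derivative vector $\mathbf{f}'(s)$ is the *signal direction*: the
direction the mean population response moves for a small stimulus change.
Geometrically, a code is robust when the noise ellipse of $\Sigma_\xi$ is
elongated *along* the signal direction — added downstream noise then barely
increases the stimulus uncertainty. The extreme case,
$\Sigma_\xi \propto \mathbf{f}'\mathbf{f}'^\top$ (**differential
correlations**), minimizes the encoded information among trace-constrained
covariances (`minimum_information_covariance()`) yet maximizes robustness.
For a linear gain the full set of maximally robust covariances is the
one-parameter family implemented by `optimal_family()`:

$$\Sigma_\xi = \frac{\alpha I_\eta}{I_x}\,\Sigma_y +
  \frac{1-\alpha}{I_x}\,\mathbf{f}'\mathbf{f}'^\top,
  \qquad \Sigma_y = (W_{\mathrm{eff}}^\top \Sigma_\eta^{-1}
  W_{\mathrm{eff}})^{-1},
  \qquad I_\eta = \mathbf{f}'^\top \Sigma_y^{-1} \mathbf{f}',$$

every member of which transmits $I_y = I_x/(1 + I_x/I_\eta)$ — the
`optimal_output()` bound. $\alpha = 0$ is differential correlations;
$\alpha = 1$ is the "matched" covariance proportional to the effective
downstream covariance. `verify_optimal_family()` checks this invariance
numerically (relative spread below $10^{-8}$) every time it is called.

## Tuning populations and their parameters

Heterogeneous populations use Von Mises tuning curves
$f_i(s) = \rho_i + \upsilon_i \exp\{\beta_i(\cos(s - \phi_i) - 1)\}$ with
parameters drawn independently and uniformly from

| parameter | meaning | default range |
|---|---|---|
| $\upsilon$ | amplitude above baseline (rate units) | $[1, 51]$ |
| $\beta$ | width (dimensionless; larger = narrower) | $[1, 6]$ |
| $\phi$ | preferred stimulus (radians) | $[0, 2\pi)$ |
| $\rho$ | baseline rate | $[0, 1]$ |

Stimuli are always in radians; $\phi$ is sampled on the half-open interval
(immaterial for a continuous distribution). The analytic derivative is used
everywhere — the information formulas are sensitive to $\mathbf{f}'$
accuracy — and finite differences appear only as a test oracle. Every
sampler takes an explicit seed; there is no hidden global default.

## The paired-covariance construction

The linear-channel experiments (`run_noise_sweep()`,
`run_synergistic_sweep()`) compare two codes with *identical tuning curves
and identical per-stimulus input information*:

* **aligned**: $\Sigma_\xi = \Sigma_0 + \epsilon\,
  \mathbf{f}'\mathbf{f}'^\top$ with $\Sigma_0 = \mathrm{diag}(\mathbf{f}(s))$
  the Poisson-like base (unit Fano factors) and $\epsilon = 10^{-3}$ by
  default;
* **tilted**: $\Sigma_\xi = \Sigma_0 + \epsilon_u(s)\, \mathbf{u}\mathbf{u}^\top$
  where $\mathbf{u}(s)$ has the same norm as $\mathbf{f}'(s)$ but makes an
  angle $\theta_u$ (default $1/8$ radian) with it, and $\epsilon_u(s)$ is the
  closed-form solution of the information-matching equation
  (`epsilon_match()`).

Three design choices here were genuinely open:

* **Tilt plane.** Rotating $\mathbf{u}$ away from $\mathbf{f}'$ leaves an
  $(n-2)$-dimensional freedom. We rotate within the plane spanned by
  $\mathbf{f}'$ and one fixed random auxiliary vector (drawn once per
  experiment and orthogonalized against $\mathbf{f}'(s)$ at each stimulus).
  This makes $\mathbf{u}(s)$ reproducible and continuous in $s$. Note that
  the *population statistics* of the tilted code — in particular the mean of
  the matched strengths $\epsilon_u(s)$, which behaves like
  $\epsilon / (\cos^2\theta_u - \epsilon \sin^2\theta_u\, w_2(s))$ with
  $w_2 = |\mathbf{f}'|^2\, \hat{\mathbf{v}}^\top \Sigma_0^{-1}
  \hat{\mathbf{v}}$ — are heavy-tailed in the tilt-plane draw, so
  $\langle\epsilon_u\rangle$ varies several-fold across seeds. The Fano
  factors are far more stable and are the quantities the acceptance script
  reports.
* **Feasibility.** Not every population draw admits the construction: the
  aligned covariance is indefinite whenever $\epsilon\, I_0(s) \le -1$
  (possible in the synergistic configuration $\epsilon = -5\times10^{-4}$
  whenever $I_0 > 2000$), and the matching equation can lack a
  positive-semi-definite solution when the weighted tilt is too large.
  Draws that are infeasible at any grid stimulus are rejected and redrawn;
  the experiments therefore condition on feasibility, as any single
  published realization of this construction implicitly does.
* **Correlation matching.** So that robustness differences cannot be
  attributed to different overall correlation levels, populations are
  redrawn until the two codes' population-averaged correlations agree to
  within $10^{-5}$ (budget $10^4$ draws). No tolerance is inherent to the
  problem; $10^{-5}$ matches the scale at which the averages themselves sit
  (both are near zero, order $10^{-4}$).

Stimulus averages are unweighted means over an equally spaced grid: 100
points for the linear-channel sweeps, 20 for the spiking sweeps.

## The spiking channel

The dichotomized-Gaussian layer binarizes its input:
$y_i = 1\{x_i + \zeta_i \ge \theta_i\}$, with thresholds at 3/4 of each
cell's peak height, $\theta_i = 0.75(\rho_i + \upsilon_i)$, so both active
and silent cells always exist. Its mean response is
$\mu_i(s) = \Phi\big((f_i(s) - \theta_i)/\sigma_i(s)\big)$ with
$\sigma_i^2 = (\Sigma_\xi)_{ii} + \sigma_\zeta^2$, which is smooth even
though the gain is a step.

For the sweeps in `run_dg_sweep()` the first-layer covariance is
$\Sigma_\xi = \gamma_u(\Sigma_0 + \epsilon_u \mathbf{u}\mathbf{u}^\top)$
with the scale $\gamma_u$ (`gamma_u_normalization()`) chosen so the input
information equals a fixed target at every $(\epsilon_u, \mathbf{u})$ — we
take the target to be $I_0(s)$, the information of the unperturbed
Poisson-like code, so that $\gamma_u \to 1$ as $\epsilon_u \to 0$. (The
scale multiplies the *whole* perturbed matrix: only then does the
Sherman–Morrison inverse give the target information exactly.)

Output information for the spiking layer has no closed form, so
`mc_fisher()` estimates $I_y = \boldsymbol{\mu}'^\top
\operatorname{Cov}(\mathbf{y}|s)^{-1} \boldsymbol{\mu}'$ with:

* $\boldsymbol{\mu}'(s)$ by central finite differences of the analytic mean
  with step $\Delta s = 10^{-4}$ radians, re-evaluating $\gamma_u$,
  $\mathbf{u}$ and the marginal variances at $s \pm \Delta s$ (analytic
  differentiation through $\gamma_u(s)$ is brittle);
* the covariance from Monte Carlo draws (default $10^6$; the test profile
  uses $n = 30$ neurons and $10^5$ draws so the suite finishes in minutes);
  sampling uses the exact structured decomposition $\mathbf{x} = \mathbf{f} +
  \sqrt{\gamma}\,\Sigma_0^{1/2}\mathbf{z} + \sqrt{\epsilon}\,\mathbf{u}\,w$
  when $\epsilon \ge 0$, and a dense PSD factorization otherwise;
* **support restriction**: binary neurons that deviate from their modal
  response on fewer than `min_events` (default 16) draws are excluded before
  inverting. Their true contribution $\mu_i'^2/(\mu_i(1-\mu_i))$ vanishes as
  $\mu_i \to 0$ or $1$, but their *estimated* variances are so unreliable
  that inverting them produces information estimates orders of magnitude
  above the data-processing bound. The batch-based standard error
  additionally requires a column to be non-degenerate within every batch.
  If *every* neuron is degenerate at a stimulus, the estimate is zero — the
  observable responses carry no measurable information there;
* a diagonal ridge of $10^{-9} \times$ the mean variance, applied only if the
  restricted covariance is still numerically singular (and logged).

The Monte Carlo standard error is estimated from 5 batches of draws;
stimulus-averaged values report the quadrature-combined error.

Nonlinear gains in the *analytic* channel are handled by linearization:
effective weights $W_{\mathrm{eff}} = \bar G' W$, where $\bar g'(h_i)$ is
the Gaussian-smoothed average slope (closed form for linear and step gains,
Gauss–Hermite quadrature for other differentiable gains), plus the excess
covariance $\delta\Sigma_g = \operatorname{Cov}[g(\mathbf{h} +
\boldsymbol{\chi})] - \bar G' \Sigma_\chi \bar G'$ estimated by Monte Carlo.
$\delta\Sigma_g$ vanishes identically for linear gains and is positive
semi-definite under Gaussian input noise, so it acts as an extra effective
noise source.

## Numerical choices

* Linear systems are solved by symmetric Cholesky factorization; explicit
  inverses appear only where the inverse matrix itself is the contract
  (`rank1_inverse()`).
* Positive semi-definiteness is accepted when the minimum eigenvalue is at
  least $-10^{-10}$ times the spectral norm, after symmetrizing
  $(\Sigma + \Sigma^\top)/2$.
* `linear_fisher()` switches to the support-restricted Moore–Penrose
  pseudo-inverse when the relative condition number exceeds $10^{12}$
  (with a warning); a signal component outside the support of a singular
  covariance would mean unbounded information and is an error. Pure
  differential correlations are the motivating singular limit.
* Inadmissible `optimal_family()` parameters are reported together with the
  admissible-interval endpoint found by bisection.

## What the synthetic generator does and does not emulate

All data are generated internally; there is no measured-data path. The
generator reproduces the study conditions: heterogeneous Von Mises tuning,
Poisson-like single-neuron variability (Fano factors near 1), weak
structured correlations (population averages of order $10^{-4}$), and
binary spiking through a threshold. It does *not* emulate temporal spike
trains, stimulus-dependent tuning adaptation, non-Gaussian first-layer
noise, or realistic (sparse, divergent) anatomical connectivity — the
identity-weight channel is the deliberately simplest case, and the
framework accepts arbitrary `W` where needed. Passing tests therefore
demonstrate the mathematical claims about covariance structure and
robustness, not a fit to any recorded dataset.

## Problem sizes used by the test suite

The shipped tests run the linear-channel pipelines at full scale
($n = 100$ neurons, 100 stimuli — they are analytic and fast) and the
spiking sweeps at a reduced profile ($n = 30$, $10^5$ Monte Carlo draws, 20
stimuli, 8 values of $\epsilon_u$, tilt angles $\{0, 0.1\}$, pre-threshold
noise variances $\{0, 1\}$). The stochastic printed-number checks average
12 population seeds. The full-scale spiking profile ($n = 100$, $10^6$
draws) is available through the configuration system and the command-line
wrapper in `inst/cli/popinfo.R`.

## Known limitations

* $\langle\epsilon_u\rangle$ of the tilted redundant code is heavy-tailed
  across tilt-plane and population draws (see above); treat its seed mean as
  indicative only. The Fano factors are the stable summaries.
* Monte Carlo information estimates are mildly biased upward at small
  draw counts (inverting a noisy covariance); qualitative orderings are
  asserted within 2 standard errors, never pointwise curve values.
* Only the $\Omega \to \infty$ members of the optimal family are
  constructed; the projection term that adds noise orthogonal to the signal
  direction changes no information quantity.
* Shannon mutual information, recurrent dynamics, and bias-corrected
  information estimation from finite trial counts are out of scope.
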