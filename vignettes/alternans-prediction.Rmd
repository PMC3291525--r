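---
title: "Eigenmodes, transfer functions and the prediction of APD alternans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eigenmodes, transfer functions and the prediction of APD alternans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochpace)
```

## The problem

Action potential duration (APD) alternans — a beat-to-beat long–short
alternation of the cardiac action potential — is a period-doubling
instability of the paced heart cell and a recognised precursor of reentrant
arrhythmias. Classical theory predicts alternans from the slope of the APD
restitution function (APD as a function of the preceding diastolic
interval, DI), but restitution slopes are unreliable markers as soon as the
cell carries *memory*: dependence of APD on more than the immediately
preceding DI.

`stochpace` implements a unified treatment. A paced cell is a discrete-time
dynamical system: the state vector **v** at one stimulus onset is mapped to
the state at the next. Linearised about the period-1 steady state at basic
cycle length (BCL) *B*,

$$\delta \mathbf v_{i+1} = \mathbf J\,\delta \mathbf v_i +
  \mathbf v'\,\delta t_i, \qquad
  \delta a_i = \mathbf a^\top \delta \mathbf v_i,$$

where $\mathbf J$ is the beat-to-beat Jacobian, $\mathbf v'$ the
sensitivity of the next state to the length $t_i$ of the current pacing
cycle, and $\mathbf a$ the sensitivity of the APD $a_i$ to the state. The
response is stable while all eigenvalues of $\mathbf J$ lie inside the unit
circle; the eigenvalue closest to $-1$, written $\lambda_{\mathrm{alt}}$,
governs alternans and reaches $-1$ exactly at the onset. The eigenvalue
closest to $+1$, $\lambda_{\mathrm{mem}}$, sets the rate-accommodation
(memory) time constant $\tau = -1/\ln|\lambda_{\mathrm{mem}}|$ beats.

In the $z$-domain the same linearisation is the strictly proper rational
transfer function from cycle-length deviations to APD deviations,

$$H_{t\to a}(z) = \mathbf a^\top (z\mathbf I - \mathbf J)^{-1}\mathbf v'
  = \frac{P_n(z)}{P_d(z)},$$

whose poles are the eigenvalues of $\mathbf J$; because every cycle splits
exactly into APD and DI ($t_i = a_i + d_i$), the DI transfer function is
$H_{t\to d} = 1 - H_{t\to a}$. The classical slopes are marginal values of
$H_{t\to a}$: the S1S2 slope is the one-beat gain
$S_{S1S2} = \mathbf a^\top \mathbf v'$ (the leading numerator coefficient),
and the dynamic slope is the steady-state ratio
$S_{\mathrm{dyn}} = H_{t\to a}(1) / H_{t\to d}(1)$. For the memoryless map
$a_{n+1} = f(d_n)$ with slope $\alpha$ these reduce to
$H_{t\to a} = \alpha/(z+\alpha)$, $H_{t\to d} = z/(z+\alpha)$ and
$S_{S1S2} = S_{\mathrm{dyn}} = \alpha$, so the three classical alternans
criteria coincide; memory is precisely any departure from this first-order
behaviour.

The practical half of the framework removes the need to access internal
state variables: pace at cycle lengths drawn from a Gaussian around the
BCL, record $(t_i, a_i)$, and fit the input–output memory model

$$\delta a_n = -\sum_{i=1}^{M} \alpha_i\, \delta a_{n-i}
             + \sum_{i=1}^{M} \beta_i\, \delta t_{n-i}$$

by least squares. This is an ARMA relation whose transfer function
$(\beta_1 z^{M-1} + \dots + \beta_M)/(z^M + \alpha_1 z^{M-1} + \dots +
\alpha_M)$ estimates $H_{t\to a}$; its pole closest to $-1$ estimates
$\lambda_{\mathrm{alt}}$ from measurable quantities only. Tracking that
pole in sliding windows while the pacing rate ramps down (or a model
parameter drifts, mimicking drug wash-in) and extrapolating its course to
$-1$ predicts the onset of alternans before it is visible.

### Sign conventions

The denominator is the monic polynomial
$z^M + \alpha_1 z^{M-1} + \dots + \alpha_M$, so for the memoryless map
$\alpha_1 = +\alpha$, $\beta_1 = \alpha$ and the pole is $-\alpha$. Some
texts write the memoryless case with $\alpha_1 = -\alpha$; the convention
used here is the one under which the worked-example coefficients
$(\alpha_1, \alpha_2, \alpha_3) = (-0.2329, -0.7401, 0.0395)$ reproduce
the reference poles $(-0.780, 0.053, 0.961)$ of that worked identification.

## The surrogate cell models

Analyses run on pluggable beat-to-beat models (`cell_model()`); three
surrogates cover the three classes of alternans mechanism, each calibrated
once so that its period-doubling bifurcation lies inside BCL 200–600 ms.

**`map1d`** — the memoryless restitution map
$a_{n+1} = f(d_n) = a_{\max} - A e^{-d_n/\tau_f}$ (defaults
$a_{\max} = 300$ ms, $A = 150$ ms, $\tau_f = 100$ ms). One state variable;
$\lambda_{\mathrm{alt}} = -f'(d^\ast)$ analytically, onset at
$B^\ast = a_{\max} - \tau_f + \tau_f \ln(A/\tau_f) \approx 240.5$ ms. Its
closed forms are the oracles for most unit tests.

**`camap2d`** — a two-variable map coupling APD to the sarcoplasmic
reticulum (SR) calcium load $l$: release
$r_{n+1} = l_n\, q(l_n)\, s(d_n)$ with a sigmoidal load dependence
$q(l) = 1/(1+e^{-(l-l_c)/k_l})$ and release restitution
$s(d) = 1 - \kappa e^{-d/\tau_r}$; uptake refills toward $l_{\max}$ with
time constant $\tau_{\mathrm{up}}$; APD $a_{n+1} = f(d_n) + \gamma r_{n+1}$
with a shallow $f$ ($\tau_f = 300$ ms). $\gamma > 0$ is positive,
$\gamma < 0$ negative calcium-to-APD coupling (default $|\gamma| = 30$ ms
per release unit). Defaults $l_{\max} = 2$, $l_c = 1.35$, $k_l = 0.08$,
$\kappa = 0.8$, $\tau_r = 80$ ms, $\tau_{\mathrm{up}} = 400$ ms place the
bifurcation near BCL 414 ms for both coupling signs; the steep release–load
relation, not the restitution slope, drives the instability. In this
simplified map the transfer-function zero $z_{td1}$ crosses $-1$ (the
$-2\pi$ phase signature of $H_{t\to a}$ at $f = 0.5$) for $\gamma = +30$,
while $\gamma = -30$ shows the monotonically rising DI gain; the
*phenomena* of the two calcium-coupled regimes are both present, but their
assignment to the sign of $\gamma$ is a property of this map, not a general
rule.

**`ms_ode`** — a minimal two-current ionic model (Mitchell–Schaeffer form),
$\dot v = h v^2(1-v)/\tau_{\mathrm{in}} - v/\tau_{\mathrm{out}} +
J_{\mathrm{stim}}(t)$, with a recovery gate $h$ opening below and closing
above $v_{\mathrm{gate}}$. The gate switch is smoothed by a logistic blend
of width $k_{\mathrm{gate}} = 0.005$: with a hard switch the one-beat map
is non-differentiable at the scale of the finite-difference perturbations
and Jacobian columns become erratic; the smoothed model is the model. Time
is in ms ($\tau_{\mathrm{in}} = 0.3$, $\tau_{\mathrm{out}} = 6$,
$\tau_{\mathrm{open}} = 80$, $\tau_{\mathrm{close}} = 150$), integrated by
forward Euler at $\mathrm{d}t = 0.02$ ms in compiled code; APD is measured
between threshold crossings ($v = 0.5$ up, $v = 0.05$ down) located by
linear interpolation. The stimulus is a 1-ms pulse at 6× the diastolic
threshold found by bisection from rest: in this model the effective
threshold at short cycles is several-fold the rest threshold, and a smaller
margin loses capture well before the bifurcation (near BCL 292 ms, with 2:1
block a few ms below it — the steep-restitution, voltage-driven regime).

**`linear2d`** — an affine two-variable diagnostic map used by the test
suite: the finite-difference Jacobian must recover its matrix exactly.

## Numerical choices

* **Steady state** (`settle()`): relative beat-to-beat variation of every
  state variable below $10^{-7}$ (default), up to 1000 beats. A period-2
  regime is reported as a classed condition carrying both alternating
  states; it requires the $i$ vs $i-2$ criterion, an alternation amplitude
  above $10^3 \times$ the tolerance, *and* amplitude persistence over a
  200-beat lookback — a slowly decaying alternation near threshold
  satisfies the first two transiently.
* **Bifurcation search** (`find_bifurcation()`): bisection to 1 ms. Within
  ~1 ms of the onset $|\lambda_{\mathrm{alt}}|$ is so close to 1 that
  neither settling criterion resolves within the beat budget; the
  classifier then falls back to the growth/decay trend of the APD
  difference series over the final beats.
* **Finite differences** (`beat_jacobian()`): central, per-element
  perturbation $\max(10^{-6}|v_c|, 10^{-9})$, one automatic tenfold
  reduction on capture failure. For `ms_ode` the cycle-length perturbation
  is snapped to a whole number of integration steps (the cycle length is
  quantized to the step), and $\mathbf v'$ is preferentially evaluated from
  the model right-hand side at the settled state.
* **Transfer-function numerator**: from the determinant identity
  $\det(z\mathbf I - \mathbf J + \mathbf v'\mathbf a^\top) =
  P_d(z)(1 + H(z))$, validated against direct evaluation of
  $\mathbf a^\top(z\mathbf I-\mathbf J)^{-1}\mathbf v'$ at 16 points
  (relative error $<10^{-8}$), with a sample-interpolation fallback for
  defective Jacobians; the object records which path was used.
* **ARMA fit** (`fit_arma()`): QR least squares on mean-removed (or
  linearly detrended) deviations; requires at least $10M$ cycles and
  non-zero cycle-length variance; the condition number is reported.
* **Alternans detection** (`detect_alternans()`): sustained alternans =
  strict sign alternation of $\Delta$APD for ≥ 20 beats with
  $|\Delta\mathrm{APD}| \ge 1$ ms; micro-alternans uses 0.05 ms. The
  reference work states no numeric criterion; these are package defaults.
* **Step-decay fit** (`lambda_from_step_decay()`): log-linear fit of
  $|\Delta\mathrm{APD}|$ over the first strictly alternating run above
  $\max(0.1, 3\sigma_{\mathrm{noise}})$ ms, skipping the first post-step
  beats where the memory-mode shift dominates.

## What the synthetic protocols emulate — and what they do not

The stochastic-pacing generator (`gaussian_cl_series()`) draws i.i.d.
Gaussian cycle lengths (default SD 5 ms at stationary regimes, 1 ms on
ramps), redrawing draws below $B - 4\,\mathrm{SD}$ or leaving less than a
minimum expected DI. Ramps decrease the cycle length by 0.1 ms/beat;
simulated drug application scales one model parameter at 0.2 %/s (the
Fig-7-style experiments in the acceptance suite drift
$\tau_{\mathrm{open}}$ at 0.5 %/s so the crossing falls inside a
320-beat record). Windowed tracking uses 30-beat windows stepped by 15
(150/75 when APD measurement noise is present), a 2nd-order model inside
windows, and regression of the tracked eigenvalue on window-mean BCL (or
window-centre beat for drift protocols) restricted to values above
$-0.85$.

Two places where the surrogates differ from a stiff ionic model matter for
interpretation:

* **Seeding of the unstable mode.** A bit-exact iterated map paced by an
  exactly linear ramp receives *no* perturbation at the alternans
  frequency: past the bifurcation the period-2 mode grows from
  double-precision rounding only, and measurable micro-alternans appears
  hundreds of beats after $\lambda_{\mathrm{alt}}$ crosses $-1$ (measured:
  alternation still $<10^{-4}$ ms 160 beats past onset). Reference
  integrators carry intrinsic stimulus-timing jitter of order half the
  integration step, which seeds the mode continuously. The "noise-free"
  control ramps used by the onset-coincidence checks therefore carry 0.01
  ms of cycle-length jitter — the stimulus-timing quantization scale, two
  orders of magnitude below the stochastic-pacing SD — and with that seed
  the micro-alternans onset coincides with the tracked eigenvalue crossing
  within one window. Passing these checks therefore shows that the tracked
  pole crosses $-1$ at the true instability, not that a strictly
  deterministic system displays alternans the same beat it becomes
  unstable.
* **Step-transient cleanliness.** The surrogates' post-step transients are
  dominated by a single eigenmode, so a large BCL step yields an
  artificially easy exponential fit. The time-domain-versus-ARMA comparison
  is run at the experimentally faithful small-step limit (1 ms step, 0.1 ms
  APD noise), where the log-linear fit starves for usable beats while ARMA
  identification, with persistent excitation, does not.

APD measurement error is modelled as additive i.i.d. Gaussian noise on APD
with DI recomputed to preserve $t = a + d$; real measurement error is
neither white nor APD-confined, and intrinsic (channel-gating) APD
variability is absent from all surrogates.

## Problem sizes

Stationary identification uses 100-beat records (512 for DFT
cross-checks); ramps 300–1300 beats; replicate studies 5–30 runs. The
bisection budget is 4000 beats per classification (30000 for the maps when
an eigenvalue is evaluated at the onset itself, where convergence is
$O(|\lambda|^n)$ with $|\lambda| \approx 1$). These sizes resolve every
tested quantity to well inside its assertion tolerance; all are arguments,
so larger studies are one keystroke away.

## Known limitations

* Single cell only: no electrotonic coupling, conduction-velocity
  restitution, or spatially discordant alternans.
* The ARMA estimator is input–output least squares, not innovations-form
  maximum likelihood; order selection is user-set (2–3 suffice for the
  built-in models), not automatic.
* $S_{\mathrm{dyn}}$ from ARMA coefficients is flagged low-confidence: it
  is the $f = 0$ limit of the transfer function, which short stochastic
  records pin down poorly.
* Calcium-transient outputs are not exposed; the transfer-function
  machinery would apply unchanged to any additional per-beat output
  channel.
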