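# stochpace

Predicting cardiac **APD alternans** from stochastic pacing.

Alternans — beat-to-beat long–short alternation of the action potential
duration (APD) — is a period-doubling instability of the paced heart cell
and a precursor of reentrant arrhythmias. The classical predictors, the
S1S2 and dynamic restitution slopes, fail whenever the cell has *memory*
(APD depends on more than the preceding diastolic interval). `stochpace`
implements the frequency-domain alternative for electrophysiologists and
modellers:

* **Eigenmode analysis.** The stimulus-to-stimulus map of a paced cell is
  linearised numerically: Jacobian **J**, APD-sensitivity vector **a**,
  cycle-length-sensitivity vector **v**′. The eigenvalue of **J** closest
  to −1 (λ_alt) governs alternans — onset occurs exactly at λ_alt = −1 —
  and the eigenvalue closest to +1 (λ_mem) sets the memory time constant
  τ = −1/ln|λ_mem| beats.
* **Transfer functions.** H_t→a(z) = **a**ᵀ(z**I** − **J**)⁻¹**v**′ and its
  complement H_t→d = 1 − H_t→a as rational functions with poles equal to
  the eigenvalues of **J**; gain/phase responses over the per-beat
  frequency axis f ∈ [0, 0.5] (f = 0.5 beat⁻¹ is the alternans frequency);
  classical slopes recovered as S_S1S2 = **a**ᵀ**v**′ and
  S_dyn = H_t→a(1)/H_t→d(1).
* **ARMA identification during stochastic pacing.** Pace at cycle lengths
  drawn from a Gaussian around the basic cycle length, then fit
  δa_n = −Σ αᵢ δa_{n−i} + Σ βᵢ δt_{n−i} by least squares. The pole of
  (β₁z^{M−1}+…+β_M)/(z^M+α₁z^{M−1}+…+α_M) closest to −1 estimates λ_alt
  from measurable quantities only — no access to internal model variables.
  A nonparametric DFT ratio estimate is included as a cross-check.
* **Protocols.** Dynamic and S1S2 restitution, memory amplitude, alternans
  detection, bisection for the bifurcation BCL, BCL ramps, simulated drug
  application (slow parameter drift), windowed λ_alt tracking, and onset
  prediction by extrapolating λ_alt to −1.
* **Surrogate cell models.** A memoryless restitution map (`map1d`), a
  calcium-coupled two-variable map with either sign of Ca→APD coupling
  (`camap2d`), and a minimal two-current ionic model integrated in
  compiled code (`ms_ode`) — three different alternans mechanisms, each
  with a bifurcation between BCL 200 and 600 ms. Models are pluggable:
  anything that advances a state vector one pacing cycle and reports
  APD/DI fits the interface.

Everything is tibble-first: beat series, restitution curves and tracking
results are tibbles; fitted objects have `tidy()`/`glance()` methods and
`autoplot()` produces Bode, restitution and tracking plots.

## Worked example

Eigenmode analysis of the calcium-coupled map near its bifurcation, then
the same eigenvalue recovered blindly from 100 stochastically paced beats:

```r
library(stochpace)

model  <- cell_model("camap2d", gamma = 30)
steady <- settle(model, bcl = 430)
eigen_summary(jacobian_pack(model, 430, v_ss = steady$state))
#> Eigen summary (BCL 430.0 ms)
#>   eigenvalues: -0.9242+0.0000i, -0.2398+0.0000i
#>   lambda_alt = -0.9242+0.0000i  lambda_mem = -0.2398+0.0000i

cls    <- gaussian_cl_series(430, sd = 5, n = 100, seed = 1,
                             apd_ref = steady$apd_ms)
series <- run_beats(model, cls, state0 = steady$state)$series
glance(fit_arma(series, order = 3))
#> # A tibble: 1 x 8
#>   order n_cycles resid_var_fraction lambda_alt_re lambda_alt_im s_s1s2 s_dyn ...
#> 1     3      100           0.000281        -0.921      3.88e-26  0.309 0.394

find_bifurcation(model, c(390, 500))
#> [1] 414.0625
```

Reading: at BCL 430 ms the true alternans eigenvalue is −0.924; the
3rd-order ARMA fit to 100 noisy-pacing beats estimates −0.921 while
explaining 99.97 % of the APD variance (residual fraction 2.8 × 10⁻⁴), and
bisection confirms the instability (λ_alt = −1) at BCL ≈ 414 ms. Tracking
`windowed_lambda()` estimates along a ramp and extrapolating with
`extrapolate_onset()` predicts that onset before alternans is visible.

The methods vignette (`vignettes/alternans-prediction.Rmd`) documents the
model equations, parameter defaults with units, numerical tolerances, and
the design decisions behind the protocols.

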