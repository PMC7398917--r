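# cpmgrd

`cpmgrd` is an R package for analysing ¹⁵N Carr–Purcell–Meiboom–Gill (CPMG)
relaxation-dispersion experiments on proteins undergoing microsecond–millisecond
two-state conformational exchange, of the kind used to characterise the
dynamics of phosphotyrosine-binding SH2 domains. It takes per-residue peak
intensities, spin-relaxation parameters and chemical shifts as delimited text
tables and carries them through to minor-state populations, exchange rates and
a free-energy landscape, with a synthetic-data generator that emulates the
whole acquisition design so every stage is testable offline.

## What it computes

**Effective relaxation rates.** For a constant-time CPMG element of length
T<sub>relax</sub>,

R₂ᵉᶠᶠ(ν<sub>CPMG</sub>) = −(1/T<sub>relax</sub>) · ln(I/I₀),
σ(R₂ᵉᶠᶠ) = 1/(T<sub>relax</sub> · SNR),

where I is the peak intensity at a given refocusing frequency, I₀ the
reference intensity at zero relaxation time, and SNR = I/noise.

**Exchange regimes.** An iterative median/MAD estimate of the exchange-free
baseline R₂ᵉᶠᶠ∞ separates residues into `no_exchange` (flat at the baseline),
`fast` (flat but elevated — exchange too fast to refocus) and `dispersive`
(decaying profiles fittable by the two-state model).

**Two-state Bloch–McConnell fitting.** For exchange A ⇌ B with rates
k<sub>AB</sub>, k<sub>BA</sub> (k<sub>ex</sub> = k<sub>AB</sub> + k<sub>BA</sub>,
p<sub>B</sub> = k<sub>AB</sub>/k<sub>ex</sub>) and a ¹⁵N shift difference Δω,
transverse magnetization evolves under

L = [[−R₂∞ − k<sub>AB</sub>, k<sub>BA</sub>], [k<sub>AB</sub>, −R₂∞ − k<sub>BA</sub> + iΔω]],

propagated exactly (2×2 matrix exponentials, ideal 180° pulses as complex
conjugation) through the relaxation-compensated train
δ/2 − 180 − δ − … − 180 − δ/2. Fits run at four levels: per residue, global
per temperature (shared p<sub>B</sub>, k<sub>ex</sub>), global across
temperatures, and thermodynamically constrained, where
p<sub>B</sub>(T) follows the van't Hoff law and k<sub>AB</sub>(T) the Eyring
law, so the whole multi-field, multi-temperature dataset is described by
ΔH, ΔS, ΔH‡, ΔS‡ plus one Δω per residue. Model selection follows the
χ² < DF criterion at every level.

**Relaxometry, CSP and temperature coefficients.** R₂/R₁ flagging of
exchanging residues (mean + 1 SD), rotational-correlation-time estimation by
numerical inversion of the rigid-rotor dipolar+CSA R₂/R₁ curve, chemical
shift perturbations CSP = √(0.5·Δδ<sub>H</sub>² + 0.5·(Δδ<sub>N</sub>/10)²)
with mean + 2 SD significance labelling, and amide-proton temperature
coefficients dδ<sub>HN</sub>/dT in ppb/K.

## Worked example

```r
library(cpmgrd)

# simulate a paper-like experiment: 2 fields x 4 temperatures, SNR 150
truth <- truth_paperlike(seed = 1)
ds <- gen_dispersion_dataset(truth, snr = 150, seed = 1)

# classify the 283 K / 800.4 MHz plane into exchange regimes
sl <- dataset_series(ds)
sel <- sl[vapply(sl, function(s) s$context$temperature_K == 283 &
                 s$context$proton_frequency_MHz > 700, logical(1))]
labels <- classify_all(sel)
table(labels$label)
#>  dispersive        fast no_exchange
#>           5           5          10

# fit one dispersive residue at both fields, 283 K
s134 <- sl[vapply(sl, function(s) s$residue_id == 134 &
                  s$context$temperature_K == 283, logical(1))]
fit_individual(s134)
#> two-state fit [individual]: chi2 = 17.85, DF = 17, converged = TRUE
#>    name       value       sigma
#>     p_B   0.1310971  0.02571087
#>    k_ex 226.9159968 63.73129054
#>  dw_ppm   2.9151996  0.15403344

# constrained multi-temperature fit of all dispersive residues
disp <- dataset_series(ds, residues = truth$dispersive$residue_id)
fit <- fit_global_all(disp, constrained = TRUE)
fit$pars[1:4, ]
#>          name      value     sigma
#> 1    dH_kJmol  -32.51019 1.8543537
#> 2    dS_JmolK -128.59689 6.2778323
#> 3 dHact_kJmol   50.51302 0.5045499
#> 4 dSact_JmolK  -38.32956 1.7889911
```

The classification recovers the generator's 5 dispersive, 5 fast and 10
exchange-free residues exactly. The individual 283 K fit is noisy (exchange is
slow at low temperature, so p_B and k_ex trade against each other within the
reported 1σ), while the constrained fit pools 40 series and recovers the
generating thermodynamics (ΔH = −30 kJ/mol, ΔS = −120 J mol⁻¹ K⁻¹,
ΔH‡ = 50 kJ/mol, ΔS‡ = −40 J mol⁻¹ K⁻¹) to a few percent: the minor state is
enthalpically favourable and entropically penalised. `landscape_table()` turns
these into the (ΔG, ΔH, −TΔS) decomposition of the A→B equilibrium and both
barriers.

## Command line

A thin CLI wraps the same functions (see `?rd_main`; script in `inst/cli/rd`):

```sh
rd generate --seed 1 --snr 150 --out data/
rd r2eff --in data/intensities_800.4MHz_283K_free.tsv --freq 800.4 --temp 283 --out r2eff.tsv
rd classify --in r2eff.tsv --out regimes.tsv
rd tc --in data/relaxation_800.4MHz.tsv --field 800.4
rd fit --mode constrained --in r2eff_all.tsv --out fits.tsv
```

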