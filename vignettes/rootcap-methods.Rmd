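---
title: "Benchmarking electrical variables as root biomass predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking electrical variables as root biomass predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootcap)
```

## The measurement and its equivalent circuits

An LCR meter driving an alternating current through a plant-soil system
reports, per injected frequency $f$, the impedance magnitude $Z$ (ohm) and
the phase angle $\theta$ (degrees, negative for capacitive systems). The
complex impedance is $Z^* = Z e^{j\theta}$. Interpreted through the two
canonical one-relaxation equivalent circuits, with $\omega = 2\pi f$, the
same sample yields the serial-circuit variables

$$R_s = Z\cos\theta, \qquad C_s = \frac{-1}{\omega Z \sin\theta},
\qquad X = Z\sin\theta,$$

and the parallel-circuit variables

$$R_p = \frac{Z}{\cos\theta}, \qquad C_p = \frac{-\sin\theta}{\omega Z},
\qquad G = \frac{\cos\theta}{Z}.$$

Together with $Z$ itself and $\theta$, these form the eight screened
candidates (`screeningVariables()`). Resistance $R$ and susceptance $B$
are computable (`allVariables()`) but excluded from ranking: $R = R_s$
and $B = -\omega C_p$ carry no independent information.

Two conventions matter and are fixed once:

* phases are **stored in degrees** (the instrument convention) and
  converted to radians exactly once, inside `computeVariable()`;
* the minus signs make capacitances positive for capacitive systems.
  Inductive samples ($\theta > 0$) are accepted and produce negative
  capacitances rather than errors, so that noise around $\theta = 0$
  cannot abort a screen. $\theta = 0$ exactly is a domain error for
  $C_s$ only (the expression is singular); $C_p$, $X$, $B$ are zero
  there. $\theta = \pm 90^\circ$ is a domain error for $R_p$.

For an ideal parallel RC circuit, $C_p$ and $R_p$ are constant across the
whole spectrum (likewise $C_s$, $R_s$ for a serial circuit). Frequency
dependence of a measured $C_p$ therefore diagnoses a multi-dispersion
system — which a plant in soil always is — and makes the choice of
measurement frequency part of the method.

## Screening a variable against root dry mass

For one variable and one terminal configuration, `screenVariable()` fits
$y = a\,\mathrm{RDM} + b$ at every frequency of the support
(`fitLinear()`: ordinary least squares; $r^2$ is the squared Pearson
correlation; the $p$-value is the two-sided slope $t$-test). The
frequency maximising the screened $r^2$ curve is the maximum
determination frequency `fMax`, with value `r2Max`. Ties are broken
toward the **lowest** frequency, where electrode and coupling artefacts
are smallest; the choice is deterministic and recorded here.

Two screening modes exist because "the $r^2$ averaged over soils" can be
read two ways:

* `pooled` — one regression per frequency over all plants;
* `soil_averaged` (default) — the $r^2$ curve is the arithmetic mean of
  per-soil $r^2$ values, while the reported slope and intercept still
  come from the pooled fit, since a single calibration line across soils
  is what a user of the method would apply.

Per-frequency $p$-values are deliberately **not** corrected for multiple
testing: the screen is descriptive, one star-annotated test per
frequency, and the output records this. Significance stars are `***` for
$p < 0.01$ and `**` for $p < 0.05$.

Degenerate inputs are handled explicitly: fewer than 3 complete pairs or
a constant RDM vector are errors; a constant response is returned as
slope 0, $r^2 = 0$, $p = 1$ (a flat response carries no information, and
this keeps noiseless null screens well-defined).

## The sensitivity score

A high $r^2$ alone does not make a variable a good estimator: if the
intercept $b$ dominates the signal $a\,m_0$ at the characteristic root
mass $m_0$, the ratio of two measurements no longer approximates the
ratio of two root masses, because

$$\frac{y_1}{y_2} = \frac{a m_1 + b}{a m_2 + b}
\longrightarrow \frac{m_1}{m_2}
\quad\text{only when}\quad \left|\frac{b}{a m_0}\right| \ll 1 .$$

The ranking statistic is therefore

$$s = \max\!\left(r^2_{max}\left(1 - \left|\frac{b}{a m_0}\right|\right),\, 0\right),$$

implemented in `sensitivityScore()` with $m_0 = 1$ g by default (the
order of magnitude of a potted cereal root system; literature
recomputation uses each study's own $m_0$). The score is invariant under
joint rescaling of $(a, b)$ — so unit choices cannot change rankings —
monotone non-increasing in $|b|$, and bounded by $0 \le s \le r^2_{max}$.
Negative slopes are legitimate (reactance is negative-valued) and
handled by the absolute value. `rankVariables()` applies the score at
each screen's `fMax`; `lcrSubset()` instead scores fixed frequencies
(the handheld-LCR-meter setting) from each frequency's **own**
regression, not the spectrum-wide maximum.

Scores are reported at full precision. When comparing against published
two-decimal tables a tolerance of ±0.01 is appropriate, because the
published inputs (ratio, $r^2$) are themselves rounded; the bundled
compilation (`bundledLiterature()`) flags one row whose printed score is
not reproducible from its printed inputs at any rounding
(`inconsistent_printed`), one typographically ambiguous row
(`ambiguous_source`), and rows lacking the intercept:slope ratio
(`incomplete`). Flagged rows pass through `recomputeScores()` unscored
or excluded from reproduction checks.

## Comparing stem electrode types

`compareElectrodes()` pairs, per plant and configuration, the parallel
capacitance measured with the alligator clamp ($C_c$) against the needle
($C_n$), reporting per frequency the mean relative difference
$|C_c - C_n|/C_c$ and a two-sided Wilcoxon signed-rank test at
$\alpha = 0.01$.

The signed-rank test is implemented in the package because the deployed
variant needs exact handling of ties: zero differences are dropped
(Wilcoxon's original treatment, recorded in the output metadata), tied
absolute differences share average ranks, and for up to 20 nonzero
differences the null distribution of the positive-rank sum is computed
exactly by dynamic programming over the doubled ranks — identical to
enumerating all $2^n$ sign assignments. Above 20, a normal approximation
with tie-corrected variance and a 0.5 continuity correction is used;
at $n = 20$ it agrees with the exact distribution to better than 0.01
absolute. Two-sided $p$-values use the standard doubling convention,
capped at 1. Per-frequency tests are uncorrected for multiplicity,
matching per-frequency reporting practice.

## The synthetic study generator

No measurement set is distributed with the package, so every pipeline
stage is exercised against `simulateStudy()`, a plant-soil
equivalent-circuit simulator. Its defaults *are* the emulated study
conditions, chosen once:

* **Cohort** — 30 plants, 14/8/8 across silt loam / loam / sandy loam;
  root dry mass truncated-normal, mean 0.2 g, sd 0.19 g on
  [0.02, 0.72] g. (Truncating at these bounds shifts the realised mean
  to ≈ 0.26 g; the stated mean/sd are the distribution's parameters,
  not the truncated moments.)
* **Circuit** — three dispersions in series,
  $Z^*(f) = Z_{plant} + Z_{soil} + Z_{contact}$, each a parallel RC.
  The plant element carries the signal:
  $C_{plant} = (4.2\,\mathrm{RDM} + 0.37)$ nF and
  $R_{plant} = 2\times10^5 / (\mathrm{RDM} + 0.05)$ ohm. The resistance
  law is a structural convenience (larger root systems conduct better;
  the offset prevents divergence), not a physical calibration. The
  contact element (1 kΩ median, 1 nF) is counted twice in 2T sensing,
  once in 3T, zero times in 4T; 4T instead receives extra multiplicative
  noise emulating its stem-base voltage electrode's position
  sensitivity. Needle electrodes distort the magnitude by
  $1 + 0.04\,\log_{10}(f/0.5\,\mathrm{Hz})$ relative to the clamp.
* **Soil presets** — (25 kΩ, 1.5 µF), (12 kΩ, 0.8 µF), (40 kΩ, 2.5 µF)
  for silt loam, loam and sandy loam. These are free structural
  parameters, set so that the soil element dominates the measured $C_p$
  at the bottom of the band and relaxes away by ~50 Hz, at
  soil-specific corner frequencies: the simulated screens then show the
  characteristic low-frequency $r^2$ collapse, an interior maximum
  determination frequency, and soil-dependent $f_{max}$.

The noise model has deliberate structure, because *where* noise lives
controls which analyses it can and cannot affect:

* per-plant terms, shared by all hookups of one plant: biological
  scatter of root capacitance about the linear relation (lognormal,
  sdlog 0.15 — clonal young wheat under controlled conditions), per-pot
  soil resistance variability (sdlog 0.5), and a cable-coupling gain
  error growing linearly with frequency (15% at 20 kHz), which belongs
  to the pot's cable/soil-electrode layout;
* per-(plant, electrode) terms: hookup gain (5%) and phase offset
  (0.01°). A stem electrode is attached once and the terminal
  configurations are cycled by moving the soil electrodes, so these are
  shared across 2T/3T/4T — the correlation structure a real re-clamping
  protocol induces;
* per-spectrum terms: contact-resistance scatter (sdlog 0.15) and, in 4T
  only, a 20% multiplicative position noise — the stem-base voltage
  electrode sits millimetres above the soil, where measured capacitance
  is very sensitive to its exact position. This single term reproduces
  the configuration's empirical signature: 4T screens are the worst of
  the three, and 4T clamp/needle differences sit on a high floor that is
  no longer monotone in frequency (unlike 2T/3T, where the needle
  distortion trend dominates);
* per-point repeatability: 0.3% magnitude, 0.005° phase —
  research-grade impedance meters resolve phase to ~0.1 mrad, which is
  precisely what makes low-frequency capacitance measurable at all
  (at 0.5 Hz the system's phase is a fraction of a degree).

Because plant-level terms cancel in the paired clamp/needle comparison
while hookup terms do not, the generator reproduces the right behaviour
on both sides: with the needle distortion switched off, the 78
per-frequency signed-rank tests are driven by a single hookup-gain
contrast per plant and the family-wise false-positive rate over whole
runs stays near the nominal per-test level; with the default distortion,
the mean relative difference increases monotonically with frequency.

`optimumFrequency()` reports the generator's structurally best grid
frequency: the argmax of the noiseless pooled $r^2$ of $C_p$ against
RDM over a deterministic quantile cohort. At low frequencies the soil
element both biases and — through the resistive divider
$(R_{plant}/R_{total})^2$, which itself depends on RDM — *inflates* the
apparent slope, so the noisy screen's $f_{max}$ (which maximises
determination, not slope fidelity) typically sits below the optimum
frequency, at which the fitted slope and intercept recover the
generating 4.2 nF/g and 0.37 nF.

All randomness flows from `SimulationConfig(seed = )`; every random
block is drawn in a fixed order whether or not it is used, so changing a
structural parameter (e.g. the contact resistance) never reshuffles the
noise realisation of unrelated spectra.

What the generator does **not** emulate: soil water content dynamics and
its confounding of capacitance, multi-relaxation (Cole-type) tissue
dispersions beyond the lumped elements, woody root anatomy, field-scale
heterogeneity, and any physically calibrated soil dielectric response.
Passing tests on synthetic studies therefore validate the *analysis
pipeline* — conversions, screening, scoring, testing — under a known
ground truth, not the field performance of the measurement itself.

## The frequency grid

The instrument's 26 logarithmically distributed frequencies between
0.5 Hz and 20 kHz are not published as a full list. The frequencies that
are printed alongside results (78, 116, 1250, 13458 Hz, ...) sit, to
~0.3% relative, on a geometric ladder of ratio $2^{4/7}$ anchored at
20 kHz. `defaultGrid()` therefore uses that ladder for the upper 25
points; the ladder's 26th value would be ≈ 1.0 Hz, so the lowest point
is set to the stated 0.5 Hz minimum instead. The reconstruction is
approximate by construction — a handful of printed values round to 1 Hz
away from the ladder — and file readers consequently snap frequencies to
the grid only within a 1% relative tolerance, keeping anything further
away untouched; the pipeline never requires the canonical grid.

## Problem sizes and numerical choices

The shipped tests run the full design (30 plants × 3 configurations ×
2 electrodes × 26 frequencies), a 100-run null study for the size of
the electrode comparison, exhaustive $2^8$ sign-pattern enumeration for
the signed-rank oracle, and $10^4$ random samples for the
variable-conversion oracle; these sizes keep the whole suite around a
minute while leaving Monte-Carlo margins wide. Screens evaluate ~600
regressions per benchmark; all linear algebra is delegated to
`stats::lm`. Exact score reproduction is asserted to ±0.01 (rounded
published inputs), conversions to 1e-9 relative, and circuit identities
to 1e-9 relative.

## Known limitations

* The ranking reflects the score at each screen's own $f_{max}$;
  nothing multivariate (e.g. water content as a covariate) is fitted.
* The soil-averaged mode averages per-soil $r^2$ but keeps pooled
  coefficients; if soils truly need different calibration lines, the
  pooled slope is a compromise by design.
* Published-table recomputation is limited to what the printed summary
  carries: rows without an intercept:slope ratio cannot be scored.
* The simulator's plant-resistance law and soil presets are structural
  stand-ins; conclusions about absolute impedance levels should not be
  drawn from it.
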