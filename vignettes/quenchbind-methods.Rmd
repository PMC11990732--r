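---
title: "Fluorescence quenching analysis of protein-ligand binding: models and methods"
author: "quenchbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluorescence quenching analysis of protein-ligand binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchbind)
```

# The problem

When a small molecule binds a fluorescent protein such as human serum
albumin (HSA), the protein's intrinsic tryptophan/tyrosine emission (peak
near 337 nm under ~295 nm excitation) is quenched. A titration — protein
held fixed, ligand added stepwise — encodes the association constant, the
binding stoichiometry, the quenching mechanism, the thermodynamic driving
forces, and (with site-specific competitors) the binding pocket. quenchbind
implements this entire inference chain on a common data model, plus a
mass-action simulator that generates titrations with known ground truth so
every estimator can be validated end to end.

The central container is `TitrationSeries`, a `SummarizedExperiment` whose
`"intensity"` assay is a wavelength x titration-point matrix; `rowData`
holds the wavelength grid, `colData` the per-point quencher concentrations
(and optional absorbances), and `metadata` the shared conditions. The first
titration point must be at zero quencher: it defines the unquenched
reference intensity $F_0$.

# Models

## Inner-filter correction

Absorbing samples attenuate both the excitation beam and the emitted light.
When optical densities at the excitation and emission wavelengths are
recorded, intensities are corrected multiplicatively:

$$F_{cor} = F_{obs} \times 10^{(A_{ex}+A_{em})/2}.$$

The correction is optional and skipped when absorbances are absent; most
users do not record them, and applying a guessed correction is worse than
none. Negative absorbances are rejected as corrupt input.

## Stern-Volmer quenching and mechanism

Quenching follows $F_0/F = 1 + K_{SV}[Q]$, fitted by ordinary least squares
of the intensity ratio on total quencher concentration. The intercept is
fitted freely rather than pinned at 1 — pinning silently changes the
reported $R^2$ and hides offset problems. Intensities are read at a single
wavelength: by default the sub-grid emission maximum of the zero-quencher
spectrum (3-point parabolic interpolation around the discrete argmax), held
fixed across the series so that every ratio compares like with like. The
bimolecular rate constant is $K_q = K_{SV}/\tau_0$.

`tau0` defaults to $10^{-8}$ s. Literature lifetime values for albumin
cluster around 8–10 ns, and tabulated $K_q$ values for albumin systems are
consistent with $10^{-8}$ s; because the choice rescales $K_q$ linearly, it
is an explicit parameter rather than a constant.

Mechanism classification uses two independent lines of evidence: the
temperature trend of $K_{SV}$ (static complexes dissociate on heating, so
$K_{SV}$ falls; collisional quenching accelerates, so it rises) and the
magnitude of $K_q$ against the diffusion-controlled ceiling for collisional
quenching, $2\times10^{10}$ L mol$^{-1}$ s$^{-1}$. The verdict is `static`
only when the trend strictly decreases *and* every $K_q$ exceeds the
ceiling, `dynamic` only when the trend strictly increases and no $K_q$
exceeds it, and `indeterminate` otherwise with both flags reported. Strict
monotonicity (ties count as non-monotone) keeps the rule reproducible;
"decreasing within error bars" would make the verdict depend on unstated
uncertainty models.

## Binding constant and stoichiometry

For static quenching, the apparent association constant $K_a$ and site
number $n$ come from the double-logarithm regression

$$\log_{10}\frac{F_0-F}{F} = \log_{10}K_a +
  n\,\log_{10}\!\left([Q]-[P]\frac{F_0-F}{F_0}\right),$$

where $[Q]$ and $[P]$ are *total* concentrations — the free ligand
concentration is not observable, and the $[P](F_0-F)/F_0$ term corrects the
total for the fraction bound. Logs are base 10 throughout; a natural-log
reading would silently rescale the intercept. Points whose log arguments
are non-positive (no measurable quenching, or a depletion estimate at or
above the total) are dropped and counted — the only choice that preserves
the model as written without inventing data.

This estimator has an exact internal oracle: for a 1:1 ground-state complex
with a non-fluorescent complex, $(F_0-F)/F$ equals
$[\mathrm{complex}]/[\mathrm{free\ protein}]$ and the corrected abscissa
equals the free ligand concentration, so the plot is perfectly linear with
slope 1 and intercept $\log_{10}K_a$. The test suite exploits this: on
noise-free simulated titrations the fit must return the generating constant
to 0.1% and $n = 1.000 \pm 0.001$.

## Thermodynamics

With $K_a$ at two or more temperatures, the van't Hoff regression of
$\ln K_a$ on $1/T$ gives $\Delta H^0 = -R\,\mathrm{slope}$ and
$\Delta S^0 = R\,\mathrm{intercept}$ ($R = 8.314$ J mol$^{-1}$ K$^{-1}$).
Gibbs energies are reported per input temperature from
$\Delta G^0 = \Delta H^0 - T\Delta S^0$ (mode `from_HS`); the alternative
route $-RT\ln K_a$ is exposed as `gibbsFromKa()`. The two differ by the
regression residual at each temperature (about 0.05 kJ/mol on typical
three-temperature fits); `from_HS` is the default because it is internally
exact for the fitted pair and matches how tabulated values are customarily
derived.

The dominant force is read from signs: $\Delta H^0>0,\Delta S^0>0$ is
hydrophobic (entropy-driven desolvation), both negative indicates van der
Waals/hydrogen bonding, and $\Delta H^0\approx 0$ with $\Delta S^0>0$
indicates electrostatics. "Approximately zero" needs a number: the default
band is $|\Delta H^0| < 4$ kJ/mol (roughly thermal energy at room
temperature, configurable), and the band takes precedence over the
hydrophobic rule so that every sign pair maps to exactly one verdict.

## Site-marker displacement

Refitting $K_a$ after pre-incubating the protein with a Sudlow site I
marker (warfarin) or site II marker (ibuprofen) localizes the binding
pocket: the marker sharing the ligand's site depresses the apparent
constant most. The reported statistic is
$100\,(K_a^{binary}-K_a^{ternary})/K_a^{binary}$ per marker, kept at full
precision (rounding is presentation only), with a strict-inequality site
call. Negative "reductions" for both markers (apparent enhancement) yield
an indeterminate call with a warning rather than an error — real ternary
data do occasionally behave this way. The comparison is temperature-agnostic
beyond requiring all three fits to share one temperature.

## Synchronous scans and absorbance trends

Synchronous fluorescence scans at a fixed emission-excitation offset probe
residue microenvironments ($\Delta\lambda$ = 15 nm: tyrosine; 60 nm:
tryptophan — labels only, no structural inference is computed). The peak of
each scan is located by the same parabolic interpolation; the result is the
net first-to-last peak shift, a direction call (blue = more hydrophobic
environment, red = more polar) under a 0.5 nm tolerance (sub-grid shifts
smaller than that are within interpolation error on 1 nm-sampled bands),
and the fractional intensity drop at the peak. Direction calls are
antisymmetric under reflection of the wavelength axis, which the suite
checks.

`uvTrend()` regresses ground-state absorbance on ligand concentration: a
rising trend supports complex formation (static quenching), a flat one —
predicted relative change below 1% across the range — supports a purely
collisional picture.

## Docking post-processing

Docking scores arrive in kcal/mol; the package converts with the
thermochemical factor 4.184 and derives the implied inhibition constant
$K_i = \exp(\Delta G/RT)$, a concentration (mol/L, below 1 M for negative
$\Delta G$). No docking is performed or rescored.

# The simulator

`simConfig()`/`simulateTitration()` emulate the standard albumin titration:
protein fixed at $1.6\times10^{-6}$ M, ligand 0 to $3.2\times10^{-6}$ M in
9 steps, emission recorded 300–450 nm at 1 nm, band centred at 337 nm
(width 25 nm), multiplicative Gaussian intensity noise of 1% by default,
seeded Mersenne-Twister PRNG (identical configs are bit-identical, and the
caller's RNG stream is left untouched).

Three mechanisms are available. `static_1to1` solves the 1:1 mass-action
equilibrium exactly — the stable quadratic branch
$x = 2K_aPQ/(b+\sqrt{b^2-4K_a^2PQ})$, $b = K_a(P+Q)+1$, avoids catastrophic
cancellation from $K_a = 0$ up to the stoichiometric limit — and scales the
band by free protein plus an optionally dim complex (default brightness 0:
a fully non-fluorescent ground-state complex). `dynamic` applies the
Stern-Volmer dilution directly. `static_competitive` adds a marker
competing for the protein, solved by bounded root-finding on free protein
(monotone residual, unique root) with Newton polishing to ~$10^{-12}$
relative mass balance; the marker complex stays fluorescent, so added
ligand displacing the marker depresses the *apparent* binding constant —
the behaviour displacement experiments rely on. Both solvers are
cross-checked in the suite against independent brute-force oracles
(bisection on the mass-action residual; a $10^4$-point log grid plus
bracketed bisection for the competitive case).

Multi-temperature studies derive $K_a(T)$ from a chosen
$(\Delta H^0, \Delta S^0)$ through the van't Hoff relation, so the full
chain — simulate, fit per temperature, regress — can be validated as a
round trip.

What the generator does *not* emulate: Raman/scatter bands, baseline drift,
photobleaching, instrument wavelength error, multi-site or cooperative
binding ($n \ne 1$), and inner-filter attenuation (optional absorbance
columns proportional to total chromophore can be attached, but spectra are
not attenuated by them). Passing tests therefore demonstrate estimator
correctness under the stated model, not robustness to every instrumental
artefact of real spectra.

# Numerical choices and problem sizes

- Peak location: 3-point parabolic interpolation around the discrete
  argmax; boundary-peaked or flat scans are errors, not guesses. Accuracy
  is better than 0.2 nm for Gaussian bands (width 5–25 nm) on a 1 nm grid,
  checked over 100 seeded bands.
- Curve reading: the wavelength is fixed from the $F_0$ spectrum; per-point
  intensities are linearly interpolated on the grid.
- Regressions are ordinary least squares via `lm()`; $R^2$ is the squared
  Pearson correlation, which for these simple regressions equals the usual
  coefficient of determination.
- The validation suite uses 9-point titrations, 100-band interpolation
  sweeps, and a 500-replicate noise study; everything runs in well under a
  minute.

# Known limitations

The double-logarithm estimator's *standard errors* are optimistic. The
intercept sits at $\log_{10}[Q_{free}] = 0$ — about six decades outside the
data — so intensity noise is strongly amplified; worse, the same noisy
$F_0-F$ enters both regression coordinates (through the depletion
correction), making per-point errors correlated across axes, and the single
noisy $F_0$ is shared by every point. Ordinary least squares assumes none
of this. The package's own 500-replicate calibration study (recomputed by
`scripts/acceptance.R` as `noise_coverage_3se_pct`) finds that a nominal
3-SE interval around the fitted $\log_{10}K_a$ covers the generating value
in well under half of replicates at 1% intensity noise, rather than the
~99% a calibrated Gaussian SE would give. Peak-mode reading adds a further
downward bias in $\log_{10}K_a$ because picking the argmax of a *noisy*
$F_0$ spectrum selects upward noise excursions into $F_0$. Practical
guidance: prefer `mode = "fixed"` at a known band position when data are
noisy, treat the reported SEs as lower bounds, and derive uncertainty from
replicate titrations (instruments typically record three) rather than from
a single fit.

Other limitations: no combined static+dynamic (sphere-of-action) model; no
lifetime fitting; no multi-site/Scatchard analysis beyond the printed
double-log model — the estimator reports $n$ without interpreting values
away from 1; no heat-capacity correction (temperature-independent
$\Delta H^0$ is assumed across the narrow 298–308 K window where albumin
is conformationally stable); circular-dichroism deconvolution is out of
scope (externally computed helix percentages can be carried in reports but
are never derived).

# The pipeline and the command line

`runStudy()` composes all stages from one config (R list or YAML), collects
per-stage errors instead of aborting, skips dependents with a reason
(e.g. a single-temperature study yields quenching and binding blocks but no
thermodynamics), and records provenance (input file hashes, parameters,
package version). `writeStudyReport()` serializes at full precision;
rounding happens only in the printed tables. Re-running an identical config
reproduces the report byte for byte.

The package's functions are the primary interface; a thin wrapper script
(`inst/scripts/quenchbind`, subcommands `run`, `simulate`, `dockpost`;
exit codes 0/2/3 for success/validation error/stage failure) covers shell
use, and the remaining operations are one function call each.
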