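---
title: "Cross-section variability and ionization cluster size distributions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-section variability and ICSDs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanodosim)
```

# Scope and model

`nanodosim` studies a single question: *how much of the disagreement
between track-structure simulations of low-energy electrons in liquid
water is caused by their total interaction cross sections alone?*  The
package therefore contains two largely independent layers.

The **simulation layer** is an event-by-event Monte Carlo transport of an
electron and its full secondary cascade.  An electron of kinetic energy
$E$ travels exponential free flights with macroscopic cross section
$\Sigma(E) = n\,\sigma_{\mathrm{tot}}(E)$, where $n$ is the molecular
number density of liquid water and $\sigma_{\mathrm{tot}}$ sums the 11
channels of the standard water scheme: ionization of the five molecular
orbitals, five discrete electronic excitations, and elastic scattering.
At each collision a channel is selected with probability
$\sigma_c/\sigma_{\mathrm{tot}}$.  Ionizations inside the scoring sphere
are tallied per history; the histogram over histories is the ionization
cluster size distribution (ICSD).

The **statistics layer** needs no transport at all: it takes families of
ICSDs (from the engine, from synthesis, or from published per-code tables)
and computes cluster-size moments, cumulative probabilities, their
uncertainties, dispersion summaries across family members, and
Wasserstein-1 distances between distributions.

# Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| number density $n$ | 33.43 | nm⁻³ | liquid water at 1.0 g/cm³, M = 18.0153 g/mol; the medium is always treated as liquid water but a number density is never printed in intercomparison reports, so it is an explicit `material` field |
| cutoff energy | 10 | eV | electrons at or below it deposit locally; track-structure practice spans 1–10 eV and nothing below the lowest threshold is harmonized anyway |
| scoring diameters | 8 / 100 | nm | nucleosome-scale and chromatin-loop-scale targets; 8 nm below 5 keV, 100 nm at 5–10 keV |
| world radius | 1000 (8 nm), 3000 (100 nm) | nm | large enough that the escape correction is negligible while allowing backscatter re-entry into the sphere |
| histories $N$ | 100,000 | — | keeps the statistical uncertainty of $M_1$ and $F_k$ well below typical inter-dataset differences |
| interpolation | log–log | — | cross sections span decades; linear mode exists because production codes genuinely differ here |
| secondary spectrum $\varepsilon_0$ | 13.6 | eV | Lorentzian-tail shape $\propto 1/(\varepsilon^2+\varepsilon_0^2)$ on $[0,(E-B)/2]$, a standard analytic stand-in |
| elastic screening | $\eta(E)=1.7\times10^{-5}\,Z^{2/3}/(\tau(\tau+2))$, $Z=7.42$ | — | screened-Rutherford with the conventional water effective charge |

## Differential models are deliberate stand-ins

Harmonization exercises on real codes prescribe only the *total* cross
sections; each code keeps its own angular distributions, secondary
spectra and binding energies.  The package mirrors that split: totals come
from the `xs_dataset`, while the differential behaviour is fixed by four
explicit defaults (screened-Rutherford elastic deflection, Lorentzian
secondary spectrum, isotropic secondary emission, undeflected primary).
These are parametrized (`epsilon0`, `eta_scale`, `z_eff`) rather than
pluggable per member: since every synthetic member shares them, the
final-phase residual variability in our experiments is purely statistical.
That is the designed behaviour — the package isolates the totals' effect —
but it also means the package cannot reproduce the *growth* of residual
variability with energy seen across real codes, which is driven by their
differing differential models.

## Numerical choices

- **Thresholds.**  Tabulated ionization values are zero at and below the
  binding energy and the validator rejects anything else.  Interpolation
  across the threshold segment falls back from log–log to linear (a zero
  endpoint has no logarithm), and the synthetic generator inserts the
  threshold energies as grid nodes so interpolated cross sections vanish
  exactly at $E=B$.  The engine additionally refuses to sample an
  inelastic channel unless $E$ strictly exceeds its transition energy.
- **Boundary rule.**  An ionization is scored if its interaction point is
  strictly inside the sphere ($|r| < d/2$).  For continuous positions the
  choice is measure-zero; it is fixed so results are bit-reproducible.
- **Degenerate media.**  If $\sigma_{\mathrm{tot}}(E)=0$ (possible below
  all thresholds when the elastic column is zero, as in closed-form test
  configurations), the electron is absorbed locally and its energy counted
  as terminated; a physical random walk would otherwise never end.
- **Energy bookkeeping.**  Every history satisfies
  $E_0 = \sum \mathrm{deposits} + E_{\mathrm{terminated}} +
  E_{\mathrm{escaped}}$ to double-precision accumulation error; tests
  assert closure to $10^{-6}$ eV.
- **Reproducibility.**  Each history draws from its own splitmix64 stream
  keyed by (seed, history index), so ensembles are independent of batching
  and bitwise reproducible; all user-facing generators (`perturbed_family`,
  `synthetic_icsd_family`) run under a private RNG scope that neither
  disturbs nor depends on the caller's `.Random.seed`.
- **Wasserstein-1.**  Computed by the cumulative-difference recursion
  $\delta_{i+1}=\delta_i+x_i-y_i$, $W_1=\sum_i|\delta_i|$ after
  zero-padding to a common support.  The test suite checks it against an
  independently coded quantile-coupling oracle
  ($W_1=\int_0^1 |Q_x(u)-Q_y(u)|\,du$) to $10^{-12}$ on 1000 random pairs,
  and verifies the metric axioms.
- **$u(W_1)$.**  First-order propagation of per-bin binomial uncertainties
  through the recursion, treating the two distributions as independent.
  When one argument is the family mean this overstates the uncertainty
  (the mean is correlated with each member); the overestimate is accepted
  and documented, and the dispersion of member $W_1$ values (standard
  error of their mean) is reported alongside, which is what published
  mean-$W_1$ uncertainties match.

## Dispersion uncertainties: a transcription caveat

`dispersion()` implements

$$u(\mathrm{SD}) = \frac{1}{n_c\,\mathrm{SD}}
  \sqrt{\textstyle\sum_k (x_k-\mathrm{MV})^2 u(x_k)^2},\qquad
  u(\mathrm{RSD}) = \frac{\mathrm{RSD}}{n_c\,\mathrm{MV}}
  \sqrt{\textstyle\sum_k \left(\frac{x_k}{\mathrm{MV}}-1-\mathrm{RSD}^2\right)^2 u(x_k)^2}.$$

These are the expressions as conventionally printed in intercomparison
reports.  Direct evaluation on the published 20–50 eV inputs yields values
about half the published ±0.0010 cells; a first-principles GUM derivation
would carry $1/(n_c-1)$ rather than $1/n_c$ in $\partial\mathrm{SD}/\partial
x_k$ and still not close the gap.  The formulas are therefore implemented
as printed, the discrepancy is documented here rather than "fixed", and
these two quantities are excluded from acceptance checks.  By contrast
$u(\mathrm{MV}) = \sqrt{\frac{1}{n_c}\sum_k u(x_k)^2 +
\frac{\mathrm{SD}^2}{n_c-1}}$ reproduces every published MV ± cell.

# The synthetic world

No production code's cross-section tables ship with this package, so the
generator produces a *stated world* that stands in for them:

- **Base shapes.**  Ionization
  $\sigma(E)=C\,\ln(E/B)/(E\,B)$ above threshold (Bethe-like rise and
  fall, interior maximum at $E=eB$); excitation
  $\sigma(E)=D\,(E/W-1)/((E/W)^2+c)$; elastic $a/(E(E+b))$, strictly
  decreasing.  Magnitudes are tuned once so mean free paths are of the
  order of nanometres at 20–100 eV, as in liquid water — e.g. total
  inelastic MFP ≈ 1.7 nm at 20 eV — giving 20 eV mean cluster sizes around
  0.6 in an 8 nm sphere, inside the published 0.21–0.83 inter-code range.
- **Family spread.**  Member $k$ multiplies each channel by
  $\exp(g_{kc}(\log_{10}E))$ with $g$ a smooth zero-mean Gaussian process:
  unit-variance cosine-blended node noise at one-decade correlation
  length, scaled by a standard deviation that interpolates linearly in
  $\log_{10}E$ from $\ln 2$ at 20 eV to 0.05 at 10 keV.  Those anchors are
  the stated world: factor-~2 disagreement at the lowest energies
  (published 20 eV $M_1$ spans a factor 4), percent-level at 10 keV.  The
  energy dependence *between* the anchors is only weakly constrained by
  published tables and is a documented modelling choice.
- **Synthetic ICSD families.**  A binomial thinning (probability 0.7) of a
  Poisson count with member mean drawn uniformly from a requested range —
  marginally Poisson with the drawn mean, so sample means and their
  standard errors have closed forms for testing.

What a green test on this world establishes: the *machinery* (transport
bookkeeping, scoring, statistics, the harmonization contrast) behaves as
designed, and the qualitative signature — most low-energy variability
attributable to the totals — emerges for the stated spread.  What it does
not establish: any quantitative claim about real codes (the ~97%
published RSD reduction at 20 eV depends on the real codes' spread), nor
realism of the synthetic shapes above a few keV, where the synthetic
ionization cross section falls somewhat faster than liquid-water data.

# Open design decisions taken

- **Averaging grid.**  Whether a common dataset should be averaged on a
  shared grid or each member's native grid is unspecified in harmonization
  practice; `average_datasets()` uses the union of member grids restricted
  to their common span, with members evaluated by their own interpolation
  mode.  At shared nodes this equals the elementwise mean exactly.
- **Per-kind member lists.**  The elastic average may draw on a different
  member subset than the inelastic one (real exercises have included an
  extra elastic-only source), so the operation takes separate selections.
- **Re-entrant ionizations.**  Every ionization inside the sphere counts,
  including those from electrons that left and re-entered — the world
  region exists precisely to allow backscatter.
- **Transition energies of the common dataset.**  Not averaged; the
  harmonized member keeps its own binding/excitation energies
  (`harmonize_dataset()`), since only totals are prescribed.
- **No auto-ionization after excitation**: excitations never ionize, which
  is one of the documented inter-code differences that stays out of scope.

# Limitations

- Electrons only; no photons, ions, radiolysis chemistry, relativistic
  transport beyond the screening parameter's $\tau$, or condensed-history
  mode.
- The default experiment at published scale (8 energies × 7 members ×
  2 phases × $10^5$ histories including 5–10 keV in 100 nm spheres) takes
  hours on one CPU; tests and the acceptance suite use documented
  scaled-down configurations (energies ≤ 1 keV, $10^4$ histories).
- Published multi-code tables at energies above 20 eV cannot be reproduced
  from printed values alone (the full per-code ICSDs live in supplementary
  data not shipped here); the statistics layer is validated on the 20 eV
  rows, where two-bin ICSDs are fully determined by $M_1$, and by
  property-based tests elsewhere.
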