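---
title: "Demographic benchmarking of forest stand models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demographic benchmarking of forest stand models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standbench)
```

`standbench` post-processes annual stand-level output of vegetation
demographic models (VDMs) — models that resolve forests as size- or
age-structured cohorts with explicit recruitment, growth and mortality —
into a set of demographic diagnostics and benchmarks. This vignette is the
package's own account of the methods: the quantities it computes, the
assumptions behind them, the numerical choices, and what the synthetic
ground-truth generator does and does not emulate.

## The stand series and its budget

The central object is an annual stand series: woody carbon `Cwood`
(kgC m⁻²), its aboveground part `Cwood_AG`, the woody mortality flux
`Cmort` and gross woody growth increment `WBgrowth` (kgC m⁻² yr⁻¹), stem
density `nstem` (stems ha⁻¹), canopy area `CA` (m² ha⁻¹) with the crown
area index `CAI = CA / 10^4`, and per-PFT shares of vegetation carbon
(`cveg_frac_*`). Units are fixed in storage; the ha↔m² factor 10⁴ appears
only inside computations that mix the per-area and per-stem bases, never in
files.

The demographic budget check asks whether annual stock changes are
explained by the net demographic flux:

$$\mathrm{residual}(t) = C_\mathrm{wood}(t+1) - C_\mathrm{wood}(t) -
\bigl(\mathrm{WBgrowth}(t) - C_\mathrm{mort}(t)\bigr)$$

summarised as the relative drift $\max_t |\mathrm{residual}|/\max_t
C_\mathrm{wood}$. This residual form — stock change minus net flux — is the
only closure consistent with the stand-level variable set; where a model
reports recruitment carbon separately, the reader must fold it into
`WBgrowth` before the check is meaningful. Two default tolerances are
sensible: `1e-6` (relative) for simulator output, which closes exactly, and
of order `1e-2` for real model output, which typically drifts.

## Rates and smoothing

The fractional mortality rate and the woody carbon turnover time are

$$\mathrm{cmort\_rate} = 100\,\frac{C_\mathrm{mort}}{C_\mathrm{wood}}
\ (\%\,\mathrm{yr}^{-1}), \qquad
\tau = \frac{C_\mathrm{wood}}{C_\mathrm{mort}}\ (\mathrm{yr}),$$

exact reciprocals (`tau * cmort_rate = 100`) wherever both are defined.
Years with `Cwood = 0` are flagged undefined rather than dropped; zero
mortality gives an explicitly infinite τ, which summary statistics exclude
with a logged count rather than coercing to a large number.

For time-series inspection the rates are smoothed with a 30-yr left-aligned
rolling mean (`zoo::rollmean(k = 30, align = "left")`), which removes the
signature of a repeated 30-yr climate forcing cycle; the first 30 years
after spin-up are dropped beforehand (`drop_post_spinup()`). Mature-forest
comparisons of τ and `WBgrowth` use unsmoothed annual values over an
equilibrium window, because interannual variability there is the model-side
analogue of the spatial variability in plot observations.

## Self-thinning

Dense even-aged stands shed stems under competition following the power law
$M = k N^p$ between mean individual biomass and stem density. The pipeline
works in "self-thinning space": per year, $\ln N$ (stems ha⁻¹, summed over
dbh classes whose lower edge is ≥ 10 cm) and $\ln M$ with
$M = \Sigma\,\mathrm{cwood\_size} \cdot 10^4 / N$ (kgC per tree). The
10-cm exclusion removes recruitment-dominated small-tree classes; when a
model cannot report a size structure, stand totals are used and the
deviation is recorded. Because mass is taken from the aboveground carbon
of the size structure, the fitted intercept $k$ is on the aboveground
basis, in kgC·(stems ha⁻¹)$^{-p}$; the slope is unaffected by any constant
rescaling of mass (this invariance is asserted in the tests by refitting in
log₁₀ and in gC).

Four period-detection methods mirror what different model outputs allow:

1. **M1** — models with a dedicated self-thinning mortality diagnostic:
   years whose diagnostic strictly exceeds the 95th percentile of the whole
   run. The percentile is linear-interpolation (type 7) and the comparison
   strict, so a constant diagnostic selects nothing.
2. **M2** — the same rule applied to the total mortality rate (the top 5%
   of annual values; with distinct values this selects ⌈0.05 n⌉ years).
3. **M3** — the consecutive run in self-thinning space that maximises the
   stem-density span, i.e. from a density maximum to a subsequent density
   minimum. The geometric "corner-to-corner" phrasing of this rule depends
   on plot orientation, so the density-extremes reading is taken as
   normative; ties resolve to the latest maximum and then the earliest
   following minimum, and the implementation (a single-pass maximum-drawdown
   scan) is tested against an exhaustive all-pairs search.
4. **M4** — a manual year range, recorded as manual provenance; it takes
   precedence over any automatic pick.

The slope is then ordinary least squares of $\ln M$ on $\ln N$ (`stats::lm`
with default settings), requiring at least three points with distinct
densities. The result is flagged against the reference band
$[-2.612, -1]$ — the observed lower and theoretical upper thresholds around
the classical $-3/2$ — with both boundaries inclusive.

## Recovery phases

Forest regrowth after a stand-replacing disturbance passes through four
qualitative phases: open-canopy grass coexistence, open-canopy growth,
closed-canopy self-thinning, and the closed-canopy late-successional stage
approaching dynamic equilibrium. The classifier thresholds a handful of
observables:

| parameter | default | meaning |
|---|---|---|
| `grass_frac_min` | 0.10 | grass share of C_veg ending the grass phase |
| `ca_closure` | 10 000 m² ha⁻¹ | canopy area at closure |
| `mort_spike_factor` | 1.5 | spike = rate ≥ 1.5 × equilibrium mean; late re-entry band ± 0.5 × |
| `equilibrium_tail` | 100 yr | final years defining the equilibrium reference |
| `smooth_k` | 3 yr | centred mean applied to nstem/CA/grass before thresholding |
| `decline_tol`, `flat_tol` | 0.02, 0.06 | 2-yr relative nstem change read as decline / as flattened |

Only the canopy-closure value is anchored in the characterisation framework
itself; the rest are configurable defaults chosen once. The equilibrium
reference (mean mortality rate over the final `equilibrium_tail` years) is
computed before classification, matching the use of the dynamic equilibrium
as the reference state.

The classifier is a sequential state machine, so the monotone phase order
is enforced by construction. This is a deliberate design choice over
per-year labelling with forward-fill smoothing: a purely pointwise rule
cannot distinguish closed-canopy growth *before* the mortality spike from
the late-successional state, because both show near-equilibrium mortality
under a closed canopy — only the history (has thinning happened yet?)
separates them. For the same reason canopy closure alone never triggers the
thinning label; the mortality-spike and density-decline conditions must
hold too, which accommodates canopy schemes in which growth continues after
closure until crown packing is optimised. Late-successional onset is keyed
on rate stabilisation (re-entry into the equilibrium band with a flattened
density decline) rather than on a compositional shift: whether a
composition change should be required cannot be settled from the
stand-level variable set, so composition is left as auxiliary evidence.

Start groups map the first label onto the three observed model behaviours:
P1 (starts in grass coexistence, mortality from near zero), P2 (starts in
open-canopy growth), P3 (starts directly in closed-canopy self-thinning,
e.g. a model restocked at high density inside the thinning regime). A run
that is already late-successional at its first year has no recovery
trajectory and is an error. `align_on_phase()` shifts runs so a chosen
anchor phase starts at year 0, excluding (with a log entry) runs lacking
that phase.

## Observation envelopes and scoring

Three envelope constructions cover the observation types:

* **Chronosequences** (age, aboveground woody carbon): half-open 20-yr age
  bins, median with 10th/90th percentile whiskers, and a minimum occupancy
  of 20 observations per retained bin.
* **Mapped plots**: square 6.25-ha subplots placed uniformly at random with
  full containment (no wrap, no tiling — the placement scheme is not
  prescribed by the source census protocols, so random placement with
  `n_boot = 1000` by default was chosen and is flagged here), summarised
  per dbh class and in total as the bootstrap median with a central 95%
  interval.
* **Few-plot censuses**: cellwise median with min–max across plots.

Model output maps onto the chronosequence axis as the mean of annual values
within each age bin; dbh-class cells match by label. Scoring classifies
each cell inside/below/above with inclusive bounds and reports signed
distances (negative below, positive above) plus per-variable fractions.
Quantiles are type 7 throughout, matching the default of the analysis
environment the reference comparisons were done in.

The dbh-class scheme is fixed: upper edges 1, 5, 10, 15, 20, 30, 40, 50,
60, 70, 80, 90, 100, 150, 200 cm plus an open top class, half-open
`[lower, upper)` so that a label `"<X"` is literal and `">=200"` is closed
below (the ASCII label is used in files for portability).

## The synthetic generator

The generator's purpose is exact, recoverable ground truth, so the
trajectory is parametric rather than emergent from an individual-based
mechanism:

* Stem density is constant at `initial_density` (restocking resets it at
  year 0 regardless of prior state; emergent mode ramps it up over
  `establishment_yrs`) and declines geometrically at `thinning_decline`
  (default 3% yr⁻¹) inside the thinning window.
* Mean individual mass follows the allometry $M = a\,\mathrm{dbh}^b$
  (defaults $a = 0.12$ kgC, $b = 2.4$; a 30-cm tree carries ≈ 0.4 tC) with
  geometric diameter growth (4% yr⁻¹) before the window, and the power law
  $M = kN^p$ inside it, with $k$ fixed by continuity at the window start —
  so the thinning points are exactly collinear when noise-free.
* Fluxes are derived to close the budget: mortality is the mass of dying
  stems plus `background_mort × Cwood` (default 1% yr⁻¹, giving a 100-yr
  equilibrium turnover time), and growth is the stock change plus
  mortality, which also folds recruitment carbon into `WBgrowth`.
* Default sapling diameter (2 cm) and growth rate put the stand at ≈ 13 cm
  dbh at canopy closure, so the whole thinning window survives the 10-cm
  exclusion.
* Grass is a single non-woody PFT whose share decays exponentially with
  timescale `grass_decay_yr` — only the share's trajectory matters to the
  phase rules, not grass physiology. Canopy area ramps linearly to closure
  carrying a 5% margin above the 10,000 m² ha⁻¹ threshold, so that
  moderate observation noise cannot hold the classifier below the
  threshold at the scripted closure year.
* Scripted phase boundaries (defaults 12, 48, 130 — grass end, canopy
  closure/thinning onset, late-successional onset — over a 420-yr run, a
  plausible temperate post-disturbance chronology) derive the consistent
  grass decay, closure year and thinning window; P3-type runs are produced
  by restocking at high density with closure at year 0.
* Each year's stems are split into three dbh cohorts (0.85×, 1×, 1.2× the
  mean diameter; weights ¼, ½, ¼) whose class totals are forced, by
  remainder construction, to sum exactly to the stand totals.

Observation noise is multiplicative lognormal and applies only to
observational copies — `nstem`, `CA`, `CAI`, the grass share (with the
woody share as its complement, so share sums cannot exceed 1) and the size
structure. The conserved pools and fluxes are never perturbed: the budget
check must have a clean pass case, and noise belongs to the observation
model, not the carbon accounting.

**What passing tests do and do not show.** The generator emulates the
diagnostic signatures the pipeline keys on — exact budget closure, a
power-law thinning trajectory, scripted phase switches, saturating regrowth
curves, Poisson-uniform stem maps — but none of the physiology that
produces them in a real model (no photosynthesis, allocation, climate
response, multi-patch landscapes, or size-dependent mortality). Recovery
of the embedded truth therefore validates the *post-processing*: that the
detection rules, fits and classifications return what was put in, under
controlled noise. It does not validate any VDM, and real model output will
exercise failure modes the generator cannot (budget drift, non-power-law
thinning, ambiguous phase transitions).

## Numerical choices

* **Exact closure in floating point.** The generator snaps `Cwood` and
  `Cmort` to a binary grid (multiples of 2⁻³⁰ kgC m⁻²) and derives
  `WBgrowth` as `diff(Cwood) + Cmort` on that grid. All terms of the
  residual are then exactly representable and cancel to exactly zero —
  "closes by construction" means a residual of 0.0, not merely small.
  Size-structure totals, built by remainder, match stand totals to within
  summation-order rounding (asserted at 10⁻¹² relative).
* **Tie-breaks.** M3 resolves equal density spans to the latest maximum,
  then the earliest following minimum; percentile selections are strict
  (`>`), so constants select nothing; `within_bounds` boundaries are
  inclusive with a 10⁻⁹ guard.
* **Degenerate inputs.** Series shorter than two years (budget), than the
  smoothing window, or with fewer than three distinct-density thinning
  points are errors; zero-density years are skipped with a log entry;
  negative fluxes in input files are clamped with a warning and the
  originals retained in an attribute — flagged, never silently fixed.
* **Problem sizes.** The test suite runs 200–420-yr simulations, 1000-case
  smoothing and detection oracle sweeps, 50 noisy phase-recovery runs,
  200-seed slope Monte Carlo, and bootstrap envelopes at a few hundred
  replicates — sizes chosen to pin each property tightly while keeping the
  whole suite under a minute on one core.

## Known limitations

* The budget check carries no harvest or disturbance export terms; models
  with such fluxes must fold them into the two-flux form or will show
  apparent drift.
* Method 1 assumes the diagnostic rate is comparable across the run; if a
  model defines it as a stem fraction rather than a flux fraction, the
  percentile rule still applies but the selected years may differ from a
  flux-based reading.
* The phase classifier needs canopy area (or CAI) and stem density; without
  a grass share it cannot see the grass-coexistence phase and starts at
  open-canopy growth.
* The stand-level variable list implemented here is the subset needed by
  these analyses, not a complete model-output exchange format; there is no
  NetCDF/CMIP reader.
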