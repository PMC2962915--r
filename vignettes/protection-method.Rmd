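---
title: "The -SH protection method: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The -SH protection method: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shprotect)
```

## The problem

Measuring how tightly a ligand binds an enzyme is awkward when the complex
has no convenient spectroscopic handle. The -SH protection method sidesteps
this by exploiting chemical modification kinetics: if an active-site
cysteine reacts with Ellman's reagent (DTNB) and a ligand bound at the same
site blocks that reaction, then the *slowing* of inactivation with
increasing ligand concentration reports directly on site occupancy — and
hence on the dissociation constant — using the most precisely measurable
property an enzyme has, its catalytic activity. The worked study shipped
with the package is NAD+-dependent glutamate dehydrogenase of *Clostridium
symbiosum*, whose single reactive cysteine (Cys-320) sits in the
coenzyme-binding cleft, together with four engineered coenzyme-binding-site
variants (F238S, P262S, F238S/P262S, D263K).

## The model

Three species are assumed to be at rapid equilibrium before the slow
covalent step: free enzyme E, the protective complex E·Co, and the reactive
complex E·DTNB. Only E·DTNB proceeds, with true first-order rate constant
$j$. Mass balance then gives the observed pseudo-first-order inactivation
constant

$$k_\mathrm{Co} \;=\; \frac{j\,[\mathrm{DTNB}]}
  {K_\mathrm{DTNB}\left(1 + [\mathrm{Co}]/K_d\right) + [\mathrm{DTNB}]},$$

with two informative special cases:

* **No ligand** ($[\mathrm{Co}] = 0$): the saturation law
  $k = j[\mathrm{DTNB}]/(K_\mathrm{DTNB} + [\mathrm{DTNB}])$. A
  double-reciprocal plot of $1/k$ against $1/[\mathrm{DTNB}]$ is linear with
  ordinate intercept $1/j$ and slope $K_\mathrm{DTNB}/j$.
* **Fixed working $[\mathrm{DTNB}]$, graded ligand**: the reciprocal rate is
  affine in ligand concentration,
  $1/k_\mathrm{Co} = \frac{1}{j}\frac{K_\mathrm{DTNB}}{[\mathrm{DTNB}]}
  \frac{[\mathrm{Co}]}{K_d} + \frac{1}{k_\mathrm{max}}$,
  the *protection line*. Its slope yields $K_d$ once $j$ and
  $K_\mathrm{DTNB}$ are known; its intercept must reproduce the unprotected
  rate $k_\mathrm{max}$ at the working DTNB concentration, which the package
  reports as a `consistency_ratio` on every protection fit.

`k_max` is defined here as the saturation law evaluated at the working
DTNB concentration — the only definition consistent with the zero-ligand
limit of the protection line. The non-binding case is carried as an explicit
sentinel (`Kd = Inf`, constructed by `non_binding()`) rather than a large
number, so a flat protection line has slope exactly zero.

Internally all concentrations are stored in molar and converted at the
interface (micromolar for DTNB, millimolar for coenzymes, matching bench
convention). This removes the silent unit-mismatch hazard in the
$K_\mathrm{DTNB}/[\mathrm{DTNB}]$ ratio, and a test asserts that rate
constants are invariant under consistent unit changes.

## Observation modes

Two observables track the same covalent event:

* **activity mode** — residual catalytic activity of timed samples,
  $a(t) = e^{-kt}$;
* **absorbance mode** — the released thionitrobenzoate anion absorbs at
  412 nm ($\varepsilon = 13.6\ \mathrm{mM^{-1}cm^{-1}}$, 1 cm path by
  default), $A(t) = \varepsilon \ell [\mathrm{SH}]_0 (1 - e^{-kt})$.

`compare_modes()` reports the ratio of the two estimates with a
delta-method SE; the modes measuring the same process is an assumption
worth checking whenever both are available. Stoichiometry
(`tnb_released()`) takes a user-supplied subunit concentration rather than
a hard-coded molecular mass.

## Estimation

Stage 1 (`fit_rate_activity`, `fit_rate_absorbance`): activity courses are
fitted by unweighted linear regression of $\log a$ on $t$ — the classical
analysis for this assay — with non-positive values dropped (and counted),
not clamped. Absorbance traces are fitted by Levenberg–Marquardt nonlinear
least squares of the exponential rise, co-estimating the plateau by default
(robust to pipetting error in $[\mathrm{SH}]_0$); fixing the plateau from
the signal model reduces the fit to a log-linear regression and is kept for
stoichiometry checks. $R^2$ is computed on the fitted scale and is
diagnostic only: it never gates a downstream fit.

Stage 2 (`fit_saturation`, `fit_kd`): both stage-2 fits are unweighted
regressions on reciprocal-transformed rates, deliberately matching the
classical graphical analysis despite its known heteroscedasticity; a direct
nonlinear saturation fit is available (`method = "nonlinear"`) and agrees
exactly on noiseless data. Standard errors propagate by the delta method,
treating the protection-line slope SE and the baseline-parameter SEs as
independent (the source study reports only marginal uncertainties);
`kd_bootstrap_se()` provides a parametric-bootstrap cross-check, which the
test suite holds to within a factor of 1.5 of the delta-method value.

Two decision rules are the package's own, since the original analysis never
met the degenerate cases: a protection-line slope not positive by more than
twice its SE returns the non-binding sentinel, and a saturation fit with a
slope indistinguishable from zero is flagged `degenerate_no_saturation`
(constant rates carry no information about $K_\mathrm{DTNB}$). A published
description of the protection plots as reciprocal-vs-reciprocal is
internally inconsistent with the model's prediction that $1/k_\mathrm{Co}$
is linear in $[\mathrm{Co}]$; the package follows the model (and the
figures), regressing $1/k_\mathrm{Co}$ on $[\mathrm{Co}]$.

## The synthetic-data generator

No raw time courses are deposited for this system, so the generator stands
in for the wet lab. It emulates the study's concentration designs: DTNB
titrations at {50, 100, 200, 300, 400, 600} µM for the baseline parameters,
and protection series at a fixed 200 µM DTNB with a graded ligand series
that always includes the zero-ligand course (defaults
$\{0, 0.25, 0.5, 1, 2, 4\} \times K_d$, spanning the informative range of
the protection line). Activity courses take 12 samples over 3 half-lives —
sampling times are not recorded in the source protocol; this choice keeps
the log-linear fit well conditioned without assuming instrumentation the
assay did not have. Absorbance traces are sampled every 10 s over the same
span. One replicate per condition is the default, as replicate counts are
likewise unrecorded.

Noise is multiplicative Gaussian on activity (assay error scales with
signal; default σ = 2 %) and additive Gaussian on absorbance (photometric
error; default σ = 0.002 AU). These scales reproduce fitted-rate relative
SEs of roughly 1 %, in line with the precision the protection method is
valued for. Child seeds are derived from the master seed by stable hashing
of the series identity, so adding or removing a series never perturbs
another's draws, and fixed seeds reproduce values bit for bit.

What the generator does **not** emulate: baseline drift, mixing dead time,
lamp flicker, enzyme denaturation over the incubation, or any departure
from strict first-order decay. Passing recovery tests therefore
demonstrates correctness of the estimation chain under the model's own
assumptions, not robustness to instrument artifacts.

## What the shipped study shows

`gdh_catalog()` carries the published baseline and binding parameters of
the five enzyme variants. The package's central self-check is exact
inversion: a noiseless study generated from the catalog and pushed through
`run_pipeline()` returns every $j$, $K_\mathrm{DTNB}$ and $K_d$ to within
1e-6 relative, with protection-line intercepts reproducing $k_\mathrm{max}$
to 1e-9. Under 2 % multiplicative noise, the median recovered wild-type
NAD+ $K_d$ across 200 seeded replicates stays within 5 % of truth (both
stages refitted per seed). The derived comparative statistics — the
NADPH/NADH discrimination ratio per variant and fold changes against
wild-type, both reported at 2 significant figures to match conventional
rounding — are computed by `build_comparison_table()`.

Problem sizes throughout (6-level grids, 12 points per course, 200-seed
noise studies, 500 bootstrap resamples) were chosen as representative
desk-scale analyses; the full test suite and pipeline run in seconds.

## Limitations

The model assumes a single reactive cysteine, one ligand binding mode,
rapid-equilibrium binding of both competitors, and modifier in large
excess. Cooperative or ternary-complex binding, two-step covalent
chemistry, thiol–disulfide exchange equilibria and pH dependence are out of
scope. Temperature is metadata only. Where a ligand protects through a
nonproductive binding mode, the method reports the overall occupancy
constant — discriminating productive from nonproductive binding requires
orthogonal activity data and is deliberately left to the user.
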