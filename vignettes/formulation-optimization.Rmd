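---
title: "Formulation optimization for microencapsulation: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Formulation optimization for microencapsulation: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(encapr)
```

## The problem

Condensed tannins from quebracho extract can modulate rumen
biohydrogenation, but only if they survive the rumen long enough to act.
Spray-drying the extract into a maltodextrin (MD) / gum arabic (GA) shell
is one route; the formulation question is how much extract to load
(core:shell ratio) and how to blend the shell (MD:GA ratio) so that yield,
entrapment and loading are simultaneously good. `encapr` implements the
full analysis pipeline for that question — designed experiment, response
computation, second-order response-surface models, multi-response
desirability optimization, and in-vitro release-kinetics characterization
— and ships the original study's printed tables as its worked fixture.

## The experimental design

A two-factor central composite design: a 2² factorial at coded ±1, four
axial points, and five center replicates, thirteen runs in all. Both
factors are two-component mass ratios with a fixed total, and are
parameterized by their first coordinate: the core mass with the shell
fixed at 5 (center 1, step 0.5), and the MD mass with MD + GA = 5 (center
2.5, step 0.5). `ccd_design()` generates designs in the canonical order
factorial, axial, center, with the first factor varying fastest — the
order in which such tables are conventionally printed.

Three numerical conventions matter here:

* **Axial distance.** The package uses the rotatable value
  α = 2^(k/4) (1.414 for two factors). The study's fixture stores the
  printed coded values verbatim (±1.414); its narrative text mentions
  ±1.14, which is inconsistent both with the printed design and with
  rotatability, and refitting the published coefficients confirms ±1.414
  is what was run.
* **The MD:GA axial settings.** The fixture's printed actual values for
  the MD:GA axial runs (1.5 and 3.5) correspond to coded ±2 under the
  factor's center and step, while the printed coded values are ±1.414.
  The two cannot both be right. All regression in this package uses the
  printed coded values — they reproduce the published coefficient tables
  — and `validate_design()` flags the actual-value mapping of those two
  runs as inconsistent rather than silently repairing it. Whether the
  axial mixtures were physically prepared at coded ±2 or ±1.414 cannot be
  determined from the published record, so both printed columns are
  preserved as printed.
* **Validator tolerances.** Orthogonality checks run at 10⁻⁸ (they are
  exact in theory), but the coded→actual mapping check uses a 0.01
  tolerance so that printed-table rounding (0.29 for 0.293) is not
  reported alongside the genuine MD:GA mismatch above.

## Encapsulation responses

Yield is recovered powder over solids fed, in percent. Loading capacity
is total minus surface phenolics; since both are assayed in g per 100 g
of powder, the nominal normalization by particle mass is the identity.
Encapsulation efficiency divides the entrapped phenolics by a
*theoretical* phenolic content, which the original study does not define.
The package takes it as the core mass fraction of total solids × 100 —
equivalently, the core extract is treated as 100% phenolics. This is the
only convention that reproduces the printed efficiencies (back-calculated
for the three runs whose inputs allow it: 72.71, 76.61, 70.05 against
printed 72.64, 76.58, 70.05); scaling instead by the extract's assayed
total phenolic content (84.37 g/100 g) does not.

Two internal inconsistencies of the printed response table are carried
explicitly rather than repaired silently:

* **Run 7's yield.** The table prints 39.75 but the accompanying text
  gives 29.75 for that same formulation, and only 29.75 is consistent
  with the published yield regression (the MD:GA linear coefficient refits
  to 5.36 with the correction versus 3.60 without). `quebracho_data()`
  applies the correction by default, keeps the printed value in
  `EY_printed`, and records the flag on the returned table.
* **Run 6's efficiency.** The printed EE (68.03) disagrees by about 1.9
  points with the value implied by run 6's own total and surface
  phenolics; the other twelve runs agree within ±0.07. The fixture stores
  the printed number; the tests pin the discrepancy so it cannot pass
  unnoticed.

Unparseable standard-deviation strings in the printed table are stored as
`NA` with the raw text preserved in an `sd_raw` column. Moisture, water
activity and color are passthrough columns: carried, never modeled.

## Response-surface regression

`fit_quadratic()` fits the full second-order polynomial on coded factors
by ordinary least squares and always reports every term — published
per-response equations often drop non-significant terms, which makes
coefficient tables ambiguous; the full model never is. p-values are
two-sided t tests on residual degrees of freedom, uncorrected (no
correction was applied in the source analysis). Fits use the thirteen
per-run mean responses: with balanced replication, OLS point estimates
from means equal those from replicate-level data, and the published
coefficients are reproduced this way.

Two scale conventions are load-bearing:

* **Tannin content** is regressed in mg/g (the tabulated g/100 g values
  × 10); only on that scale do the published TC coefficients reproduce
  (intercept 98.66 against a center-point mean of 9.87 g/100 g).
* **Efficiency** does *not* reproduce the published EE coefficient column
  from the printed means (refit intercept 73.75 vs published 73.484),
  with no replicate-level data available to resolve it. The EE fit is
  produced like any other; the package's tests assert its internal
  consistency only.

The lack-of-fit ANOVA splits residual variation into pure error, computed
within groups of runs at identical coded settings (the center replicates),
and lack of fit, with F = MS_LOF/MS_PE. One caveat follows from
means-based fitting: pure error estimated from the five center-run
*means* is roughly a third of the replicate-level assay error, so
lack-of-fit p-values computed here are conservative (smaller) relative to
software fitting triplicate-level data, and the published lack-of-fit
p-values are not expected to reproduce from the printed means. The
decomposition itself is exact: SS_residual = SS_LOF + SS_PE to machine
precision, asserted in the tests.

## Desirability optimization

The Derringer–Suich transform maps each fitted response onto [0, 1] and
combines them by a weighted geometric mean, so one unacceptable response
vetoes the compromise. The original study states only that responses were
maximized; the anchors and weights it used are not recorded, so the
package adopts parameter-free defaults and documents them:

* anchors: each response's own fitted minimum and maximum over the search
  region (so every response always attains d = 0 and d = 1 somewhere);
* weights: equal;
* search region: the factorial square [−1, 1]², within which the
  factor settings were actually varied jointly.

The optimizer is deterministic: a dense grid scan (default 201 per axis,
ties broken by first-found lexicographic order) followed by an L-BFGS-B
polish constrained to the region, guaranteed never to return less than
the grid maximum. Under these conventions the single-response LC optimum
lands on the coded corner (+1, −1) — core:shell 1.5:5, MD:GA 2:3 — the
same formulation the original study selected. The study's reported
overall desirability of 0.9 at that point is **not** reproducible from
any parameter-free convention (under min/max anchors the corrected-yield
term is strongly penalized there); the package reports D under its own
documented convention and makes no claim to match that value.

## Release kinetics

In a replaced-aliquot dissolution test (1 mL drawn and replaced from a
50 mL vessel at 0.5, 1, 2, 4, 8, 24 h), analyte removed in earlier draws
must be added back: `volume_correction()` implements the standard
correction Qt_i = C_i + (v/V) Σ_{j<i} C_j. Four laws are fitted in their
linearized forms — the form in which such analyses are conventionally
reported as straight-line equations with R²:

| model            | regression                  | parameters        |
|------------------|-----------------------------|-------------------|
| zero order       | Qt on t                     | k₀, Q₀            |
| first order      | log₁₀Qt on t                | k₁ = −slope, Q₀   |
| Higuchi          | Qt on √t                    | k_H, Q₀           |
| Korsmeyer–Peppas | log Qt on log t             | k_KP, n           |

Numerical choices: the first-order law is fitted exactly as written
(log Qt linear in t), and the signed slope is reported as fitted — for
release data Qt increases, so the printed-form rate constant k₁ = −slope
is typically negative; the convention is stated rather than silently
sign-flipped. The power-law exponent n is log-base invariant. The
Korsmeyer–Peppas fit excludes t = 0 and non-positive Qt; no "first 60% of
release" truncation is applied by default (none was used in the source
analysis) and intercept-free variants of the zero-order and Higuchi lines
are available via `intercept = FALSE`. Models are ranked by the R² of
their linearized fits; all four have two fitted parameters, so ties fall
through to the fixed order zero, first, Higuchi, Korsmeyer–Peppas. A
constant series degenerates gracefully (slope 0, R² undefined → ranked
by model order).

Transport classification from n uses the conventional sphere thresholds —
n ≤ 0.43 Fickian, 0.43 < n < 0.85 anomalous, n ≈ 0.85 Case II (±0.01
band), n > 0.85 Super Case II — with film thresholds (0.5, 1.0)
available. The categories are standard; the numeric cutoffs are this
package's documented choice of the published sphere values.

## Synthetic data: what it emulates and what it does not

`simulate_surface()` draws y = full quadratic + N(0, σ²) at the design
points — the data-generating model the regression assumes — and
`simulate_release()` generates a true cumulative curve from one kinetic
law, inverts the volume correction to per-draw concentrations, and
applies multiplicative Gaussian noise per draw (assays report means ±
SD; Gaussian is the minimal error model consistent with that). Both are
pure functions of their spec: the seed fixes every draw and the caller's
RNG stream is left untouched.

Defaults follow the study conditions: the 13-run design; the 0.5–24 h
sampling grid with 1 mL aliquots from 50 mL. For release-recovery
simulations the package uses k_H = 10 with a burst intercept Q₀ = 15,
the magnitude of the study's own fitted Higuchi intercepts. The Q₀
choice is not cosmetic: a pure square-root curve with Q₀ = 0 *is* an
exact power law (10√t = 10·t^0.5), so the two-parameter Korsmeyer–Peppas
fit ties the Higuchi fit identically and no ranking experiment can favor
the generator. With a realistic burst intercept the laws separate, but
only partially: because R² is invariant to adding a constant, the
zero-order fit's R² on a Higuchi curve (≈ 0.956 on this time grid) does
not depend on Q₀ at all, and the Korsmeyer–Peppas R² approaches 1 as
Q₀ → 0. At 5% measurement noise on six time points the resulting R²
margins (0.02–0.04) are overturned in roughly 10–15% of replicates —
a genuine statement about the discrimination power of R²-ranking on
six-point release curves, which practitioners should keep in mind when a
single experiment "selects" a release law.

What the simulators deliberately do not emulate: spray-drying physics,
particle-size distributions, replicate-level assay error structure
(within-run correlation), pH-dependent shell swelling, or any systematic
deviation from the fitted laws. Passing recovery tests therefore
demonstrates correctness of the estimators under the assumed models, not
validity of those models for any particular real formulation.

## Problem sizes and reproducibility

The packaged analyses are small and deterministic: 13-run refits are
instantaneous; desirability scans use 201×201 grids; recovery studies use
200 seeded release replicates and 500 seeded surface replicates, sizes at
which Monte-Carlo standard errors are a few percent of the quantities
checked. `scripts/acceptance.R --seed N` re-derives every headline number
from scratch; the same seed reproduces the output exactly.

## Known limitations

* Replicate-level (triplicate) responses are not modeled; consequences
  for lack-of-fit p-values are described above.
* The published EE coefficient column and the reported overall
  desirability are not reproducible from the printed record; both are
  documented rather than approximated.
* Release-kinetics selection is by linearized R², as reported in this
  literature — not information criteria on nonlinear fits, which would
  discriminate better but would not correspond to the published analysis.
* No blocking, randomized run order, Box-Behnken or optimal designs; no
  Weibull or Hixson–Crowell release laws.
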