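---
title: "Closed-loop Bayesian optimization of antibody formulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop Bayesian optimization of antibody formulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formubo)
```

## The problem

A therapeutic monoclonal antibody is never dosed as bare protein: it ships
in a formulation whose buffer species, sugars and amino-acid excipients
determine whether the molecule survives storage, shaking and temperature
stress. formubo implements a closed-loop, model-based design strategy for
this problem. Three developability objectives are maximized simultaneously:

* **Tm (°C)** — the unfolding midpoint read from nanoDSF melt curves;
  thermal stability.
* **kD (mL/g)** — the diffusion interaction parameter from DLS dilution
  series; positive values indicate net repulsive protein–protein
  interactions, i.e. colloidal stability.
* **RM (%)** — retained monomer after an agitation stress assay;
  interfacial stability.

The design space has six independent variables: sorbitol (0–550 mM),
arginine (0–250 mM), pH (4.5–7.5) and the relative fractions of aspartic
acid, glutamic acid and HCl in the acid blend used to titrate a fixed
10 mM histidine buffer to the target pH. The acetic acid fraction is
derived (`1 - f_asp - f_glu - f_hcl`), which induces the simplex
constraint; the total osmolality must stay in 100–600 mOsm/kg. Because
the total acid concentration is implied by the target pH rather than
chosen directly, every candidate point must be pushed through an
acid–base speciation model before its feasibility is even known.

## The optimization loop

One campaign iteration is:

1. **Surrogates.** Each objective gets an independent Gaussian-process
   regression on the unit-hypercube design coordinates, with a Matérn 5/2
   kernel, per-dimension length scales, and targets standardized to zero
   mean and unit variance. Length scales, output variance and a noise
   variance are fitted jointly by maximizing the log marginal likelihood
   (multi-restart L-BFGS-B with analytic gradients; 10 restarts by
   default, the extra starts drawn log-uniformly inside the bounds).
   Length-scale bounds are `[0.01, 100]` on the unit cube; the noise
   standard deviation is bounded below at `1e-4` (a variance floor of
   `1e-8`). A noise term is fitted because measurements are triplicate
   averages with real replicate scatter.
2. **Pareto search.** NSGA-II evolves a population on the unit cube,
   maximizing the three posterior means, with a generation size of 100
   over 100 generations in a full-size campaign. Genetic operators are
   the canonical ones: binary tournament on (rank, crowding distance),
   simulated binary crossover (η = 15, p = 0.9) and polynomial mutation
   (η = 20, per-gene probability 1/6). Constraints are handled purely by
   rejection: a crossover/mutation product that violates the simplex or
   osmolality constraint is discarded and the move is attempted again
   (up to a configurable cap), so infeasible points never enter the
   population.
3. **Acquisition.** With probability 0.75 a suggestion takes the
   *exploitation* route: every candidate on the surrogate Pareto front is
   scored by its minimum Euclidean distance to the existing observations
   in variable space and (separately) in standardized objective space;
   the two distances are each normalized by their maximum over the front
   and combined as `0.5 d_obj + 0.5 d_var`; the maximizer is selected
   (ties go to the lowest index). Otherwise the *exploration* route
   minimizes the Steinerberger proximity sum
   `S(x) = Σ_p Π_d (1 − log(2 sin(π |x_d − p_d|)))`
   over explored points `p`, using bounded Nelder–Mead from 20 random
   feasible starts (200 iterations each; infeasible iterates receive a
   large sentinel value, which is equivalent to rejection).
4. **Batching (Kriging believer).** Five suggestions are generated
   greedily: after each pick, every surrogate is augmented with its own
   posterior mean at that point as if it had been measured, and the
   hyperparameters are re-estimated, so later picks in a batch spread
   away from earlier ones.
5. **Measurement and bookkeeping.** The batch is decoded into concrete
   formulations, measured (by a wet lab or the virtual lab), and appended
   to the ledger — the append-only CSV that is the single source of truth
   for a campaign. A campaign starts from 13 initialization points drawn
   uniformly on the cube and rejection-sampled to feasibility; with four
   batched iterations the ledger holds 13 + 4×5 = 33 experiments.

## The chemistry layer

Feasibility checking requires reconstructing per-acid concentrations
from (pH, fractions). The speciation model uses tabulated pKa ladders
(histidine 1.82/6.04/9.17, arginine 2.03/9.00/12.10, aspartic acid
1.99/3.90/9.90, glutamic acid 2.10/4.07/9.47, acetic acid 4.76; HCl fully
dissociated; Kw = 1e−14) — standard handbook values at 25 °C, shipped as
an editable table (`species_db()`) so an alternative set is a data edit,
not a code change. Histidine and arginine enter as free bases titrated by
the added acids; no pre-formed salts are assumed.

Two solver design choices matter:

* The **forward problem** (composition → pH) is a root find on the
  charge-balance residual, which is strictly decreasing in pH; a
  vectorized bisection on `[0, 14]` (60 halvings) solves whole
  populations of compositions at once to far below the 1e−10 M residual
  tolerance.
* The **inverse problem** (target pH → total acid) needs no iteration at
  all: at fixed pH the alpha fractions — and hence the average charge of
  every component — are constants, so the charge-balance residual is
  *linear* in the total acid concentration and the solution is a single
  division. A negative solution means the target pH lies above the pH of
  the acid-free base mixture; a solution above the 2 M cap is likewise
  reported infeasible. Tests verify the closed form against a brute-force
  1 µM grid search. This exactness also removes what would otherwise be
  the dominant cost of the whole loop, since every genetic move must be
  pushed through this solve.

Osmolality uses a deliberately simple ideal model: the sum of analytical
solute particles (sorbitol, histidine, arginine, each weak acid counted
once) plus the chloride delivered by HCl, identifying molar and molal
scales and ignoring osmotic coefficients. The model lives behind a single
function (`estimate_osmolality()`) so a nonideal variant can be swapped
in without touching anything else. Activity coefficients, ionic-strength
corrections to pKa and temperature dependence are out of scope.

## Measurement models

* `tm_from_curve()` smooths the 350/330 nm fluorescence ratio with a
  Savitzky–Golay filter (window 9 points, order 3), takes the
  central-difference derivative and returns the temperature of the global
  derivative maximum refined by a three-point parabola. A derivative
  maximum below `min_slope` (default 1e−3 per °C) is reported as "no
  transition" rather than returning a meaningless temperature. Only
  single-transition curves are in scope; how multi-domain unfolding
  should be disambiguated is instrument-software territory.
* `fit_kd()` is ordinary least squares of `D = D0 (1 + kD c)`:
  `D0` is the intercept and `kD` the slope/intercept ratio, converted
  from mL/mg to the conventional mL/g. Replicate series are fitted
  separately and averaged. A non-positive intercept makes `kD` undefined
  and is an error, not a number.
* `retained_monomer()` is the supernatant fraction in percent,
  `100 − (c_ref − c_shaken)/c_ref × 100`. Values above 100% (shaken
  concentration above the reference) are returned as-is and left to the
  caller, since silently clipping would hide assay problems.

## The virtual laboratory

`virtual_lab()` exists so that full campaigns are testable without a wet
lab. Its deterministic ground-truth surfaces are *invented test
fixtures* with the qualitative structure expected of this system — they
are not fitted to any experimental data:

* Tm rises with pH and with sorbitol (saturating), and falls mildly with
  arginine;
* kD falls with pH (the classic thermal/colloidal trade-off: far below
  the isoelectric point the protein is more charged and more repulsive,
  but less thermally stable), peaks at an intermediate sorbitol
  concentration near 324 mM, and falls strongly and linearly with
  arginine (−0.2 mL/g per mM);
* RM saturates in a 90–100% plateau for favorable compositions.

The coefficients are chosen once so that the best achievable values land
near plausible optimized magnitudes for a stable IgG (kD in the mid-40s
mL/g, Tm around 72 °C). Simulated measurements go through the *full*
assay pipeline: replicate logistic melt curves (replicate-to-replicate
center shifts, sd 0.2 °C), DLS dilution series (replicate kD shifts, sd
1.5 mL/g, plus 0.5% relative noise on individual readings) and agitation
supernatant concentrations (sd 2 percentage points), three replicates
each, then `tm_from_curve()`/`fit_kd()`/`retained_monomer()`. Passing
tests therefore exercise the estimators, not just the surfaces. What the
virtual lab does *not* emulate: mechanistic biophysics (electrostatics,
preferential exclusion), assay artifacts such as multi-transition melts
or non-linear DLS series, and any coupling between objectives beyond the
shared inputs — so a passing campaign demonstrates that the loop
optimizes *a* landscape of realistic shape, not that it reproduces any
particular molecule.

## Diagnostics

* `hypervolume_trace()` standardizes all measured objectives over the
  full ledger, fixes the reference point at the per-objective
  standardized minimum minus 0.5, and reports the dominated hypervolume
  of everything measured up to each iteration. With the reference fixed,
  the trace is non-decreasing by construction; its *shape* (how fast it
  saturates) is the convergence diagnostic. An exact sweep algorithm is
  used (at most three objectives); absolute values depend on the
  reference-point convention and are comparable only within a report.
* `prediction_mae_trace()` refits the surrogates on iterations `< t` and
  scores their posterior means against iteration `t`'s measurements —
  an honest out-of-sample view of model quality in raw units.
* `spearman_table()` screens excipient–objective monotone associations
  via mid-rank Spearman correlations.

## Numerical choices and degenerate inputs

Tie-breaks are deterministic everywhere (lowest index). Objectives with
zero variance are fitted with a floored standardization (and a warning)
and predict their constant mean. The Steinerberger kernel is singular
when any coordinate coincides with an explored point's coordinate; such
evaluations return a large sentinel (1e18), which both protects the
optimizer and acts as rejection. Duplicate batch picks are perturbed once
(±1e−3) and then raise an error. All randomness flows through R's global
RNG; a campaign seeded once is reproducible to the byte, and the RNG
state is carried in the campaign object so resumed runs continue the
stream rather than replaying it.

## Problem sizes used by the test-suite

The packaged tests run a full closed-loop campaign at a reduced NSGA-II
setting (generation size 40, 40 generations) with the default 13 + 4×5
design, which preserves the qualitative behavior (hypervolume growth,
arginine elimination, the pH trade-off) at a fraction of the cost of the
full 100×100 search; property tests use 1D/2D toys where analytic
oracles exist. These sizes are the package's testing choices — production
campaigns should use the defaults.

## Known limitations

* The speciation model is ideal-dilute; at the upper end of the ionic
  content the true feasibility boundary will differ somewhat from the
  computed one.
* Exact hypervolume is implemented for up to three objectives only.
* The GP surrogates are independent per objective; correlated-objective
  models and heteroscedastic noise are out of scope.
* Exploration minimizes a specific low-discrepancy energy; other
  space-filling criteria would need a one-line kernel swap in
  `steinerberger_sum()`.

## A minimal session

```{r example, eval = FALSE}
cfg <- campaign_config(
  acquisition = acquisition_config(pop = 40, gens = 40),
  seed = 1
)
st <- simulate_campaign(cfg, virtual_lab(), iterations = 4)
glance(st)
hypervolume_trace(st)
autoplot(st, "hypervolume")
spearman_table(st)
```
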