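# formubo

Constrained multiobjective Bayesian optimization of protein formulations.

Therapeutic antibodies are shipped in carefully balanced excipient
mixtures, and finding a good mixture by one-factor-at-a-time screening is
slow: stability objectives trade off against each other, and the feasible
region is bounded by chemistry (the acid blend that sets the pH also sets
the osmolality). formubo is a closed-loop experimental-design toolkit for
this problem, aimed at formulation scientists and at anyone who wants a
fully testable, self-contained reference implementation of constrained
batch multiobjective Bayesian optimization.

## What it does

Three developability objectives are maximized jointly:

| objective | assay | meaning |
|---|---|---|
| *T*ₘ (°C) | nanoDSF melt curve, max of d(F350/F330)/dT | thermal stability |
| *k*D (mL/g) | DLS dilution series, slope/intercept of *D* = *D*₀(1 + *k*D·*c*) | colloidal stability |
| RM (%) | agitation stress, 100 − (c_ref − c_shaken)/c_ref·100 | interfacial stability |

over six design variables — sorbitol (0–550 mM), arginine (0–250 mM),
pH (4.5–7.5) and the aspartate/glutamate/HCl fractions of the acid blend
that titrates a fixed 10 mM histidine buffer (the acetic acid fraction is
derived) — subject to the acid-fraction simplex and a 100–600 mOsm/kg
osmolality window.

Per iteration: independent Matérn-5/2 Gaussian-process surrogates (MLE
hyperparameters, standardized targets) → NSGA-II search of the surrogate
Pareto front under rejection-based constraint handling → a 75%/25%
exploit/explore acquisition rule (combined variable/objective-space
distance on the front; Steinerberger-sum minimization for exploration) →
a greedy Kriging-believer batch of five suggestions → measurement →
ledger. A campaign starts from 13 feasible uniform points, so four
iterations cost 33 experiments. An acid–base speciation solver
reconstructs per-acid concentrations from (pH, fractions) in closed form,
and a synthetic "virtual lab" with realistic response surfaces and
replicate noise makes whole campaigns runnable and testable without a wet
lab.

## Worked example

A full closed-loop campaign on the virtual lab (reduced NSGA-II settings;
about 20 s):

```r
library(formubo)

cfg <- campaign_config(
  acquisition = acquisition_config(pop = 40, gens = 40),
  seed = 1
)
st <- simulate_campaign(cfg, virtual_lab(), iterations = 4)
glance(st)
#> # A tibble: 1 × 6
#>   n_obs iterations best_tm_C best_kd_mL_per_g best_rm_pct hypervolume
#>   <int>      <int>     <dbl>            <dbl>       <dbl>       <dbl>
#> 1    33          4      72.0             40.6        100.        44.2

hypervolume_trace(st)
#> # A tibble: 5 × 3
#>   iteration n_observations hypervolume
#>       <int>          <int>       <dbl>
#> 1         0             13        32.8
#> 2         1             18        40.1
#> 3         2             23        41.7
#> 4         3             28        42.4
#> 5         4             33        44.2
```

The 33-row ledger (`tidy(st)`) holds every formulation with its decoded
chemistry and measured objectives. The hypervolume trace — the dominated
volume in standardized objective space against a fixed reference point —
grows monotonically and saturates as the Pareto front fills in. Rank
correlations recover the structure of the (synthetic) landscape:

```r
spearman_table(st) |> dplyr::filter(variable %in% c("arginine_mM", "pH"))
#> # A tibble: 6 × 3
#>   variable    objective      rho
#>   <chr>       <chr>        <dbl>
#> 1 arginine_mM tm_C        -0.424
#> 2 arginine_mM kd_mL_per_g -0.558
#> 3 arginine_mM rm_pct      -0.831
#> 4 pH          tm_C         0.807
#> 5 pH          kd_mL_per_g -0.810
#> 6 pH          rm_pct      -0.125
```

pH pulls thermal and colloidal stability in opposite directions (+0.81
vs −0.81) — the central trade-off of the problem — and arginine is
detrimental across the board, so the optimized iterations abandon it:
the best colloidal-stability formulation found is 434 mM sorbitol,
0.1 mM arginine, pH 4.55 (all-acetate blend, 458 mOsm/kg) with
*k*D = 40.6 mL/g. `autoplot(st, "hypervolume")`, `autoplot(st,
"objectives")` and `autoplot(st, "mae")` plot the diagnostics;
`prediction_mae_trace(st)` reports out-of-sample surrogate error per
iteration.

Campaigns can also be driven file-by-file (suggestion CSVs in, measured
CSVs back) through the CLI at `inst/cli/formubo.R`, with subcommands
`init`, `suggest`, `record`, `report`, `simulate` and
`simulate-campaign`, configured by a small YAML file
(`read_campaign_config()`).

See the vignette (`vignettes/formulation-optimization.Rmd`) for the
models, the chemistry layer, all tunable parameters and the design
decisions.

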