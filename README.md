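# radassay

Analysis chain for the three classical quantitative assays of cellular
radiobiology, aimed at labs characterising the radiation response of
cultured cells (stem cells, tumour lines, fibroblasts):

1. **Cell-cycle analysis** of propidium-iodide DNA-content histograms:
   pulse width-vs-area doublet gating, then deconvolution of the histogram
   into five Gaussian subpopulations — sub-G1 (apoptotic), G1, S, G2,
   polyploid — by bounded nonlinear least squares, and G2-arrest kinetics
   over a post-irradiation time course.
2. **Clonogenic survival**: plating efficiency, surviving fractions and the
   single-hit multi-target model
   `S(D) = 1 − (1 − exp(−D/D0))^n`, reporting `D0` (the reciprocal of the
   ln-survival slope in the linear range), the extrapolation number `n` and
   the quasi-threshold (shoulder) dose `Dq = D0·ln n`.
3. **MTT viability** from 96-well OD plates:
   `viability(%) = (OD_treated − OD_blank)/(OD_untreated − OD_blank) × 100`,
   pooled across experiments, with flagging of doses at the ~20% limit of
   quantification.

A seeded synthetic-data module (`cellcycle_truth()` / `survival_truth()` /
`viability_truth()` plus `simulate_*()`) generates event-level cytometry
data, colony-count tables, OD plates and arrest time courses with the
statistical structure each stage assumes, so every fit can be validated
against a known ground truth without instrument files.

## Worked example

```r
library(radassay)

## clonogenic survival: simulate the classic design (6 dishes/dose x 3
## experiments, ~50 colonies/dish) and fit the multi-target model
counts <- simulate_colony_counts(survival_truth(), seed = 42)
pe <- plating_efficiency(counts)
fit <- fit_multitarget(survival_fraction(counts, pe$pe))
fit
#> Single-hit multi-target fit (linear stage primary)
#>   D0 = 1.472 Gy, n = 1.250, Dq = 0.329 Gy (R^2 = 0.9998)
#>   linear range: 1, 2, 4, 6, 8, 10 Gy
#>   nonlinear refinement: D0 = 1.484 Gy, n = 1.322, Dq = 0.414 Gy
predict_survival(fit, 4)
#> [1] 0.082
```

`D0 ≈ 1.47 Gy` recovers the generating value 1.45 Gy (normal mammalian
radiosensitivity range); the small `Dq` is a narrow survival-curve
shoulder, i.e. little sublethal-damage repair capacity; roughly 8% of cells
survive 4 Gy.

```r
## cell-cycle fractions from 2e4 simulated events with 5% doublets
truth <- cellcycle_truth(c(subG1 = 0.03, G1 = 0.34, S = 0.25, G2 = 0.36,
                           polyploid = 0.02), doublet_fraction = 0.05)
events <- simulate_flow_events(truth, 20000, seed = 42)
round(100 * events_to_fractions(events), 1)
#>     subG1        G1         S        G2 polyploid
#>       3.1      34.0      25.2      35.8       1.9
```

Each recovered phase fraction lands within a few tenths of a percentage
point of the generating mixture.

`run_pipeline(config)` binds the stages into one seeded, reproducible JSON
report; `radassay_cli()` (wrapped by `inst/exec/radassay`) exposes
`simulate`, `cellcycle-fit`, `cfa-fit`, `mtt` and `report` subcommands over
the CSV schemas documented in `?read_flow_events`, `?read_colony_counts`
and `?read_od_table`.

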