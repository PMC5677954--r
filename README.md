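# osteoscale

A multiscale systems model of osteoblastic differentiation of bone marrow
stromal cells (BMSCs) under timed BMP-2 / IGF-1 delivery, for computational
biologists studying growth-factor scheduling in bone regeneration.

The package couples two ODE systems:

* **Molecular scale** — mass-action signaling. For each protein *M* with
  activators *pA<sub>j</sub>* and inhibitors *I<sub>j</sub>*:

  d[pM]/dt = Σ<sub>j</sub> a<sub>j</sub>[pA<sub>j</sub>][M] −
  Σ<sub>j</sub> d<sub>j</sub>[I<sub>j</sub>][pM],  with [M] = C<sub>M</sub> − [pM]

  The canonical network (BMP-2 → TAK1/p38 and SMAD1/5 → Runx2; IGF-1 →
  Ras/MAPK and PI3K/Akt branches → β-catenin, osterix, proliferation; ERK ⊣
  SMAD1/5 cross-talk) has exactly 20 dynamic species, 16 conservation
  relations (36 variables) and 37 rate parameters.

* **Cellular scale** — a four-compartment lineage model (BMSC,
  preosteoblast, osteoblast, non-osteoblastic cells) with time-dependent
  proliferation/differentiation/exit rates, modulated by
  transcription-factor readouts of the signaling model during each cytokine's
  effective window *t<sub>p</sub>*.

Around the model: MCMC calibration of kinetic rates against RPPA-like
phospho-protein time courses, least-squares calibration of lineage rates
against dsDNA/ARS observables, global sensitivity analysis (LHS + PRCC and
eFAST first/total-order indices), an in silico grid screen over 49 delivery
schedules, and a seed-reproducible synthetic-data generator emulating the six
experimental treatment scenarios (control, I1, B1, I1B1, I1B4, B1I4 — letter
= cytokine, digit = delivery day).

## Worked example

```r
library(osteoscale)

net <- build_canonical_network()
validate_network(net)
#> character(0)                       # all structural invariants hold

kp <- default_kinetic_params()       # 37 ground-truth rates
lp <- default_lineage_params()

# simulate the optimal scenario: BMP-2 at day 1, IGF-1 at day 4
sch <- treatment_schedule(c("BMP2", "IGF1"), c(1, 4))
run <- simulate_scenario(net, kp, lp, sch)
run$tf
#>   cytokine day dose     Runx2   osterix  bcatenin proliferative
#> 1     BMP2   1   50 0.5819066 0.0000000 0.2000001     0.0000000
#> 2     IGF1   4   50 0.3464576 0.4832472 0.3585744     0.5574296

ctrl <- simulate_scenario(net, kp, lp, treatment_schedule())
observables(run$lineage, oba_day = 29, control = ctrl$lineage)$oba_norm
#> [1] 16.53305                       # ~17x the control osteoblast mass

# screen all 49 delivery schedules
g <- run_grid(net, kp, lp)
g$optimum
#> day_B day_I
#>     1     4                        # BMP-2 day 1, IGF-1 day 4: interval 3
```

The per-event TF readouts show the mechanism: the day-1 BMP-2 delivery
activates Runx2 (0.58, undisturbed because IGF-1 arrives only after the
BMP-2 readout window closes) and commits BMSCs to the preosteoblast fate;
the day-4 IGF-1 delivery then drives maturation and expansion through
β-catenin (0.36) and the proliferative program (0.56). Delivering IGF-1
earlier pushes the ERK-mediated SMAD1/5 suppression into the BMP-2 window
and blunts differentiation; delivering it later wastes preosteoblasts,
which slowly exit the lineage.

Calibration against synthetic data with known truth:

```r
ds <- generate_synthetic(seed = 1, noise_cv = 0)   # zero-noise dataset
fit <- fit_cellular(ds$dsdna, ds$ars, ds$tf, scenario_table())
coef(fit)
#>    b_1    i_3 D0_MSC D0_OBp
#>   0.65   0.06   0.01  0.015                      # exact recovery
```

## Pipeline

`run_pipeline()` (or the `inst/exec/osteoscale` wrapper) chains the stages
`synth → fit_molecular → fit_cellular → simulate → gsa → screen` from a
YAML/JSON config, writing CSV/JSON products and a manifest with seeds and a
config hash; identical configs reproduce identical outputs.
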