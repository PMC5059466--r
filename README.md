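# atnsim — dynamic allometric trophic network simulation

`atnsim` is an R package for simulating **body-mass-structured food webs**
and measuring how ecosystem functions scale with animal diversity. It is
aimed at community ecologists studying biodiversity–ecosystem-functioning
(BEF) relationships in multi-trophic systems, where experiments cannot vary
animal richness over a wide, controlled gradient.

Species are defined by body mass alone. Mass sets

* **who eats whom** — a Ricker success curve
  `L = [(m_i / (m_j R_opt)) e^(1 − m_i/(m_j R_opt))]^γ` of the
  consumer–resource mass ratio (optimum `R_opt = 100`, width `γ = 2`;
  links with `L < 0.01` are pruned);
* **how fast** — a multi-prey Beddington–DeAngelis functional response
  with Hill exponent `1 + q`,
  `F_ij = ω_i b_ij R_j^(1+q) / (m_i [1 + c A_i + ω_i Σ_k b_ik h_ik R_k^(1+q)])`,
  with allometric capture coefficients `b_ij = b0 m_i^βi m_j^βj L_ij` and
  handling times `h_ij = h0 m_i^ηi m_j^ηj`;
* **at what cost** — per-biomass metabolism `x m^(−1/4)`
  (`x_A = 0.314`, `x_P = 0.138`).

Plants compete for two shared nutrients under Liebig's minimum law; animals
eat plants (assimilation `e_P = 0.45`) and each other (`e_A = 0.85`). Each
replicate community is integrated to `t = 150,000` with a stiff implicit
solver (3-stage Radau IIA, tolerances `1e-10`) and an extinction threshold
of `1e-6`, then summarised over a 10,000-time-unit stationary window by six
ecosystem functions: biomass stocks `A`, `P`, gross flows `F_P` (herbivory)
and `F_A` (intraguild predation), and metabolic losses `X_A`, `X_P`. A
richness sweep fits power laws `x = a S_A^α` to each function by log–log
OLS.

## Worked example

```r
library(atnsim)

# one replicate: 15 animal species on 30 plants
res <- simulate_replicate(S_A = 15, S_P = 30, seed = 1,
                          keep_trajectory = TRUE)
res$trajectory
#> Trajectory to t = 150000 (ok), 11401 stored samples
#>   survivors: 2/30 plants, 1/15 animals; 42 extinction events
round(unlist(res$record[c("A_total","P_total","F_P","F_A","X_A","X_P")]), 4)
#> A_total P_total     F_P     F_A     X_A     X_P
#>  0.1300 24.8509  0.0027  0.0000  0.0012  2.5162
```

`A_total = 0.13` and `P_total = 24.9` are the window-mean summed biomasses
of the surviving animal and plant guilds; `F_P = 0.052` biomass units per
unit time flow from plants to animals (before assimilation losses), of
which the animal guild re-circulates `F_A = 0.0015` internally;
`X_A`/`X_P` are the guilds' summed metabolic losses per unit time. A
replicate whose final state contains a surviving plant with no surviving
consumer is flagged `discarded` and excluded from fits.

```r
# a small richness gradient and the diversity–function power laws
recs <- run_sweep(sweep_design(S_A_values = c(10, 30, 50, 70, 90),
                               replicates = 6, master_seed = 20260910),
                  simulation_settings(t_end = 50000, max_steps = 3e5))
fit_power_law(recs, "A_total")
#> A_total = 5.344 * S_A ^ 0.493  (se(alpha) = 0.343, R^2 = 0.090, n = 23)
```

The exponent says how animal biomass scales with animal richness (the
full-scale experiment, 21,461 webs, reports `α = 1.2`; at 23 webs the
estimate is noisy and, under this package's reconstructed defaults,
systematically flatter — see the methods vignette). Desk-scale fits carry
large sampling noise; signs and approximate magnitudes of the six
exponents, and the ~21% discard fraction, are the reproducible content.

A CLI wraps the same operations (`simulate`, `sweep`, `fit`, `fixtures`):

```sh
Rscript inst/cli/atnsim sweep --preset desk --seed 1 --out records.csv
Rscript inst/cli/atnsim fit --records records.csv --out fits.csv
```

## Package layout

| file | contents |
|---|---|
| `R/community.R` | mass sampling, Ricker kernel, web assembly, parameter draws |
| `R/rates.R` | capture, handling, metabolism, Liebig factor, functional response |
| `R/dynamics.R` | reference R implementation of the coupled ODE right-hand side |
| `src/integrate.cpp` | compiled RHS + Radau IIA and Dormand–Prince integrators |
| `R/simulator.R` | initialization, integration, extinction handling, discard rule |
| `R/ecosystem_functions.R` | window-averaged stocks, flows, metabolism, mean masses |
| `R/experiment.R` | richness sweeps, seed policy, power-law fits |
| `R/cli.R`, `inst/cli/atnsim` | command-line interface |
| `vignettes/allometric-food-webs.Rmd` | model, numerics and design choices |

The methods vignette documents parameter provenance (a few constants are
reconstructions of the original study's released code, flagged as such),
the stiff-solver implementation, and every genuinely open design choice.
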