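# waitcea

`waitcea` is an R package for valuing reductions in elective-surgery
waiting times with a cost-utility model designed for data-limited health
systems. It is aimed at health economists and health-technology-assessment
analysts who need to ask: *was a programme that moved patients to earlier
surgery worth what it cost?* — when the only available inputs are a
handful of utilities, event times, per-patient costs and patient counts
per intervention.

## The model

For each surgical cohort, patients follow one of three counterfactual
pathways, each compared against early surgery:

* **RWT** (reduced waiting time): the patient would have had surgery
  anyway, just later;
* **AMS** (avoided missed surgery): the patient would have become
  ineligible and lived unoperated;
* **MA** (mortality averted): the patient would have died while waiting
  (death is assumed to coincide with the scheduled early-surgery date).

Health gains are incremental QALYs: the discounted area between the two
arms' flat health-state curves, decomposed into segments. With utilities
`u_wait`, `u_post_early`, `u_post_delayed` and event times `t_e` (early
surgery), `t_d` (delayed surgery), `t_dc` (counterfactual death),
`t_de` (death after early surgery), and writing
`D(a,b) = ∫_a^b (1+r)^{-t} dt` for discounted exposure at annual rate
`r`, the general (RWT) scenario is

```
A = (u_post_early - u_wait)        * D(t_e,  t_d)    # waiting-time gap
B = (u_post_early - u_post_delayed)* D(t_d,  t_dc)   # post-surgery gap
C =  u_post_early                  * D(t_dc, t_de)   # survival gap
ΔQALY = A + B + C
```

AMS collapses B away (segments V, W with the unoperated utility
`u_missed`); MA keeps only the survival gap (segment X). Incremental
costs are discounted lump sums (early arm minus counterfactual arm) in
three components — direct medical, patient productivity, caregiver
productivity — giving a **societal** total (all three) and a **payer**
total (direct only). Outcomes follow the standard definitions:

```
ICER = Δcost / ΔQALY                      (societal and payer)
BCR  = (ΔQALY × GDP per capita) / Δcost   (societal)
```

with population aggregation by summation before any ratio is formed.
The package also estimates catastrophic health expenditure (CHE) under
the budget-share method (an out-of-pocket price is catastrophic for a
household when it exceeds 10% or 25% — the base case — of the household's
total expenditure), and ships one-way (tornado) and probabilistic
(Monte Carlo, beta/normal/gamma) sensitivity analyses.

Everything is driven by a declarative YAML configuration (see
`inst/extdata/five_surgeries.yaml` for a complete five-surgery example);
no external dataset is required.

## Worked example

```r
library(waitcea)
run <- load_model_run(system.file("extdata", "five_surgeries.yaml",
                                  package = "waitcea"))
res <- evaluate_model_run(run)
res
#> <cea_results: 5 cohorts, discount rate 0.035/yr>
#> composite:
#> <outcome_set>
#>   delta QALYs: 55769.26
#>   delta cost (societal): 971206640  (payer: 1923529693)
#>   ICER societal: 17415 | payer: 34491 | dominance: none
#>   BCR: 3.22 | NMB: 2151872115 | cost-effective at WTP: TRUE
```

Reading: across the five illustrative cohorts the initiative buys 55,769
QALYs at a societal incremental cost of EGP 971m, i.e. EGP 17,415 per
QALY — under the configured willingness-to-pay threshold of EGP 56,000
per QALY, so the composite programme is cost-effective. The payer-only
ICER is higher (34,491) because productivity savings accrue outside the
payer's budget. Per-cohort rows show the heterogeneity:

```r
results_table(res)[, c("unit", "icer_societal", "dominance")]
#>                      unit icer_societal dominance
#> 1      open_heart_surgery       20191.4      none
#> 2 cardiac_catheterization       18938.9      none
#> 3   cochlear_implantation      -39233.0  dominant
#> 4         retinal_surgery       67329.4      none
#> 5       joint_replacement       29313.0      none
#> 6               composite       17414.7      none
```

Cochlear implantation is *dominant* (more QALYs, net societal savings),
while retinal surgery sits above the threshold. Sensitivity and
financial-protection analyses hang off the same run object:

```r
dsa <- run_dsa(run)                      # tornado table
psa <- run_psa(run, n_draws = 5000, seed = 1)
che_table(c(cochlear = 350000),          # out-of-pocket price
          expenditure_distribution(meanlog = log(40000), sdlog = 0.7))
```

A command-line wrapper is installed as `exec/waitcea` with subcommands
`run`, `dsa`, `psa`, `che` and `synth`; each writes deterministic CSVs
plus a manifest into an output directory.

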