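# rbcflow

Stock-and-flow Monte Carlo simulation of a national red blood cell (RBC)
supply chain, built to ask one question: **what happens to the blood
supply if critically ill patients are preferentially transfused with
fresher stored blood?**

Some clinical evidence suggests that high-risk patients — intensive care
(ICU), cardiac surgery (CS), coronary care (CCU) and trauma (TR)
patients — may do better when transfused with RBC units stored only a
short time. Reserving fresh units for them, however, perturbs a supply
chain that normally issues its *oldest* compatible stock first precisely
to avoid outdating. `rbcflow` quantifies that trade-off for analysts of
blood-supply policy.

## The model in brief

Two aggregate banks hold integer inventories of RBC units stratified by
ABO/Rh phenotype and storage age *a* ∈ {1, …, *L*} (shelf life *L* = 42
days by default): a **Collector** receiving donations and a **Hospital**
transfusing patients. Each simulated day: donations arrive, the Hospital
transfuses each recipient class, the Collector resupplies the Hospital
(young units for tomorrow's high-risk demand, then oldest-first up to a
6-day inventory target), and all stock ages one day, expiring past *L*.

Baseline recipients are served oldest-compatible-first (**LO**). Each
high-risk class with threshold age τ ∈ {7, 14, 28} is served by the
three-stage **Threshold Method (TM)**: (1) exact-phenotype units with
*a* ≤ τ, (2) compatible units with *a* ≤ τ, (3) the freshest available
compatible unit regardless of age. Stage-3 issues plus unfilled demand
are **unmet by age**; for a class with total demand *D*,

    % unmet by age = 100 · (units failing the age requirement) / D,
    efficiency     = 100 − % unmet by age.

Performance is reported as annual-average-daily (AAD) statistics across
replicates with 95% CIs: AAD total supply (Collector + Hospital), AAD
expired units, AAD unmet-by-age, and the unit-weighted mean storage age
of transfused blood. Scenarios share initial banks (steady-state
burn-in) and daily draws (common random numbers), so contrasts are
paired. Group shares come from a packaged table of mutually exclusive
high-risk-group combinations; a scenario's recipient classes are sums of
its rows, with overlapping patients assigned the youngest threshold
among their groups. Daily donation/demand streams are synthetic:
negative-binomial day totals thinned to phenotypes by a
Dirichlet-multinomial prevalence model (see the methods vignette,
`vignettes/threshold-method.Rmd`).

## Worked example

```r
library(rbcflow)

tab <- hrg_share_table()
round(union_share(tab, "ICU"), 1)            # 43.2  (% of units, any ICU patient)
round(difference_share(tab, "CS", "ICU"), 1) # 11.7  (CS patients outside the ICU)

builtin_scenario("icu-cs")
#> <rbc_scenario 'icu-cs', shelf life 42 days>
#>      name share method threshold_age
#>   HRG-TM7 43.20    TM7             7
#>  HRG-TM14 11.73   TM14            14
#>       BBR 45.07     LO            NA

cfg  <- simulation_config(horizon = 365, n_replicates = 5,
                          n_steady_state_runs = 5, burn_in_days = 600, seed = 1)
flow <- flow_model(mean_daily_donations = 2160, mean_daily_demand = 2000)
ex   <- run_experiment(list(builtin_scenario("baseline"),
                            builtin_scenario("icu"),
                            builtin_scenario("all-hrgs-tm14")),
                       cfg, flow, prevalence_model())
compare_to_baseline(summarize_experiment(ex))
#>        scenario aad_total_supply pct_reduction_supply aad_expired
#> 1      baseline            88612                  0.0         163
#> 2           icu            60076                 32.2         245
#> 3 all-hrgs-tm14            54768                 38.2         265
#>   aad_unmet_by_age pct_unmet_by_age age_transfused
#> 1              0.0             0.00           42.0
#> 2             27.3             1.37           27.0
#> 3             27.5             1.38           24.3
```

Reading the table: reserving ≤7-day-old blood for the 43.2% of demand
from ICU patients cuts AAD total supply by 32% and raises daily expiries
from 163 to 245 — fresh units are consumed young while old stock outdates
— and the mean age of transfused blood falls from 42 to 27 days. Within
the ICU class itself (`summarize_experiment(ex)[["icu"]]$summary`), 3.2%
(95% CI 3.0–3.3) of demanded units miss the 7-day requirement and the
class's transfused blood averages 7.4 days old, versus 41.9 for the
baseline recipients. Supply and expiry move in opposite directions
across scenarios, the model's central trade-off.

A command-line runner with the built-in scenario names (`baseline`,
`icu`, `cs`, `ccu`, `tr`, `icu-cs`, `all-hrgs-tm7`, `all-hrgs-tm14`,
`bbr-tm7`, `bbr-tm14`, `sl-35` … `sl-7`) writes per-replicate ledgers,
metrics and metadata:

```sh
Rscript scripts/run_simulation.R --scenario baseline,icu --replicates 20 \
    --seed 1 --out results/demo
```

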