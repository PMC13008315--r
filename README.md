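# bbbivive

Blood–brain-barrier (BBB) permeability analysis and in-vitro-to-in-vivo
extrapolation (IVIVE) for bidirectional Transwell assays.

## The problem

In vitro neurotoxicity screens usually expose neurons directly to a test
chemical, ignoring the restrictive blood–brain barrier and therefore
overestimating brain exposure. A Transwell barrier model (e.g. an
endothelial/pericyte/astrocyte triculture on a permeable insert) measures
how fast a compound actually crosses a BBB-like cell layer, in both the
apical→basolateral (AB, blood→brain surrogate) and basolateral→apical
(BA, brain→blood) directions. This package turns the raw assay
timecourses into apparent permeability coefficients and extrapolates them
to predicted brain exposure, for toxicologists and DMPK scientists
triaging environmental chemicals and CNS drugs.

## The model

**Apparent permeability.** Receiver-chamber samples (with buffer
replacement) are first corrected to cumulative transported mass

    M_k = V_receiver · C_k + Σ_{i<k} V_sample · C_i

then the flux dM/dt is fitted by ordinary least squares (free intercept)
and converted to

    Papp = (dM/dt) / (C0 · SA · 60)        [cm/s]

with C0 the initial donor concentration (µM), SA the membrane area (cm²)
and 60 converting minutes to seconds. Replicates are aggregated as mean ±
sample s.d. with QC flags (`SINK_VIOLATION`, `POOR_LINEARITY`,
`CENSORED_FAST`, `BELOW_LOQ`); too-fast compounds are reported as typed
lower bounds ("> 500×10⁻⁶ cm/s"), never as plain numbers.

**Transport metrics.** The efflux ratio `ER = Papp_BA / Papp_AB`
(censoring-aware: a "> 500" AB bound yields an "< x" ER bound), rate
classes (Slow < 1, Moderate 1–12, Fast 12–500, Very fast ≥ 500, ×10⁻⁶
cm/s), and transport calls (Efflux at ER ≥ 2.5, Influx at ER < 0.4).

**IVIVE.** Acute brain uptake is first-order with
`PS = Fub · A_BBB · Papp_AB` (A_BBB = 20 m² adult human),
`k = PS / V_ref` (V_ref = 5 L reference volume, configurable) and
`t½ = ln 2 / k`. Chronic steady state uses
`Css,brain = Css,serum / ER` (Fub deliberately excluded, assuming similar
binding on both sides of the barrier). Bounds propagate end to end.

A two-compartment Transwell simulator (exact exponential interval
solution, multiplicative lognormal measurement noise, sampling with
replacement) provides ground-truth data for every stage.

## Worked example

```r
library(bbbivive)

panel   <- load_reference_panel()              # 48-compound printed panel
results <- bidirectional_results(panel)
results[results$compound_id %in% c("Verapamil", "Mefloquine",
                                   "Belinostat", "Valproic acid"),
        c("compound_id", "er", "er_bound_type", "rate_class",
          "transport_call")]
#>      compound_id          er er_bound_type rate_class transport_call
#> 3      Verapamil 1.754385965         point       Slow         NoBias
#> 8     Mefloquine 7.851063830         point   Moderate         Efflux
#> 32    Belinostat 0.003723404         point       Fast         Influx
#> 47 Valproic acid 0.234000000         upper  Very fast         Influx
```

Mefloquine's ER ≈ 7.85 means active efflux keeps it out of the brain;
belinostat's ER ≈ 0.004 means net influx. Valproic acid's AB permeability
is censored ("> 500×10⁻⁶ cm/s"), so its ER is an upper bound (< 0.234)
— still decisive for an Influx call.

```r
er <- efflux_ratio(18.8e-6, 0.07e-6)   # belinostat AB, BA (cm/s)
css_brain(1, er)                       # steady-state brain conc at 1 µM serum
#> [1] 268.5714
```

At steady state belinostat is predicted to accumulate ~269-fold over
serum. Extrapolating the whole panel with (here synthetic) toxicokinetic
parameters:

```r
tk       <- make_toxkinetic_table(results$compound_id, seed = 1)
exposure <- predict_panel(results, tk)
head(exposure[, c("compound_id", "ps_mL_min", "k_per_s", "t_half_s",
                  "css_brain_uM")], 3)
#>   compound_id  ps_mL_min      k_per_s    t_half_s css_brain_uM
#> 1 DL-Nicotine 0.01399726 4.665752e-08 14856066.16    2.5338468
#> 2   Edaravone 0.13251799 4.417266e-07  1569176.75    1.5075761
#> 3   Verapamil 0.58504532 1.950151e-06   355432.56    0.4512146
```

`ps_mL_min` is the permeability–surface-area clearance into brain,
`t_half_s` the acute uptake half-life (long for these slow, highly bound
compounds), and `css_brain_uM` the chronic steady-state brain
concentration.

## Command line

```sh
inst/cli/bbb-ivive simulate --truth truth.csv --seed 1 --out tc.csv
inst/cli/bbb-ivive estimate --timecourse tc.csv --out est.csv
inst/cli/bbb-ivive metrics  --estimates est.csv --out res.csv
inst/cli/bbb-ivive predict  --results res.csv --toxkinetics tk.csv --out exp.csv
inst/cli/bbb-ivive report   --results res.csv --exposures exp.csv --dir reports
```

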