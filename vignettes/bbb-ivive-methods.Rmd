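---
title: "Methods: Transwell permeability estimation and brain-exposure IVIVE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Transwell permeability estimation and brain-exposure IVIVE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbbivive)
```

# The measurement model

A bidirectional Transwell assay grows a barrier cell layer on a permeable
insert separating an apical chamber (0.5 mL here) from a basolateral
chamber (1.5 mL). Compound is dosed into the donor chamber at C0 and the
receiver chamber is sampled repeatedly; each sample (0.2 mL) is replaced
with blank buffer to keep the volume constant. The apparent permeability
coefficient is

$$P_\mathrm{app} = \frac{dM/dt}{C_0 \cdot SA \cdot 60} \quad [\mathrm{cm/s}]$$

where $dM/dt$ is the flux of transported mass (nmol/min), $C_0$ the
initial donor concentration (µM ≡ nmol/mL), $SA$ the membrane area (cm²)
and 60 converts minutes to seconds. The formula assumes *sink
conditions*: the receiver concentration stays negligible and the donor
concentration stays at $C_0$, so the flux is constant and the cumulative
mass is linear in time. Neither ionization state nor membrane binding is
modelled.

## Sampling-with-replacement correction

Because each withdrawal removes transported mass and the refill dilutes
the receiver, the raw concentration series underestimates transport. The
corrected cumulative mass at timepoint $k$ is

$$M_k = V_r C_k + \sum_{i<k} V_s C_i ,$$

the mass currently in the receiver plus everything previously withdrawn.
This is exact bookkeeping (verified in the tests against a brute-force
event-by-event ledger), independent of any kinetic assumption.

## Flux regression

`fit_flux()` regresses $M_k$ on time by ordinary least squares **with a
free intercept**. The design was open here; we use the intercept because
it absorbs lag time and pre-steady-state transients without biasing the
slope, and we use all six default timepoints (30–180 min) because
discarding points without a stated rule invites cherry-picking. A
degenerate flat series (no flux) is given $r^2 = 1$ by convention — a
flat line fits a no-flux series perfectly and must not trigger the
linearity flag.

## Quality control and censoring

Per replicate (`qc_config()` defaults; all configurable):

* `SINK_VIOLATION` — more than 10% of the initial donor mass transferred
  by the last timepoint. 10% is standard Transwell practice.
* `POOR_LINEARITY` — regression $r^2 < 0.90$.
* `CENSORED_FAST` — the first sample already exceeds 50% of the
  closed-system equilibrium concentration
  $C_\mathrm{eq} = C_0 V_d/(V_d+V_r)$: transport finished before the
  first observation, so the slope is uninformative and the estimate is
  reported as the typed lower bound "> 500×10⁻⁶ cm/s".
* `BELOW_LOQ` — concentrations below a user-supplied limit of
  quantification are replaced by LOQ/2 (a conventional substitution; the
  choice matters little because such series carry almost no flux).

Replicates aggregate as mean ± sample standard deviation (n−1
denominator; a single replicate reports `sd = NA`, never 0) with the
union of flags. Censoring is carried as a typed bound object
(`bound()`), and every downstream operation — efflux ratio, clearance,
rate constant, half-life, steady-state concentration — propagates the
bound direction through monotone transforms instead of degrading it to a
point value.

# Transport metrics

The efflux ratio is $ER = P_\mathrm{app,BA}/P_\mathrm{app,AB}$; values
above 1 indicate net active export toward blood, below 1 net import
toward brain. (The reciprocal convention exists in the literature; this
package fixes BA/AB, under which strong apical efflux gives large ER.)
A lower-bounded AB permeability yields an upper-bounded ER and vice
versa.

Two ER uncertainty rules are provided because neither is canonical: the
`"largest"` rule, $ER\cdot\max(sd_{AB}/P_{AB},\,sd_{BA}/P_{BA})$, matches
the convention used for published error bars; the `"quadrature"` rule
(default for new analyses) is the first-order propagation for an
independent ratio. Both are first-order approximations and can misstate
the spread of a noisy ratio with a small denominator, which is why both
are exposed and recorded.

Rate classes use thresholds 1, 12 and 500 (×10⁻⁶ cm/s) inferred from the
class boundaries of the packaged reference panel (0.75 → Slow vs 2.2 →
Moderate; 10.6 → Moderate vs 12.2 → Fast; "> 500" → Very fast); they are
configurable because they are conventions, not physical constants.
Transport calls are Efflux at ER ≥ 2.5, Influx at ER < 0.4, NoBias
between; a censored ER is classified only when the bound itself decides
the call (e.g. "< 0.234" is Influx), otherwise the call is NoBias with
an explicit indeterminate marker.

# IVIVE

## Acute uptake

Only unbound compound crosses the barrier, so the transport clearance
into brain is $PS = F_{ub} \cdot A_{BBB} \cdot P_\mathrm{app,AB}$
(volume/time; 20 m² = 2×10⁵ cm² of capillary endothelium for an adult
human). A first-order rate constant needs a distribution volume:

$$k = PS / V_\mathrm{ref}, \qquad t_{1/2} = \ln 2 / k .$$

The normalizing volume is the one genuinely open quantity in this chain
— the clearance-to-rate-constant conversion is undefined without it, and
no standard value exists for this use. We default to
$V_\mathrm{ref} = 5$ L (systemic blood volume), surface it prominently in
`physiology_config()`, and record it in the run manifest; reported
half-lives scale linearly with it, so they should be read as relative
rankings, not absolute times. $t_{1/2}$ is infinite at zero
permeability and is serialized as the token `Inf`, which survives the
CSV round-trip.

## Chronic steady state

At steady state influx and efflux balance, giving
$C_{ss,\mathrm{brain}} = C_{ss,\mathrm{serum}} / ER$. $F_{ub}$ is
deliberately **excluded** here, assuming protein binding is similar in
blood and brain; the asymmetry with the acute model (which includes
$F_{ub}$) is intentional and follows the standard convention of this
framework. Consequences the tests pin down: ER = 1 gives brain = serum;
the ER = 2.5 efflux threshold maps to 40% of serum; an ER of 0.004 (the
strongest influx in the panel) gives ~269-fold accumulation. Serum
concentrations come from an external toxicokinetics workflow as a CSV
(µM at a 1 mg/kg/day reference dose) and are linearly rescaled to other
doses; the toxicokinetic model itself is consumed, never re-implemented.

# The synthetic-data generator

`simulate_timecourse()` integrates the two-compartment balance
$dM_r/dt = P\,SA\,(C_d - C_r)$ between sampling events — **including
back-diffusion**, precisely so the data can violate the estimator's sink
assumption and the QC flags can be exercised honestly — with exact
exponential interval solutions (the system is linear, so no ODE solver
is needed). At each event the true concentration is recorded with
multiplicative lognormal noise (CV default 0.05, typical of HPLC
quantification; noise scales with signal, as analytic errors do), then
$V_s C_r$ of mass leaves and buffer restores the volume. The donor is
depleted and never replenished. Defaults state the assumed world: 12 mm
insert (SA 1.12 cm², apical 0.5 mL, basolateral 1.5 mL — standard insert
geometry, since chamber volumes are conventions of the plate format),
C0 = 50 µM (the lower of the two customary dosing levels; recorded per
compound), samples at 30–180 min, triplicates, no lag by default.

What it does **not** emulate: transporter saturation (Michaelis–Menten),
metabolism, adsorption to plastic, cell-layer retention, inter-day
barrier variability. A green recovery test therefore establishes that
the estimator inverts the stated transport-and-sampling model — not that
it is robust to biology the model omits.

## Estimator bias near the sink boundary

A point worth stating exactly, because it limits what "recovery" can
mean. With donor depletion and receiver back-pressure, the cumulative
mass curve relaxes at rate
$\lambda = 60\,P\,SA\,(1/V_d + 1/V_r)$ (min⁻¹). Expanding
$M(t) \approx M_\mathrm{eq}(\lambda t - \lambda^2 t^2/2)$, the OLS slope
over timepoints $t_1..t_n$ underestimates the initial flux by the
relative factor
$\lambda \cdot \mathrm{cov}(t, t^2) / (2\,\mathrm{var}(t))$, which is
$105\,\lambda$ for the default 30–180 min grid. At
$P = 1\times10^{-6}$ cm/s this is ≈1.9% (measured 1.76% with sampling
included) while only ≈2.4% of donor mass has transferred — below the 10%
sink-violation threshold. So there is a narrow regime where no QC flag
fires yet the structural bias exceeds 1%; sub-1% recovery requires
roughly ≲1.3% mass transfer under this geometry. The acceptance suite
asserts the 1% bound as specified and this grid point fails honestly;
the thresholds were left at their stated defaults rather than tuned to
hide it. In the well-within-sink regime (e.g. $0.1\times10^{-6}$ cm/s,
or $5\times10^{-6}$ cm/s with 10 mL chambers) recovery is comfortably
inside 1%, and with 5% CV noise and triplicates the median absolute
relative error across 200 seeds is ≈2%.

A related second-order effect: with symmetric true permeabilities the
AB and BA estimates carry slightly different biases (sampling withdraws
a larger *fraction* of the smaller apical receiver), so a noiseless
symmetric simulation recovers ER ≈ 1.007, not 1.000.

# Numerical and formatting conventions

* Internal units are cm/s, nmol, µM, mL, minutes at the interface and
  seconds for reported kinetics; display scaling (×10⁻⁶ cm/s) happens
  only in report writers and round-trips exactly.
* Negative fitted slopes (pure noise at zero flux) floor at Papp = 0.
* ER display: two decimals, one significant figure below 0.01; machine
  files always carry full precision plus a `bound_type` column.
* Reports are deterministic: sorted by ascending Papp_AB (panel) or
  descending Css,serum (exposure), with every applied threshold logged
  to `run_manifest.json`.

# Known limitations

* Half-life magnitudes are conditional on $V_\mathrm{ref}$ (see above).
* The steady-state relation ignores brain-tissue binding
  ($f_{u,\mathrm{brain}}$), so compounds with similar ER but very
  different tissue binding will differ in unbound brain exposure in ways
  this model cannot see.
* The ER-threshold transport calls inherit the arbitrariness of the
  2.5/0.4 conventions; both thresholds are configurable.
* External permeability comparisons (`compare_external()`) exclude
  censored rows, which biases the comparison toward slower compounds.
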