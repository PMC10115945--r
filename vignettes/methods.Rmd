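---
title: "Virtual-patient modelling and evolutionary dosing optimization in glycopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual-patient modelling and evolutionary dosing optimization in glycopt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycopt)
```

## The problem

In type 2 diabetes (T2DM), hyperglycemia results from insulin resistance
combined with a progressive loss of beta-cell secretory capacity. Glycemic
management aims at the targets recommended by the American Diabetes
Association: plasma glucose between 80 and 130 mg/dL before meals and below
180 mg/dL two hours after meals. When insulin therapy is needed, a clinician
must choose a basal infusion rate and prandial bolus doses — but the
glycemic outcome depends just as strongly on *when* and *how much* the
patient eats. `glycopt` treats the whole day as one optimization problem:
given a fixed total daily carbohydrate intake, find the meal times, meal
sizes, bolus doses and basal rate that keep glucose in range with the least
insulin.

Because such a search needs thousands of candidate days, it runs on a
simulated (virtual) patient rather than a person. The package therefore has
two halves: a physiological glucose–insulin simulator, and an evolutionary
search over dosing plans scored on that simulator.

## The virtual patient

The simulator is a compartmental meal-simulation model of whole-body glucose
and insulin dynamics with 14 states, integrating the standard subsystems of
this model family:

* **Gastrointestinal transit.** Ingested glucose passes through two gastric
  compartments and the gut. The gastric emptying rate is nonlinear in
  stomach content: fast when the stomach is nearly full or nearly empty
  relative to the size of the most recent meal, slow in between (bounds
  `kmax`, `kmin`; shape fractions `b`, `d`). Gut glucose is absorbed at rate
  `kabs` with bioavailability `f = 0.9`, so at most 90 % of an ingested load
  ever reaches plasma.
* **Glucose kinetics.** Two compartments (plasma + rapidly equilibrating,
  and slowly equilibrating tissue) with exchange rates `k1`, `k2` and
  distribution volume `VG` = 1.88 dL/kg.
* **Endogenous glucose production.** Hepatic output
  `EGP = kp1 − kp2·Gp − kp3·Id`, clamped at zero, suppressed both by
  glucose itself and by a twice-delayed insulin signal `Id` (rate `ki`).
  The liver insulin sensitivity `kp3` is one of the six severity
  parameters.
* **Utilization.** A constant insulin-independent uptake `Fcns`
  (mainly brain) plus Michaelis–Menten tissue uptake whose capacity
  `Vm0 + Vmax·X` rises with remote insulin action `X` (rate `p2U`);
  `Vmax` is a severity parameter.
* **Renal excretion.** Linear above a plasma-glucose mass threshold
  (`ke1`, `ke2`), zero below.
* **Insulin secretion and kinetics.** The beta cell responds to the glucose
  level above basal (responsivity `beta`, low-pass filtered at rate
  `alpha`) and to the positive rate of change of glucose (responsivity
  `K`). Secreted insulin enters a portal compartment (release rate `gamma`)
  and then two-compartment plasma/liver kinetics (`m1..m4`).
* **Subcutaneous insulin delivery.** Pump basal infusion and boluses enter
  a two-compartment subcutaneous depot (`kd`, `ka1`, `ka2`) before
  appearing in plasma, so injected insulin acts with a realistic delay.

Excluded on purpose: C-peptide, counter-regulatory hormones (glucagon,
epinephrine, growth hormone), exercise, mixed-macronutrient meals, oral
agents, and pharmacokinetic differences among insulin analogues. The
simulated "meal" is pure glucose.

### Patient severity and basal calibration

A patient is specified by six severity parameters — basal insulin `Ib`,
basal glucose `Gb`, utilization capacity `Vmax`, secretion responsivities
`K` and `beta`, and liver sensitivity `kp3` — plus body mass; the three
built-in presets T2DMA (prediabetes), T2DMB (intermediate) and T2DMC
(advanced) span increasing severity:

```{r presets}
sapply(c("T2DMA", "T2DMB", "T2DMC"), function(nm) {
  p <- patient_preset(nm)
  c(Ib = p$Ib, Gb = p$Gb, Vmax = p$Vmax, K = p$K, beta = p$beta,
    kp3 = p$kp3)
})
```

Three constants are not free: the EGP intercept `kp1`, the basal
utilization capacity `Vm0` and the basal secretion `Sb` are derived in
closed form from the requirement that `(Gb, Ib)` be an exact equilibrium of
the zero-input system. This makes basal calibration structural rather than
fitted: every preset holds its printed basal glucose and insulin to
integrator precision over a day with no meals and no insulin.

```{r basal}
tr <- simulate_day(patient_preset("T2DMB"), empty_plan())
range(tr$glucose_mg_dl)
```

Two unit conventions required a decision. The secretion responsivities
`beta` and `K` are stated as whole-body quantities (pmol/min per mg/dL and
per mg/dL/min) and divided by body mass inside the equations; this reading
gives postprandial secretion fluxes a few-fold above basal, as physiology
requires, whereas a per-kilogram reading would produce absurd insulin
levels. Insulin doses are in pump Units (1 U = 6 nmol), converted internally
to pmol/kg.

### Numerics

The integrator is fixed-step classical Runge–Kutta (RK4) at 1-min
resolution, implemented in C++. All forcings (meal pulses, bolus pulses,
basal infusion) are piecewise constant with edges aligned to the step grid,
so delivered masses integrate exactly. Mass compartments that overshoot
zero are clamped, the largest clamp is tracked, and a clamp beyond
`1e-6` of the state scale aborts the run as an integration instability —
such plans exist in early random populations (enormous boluses driving
glucose to zero) and are assigned worst fitness rather than propagated.
Halving the step changes the daily glucose extrema by well under
0.1 mg/dL, and the trace agrees with an adaptive multistep reference solver
to a few tenths of a mg/dL over a full day; both checks are in the test
suite.

A scored day is simulated as 48 h with the plan repeated on both days, and
only the second day is scored. This removes initial-condition artifacts
while keeping genuine overnight carryover (a late-evening meal still raises
the next morning's glucose).

## Dosing plans

A plan holds up to five meals (start time, grams of glucose), one bolus per
meal delivered 15 min before it, and a constant basal rate. Ingestion is a
20-min square pulse; a bolus is a 1-min square pulse into the subcutaneous
depot (pump boluses are near-instantaneous at this resolution; the depot
kinetics shape the appearance). Meals are confined to a 14-h eating window,
06:00–20:00 by default; a bolus paired with a meal at the window start may
precede the window. Meals under 0.5 g are treated as skipped together with
their bolus, which lets the optimizer effectively use fewer than five
meals. Total daily intake is fixed at 195 g of glucose.

## The evolutionary algorithm

Each candidate day is scored by

$$f = \mu_1 f_L + \mu_2 f_H + \mu_3 I_B + (1 - \mu_1 - \mu_2 - \mu_3)\sum_i D_i$$

with defaults $\mu_1 = 0.35$, $\mu_2 = 0.35$, $\mu_3 = 0.15$, chosen to
prioritize avoiding hypoglycemia over insulin economy. $f_L$ is zero when
the daily glucose minimum lies in 80–100 mg/dL and otherwise the *absolute*
deviation of the minimum from the 90 mg/dL target — the absolute value
matters, since a signed difference would reward dangerous lows. $f_H$ is
zero when the daily maximum stays below 170 mg/dL and otherwise the excess
above it, penalizing hyperglycemic overshoot in proportion. $I_B$ is the
total daily basal dose in U (24 × the pump rate), making the basal and
prandial dose terms commensurate; with these weights, one mg/dL of
glycemic violation trades against about 0.43 U of insulin.

The search loop, with population $N$:

1. draw $N$ random plans within the scenario constraints;
2. simulate and score each;
3. sort by fitness, ties broken by lower total insulin;
4. keep the best 25 % unchanged (elitism — the generation-best fitness is
   provably non-increasing, and the suite asserts it);
5. refill to $N$ with copies of survivors drawn with probability
   proportional to reciprocal fitness, each copy receiving exactly one
   mutation. Plans that have already reached fitness zero are optimal; if
   any exist the selection mass is split uniformly among them (the
   reciprocal law is singular there).

There is no crossover: exchanging meals between two plans would break the
fixed total intake.

**Mutation.** One element class is drawn uniformly among those the scenario
leaves free — meal size, meal time, bolus dose, basal rate — then a slot,
then a relative perturbation $\varepsilon \sim U(-\rho, +\rho)$ with
$\rho = 0.1$. Time, dose and basal mutations are multiplicative,
$x \to x(1+\varepsilon)$, with times clamped to the eating window. A size
mutation moves the mass change $\varepsilon Q_i$ from a randomly chosen
donor meal onto the mutated one (truncated so neither goes negative), which
conserves the daily total *exactly* — a purely multiplicative pair
$Q_i(1+\varepsilon), Q_k(1-\varepsilon)$ would conserve it only when the
two meals happen to be equal. The suite checks conservation to 1e-9
relative through 1000 consecutive mutations.

**Initialization.** Meal times are uniform in the window, sizes are a
normalized uniform split of 195 g, and each insulin element (five boluses,
one basal rate) is independently zero with probability 1/2, otherwise
uniform (boluses up to 15 U, basal up to 2 U/h). The point mass at zero is
structural, not cosmetic: multiplicative mutation can shrink a dose
geometrically but never reach zero, so genuinely insulin-free schedules —
which are the optimum for the prediabetic preset — are reachable only if
the no-insulin corner of dose space is populated from the start.

**Scenarios.** `free` evolves everything; `time_restricted` fixes meal
times at 06:00, 10:00, 13:00, 17:00, 20:00; and
`time_and_quantity_restricted` fixes times at 06:00, 09:00, 12:00, 16:00,
19:00 and sizes at 35, 15, 70, 20, 55 g, leaving only the doses free.
Locked elements are masked out of both initialization and the mutation
draw, so constraint violation is impossible by construction rather than
penalized.

## Scale, determinism and what the tests show

The reference configuration is a population of 10,000 evolved for 600
generations — an overnight run. The test suite and examples use a
scaled-down setting of 200 plans over 100 generations (about half a minute
per run), which is enough to reach the qualitative endpoints: the
prediabetic preset reaches both glycemic targets with (near) zero insulin
under free meal patterning in most seeds, and for the sicker presets the
median insulin requirement rises sharply once both meal times and sizes
are fixed, while fixing times alone at a uniform spread costs little or
nothing — an evenly paced meal schedule is itself a form of glycemic
control. At this scale a minority of seeds converge to local optima in
which a small residual bolus props up the glucose minimum; the full-scale
population is far less prone to this, and the scaled-down checks are
therefore counted over seeds rather than asserted per seed.

Runs are bit-reproducible: all randomness flows from one configured seed
through R's generator, sorts are stable, and re-running a configuration
reproduces the history and best plan exactly. Long runs can checkpoint the
population and generator state every 10 generations.

The virtual patient emulates average whole-body dynamics of three severity
archetypes. It does not emulate day-to-day variability, meal composition,
stress or activity, sensor noise, or inter-individual spread around an
archetype — so a plan that is optimal here is a starting hypothesis for a
clinician, not a prescription, and passing tests certify the algorithmic
contracts, not clinical safety.

## Known limitations

* Meal glucose only; no protein/fat effects on gastric emptying or
  absorption.
* No hypoglycemia counter-regulation, so the simulator is *more*
  permissive of aggressive insulin than a real patient — one reason the
  fitness weights penalize lows heavily.
* The emptying-curve reference size is the most recent meal; two meals in
  very close succession are digested as one effective load.
* Single-day periodic scoring: a plan is assumed to repeat daily.
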