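---
title: "A whole-body model of fluid, electrolyte and acid-base regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A whole-body model of fluid, electrolyte and acid-base regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ikedasim)
```

## What the model is

`ikedasim` implements a classic whole-body regulation model of the
Ikeda/Guyton family: a system of nonlinear ordinary differential and
algebraic equations describing, for a healthy adult male of roughly 55 kg,
the coupled regulation of

* **body fluids** — extracellular (`VEC`), intracellular (`VIC`),
  plasma (`VP`) and interstitial (`VIF`) water, exchanged osmotically;
* **circulation** — reduced to its settled steady state: arterial
  pressure (`PAS`) and cardiac output (`QCO`) as monotone functions of
  plasma volume;
* **respiration** — alveolar CO~2~ and O~2~ stores, a body gas store, and
  a chemoreflex ventilation controller `VI(pH, PCO2, PO2)`;
* **blood buffer chemistry** — Henderson–Hasselbalch, a Hill oxygen
  saturation curve with a Bohr shift, and an in vivo CO~2~ content
  relation with a Haldane correction;
* **electrolytes and metabolites** — Na, K (ECF and ICF), Cl,
  bicarbonate/buffer base, glucose with an insulin axis, urea, mannitol,
  and the minor ions (Ca, Mg, phosphate, organic acids);
* **renal function** — a pressure-sigmoid GFR modulated by extracellular
  volume and hormones, proximal reabsorption under the volume-expansion /
  pressure-diuresis signal `THDF`, distal handling under aldosterone and
  ADH, a tubular maximum for glucose, and urinary acid excretion
  (ammonium, titratable acid, bicarbonate) with urine pH.

The time unit is the minute throughout; 48-hour experiments run to
t = 2880. Variables keep their uppercase field mnemonics (`QWU`, `XCO3`,
`THDF`, ...); `variable_units()` maps each to its unit string.

The model state comprises 32 integrated variables (volumes, solute and gas
stores, hormone effect levels, the ammonium-excretion adaptation, and ten
cumulative intake/output integrals used by the mass-balance audit). All
other quantities — 175 of them — are algebraic, recomputed from the state
at every instant by `snapshot()`, giving a census of 207 named model
variables (`variable_census()`).

## Calibration philosophy: the baseline is an exact fixed point

Every regulated flux is written in normalized form,
`baseline_value × (dimensionless factors that equal 1 at the nominal
operating point)`. The nominal operating point is standard quantitative
physiology scaled to 55 kg: `VEC` 11 l, `VIC` 22 l, plasma Na 142 mEq/l,
pH 7.40 at PCO~2~ 40 mmHg, alveolar ventilation 5 l/min, GFR 100 ml/min,
arterial pressure 100 mmHg, plasma osmolality 287 mOsm/l. Baseline
external inputs are oral water 0.001 l/min, Na 0.12 mEq/min and Cl 0.1328
mEq/min, with zero intravenous water, glucose and inspired CO~2~.

Because intake and excretion balance identically at this point,
`initial_state()` is an exact fixed point of `derivatives()` (residuals at
machine precision), and `equilibrate()` — long forward integration, 14
simulated days by default — confirms rather than finds it. Forward
integration is used instead of root-finding on the full system because the
regulated physiology is built to settle and integration cannot land on an
unphysiological root.

Two balance terms deserve a note. Metabolic water production and
insensible water loss are both set to 3×10⁻⁴ l/min (≈0.43 l/day each), so
at rest urinary water output equals the drinking rate exactly; the two
terms are physiologically of this order and their difference is not
observable in any of the shipped experiments.

## Acid-base formulation

The extracellular acid-base state is carried as a single store, the ECF
*buffer base* (`YBBE`, mEq). At any instant the arterial pH is the root of

$$S\,P_{CO_2}\,10^{\,pH-pK} \;+\; \beta\,(pH-7.4) \;=\; \frac{YBBE}{VEC},$$

with $S = 0.03$, $pK = 6.1$ and a non-bicarbonate buffer value
$\beta = 22$ mEq/l per pH unit. The left side is smooth, convex and
strictly increasing, so a damped Newton iteration (tolerance 10⁻¹⁰,
analytic derivative, bracketed to pH 6–8.5) converges in a handful of
steps; this is the only implicit equation in the model — the remaining
algebra is evaluated in a fixed dependency order with no residual loop.
Bicarbonate `XCO3` then follows from Henderson–Hasselbalch, and the
*standard bicarbonate* `STBC` is the same root evaluated at PCO~2~ 40.

The store changes only through renal net acid excretion versus a fixed
metabolic acid production (0.05 mEq/min). Ammonium excretion adapts slowly
(time constant 600 min, ceiling 3× baseline) toward an exponential
function of acidemia; titratable acid responds immediately within
buffer-limited bounds; bicarbonate reabsorption capacity scales linearly
with PCO~2~, and any spill is additionally capped by a maximal urine
bicarbonate concentration of 40 mEq/l. These four constants jointly set
the compensation kinetics seen in the chronic experiments: 48 h of 10 %
CO~2~ raises bicarbonate from ~28 to ~38 mEq/l and lifts pH from 7.21 to
7.31 (partial compensation — the ammonium ceiling makes full compensation
take ~4–5 days), while 48 h of fixed hyperventilation at 15 l/min drains
bicarbonate monotonically toward ~8 mEq/l with pH returning from 7.71 to
7.41 (near-complete compensation, limited by the spill cap).

## The protocol engine

A `protocol()` is a list of `override()`s (stepwise replacement of an
external input over a window) and `clamp()`s (replacement of an algebraic
variable's defining equation by a constant). Windows are **closed on both
ends** — the instant exactly at a boundary uses the override — matching
the `IF (TIME >= a AND TIME <= b) THEN x ELSE y` idiom in which such
experiments are conventionally written; this convention is tested.
Partially overlapping windows on one target are rejected at construction.

Integration is by `deSolve::lsoda` (variable-step, stiff-capable), with
the run **segmented at every window boundary** and restarted, so step
discontinuities in the inputs are never smoothed across. Default relative
tolerance is 10⁻⁷ with per-state absolute tolerances scaled to baseline
magnitudes; refining to 10⁻⁸ moves 60-min endpoints by well under 0.1 %.
Output is sampled every 0.5 min for runs up to 3 h and every 5 min for
longer runs, always augmented with the event times; the full algebraic
snapshot is evaluated on that grid after integration, under the same
closed/closed input convention. The model is fully deterministic — there
is no randomness anywhere; a `--seed` option exists on the command line
only for interface uniformity.

## The shipped experiments

`build_scenario()` encodes six protocols: a 1-litre oral water load
(`QIN` = 0.2 l/min on [5, 10] min), intravenous 0.9 % saline at the same
rate (`QVIN` = 0.2, `YNIN` = `YCLI` = 154 × 0.2 = 30.8 mEq/min), 5 %
CO~2~ inhalation for 30 min (`FCOI` = 0.05 on [5, 35]), a glucose
tolerance test (`YGLI` = 1000 mg/min on [5, 55]), chronic 10 % CO~2~ for
48 h, and fixed hyperventilation (`VI` clamped to 15 l/min, three times
normal) for 48 h. `davenport_trajectory()` samples (pH, bicarbonate)
pairs — by default at log-spaced times {12, 30, 60, 120, 360, 720, 1440,
2880} min, chosen to resolve the fast respiratory and slow renal phases —
for plotting against the 13.3 / 40.0 / 73.0 mmHg equi-PCO~2~ isopleths
(`davenport_isopleth()`).

## Parameters that matter most

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `GVCO2`, `GVPH` | chemoreflex gains | 0.08 /mmHg, 30 /pH | combined ≈1.2 l/min per mmHg CO~2~; yields VI ≈ 15 under 5 % CO~2~ |
| `GFP50`, `GFSL` | GFR pressure sigmoid | 70, 8 mmHg | filtration collapses below ~50 mmHg, plateaus above ~90 |
| `KTHV`, `KTHP` | THDF volume/pressure exponents | 3, 1.5 | pressure diuresis and volume escape |
| `FWE0`, `KWADH` | water excretion vs ADH | 0.04, 2 | urine flow spans ~0.06–20 ml/min |
| `CGL1–CGL3` | glucose uptake/production | 70, 70, 140 mg/min | vary these to emulate disorders of glucose metabolism |
| `TMG` | glucose tubular maximum | 220 mg/min | glycosuria threshold ≈220 mg/dl at GFR 100 ml/min |
| `BUFB` | non-bicarbonate buffer value | 22 mEq/l/pH | sets the acute CO~2~ titration line |
| `TAUNH4`, `ANH4MX` | ammonium adaptation | 600 min, 0.09 mEq/min | renal compensation partial at 48 h |

Excretion steepness constants (`KKXK` 6, `KCLX` 8, `KNAX` 8, `GALDK` 1.5)
are set so that the fixed point *attracts*: a 1 % perturbation of any
single representative state returns to within 0.1 % of baseline over 48 h
of integration — the regulation property the model exists to exhibit.

## Numerical choices and degenerate inputs

Concentrations and gas pressures are floored at 10⁻⁹ in native units
before logarithms; this never fires on the shipped protocols. Zero or
negative compartment volumes raise an error rather than being clamped —
they indicate an invalid state, not a physiological regime. The renal
glucose spill uses a hard tubular maximum (no splay), so urinary glucose
is exactly zero at baseline. Non-finite derivatives abort the run with the
name of the offending variable. Conservation of water, Na, Cl, K and
glucose is audited by `mass_balance_report()` using cumulative
intake/output integrals carried *as states*, so the audit measures the
equations' conservation to solver tolerance (≈10⁻¹³ relative) rather than
quadrature error.

## Design choices where the design was open

* **Aldosterone and potassium.** Aldosterone in this package *stimulates*
  distal potassium secretion (and retains sodium, and promotes acid
  excretion), the textbook sign; descriptions of models of this family
  occasionally state the opposite sign for potassium, which is
  inconsistent with the potassium dynamics the glucose-tolerance
  experiment must show.
* **Intracellular osmoles.** The ICF impermeant-osmole content is treated
  as a fixed, regulated pool (cell-volume regulation) rather than tracking
  shifted potassium salt; coupling it to the K store osmotically traps
  perturbations in a way real cells avoid by active volume regulation.
* **Plasma partition.** `VP = VP0 + 0.25 (VEC − VEC0)`: a quarter of any
  ECF volume change is borne by plasma, the Starling-equilibrated
  fraction.
* **Clamp scope.** `VI`, `GFR`, `ADH` and `ALD` are clampable; clamping a
  hormone freezes its effect level and suspends its relaxation equation.

## Known limitations

* Whole-body **potassium** turns over in weeks (≈3350 mEq against an
  86 mEq/day intake), so a 1 % perturbation of the intracellular K store
  only halves in 48 h — it decays monotonically but slower than the other
  pools; distal secretion steep enough to clear it in two days would be
  switch-like and unphysiological.
* Thirst is not modelled: water intake is an external input, so sustained
  hypertonic states are corrected only renally.
* The circulation is a settled steady state — no autonomic transients, no
  posture, no short-term baroreflex.
* The RAAS is a reduced transfer function of K, pressure and volume;
  renin and angiotensin are not resolved. No re-calibration for other
  body weights or for females is attempted.
* Simulated experiments reproduce the *directional and steady-state*
  physiology (diuresis surges, CO~2~ kinetics, glycosuria thresholds,
  Davenport trajectories); individual transient magnitudes depend on
  gains that real subjects vary in.

## Problem sizes used in the test suite

The suite equilibrates once (14 simulated days from the nominal point,
which is already the fixed point), runs the four 1–3 h scenarios at 0.5-min
sampling and the two 48-h scenarios at 5-min sampling, and integrates six
48-h single-perturbation runs at 6-h sampling. The whole suite completes
in well under a minute on one core.
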