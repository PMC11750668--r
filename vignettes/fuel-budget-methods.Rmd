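---
title: "Methods: marathon fuel-budget accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marathon fuel-budget accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuelbudget)
```

## The model and its assumptions

`fuelbudget` implements a closed-book substrate budget for two hours of
running at sub-2-hour-marathon intensity (≈21.1 km/hr, >90 % VO~2~max). It
is an accounting model, not a differential one: oxidation rates are taken
as constant over the bout, so every quantity is a product, difference or
ratio of printed parameters. The assumptions it inherits and makes
explicit:

1. **Obligatory CHO flux.** The athlete's carbohydrate oxidation rate
   $r_{CHO}$ (g/min) is fixed by pace; total demand over a bout of length
   $T$ minutes is $C = r_{CHO}\,T$.
2. **A glycogen-depletion threshold.** Pace is assumed to fail once muscle
   glycogen falls below a fraction $f$ of its starting content $G$. The
   model treats $f$ as a free parameter because the value is contested:
   0.32 is used by the model under critique, while the classic depletion
   studies support values nearer 0.20 (their subjects stopped at 10–20 %).
   Both are computed side by side by default.
3. **Liver glucose accounting.** A pool $L$ grams of hepatic glucose is
   oxidized over the bout. Two conventions are implemented because the
   published arithmetic is genuinely ambiguous (see *Design choices*).
4. **Energy-density conversion.** Substrate and energy interconvert through
   fixed densities $e_{CHO}$ and $e_{fat}$ (kJ/g).
5. **Exogenous oxidation is kinetics-limited.** Ingested CHO is not
   oxidized at the ingestion rate; an instantaneous oxidation-rate curve
   rises from zero toward a plateau, and only its time-integral counts.

## Parameters, units, defaults

All internal units are grams, kJ and minutes; per-hour numbers are produced
only at reporting boundaries (this single canon avoids the unit slips that
mixed g/min, g/hr and g/2hr tables invite).

| Parameter | Units | Default | Why |
|---|---|---|---|
| `duration` | min | 120 | a 2-hour race; a profile field, not a constant, so shorter/longer bouts work |
| `thresholds` | fraction | 0.32, 0.20 | the contested value and the depletion-study alternative |
| `liver_mode` | — | `"printed"` | matches the published headline requirements (211/238 g) |
| `e_cho` | kJ/g | 17.3 | back-computed from 88.3 kJ/min at 5.1 g/min CHO |
| `e_fat` | kJ/g | 38.0 | back-computed from 57 kJ/min at 1.5 g/min fat |
| `bin_width` | min | 30 | the bin used when cumulative-oxidation panels are built from rate curves |

The energy densities deserve a flag: no published value for them
accompanies the model parameters, so the defaults are reverse-engineered
from the internally stated rate/energy pairs. They land inside the
physiological ranges (CHO 16–18, fat 37–40 kJ/g) but are chosen for
internal consistency, not from bomb calorimetry; both are overridable in
`energy_constants()`, and `audit_energy_closure()` reports how well any
(profile, constants) pair closes — 2.9 % and 3.6 % for the packaged male
and female fixtures, comfortably inside rounding of the printed inputs.

## Numerical choices

- **Rounding** happens exactly once, at the glycogen remnant, half away
  from zero to whole grams (so 220.8 → 221 and 159.68 → 160). Every
  downstream row consumes the rounded remnant, which is what keeps the
  whole budget in integer grams (612 − 469 = 143, etc.). Half-away rounding
  rather than R's banker's rounding is deliberate: it matches how the
  printed table was evidently produced, and it is the only site where the
  two rules differ.
- **Clamping.** Deficits and scenario requirements clamp at zero rather
  than going negative — a negative exogenous requirement is physiologically
  meaningless — and the clamp is surfaced: `cho_deficit()` attaches a
  `surplus` flag, and the scenario sweep exposes the exact
  `zero_crossing_fat_rate` where the clamp engages.
- **Curve integration.** Tabulated oxidation curves are treated as
  piecewise linear (no interpolation rule is published; linear is the
  least-structured choice). The per-bin amount is the exact time-integral
  of the interpolant over the bin — equivalently the bin mean times the bin
  width — computed by inserting the bin edges as knots and applying the
  trapezoid rule. A consequence worth stating: per-bin amounts sum to the
  trapezoid integral of the whole curve for *any* bin width that divides
  the duration, so refining `bin_width` can only reduce (never increase)
  the distance to that integral, and the 1 % agreement with the analytic
  integral of synthetic ramps measures pure interpolation error.
- **Degenerate inputs** are rejected loudly: zero duration, zero total
  energy in the closure audit, zero ingestion in the efficiency, fractions
  outside [0, 1], curves not starting at 0 or not covering the bout,
  oxidized totals exceeding ingested totals.

## Design choices that were genuinely open

- **Two liver conventions.** The published requirement adds the liver pool
  on top of the deficit ("printed": $X = D + L$), reasoning that high CHO
  ingestion suppresses hepatic output so the liver's share must also come
  from drinks. Under strict accounting this double-counts — if the liver
  gives nothing, the requirement should equal the deficit ($X = D$,
  "strict"). Both are implemented; `printed` is the default because it is
  what the headline 211 g and 238 g requirements use, and the pipeline
  identity `printed − strict = L` is tested so the two can never drift.
- **Scenarios act on the per-hour requirement**, not by re-running the full
  budget. The fat counterfactual is drawn at the requirement level, which
  keeps it orthogonal to the threshold and liver choices: any base rate —
  a computed one (105.5 g/hr) or the upstream model's externally stated 90
  or 106 g/hr — can be swept against the same fat grid.
- **Externally stated requirements are inputs, not outputs.** The 90 and
  106 g/hr rates, and the body-mass-specific table shipped in
  `inst/extdata/mass_specific_reference.csv`, come from the upstream
  differential model and are consumed as reference data, never recomputed.
- **Values the analysis cannot reproduce are left irreproducible.** The
  intermediate 0.5 g/min fat scenario computes to ≈33 g/hr under any
  consistent energy-constant pair, not the published 25 g/hr (whose female
  counterpart also carries a unit typo), and the published 43.6 g male
  shortfall implies an unprinted 90.3 g/hr requirement where 90 g/hr gives
  43 g. The test-suite asserts the *computed* values and asserts that they
  differ from the published ones, rather than tuning constants until they
  agree.

## The synthetic-data generator

`make_ramp_curve()` emulates the one structural feature of measured
exogenous-oxidation curves the analysis depends on: zero oxidation at the
first drink rising with a single time constant toward a plateau,
$r(t) = r_{max}(1 - e^{-t/\tau})$, with optional Gaussian noise (clipped at
zero) and a single integer seed for reproducibility. Defaults
($r_{max} = 1.5$ g/min, $\tau = 30$ min, 5-min sampling over 120 min) put
the plateau at the best observed oxidation rates and the ramp over the
first half hour, consistent with gut-delivery saturation. The closed form
$\int_0^T r = r_{max}(T - \tau(1-e^{-T/\tau}))$ gives the integrator a free
analytic oracle. What the generator does **not** emulate: inter-subject
variability, drink-formulation differences beyond the plateau height,
multi-compartment gut kinetics, or any feedback of ingestion on oxidation —
so passing tests demonstrate correct accounting on curves of the right
shape, not predictive accuracy on any athlete's measured curve. The
packaged curve `jentjens_binavg_synthetic.csv` is likewise synthetic: its
knots are chosen so the 30-min bin means equal the published bin-average
summary (0.30, 0.95, 1.30, 2.02 g/min; 137.1 g total), not digitized from
the original figure.

`make_profile_grid()` scales a reference profile's extensive quantities
linearly with body mass — the simplest defensible allometry over the
narrow elite-runner mass range — purely to exercise downstream code on
plausible parameter spreads.

## Problem sizes

Everything here is desk-scale arithmetic: budgets are exact integer
bookkeeping, scenario sweeps use 0.01 g/min grids (~100–250 points),
property sweeps use a few hundred randomized small instances under fixed
seeds, and curve integration uses 25-point curves with 4–24 bins. The full
test-suite runs in seconds.

## Known limitations

- Constant-rate accounting: no within-race dynamics, pacing variation, or
  progressive substrate shifts.
- Amino-acid and ketone contributions are ignored, as in the source
  analysis.
- The insulin-mediated increase in glycogen use reported under very high
  ingestion rates (~67 % in one study) is noted but not modelled; it would
  only widen the deficits computed here.
- Fat-oxidation capacity is a scenario knob, not a model of diet
  adaptation.
- The depletion threshold is a hard cliff; real performance decrements are
  graded.
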