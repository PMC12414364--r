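---
title: "A daily energy-allowable growth model for dairy calves: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A daily energy-allowable growth model for dairy calves: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calfplanr)
```

## The modelling problem

A preweaning dairy calf draws energy from two streams whose proportions
shift daily: a liquid diet (whole milk or milk replacer) set by the
farmer's allowance plan, and a starter concentrate whose intake — and
whose digestibility — develops with the calf. `calfplanr` simulates this
system one day at a time on an *energy-allowable growth* basis: the day's
metabolizable energy (ME) intake is computed first, maintenance is
subtracted, and whatever net energy remains determines the day's gain.
Growth is therefore an output of nutrient supply, never an input.

## Daily recurrence

Within each day the engine applies, in order: liquid intake → starter
intake → digestibility → energy budget → gain, with body weight (BW)
updated at the end of the day (a forward recurrence; the ordering is a
convention, chosen for reproducibility, as nothing in the equations pins
it down).

**Liquid intake.** All offered litres are consumed, capped at 14 L/d —
the volume ad libitum-fed calves do not exceed. Litres become kg DM via
the solids content (for whole milk, DM fraction × 1.03 kg/L density; for
milk replacer, the declared mixing rate in g powder/L), and DM becomes ME
via the declared energy density (Mcal/kg DM). The cap applies to
consumption: an accelerated plan may offer more, but the calf never drinks
more than 14 L.

**Starter intake.** Predicted from BW, the day's liquid ME intake
(`MEiLD`, Mcal/d) and the time since starter was first offered
(`FPstarter`), with separate temperate (≤ 35 °C) and semitropical
(> 35 °C) regressions; the switch is a strict step at 35 °C. Negative
regression output in the first days of life is clamped to zero. The
negative `FP × MEiLD` interaction in the temperate equation carries the
milk-substitution effect: at a given BW and age, more milk energy means
less starter eaten. Note that *through the simulator* extra milk also
grows the calf, and the positive BW term can dominate, so trajectories of
generously fed calves need not show lower absolute starter intake — the
substitution effect is a fixed-BW statement.

**The starter-exposure clock.** The intake regressions are declared
against time in days since first starter offer, but at day scale the
quadratic term (`13.496 FP²`) makes intake explode within weeks — at
`FP = 50` days it alone contributes ~34 kg/d. The coefficients are only
biologically plausible when the clock runs in weeks, so the package
default is `fp_unit = "weeks"` (days since first offer / 7); the literal
`"days"` reading remains available as a switch for anyone wanting to test
it. Starter is first offered on day 3 of life by default (the common
practice window); the day is configurable because the regressions only
define time *relative to first offer*.

**Digestibility maturation.** A young calf's reticulorumen ferments
solid feed poorly, so starter nutrient digestibilities rise with gut
development, indexed by cumulative starter-NFC intake. The four
digestibilities (CP, fat, NDF, NFC) are linear in
`ln(cumulative NFC, kg)` with pelleted/texturized form effects (TMR is
the indicator baseline) and plateau at 15 kg cumulative NFC — the point
treated as full maturation. Two numerical guards: the log argument is
floored at 0.1 kg (ln → −∞ at zero intake; with the floor, first-days
digestibility is deliberately poor, which is the intended biology), and
each digestibility is clamped into [0, 1] after evaluation since a linear
form can stray outside physical bounds at extreme log values.

**Starter ME.** From the digestible fractions through a summative
digestible-energy convention (DE = 4.2·dNFC·NFC + 4.2·dNDF·NDF +
5.6·dCP·CP + 9.4·dFat·Fat − 0.3 Mcal/kg DM; ME = 1.01·DE − 0.45, clamped
at ≥ 0). These coefficients are a standard dairy-energy convention, stated
here explicitly so the package's contract is self-contained.

**Energy budget and gain.** Maintenance net energy is allometric,
`NEM = 76.9·EBW^0.75` kcal/d preweaning and `97.0·EBW^0.75` kcal/d for
weaned calves, with empty body weight `EBW = 0.91·BW` preweaning and
`0.85·BW` weaned (gut fill differs between the stages). ME for
maintenance is `NEM/k_m`, with `k_m = 0.69` fixed preweaning; after
weaning `k_m` is the cubic-over-ME function of diet energy density,
evaluated at the day's starter ME density and clamped into (0, 1] with a
warning outside the starter-typical ME range (~2.9–3.6 Mcal/kg DM) where
the cubic is meaningful. Energy above maintenance converts to net energy
for gain with efficiency `k_g`, and gain inverts the retention equation
`RE = EBWgain^1.1 · EBW^0.205`. BW change is EBW gain divided by the
stage factor, the only printed EBW↔BW bridge.

## Parameters the equations do not pin down

| Parameter | Default | Unit | Why it exists |
|---|---|---|---|
| `k_g` | 0.60 | fraction | The model family defines net energy available for gain but no printed ME→NE(gain) efficiency accompanies the daily formulation. 0.60 is a conventional calf-diet value; it is a named scenario field so every run can audit or vary it. |
| `fp_unit` | `"weeks"` | — | See the clock discussion above. |
| `first_starter_offer_day` | 3 | d | Starts the `FPstarter` clock. |
| NFC log floor | 0.1 | kg | Keeps the digestibility log finite pre-intake. |
| BW floor | 1 | kg | Keeps allometric terms defined under pathological starvation scenarios; flagged by the negative-balance indicator long before it binds. |

Two sign conventions: `k_g` is applied symmetrically to surpluses and
deficits, and a negative net energy maps to weight loss through the
odd-symmetric extension `−(|NE|/EBW^0.205)^{1/1.1}` (the fractional power
is undefined below zero; the symmetric form is the least-surprising
extension and is flagged per-day in the trajectory).

**Weaning.** The weaned equation set (0.85 factor, 97.0 coefficient,
cubic `k_m`) engages on the first day with zero milk allowance at or after
the declared weaning age and never reverts; a step-down plan that still
delivers milk keeps the preweaning coefficients until then.

**KPI windows.** Dashboard-style KPIs (final BW, ADG, age at 15 kg
cumulative NFC, total feed cost, cost per kg gain) are reported over two
windows — birth to weaning age, and the full horizon — because either
convention is defensible; the 15-kg-NFC age is a trajectory property
reported identically in both rows.

## The assessment model

Observed BW from a multi-study dataset is regressed on simulator
predictions in a linear mixed model with a fixed intercept and slope and a
random study intercept. A treatment-within-study component is first tested
against zero by likelihood ratio on ML fits; because the null pins a
variance on the boundary of its space, the p-value uses the standard
`0.5·χ²(0) + 0.5·χ²(1)` mixture. When non-significant (α = 0.05) the
component is dropped and the final model is refit by REML. Accuracy is
read from Wald tests of intercept = 0 and slope = 1 (normal
approximation); precision from RMSE, R² and Lin's CCC; heterogeneity from
the variance components and `ICC = σ²study/(σ²study + σ²res)`.

Definitional choices, made because more than one reading is defensible:
R² is reported both as the squared correlation of observed with
conditional fitted values (study effects in) and marginally (fixed part
only); RMSE both raw and study-adjusted; CCC both on raw pairs and after
within-study centering. Lin's CCC uses population (divide-by-n) moments.
When observed equals predicted up to exact study shifts the mixed model
would sit on a zero-residual boundary it cannot represent, so the fit
short-circuits to the analytic answer with `degenerate = TRUE` — a
reported diagnostic, never a silent failure.

## The synthetic generator

`generate_synthetic_studies()` emulates the structure of a literature
evaluation dataset: studies (default 27) with treatments nested inside
(default 3), each treatment a constant milk allowance simulated by the
package's own engine, BW observed at up to four ages (28 d, 56 d, weaning,
weaning + 14 d within the ≤ 100 d horizon). Scenario inputs are drawn
uniformly within literature-typical ranges — initial BW 34.1–48.9 kg,
weaning 42–90 d, liquid ME 3.67–5.76 Mcal/kg DM, allowance 1–13.5 L/d —
at a fixed 20 °C, the fallback temperature used when studies do not report
one. Observed BW is the noise-free prediction plus a study-level shift
`N(0, σ²study)` (default SD 9 kg) and residual noise `N(0, σ²res)`
(default SD 7.5 kg), implying an analytic ICC of 81/137.25 ≈ 0.59 —
heterogeneity of the magnitude multi-study calf data shows.

What the generator deliberately does *not* emulate: model misspecification
(observations are the simulator's own predictions plus noise, so slope
recovery tests the statistics, not the biology), treatment-level variance
(zero by construction, making the LRT's behaviour under the null
testable), non-constant milk plans, disease, heat/cold stress, or
between-study differences in starter composition. Passing
parameter-recovery tests therefore demonstrates that the assessment
machinery is calibrated — not that the growth model is unbiased on real
farms.

## Verification strategy and problem sizes

The test suite asserts, among others: the exact algebraic inversion of the
retention equation (round-trip to 1e−9 relative over a gain × EBW grid);
per-day energy conservation `MEI − MEm = NE/k_g` to 1e−9 along simulated
trajectories; bit-identical determinism of the simulator; the
stage-coefficient switch happening in a single day; equivalence of the
fast trajectory path (`simulate_bw()`) with the full record-keeping engine
to the last bit across a scenario grid; and parameter recovery of the
assessment module over 200 synthetic datasets of 27 studies × 3
treatments (mean recovered slope within 0.03 of 1, mean ICC within 0.05 of
the analytic value, 95% CI coverage for the slope within [0.92, 0.98]).
These sizes keep the whole suite comfortably within a few minutes on one
CPU while leaving Monte Carlo error well below the asserted bands.

## Known limitations

- Crude-protein requirements and supply are not modelled; growth is
  energy-allowable only, so protein-limited rations will be over-predicted.
- Ambient temperature acts only through the starter-intake equation
  switch; maintenance is not cold- or heat-adjusted.
- The digestibility plateau is hard at 15 kg cumulative NFC; the
  alternative reading (letting the linear form continue) is not offered.
- The `k_g` default is a convention, not an estimate; conclusions
  sensitive to it should be checked across a plausible range (0.45–0.70).
- Weight loss under energy deficit uses a symmetric inversion that has no
  catabolic-efficiency correction; prolonged-deficit trajectories are
  qualitative.
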