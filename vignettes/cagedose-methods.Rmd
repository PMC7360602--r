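---
title: "Closed-loop home-cage oral dosing: models, estimators and the virtual cage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop home-cage oral dosing: models, estimators and the virtual cage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagedose)
```

## The problem

Chronic oral drug studies in mice need each animal to receive a fixed dose
per kilogram of bodyweight every day, for weeks to months, without the
handling stress of gavage or injection.  A home-cage device can do this by
(i) identifying each group-housed mouse by its RFID transponder when it
enters a small dosing module, (ii) weighing it passively on the load cell
the module rests on, and (iii) letting it trigger 10 µL drops of drug
solution or plain water by licking a spout, with the day's drug-drop count
set from its current bodyweight.  `cagedose` implements that control logic
as an ordinary, hardware-free R library, together with a virtual cage —
simulated mice, load cell, valve and syringe pump — so that every accuracy
claim can be exercised at desk scale.

## The dosing model

One drop carries a fixed drug quantum

$$q = c \cdot v / 1000 \quad [\mu g],$$

with concentration $c$ (µg/mL) and drop volume $v$ (µL); the defaults
(50 µg/mL, 10 µL) give $q = 0.5$ µg.  For a target dose $D$ (mg/kg) and
bodyweight $w$ (g), the daily quota of drug drops is

$$n(w) = \mathrm{round}\!\left(\frac{D\,w}{q}\right),$$

rounded to the nearest integer with ties up.  With the defaults this is
$n(w) = \mathrm{round}(2w)$: two drops per gram per day, one extra drop per
0.5 g gained, and a delivered dose within half a drop quantum of target
($|n q / w - D| \le q/2w$, at most 1% at 25 g) whenever the quota is met.
Quotas are fixed once per day at rollover (midnight by default) from the
previous day's weight estimate; mid-day weight updates never alter the
active quota.  Drug drops are dispensed from the start of the dosing day
until the quota is met — on every drop by default, or on every $n$-th drop
(`drug_interleave_n`) to spread the dose across the day — and water
afterwards.

```{r quota}
cfg <- system_config()
required_drug_drops(25.0, 1, cfg)
required_drug_drops(25.5, 1, cfg)
delivered_dose_mg_per_kg(50, 25.0, cfg)
```

## Daily bodyweight estimation

While a mouse occupies the module the load cell is sampled at 5 Hz, so a
typical day yields thousands of readings mixing the true weight with sensor
noise and large positive transients (climbing, half-entered body, a second
mouse at the entrance).  The daily estimate is the **mode of the rounded
readings** after a two-stage filter:

1. discard readings outside the plausible weight interval
   (`plausible_weight_g`, default [10, 60] g — generous margins around the
   20–45 g range the device was validated on);
2. discard readings more than 3 MAD-scaled deviations from the median of
   the survivors.

Survivors are rounded **half away from zero** to one decimal place and the
most frequent value wins; a tie is broken toward the value nearest the
median of the retained readings, and the smaller value if still
equidistant.  Filtering operates on raw values and rounding happens before
mode counting.  The mode is what makes the estimator robust: it ignores
how much probability mass sits in the tails as long as the central bin
stays the biggest, so the answer is insensitive to the exact transient
rate.  If no reading survives, the previous day's estimate is carried
forward and flagged.

The stability test that gates automatic re-zeroing uses the same sensor:
after a mouse has been gone for 30 s, 20 readings are taken and the cell is
tared only if none deviates more than 0.1 g from their mean.

## The session state machine

The controller is event-driven and clock-agnostic: it consumes a
time-ordered stream of sensor events (tag reads, tag-out transitions,
licks, weight samples, elapsed exit waits) so the identical code can run
against the simulator or real transducers.  Three phases: `IDLE`,
`OCCUPIED` (one confirmed tag; the chamber physically admits one mouse),
`EXIT_WAIT`.  Rules worth calling out:

* every tag-in-range transition triggers a fresh read; the same tag
  confirms silently, a different tag closes the old session implicitly;
* unreadable or unregistered tags are logged (`RFID_FAIL`) and never
  dosed; `max_failed_reads` consecutive failures trigger a `REBOOT` event
  that resets session state only — per-day drop counters persist, so a
  reboot can never double-dose;
* the 10 s post-drop lockout belongs to the spout, not the session: it
  survives exits, re-entries and mouse switches;
* every drop is immediately followed by an `IMAGE` event at the same
  timestamp (the hook for photographic ingestion validation);
* a day rollover during an occupancy splits the weight buffer at the
  boundary (each sample is keyed to its own dosing day) while drop
  accounting joins the new day.

## The virtual cage

**Pump.** Drug drops come from a stepper-driven syringe pump calibrated at
57 steps per 10 µL drop from a 30 mL syringe; realised volume is linear in
steps plus Gaussian noise (sd 0.12 µL) and is conserved against the
syringe fill.

**Valve.** Water drops come from a gravity-fed valve: per-drop CV of 4%
plus a signed multiplicative drift of 2%/day since the last recalibration,
reflecting reservoir-level and line-resistance changes; the simulation
recalibrates every 3 days.

**Load cell.** Occupied readings get movement noise (sd 0.2 g) and, with
probability 0.05, a positive transient offset (mean 15 g, sd 5 g,
truncated at zero) — the regime the outlier filter is built for.  An empty
cell shows only electronic noise (sd 0.02 g); this distinction is what the
tare stability test relies on, and without it the zero offset would drift
unchecked.  The zero point random-walks slowly between tares.

**Mice.** Visits follow an inhomogeneous Poisson process with hourly rates
2.5/h (dark) and 0.883/h (light), scaled by a mean-one lognormal daily
engagement factor (CV 0.25); visit durations are shifted exponentials
(mean 50 s).  Within a visit, effective licks arrive every ~0.7 s, so
drops accrue at close to the lockout rate while the mouse is present.
Daily intake is capped by a lognormal target (mean 2.2 mL, CV 0.35) that
is *paced across the day in proportion to the cumulative visit-rate
profile*; a greedy daily tank would be drained entirely in the early dark
hours and destroy the circadian structure.  True weights follow a linear
growth curve (5 g per 60 days from ~25 g) with 0.25 g daily fluctuations.

These defaults were calibrated, once, to the empirical operating point of
the real system: ~74% of drops in the dark phase, ~30 min of module
occupancy (~9,000 readings) per day, realised consumption of roughly
1.4–1.7 mL/day with 25–37% day-to-day CV, and ~1–1.5% mean day-to-day
weight change.  The intake *target* mean (2.2 mL) deliberately sits above
realised consumption because pacing, finite occupancy and the lockout
truncate it.  Per-visit lick-bout statistics are invented defaults — no
empirical bout data constrains them — and are flagged as such in the
documentation.

All stochastic components draw from independent seeded streams fanned out
from one master seed, so runs are exactly reproducible and a component can
be re-seeded without perturbing the rest; with all noise parameters zero
the whole system is deterministic end to end.

```{r colony, eval = FALSE}
profiles <- c(lapply(1:3, function(i) mouse_profile(sprintf("T%02d", i), "treatment")),
              lapply(1:1, function(i) mouse_profile(sprintf("C%02d", i), "control")))
names(profiles) <- sapply(profiles, `[[`, "rfid_tag")
run <- run_colony(system_config(), profiles, days = 14, seed = 1)
dark_phase_fraction(run$events, system_config())
```

## What the simulation does and does not show

A passing virtual-colony run demonstrates that the *control logic* is
correct under the modelled noise: quotas derived from mode-filtered
weights hit the mg/kg target to quantization accuracy, safety invariants
hold (no drop without a confirmed identity, lockout respected, quota never
exceeded, controls never dosed), and the log formats round-trip.  It does
not validate the *sensor models themselves* against a physical cage: real
load-cell artifacts, RFID read failures and lick microstructure are richer
than their stand-ins here, and the paced-intake model is a behavioural
caricature.  Empirical quantities that depend on real animals (absolute
weighing discrepancy against hand weighing, image-validation rates,
exact consumption volumes) are represented as simulator defaults and
property bounds, not as reproduced measurements.

## Numerical choices and degenerate inputs

* Rounding is half-away-from-zero with a $10^{-9}$ guard against binary
  representation error at exact halves; quota rounding is nearest-with-
  ties-up, which aligns quota steps exactly with 0.5 g boundaries.
* The MAD filter falls back to "keep only values equal to the median"
  when the MAD is zero (more than half the readings identical), which
  keeps constant streams intact.
* Empty reading sets yield an absent estimate and a carried-forward
  weight, never an error; a carried weight with no predecessor leaves the
  quota at zero (no dosing without any weight evidence).
* Event timestamps are logged at millisecond resolution (ISO-8601, UTC);
  parsers are exact inverses of writers so write→parse→write is
  byte-identical.
* Dark phase is the half-open complement of `[lights_on, lights_off)`,
  with schedules spanning midnight handled explicitly.

## Problem sizes

The shipped test suite runs the full virtual colony at 4 mice × 14 days
(the desk-scale analogue of the two-month, 10-mouse study), estimator
recovery over 200 synthetic mouse-days of 3,000–10,000 readings each, and
generator-level circadian checks at 10 mice × 56 days — sizes chosen so
the statistical bounds under test have comfortable margins while a full
run of the suite stays in the minutes range.

## Known limitations

* No pharmacokinetics: the controller targets delivered mass per
  bodyweight, not blood concentration.
* The dosing window (first-to-last drug drop) emerges from the behaviour
  model and runs shorter here (~5–8 h) than the ~10 h observed in vivo
  when intake targets are generous; it is not a calibrated quantity.
* One cage per controller instance; multi-cage fleets are just multiple
  controllers.
* `IMAGE` events carry only a reference string — no image content is
  modelled, and ingestion-validation scoring is out of scope.
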