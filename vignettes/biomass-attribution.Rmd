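---
title: "Partitioning carcass biomass loss among urban scavengers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning carcass biomass loss among urban scavengers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carrionfate)
```

## The problem

A carcass-fate experiment deploys carcasses of known mass in front of
motion-triggered cameras, retrieves and re-weighs them days later, and asks
how the lost mass should be divided among the vertebrate scavengers seen on
camera — and how much was never taken by vertebrates at all. The raw
material is noisy and indirect: a camera gives presence and behaviour, not
grams. `carrionfate` turns the camera stream into a defensible biomass
ledger and, because such experiments rarely come with ground truth,
ships a study generator whose hidden consumption ledger lets every stage be
checked by parameter recovery.

## From frames to observations

The unit of replication is the *observation*: a contiguous interval during
which one species shows one behaviour at one carcass. Frames of the same
species at the same carcass belong to one presence run while inter-frame
gaps stay within `gap_threshold_s`; a change of behaviour starts a new
observation within the run. Two conventions needed fixing where the design
is silent:

* **Gap threshold, default 60 s.** The camera's reset gap is ~0.5 s, so any
  threshold in the range of seconds to a few minutes separates "the animal
  was continuously present" from "the animal came back". 60 s is long
  enough to bridge trigger hiccups and short enough that revisits remain
  distinct events.
* **Single-frame observations have duration zero.** They count toward
  observation tallies but contribute nothing to feeding time. The
  alternative (crediting one frame-interval) would manufacture feeding time
  out of camera cadence.

An observation's duration is last-frame minus first-frame *within its
behaviour segment*; when a run is split by behaviour changes, the segments'
durations do not include the one-frame seams between them. Different
species present simultaneously are independent runs.

## Diel classification

Sunrise and sunset are computed, not fetched: the NOAA closed-form solar
equations (fractional year, equation of time, declination, hour angle at
zenith 90.833°, one fixed-point refinement of the event hour). The test
suite holds them within ±3 minutes of an independent minute-scan oracle
built on a Meeus-style ephemeris. Latitudes beyond ±66.5° are rejected
rather than mishandled. A user-supplied sunrise/sunset table
(`suntimes.csv`) overrides computation for exact replication of analyses
that used a published almanac.

Conventions, chosen once: the day interval is half-open, `[sunrise,
sunset)` — closed at sunrise so an animal arriving exactly at sunrise is
diurnal; an observation's diel class comes from its *start* time, and bouts
spanning sunset are not split. All computation is UTC; local civil time is
display-only (`time_of_day_hours(utc_offset_h = )`).

Activity curves use a *circular* Gaussian kernel density on the 24-h clock:
kernel contributions are wrapped modulo 24 h, so the estimate has no
artificial trough at midnight — which matters here, because fox activity
straddles it. The plain linear estimator (what generic density software
computes on [0, 24]) is available via `wrap = FALSE`, renormalised to unit
mass, for replication. Bandwidth `"auto"` is the normal reference rule on
the linearised sample; the wrapped estimate integrates to 1 within 1e-3 by
construction (wrapping copies at ±24 h, more when the bandwidth is large).

## The attribution model

Let carcass $c$ have initial mass $M_c$ and measured loss
$\ell_c = M_c - \text{final}_c$; a carcass removed whole from camera view
is treated as fully consumed elsewhere, $\ell_c = M_c$.

**Step 1 — non-vertebrate adjustment.** Caged controls and experimental
carcasses with no scavenging behaviour estimate the pooled fraction

$$ f = \frac{\sum (M_c - \text{final}_c)}{\sum M_c} $$

over those carcasses. Each carcass's vertebrate-attributable loss is
$L_c = \max(0,\ \ell_c - f M_c)$. The adjustment is applied per carcass by
default; a `study_wide` option instead rescales so the study-level
non-vertebrate pool is exactly $f \sum M_c$. Per-carcass is the default
because it keeps each carcass's ledger self-contained and never attributes
more than the carcass actually lost.

**Step 2 — allocation by feeding time × body mass.** The two working
assumptions are that biomass intake is proportional to time spent feeding
and to the scavenger's body mass. With $t_{ci}$ the EATING minutes of
species $i$ at carcass $c$ and $m_i$ its body mass (kg), non-removed
carcasses allocate

$$ g_{ci} = L_c \frac{m_i t_{ci}}{\sum_j m_j t_{cj}}. $$

If no species ate ($\sum_j m_j t_{cj} = 0$), the loss stays *unattributed*
rather than being forced onto whoever merely looked. The weights normalise,
so allocations are invariant to rescaling all body masses — the absolute
masses only matter across species.

**Step 3 — removed carcasses and κ.** A removal leaves no proportionality
to lean on: the remover may have eaten nothing in situ (the fox in this
community never does) yet carried everything away. The package calibrates
an in-situ consumption rate

$$ \kappa = \frac{\sum_c L_c S_c}{\sum_c S_c^2}, \qquad
   S_c = \sum_j m_j t_{cj} $$

— least squares through the origin over scavenged, non-removed carcasses
(units: g per kg of scavenger per minute of eating). On a removed carcass,
each in-situ eater is credited $\kappa\, m_i t_{ci}$ (rescaled
proportionally if the sum would exceed $L_c$), and the remover receives the
remainder. This split rule is this package's own construction: the source
designs state only the two proportionality assumptions and the
fully-consumed convention, so the exact original computation for removed
carcasses is not recoverable; a `proportional` fallback (remover treated as
sole consumer of $L_c$) is provided, and neither rule is claimed to be the
original. REMOVING observations contribute no eating minutes; removal
credit flows only through the remover rule.

**Scopes.** Study totals and percentages are reported with three
denominators: all deployed experimental biomass; biomass of scavenged
carcasses only (any EATING/REMOVING observation); and scavenged carcasses
at sites accessible to foxes. Display percentages are rounded half-up to
integers, and a ledger's displayed total is the sum of its rounded
per-species percentages — the convention of printed field ledgers — while
raw values are retained (`pct` vs `pct_display`).

**Conservation.** By construction, per carcass, allocated + unattributed
= $L_c$ exactly, and allocated + unattributed + non-vertebrate = $\ell_c$;
the tests enforce the residual below 1e-9 g.

## The study generator

`default_paperlike_config()` encodes the emulated design: 63 experimental
rat carcasses of 250–300 g (weighed to 1 g) and 10 caged controls, deployed
in the daytime (09:00–15:00 UTC) for 48–96 h across nine urban green-space
sites in three UK towns, three sites rooftop (avian-only); a three-species
community — carrion crow, Eurasian magpie, red fox — with gamma
first-arrival latencies of mean 683 (SD 460), 504 (SD 436) and 755 (SD 278)
minutes; corvid day-activity probabilities 0.98 and 0.996 against 0.092 for
the fox; and mean non-vertebrate loss of 9.6% of initial mass per
deployment.

Where the emulated design reports nothing, the generator's defaults are
realistic choices made once:

| parameter | default | rationale |
|---|---|---|
| attendance probability | crow 0.45, magpie 0.35, fox 0.6 | matches the attended-carcass rates of the emulated community (41/33/59% of accessible carcasses) |
| revisit rate (per h) | crow 0.12, magpie 0.2, fox 0.05 | magpies the most frequent visitors, foxes occasional; yields observation counts in the hundreds per study |
| eating bout mean (min) | crow 10, magpie 8 | bouts of minutes to tens of minutes; exponential durations |
| in-situ eat rate (g/kg/min) | 2 for corvids, 0 for fox | corvid-scale intake; the fox removes whole carcasses instead |
| removal prob. per visit | crow 0.01, magpie 0.008, fox 0.15 | reproduces the observed removal ledger (~12 fox vs 3 + 2 corvid removals per study) |
| background loss SD | 0.03 between carcasses | controls vary; keeps realised fractions in (0, 0.2) |
| frame interval | 1 s | the 0.2 s trigger / 0.5 s reset camera emulated as a regular stream |

Mechanically: each attending species draws a gamma latency; each visit
(first arrival included) draws a diel class from `day_activity_prob` and is
placed inside a window of that class, whole visits confined to one window
so degenerate preferences (0 or 1) produce perfectly pure streams; return
visits follow a homogeneous Poisson process; eating depletes mass at
`eat_rate × body mass × minutes`, never below zero; a successful removal
(per-visit Bernoulli, only while mass remains) zeroes the carcass and ends
its stream; background loss accrues linearly in time for experimental and
control carcasses alike. All random draws are made before the
mass bookkeeping, so, at a fixed seed, raising an eat rate changes no event
times — which makes "more rate never means less consumption" an exact,
testable monotonicity. The ledger identity in-situ + removed +
non-vertebrate + remaining = initial holds to floating-point precision on
every run.

Two generator subtleties worth knowing:

* **Diel placement vs latency.** A drawn arrival that lands in the wrong
  diel class is advanced to the next window of the drawn class. The truth
  ledger records both the drawn and the realised latency, and
  stream-recovery tests compare against the realised value. Consequently
  realised latencies are right-shifted relative to the gamma parameters —
  markedly for a diurnal species whose drawn arrival falls at night. The
  latency parameters are inputs to the generator, not quantities the
  pipeline is expected to re-estimate from the stream.
* **What the estimator cannot see.** The generator accrues background loss
  on a removed carcass only until the removal, while the estimator
  subtracts the full-deployment fraction $fM_c$; removals therefore get
  slightly over-adjusted and remover credit is biased a few percent low.
  This mirrors the field situation — nobody knows when the background
  stopped — and is why the recovery tolerance for per-species grams is a
  relative ±10%, not exact.

## What the simulator does not emulate

Passing recovery tests show the pipeline inverts *this* generator, not
nature. Real data differ in ways the generator deliberately omits:
individual identity (revisits may be one bird or five), behaviour
misclassification and missed triggers, temperature-dependent decomposition
(held linear here), multi-species interference at the carcass, partial
removals, and the 21-odd incidental non-scavenger species a real camera
records. The attribution model itself shares the field method's structural
assumptions — equal per-kg intake rates across species and
time-proportional intake — so recovery succeeds partly because generator
and estimator share them; that is the point of the exercise (validating the
arithmetic and the plumbing), not evidence that the assumptions hold for
real scavengers.

## Numerical and validation choices

* Tolerances: ledger conservation 1e-6 g (simulator) and 1e-9 g
  (attribution); KDE unit mass 1e-3; solar times ±3 min of the minute-scan
  oracle; extraction must equal a naive quadratic grouping *exactly*.
* Validation problem sizes, chosen to make sampling noise small relative to
  the tolerance while keeping the default suite fast: 50 replicate
  63-carcass studies for fraction recovery (binomial SE ≈ 0.4 pp); one
  200-carcass study for per-species gram recovery; a ~6,000-visit
  single-species probe for the day-fraction check (SE ≈ 0.4 pp against a
  ±1.5 pp band). The probe keeps visits sparse (0.6/h) because overlapping
  visits merge into single observations and would otherwise undercount the
  crowded diel class.
* Degenerate inputs are contracts, not accidents: empty frame streams yield
  empty observation tables; a species with no observations is *missing*
  from diel fractions, not 0%; an unscavenged study attributes nothing and
  flags the scavenged-only scope as undefined; κ calibration with no usable
  carcass raises a calibration error and the caller falls back to the
  proportional rule.
* Errors are classed conditions (`carrionfate_validation_error`,
  `_integrity_error`, `_ordering_error`, `_insufficient_data_error`,
  `_calibration_error`) naming the offending field, carcass or line.

## Limitations

Point estimates only — the attribution carries no uncertainty intervals,
matching the descriptive character of the method. The κ split for removed
carcasses is identifiable only when some scavenged carcasses are *not*
removed. Latitudes beyond the polar circles are unsupported. And the
generator's visit process (Poisson revisits, exponential bouts) is a
modelling convenience: nothing in the pipeline depends on it, but
recovery results quoted here are conditional on it.
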