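# carrionfate

Who eats the dead in cities? When a carcass appears in an urban green
space, some of its mass is taken by vertebrate scavengers — corvids by day,
foxes by night — and the rest is lost to invertebrates, microbes and
desiccation. `carrionfate` is an R package for camera-trap carcass-fate
experiments that answers, quantitatively: *what fraction of carcass biomass
do vertebrate scavengers remove, and how is it partitioned among species?*

It is written for ecologists running (or re-analysing) experiments of the
standard design: carcasses of known mass deployed in front of
motion-triggered cameras for a few days, re-weighed at retrieval, with
caged control carcasses that admit invertebrates but exclude vertebrates.

## What the package does

1. **Observation extraction** (`extract_observations()`). Camera frames
   (`carcass_id`, timestamp, species, behaviour) are collapsed into
   *observations* — contiguous single-species, single-behaviour presence
   intervals — the unit of replication. Behaviours are `NONE`, `LOOKING`,
   `EXAMINING`, `EATING`, `REMOVING`; the last two are scavenging.
2. **Diel classification** (`classify_observations()`, `diel_fraction()`,
   `activity_density()`). Sunrise and sunset are computed from the NOAA
   closed-form solar equations (zenith 90.833°); an observation is DAY iff
   its start lies in [sunrise, sunset). Activity curves over the 24-h clock
   use a circular (wrapped) Gaussian kernel density.
3. **Biomass attribution** (`attribute_study()`), the analysis core. For
   each carcass the measured loss (initial − final mass; a carcass removed
   whole is taken as fully consumed elsewhere) is first adjusted by the
   pooled non-vertebrate loss fraction

   `f = Σ(initial − final) / Σ(initial)` over controls and unscavenged
   carcasses,

   so the vertebrate-attributable loss is `L = max(0, loss − f·initial)`.
   `L` is then divided among species in proportion to *feeding time ×
   body mass*: species *i* receives `L · m_i t_i / Σ_j m_j t_j`, where
   `t_i` is its total EATING minutes and `m_i` its body mass. For removed
   carcasses, an in-situ consumption rate κ (g per kg of scavenger per
   minute, least squares through the origin on scavenged non-removed
   carcasses) credits pre-removal eaters with `κ·m_i·t_i`, and the remover
   receives the remainder. Totals are reported under three scopes: all
   carcasses, scavenged-only, and scavenged carcasses at sites accessible
   to foxes.
4. **Descriptive summaries** (`attendance_summary()`,
   `scavenging_detection_summary()`, `mass_loss_comparison()`), and a
   one-call pipeline (`run_pipeline()`).
5. **A synthetic study generator** (`simulate_study()`,
   `default_paperlike_config()`) with a hidden ground-truth consumption
   ledger, used to validate every stage by parameter recovery. The default
   configuration emulates the classic urban design: 63 experimental rat
   carcasses (250–300 g) and 10 caged controls over nine sites in three
   towns for 2–4 days, three scavenger species (carrion crow, Eurasian
   magpie, red fox) with gamma arrival latencies, near-total diel
   separation, and ~9.6% background loss per deployment.

## Worked example

```r
library(carrionfate)

cfg   <- default_paperlike_config(seed = 42)
study <- simulate_study(cfg)
obs   <- extract_observations(study$detections)
att   <- attribute_study(study$deployments, obs)
print(att)
```

```
<carcass_attribution> 63 experimental carcasses (42 scavenged, 14 removed), 10 controls
  non-vertebrate loss fraction: 0.0904 (9.0%)
  kappa (in-situ rate): 1.97 g/kg/min; removal rule: kappa
  biomass share of total deployed:
    CROW           2417.7 g  (14%)
    MAGPIE          466.9 g  (3%)
    FOX            3077.7 g  (18%)
    TOTAL          5962.3 g  (35%)
```

Reading this: 42 of the 63 simulated carcasses were scavenged; the pooled
control/unscavenged estimate says 9.0% of initial mass vanished to
non-vertebrate causes (the generator's true mean is 9.6%); the calibrated
in-situ rate is 1.97 g/kg/min against a generator truth of 2; and 35% of
all deployed biomass is attributed to the three scavengers — crows and the
fox dominating, the fox mostly via whole-carcass removals (it never eats
in situ in this community). Diel partitioning is recovered too:

```r
diel_fraction(obs, study$deployments)
```

```
  species n_observations n_day  day_pct
1    CROW            503   496 98.60835
2     FOX            121    15 12.39669
3  MAGPIE            336   333 99.10714
```

against generator day-activity probabilities of 0.98, 0.092 and 0.996.

Field data enter through the same door: `read_study()` validates the
deployments/detections/observations CSV schemas (see `?read_study`) and
`run_pipeline()` produces the attribution, the summaries and a report. A
thin command-line front end with `simulate`, `extract`, `classify`,
`attribute`, `summarize` and `run` subcommands lives at
`inst/cli/carrionfate.R`.

## Package layout

- `R/simulate.R` — study generator and configurations
- `R/observations.R` — frame-to-observation extraction, eating times,
  first-arrival latencies
- `R/diel.R` — solar times, DAY/NIGHT classification, circular KDE
- `R/attribution.R` — loss adjustment, κ calibration, allocation, ledgers
- `R/summaries.R` — descriptive study ledgers
- `R/io.R` — CSV schemas, YAML configs, `run_pipeline()`
- `vignettes/biomass-attribution.Rmd` — the methods vignette: model,
  assumptions, parameter defaults, numerical choices, limitations
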