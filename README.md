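# semilunar

Period estimation and clock-architecture model selection for
circasemilunar (~15-day) and circadian emergence rhythms.

Intertidal insects such as the marine midge *Clunio marinus* time adult
emergence to the spring tides with an endogenous circasemilunar clock,
while a circadian clock sets the hour of emergence.  Three architectures
could generate the ~15-day rhythm, and they make different predictions
for how the free-running circasemilunar period τ (days) responds to the
length T (hours) of the diel light–dark cycle:

| architecture | prediction |
|---|---|
| counter (C circadian cycles counted) | τ = C·T/24 — linear in T, slope C/24 |
| independent ~15-day oscillator | τ independent of T |
| circadian × circatidal beat (lunar day k hours) | τ = T·k/(2·\|T−k\|)/24 — hypersensitive to T |

The package provides the full inference chain for this experiment family:

* **Data model & I/O** — daily and hourly emergence-count series with
  missing-value masks, per-cycle counts credited to the solar day of the
  preceding lights-off (days without a lights-off under T > 24 h are
  masked), the 82-day analysis window (days 31–112), zeitgeber-time
  alignment, and delimited-text readers/writers with a light-regime
  sidecar.
* **Rhythm statistics** — missing-data autocorrelation, Lomb–Scargle
  periodograms, a JTK-style Kendall-tau cosine scan with exact
  small-sample nulls, meta2d-style integration (mean period,
  Fisher-combined p), and Benjamini–Hochberg significance calls at
  q < 0.05.
* **Model selection** — counter/oscillator/beat fits to (T, τ)
  observations, residual standard errors, small-sample AICc, Akaike
  weights, and a ranked comparison table.
* **Simulator** — population emergence under each architecture, with
  circadian entrainment limits (range [20, 28) h), frequency
  demultiplication under short T-cycles (LD 6:6 → 24-h rhythm), and
  constant-light desynchronization, so every stage can be validated
  against ground truth.
* **Recipes & CLI** — `run_tcycle()`, `run_demultiplication()`,
  `run_ll()` orchestrate whole experiments and write text + JSON
  reports; `inst/scripts/emergence-clock.R` exposes them as shell
  subcommands (exit code 4 marks the scientific outcome "no rhythmic
  series").

## Worked example

Simulate a day-counting population (C = 13 cycles) under LD 13:13
(T = 26 h), estimate its free-running circasemilunar period, then run the
whole T-cycle experiment and rank the architectures:

```r
library(semilunar)

pop <- simulate_population(sim_config(seed = 11), light_regime(26))
pop$daily
#> <emergence_series> 'counter_T26_seed11': 113 bins of 24 h from day 0
#>   (9 missing, total 438)

estimate_period(window_semilunar(pop$daily))
#> <period_estimate> tau = 13.98, p = 8.4e-21
```

The 113-day series has 9 masked days — the solar days without a
light-to-dark transition under T = 26 h — and the estimated period,
13.98 days, recovers the generative expectation 13 × 26/24 = 14.08 days
to within the period-grid resolution.  The full experiment (T = 22–30 h;
T = 28 and 30 h lie outside the circadian range of entrainment and
produce no significant rhythm):

```r
rep <- run_tcycle(seed = 1, replicates = c(2, 3, 2, 1, 1))
rep$comparison
#> Model comparison on 7 period observations:
#>  hypothesis                 model   rse   aicc   weight
#>     counter           lm(tau ~ T) 0.024 -20.79 1.00e+00
#>  oscillator           lm(tau ~ 1) 0.828  23.14 2.89e-10
#>        beat nls(tau ~ beat(T, k)) 4.704  47.46 1.51e-15
```

The counter model wins decisively, and its fitted slope (0.507 days/h)
matches the generative C/24 = 13/24 = 0.542.  A clock counting the
*entrained* 15 cycles predicts slope 15/24 = 0.625 days per hour.

From a shell, the same analyses run as subcommands:

```sh
Rscript inst/scripts/emergence-clock.R simulate --hypothesis counter \
    --t-cycle 26 --seed 3 --out sim/
Rscript inst/scripts/emergence-clock.R period --in sim/daily.csv --layout daily
Rscript inst/scripts/emergence-clock.R run-tcycle --seed 7 --out report/
```

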