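# dashtrack

Scoring, feedback, and trial analytics for app-based DASH diet
interventions.

The DASH (Dietary Approaches to Stop Hypertension) dietary pattern lowers
blood pressure, but population adherence is poor, and digital interventions
that coach people toward DASH need three computational pieces that are easy
to get subtly wrong: a daily adherence score computed from diet-tracking
logs, a tailored feedback message engine on a fixed cadence, and the
statistics of the feasibility trial that evaluates the whole thing.
`dashtrack` implements all three for R users — intervention developers,
nutrition researchers, and trial statisticians — together with a
synthetic-cohort simulator so the full pipeline can be exercised and
validated without participant data.

## The index

One day of intake is scored on nine nutrients. Raw amounts are standardized
to calorie-relative bases — percent of energy for total fat, saturated fat
and protein (Atwater factors 9 and 4 kcal/g), amount per 1000 kcal for
cholesterol, fiber, magnesium, calcium and potassium, and absolute mg/day
for sodium — and each standardized value x_i earns a credit against its
target T_i and intermediate threshold I_i:

    c_i = 1    if x_i meets T_i        (>= for "more is better", <= for "less is better")
        = 0.5  if x_i meets only I_i
        = 0    otherwise
    DASH total = sum of the nine c_i, in [0, 9]; 9 = full adherence

Targets default to the published DASH standards (fat <27% of energy,
saturated fat <6%, protein >18%, cholesterol <71.4 mg/1000 kcal, fiber
>14.8 g/1000 kcal, magnesium >238, calcium >590, potassium >2238 mg/1000
kcal, sodium <2400 mg/day); intermediates default to 2/3 of target
("more is better") or 1.5x target ("less is better") and are overridable
through a JSON/YAML targets file. See the methods vignette
(`vignettes/dash-adherence-methods.Rmd`) for every rule and design choice.

## Worked example

Score a tracked day and compose its feedback message:

```r
library(dashtrack)

d <- daily_intake("p07", "2017-09-04", energy_kcal = 2000,
                  total_fat_g = 84.2, saturated_fat_g = 28, protein_g = 80,
                  cholesterol_mg = 344, fiber_g = 18.2, magnesium_mg = 284.4,
                  calcium_mg = 1100, potassium_mg = 2800, sodium_mg = 3000)
prof <- compute_densities(d)       # fat 37.9% of energy, fiber 9.1 g/1000 kcal, ...
s <- score_day(as.list(prof))
s$credits
#>     total_fat saturated_fat       protein   cholesterol         fiber
#>           0.5           0.0           0.5           0.0           0.0
#>     magnesium       calcium     potassium        sodium
#>           0.0           0.5           0.0           0.5
s$total
#> [1] 2
```

Fat sits between its 27% target and the 40.5% intermediate (half credit),
fiber at 9.1 g/1000 kcal misses even its 9.87 intermediate (zero), and the
four half-credits sum to a total of 2 — a typical low-adherence Western
diet day. The feedback composer turns this into the message text:

```r
cls <- classify_components(s, dash_targets(), as.list(prof))
msg <- compose_daily_message("p07", "Dana", s$total, cls$best, cls$struggle,
                             study_day = 4)
msg$body
#> Hello, Dana! Your DASH score yesterday was 2.0. You did best with calcium
#> and protein and seemed to struggle with cholesterol and saturated fat.
#> Tip: Pick plant proteins like lentils in place of meat once today.
```

A full simulated study runs end to end from the shell:

```sh
./exec/dashtrack simulate --n 59 --seed 42 --outdir cohort
./exec/dashtrack score    --intake cohort/intake.csv --out scores.csv
./exec/dashtrack engage   --intake cohort/intake.csv --roster cohort/roster.csv --out engagement.csv
./exec/dashtrack analyze  --outcomes cohort/outcomes.csv --out results.json
```

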