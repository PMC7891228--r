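# tolsim

Spatial agent-based simulation of intergroup tolerance in forager
populations.

## The problem

For most of the deep human past, neighbouring hunter-gatherer groups could
either avoid one another or tolerate one another — and tolerance opens the
door to sharing food across group boundaries. `tolsim` implements an
individual-based model built to ask *when* that tolerant disposition pays:
whole populations of group-living foragers are simulated on a dynamic prey
landscape, under an environmental-harshness gradient expressed as the **cost
of reproduction** *c* (the surplus food a group must commit per birth,
varied 26–35 food units), with every group in a run either *avoidant* (no
exchanges) or *tolerant* (food flows from a group with surplus to one in
deficit when groups meet). The package is aimed at modellers in
evolutionary anthropology and behavioural ecology who want a transparent,
fully reproducible re-implementation of this experiment.

## The model in brief

* **Landscape** — a 100 × 100 toroidal grid; each cell holds a prey
  population with logistic regrowth *n* → *n* + *r n*(1 − *n*/*K*)
  (defaults *r* = 0.06, *K* = 100).
* **People** — individuals with age and sex, belonging to groups with a camp
  in continuous space. Each year, every individual older than 10 forays
  from camp (4 random-walk steps; a hunt at each step succeeds with
  probability *n*/(*n* + 25), removing one animal and pooling one food unit
  into the group stock). Depletion halos form around camps.
* **Encounters** — random pairs of groups meet with probability
  e^(−*d*/15) of the distance between camps. Tolerant pairs transfer
  min(donor surplus, recipient deficit), both measured against a group's
  annual reserve (one food unit per member plus one birth at this year's
  cost); avoidant pairs do nothing.
* **Demography** — one food unit per member of upkeep (shortfalls starve
  members); age-specific mortality from a U-shaped hunter-gatherer-style
  life table; each female aged 16–39 can have one child per year while her
  group's remaining stock covers the cost of reproduction.
* **Groups** — split at 50 members, dissolve (fatally) below 4.
* **Experiment** — strategy × cost factorial with deterministic
  per-replicate seeding; headline output per realisation is the mean total
  population over a late measurement window, plus survival. Summaries
  include survival proportions, paired tolerant:avoidant population ratios,
  and a two-way fixed-effects ANOVA with classical and partial η².

## Worked example

Paired runs at harshness 32, desk scale (500 years, measured over years
301–500):

```r
library(tolsim)

avoid <- run_realisation(sim_config(cost_of_reproduction = 32, n_years = 500,
                                    measure_window = c(301, 500), seed = 42))
toler <- run_realisation(sim_config(cost_of_reproduction = 32, n_years = 500,
                                    measure_window = c(301, 500), seed = 42,
                                    tolerant = TRUE))
avoid
#> Realisation: avoidant, cost 32, seed 42
#>   mean population 1406.9 | survived
toler
#> Realisation: tolerant, cost 32, seed 42
#>   mean population 2103.3 | survived
toler$mean_population / avoid$mean_population
#> [1] 1.49
```

At this harshness, food sharing supports a population roughly one and a half
times larger — the model's central comparative result. A full factorial
sweep and its analysis:

```r
sc  <- scale_design(sim_config(), n_reps = 200, scale = 0.5, window_frac = 0.4)
tab <- run_factorial(sc$config, costs = 26:35, n_reps = 16, master_seed = 1)
ratio_by_cost(tab)            # tolerant:avoidant ratio per cost level
two_way_anova(tab)            # cost x tolerance decomposition with eta^2
```

There is also a command-line surface
(`inst/exec/tolsim run|sweep|analyze|snapshot`) that writes `years.csv`,
`experiment.csv`, `effects.csv`, landscape snapshots (CSV/PGM) and a
reproducibility manifest per run.

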