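---
title: "Modelling intergroup tolerance in forager populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intergroup tolerance in forager populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Why would mobile hunter-gatherer groups tolerate — even feed — their
neighbours?  `tolsim` implements a spatially explicit, individual-based model
built to ask when a *tolerant* intergroup disposition (food is shared between
groups that meet) outcompetes an *avoidant* one (groups never exchange
anything), and how that answer depends on how harsh the environment is.
Harshness is operationalised as the **cost of reproduction**: the amount of
surplus food a group must commit to rear one child, varied over 26–35 food
units.  The model tracks whole populations over a millennium, so the outcome
variables are demographic: mean total population in a late measurement
window, and survival (did the population persist?).

## The model

The world is a `grid_side x grid_side` (default 100 x 100) lattice of
landscape cells on a torus, each cell carrying an independent prey population
with logistic regrowth,

$$ n_{t+1} = n_t + r\,n_t\,(1 - n_t/K), $$

with defaults $r = 0.06$ and $K = 100$.  On this landscape live humans, each
belonging to a group with a camp (focus) in continuous space.  A model year
runs through fixed phases:

1. **Camp relocation** — each focus moves to a uniform point within
   `camp_relocation_radius` (default 5) of its old location; camps are fixed
   within a year.
2. **Stock reset** — there is no storage: every group starts the year with
   zero food.
3. **Cost realisation** — in a variable environment the year's cost of
   reproduction is the base cost plus a uniform integer on $[-7, 7]$, drawn
   independently each year (no autocorrelation), floored at 0.
4. **Hunting** — every individual older than 10 walks a foray of
   `foray_steps` (default 4) steps of length 1 from the camp, in uniform
   random directions with toroidal wrap.  After each step a hunt is attempted
   in the current cell; with $n$ animals present it succeeds with probability
   $n/(n + h)$, $h$ = `capture_halfsat` (default 25), removing one animal and
   adding one food unit to the group stock.  A success requires at least one
   whole animal in the cell, so cells never go negative.  Depletion halos
   develop around camps because forays start there.
5. **Intergroup encounters** — three random pairs of distinct groups are
   drawn per group per year; a drawn pair actually meets with probability
   $e^{-d/\lambda}$ of the toroidal distance $d$ between foci
   ($\lambda$ = `encounter_scale`, default 15).  Nothing happens between
   avoidant groups.  Between tolerant groups, food moves from a group with
   a surplus to one with a deficit, both measured against the group's annual
   **reserve** — its maintenance need (one unit per member) *plus* one birth
   at the year's realised cost.  The transfer is
   `min(donor surplus, recipient deficit)`: donors never give away food they
   need to subsist and reproduce, recipients can be lifted out of starvation
   and up to a funded birth.  Transfers conserve food exactly.
6. **Maintenance** — each group pays one food unit per member; if the stock
   cannot cover it, the stock empties and one member starves per missing
   unit (chosen uniformly at random).
7. **Ageing, death, birth** — survivors age one year and die with an
   age-specific annual probability from a closed life table (below).  Then,
   group by group, each female aged 16–39 can produce one offspring while
   the group's remaining stock covers the year's cost of reproduction,
   debiting the stock per birth; newborns enter at age 0 with even-chance
   sex.  Because fertile females are demographically interchangeable, the
   number of births in a group is `min(fertile females, floor(stock/cost))`.
8. **Fission and loss** — groups of 50 or more split (members assigned to
   daughters by fair coin; one daughter keeps the focus, the other moves to
   a uniform point within 10 grid units; stock divides in proportion to
   size), repeating until none remain at 50.  Any group then below 4 members
   dissolves and its members die.  Surviving groups therefore end every year
   with 4–49 members.
9. **Prey regrowth** — every cell takes one logistic step.

Extinction (population 0) is absorbing: stepping an extinct state changes
nothing and reports zeros.

### Initial conditions

160 group foci uniform in continuous space; 3000 individuals with uniform
random group assignment, uniform ages 1–50 and even-chance sex; every cell's
prey drawn as a uniform integer 1–100.

### The mortality table

The cited hunter-gatherer life tables are not reproduced anywhere in the
model description, so the package ships its own piecewise-constant schedule
(`default_mortality_schedule()`): infant mortality 0.20, a juvenile decline
to a prime-age plateau of about 0.01/year, senescent rise from age 60, and
certain death at 85.  It is U-shaped, yields a crude death rate near
2.5–3%/year in a stationary age structure, and is an explicit package
default, swappable through `sim_config(mortality_schedule = ...)`.

## Calibrating the open mechanism constants

The published description fixes the demographic and social constants (group
thresholds 4 and 50, fertility at 16–39, hunting above 10, maintenance 1,
costs 26–35, perturbation ±7) but leaves the foraging and ecological
mechanics open: foray length, the hunt-success function, logistic prey
parameters, and the encounter model.  These defaults were calibrated — once,
at coarse replication, against the qualitative regime the experiments
require — rather than guessed, because the regime is genuinely narrow:

* **Foray length 4.**  Per-hunter annual harvest is capped at
  `foray_steps` x success probability.  Long forays (20 steps) make food so
  abundant that the birth cost never binds; the population is then limited
  by prey overexploitation, mean population *rises* with the cost of
  reproduction (cheap births cause violent boom–bust cycles), and nothing
  ever goes extinct.  Short forays (3 steps) are fatal in the opposite way:
  with per-capita surplus below ~1.3 food units, a typical 19-member group
  can never pool one 26–35-unit birth, and the whole population dies of
  birth-cost granularity from the published initial conditions.  Four steps
  sit between those failure modes.
* **Prey growth $r = 0.06$.**  Landscape productivity scales population size
  directly.  At $r = 0.2$ the landscape feeds tens of thousands and the cost
  gradient never threatens persistence; at 0.06 the gradient 26–35 spans
  healthy populations (thousands) down to stochastic extinction, which is
  the regime the factorial experiment is about.
* **Encounter kernel ($\lambda = 15$, 3 pairs per group-year).**  With one
  uniform pair per group and $\lambda = 10$, a group realises ~0.06 meetings
  per year — food sharing is then so rare that the two strategies are
  statistically indistinguishable.  The calibrated kernel yields roughly 0.3
  meetings per group-year, enough for sharing to function as insurance while
  remaining local and random rather than directed.
* **Transfer rule.**  Measuring surplus and deficit against maintenance need
  alone makes sharing purely life-saving; it can never fund a birth.  In
  that variant tolerant populations were no larger than avoidant ones and
  went extinct *more* often: saved individuals deepen prey depletion but
  produce no extra recruits.  Measuring both sides against the
  maintenance-plus-one-birth reserve lets groups pool reproduction across
  group boundaries — exactly the margin on which the birth-cost granularity
  operates — and is what makes tolerance demographically valuable.

## The factorial experiment

`run_factorial()` crosses strategy (avoidant, tolerant) with the cost
gradient 26–35, running `n_reps` independent realisations per cell.  Each
realisation's seed derives deterministically from
(master seed, strategy, cost, replicate), so a sweep is exactly reproducible
and tolerant/avoidant runs with equal replicate index form a pair.  The
summary per run is the mean total population over the measurement window
(post-extinction years count as 0) plus a survival flag.

At full scale the design is 200 replicates of 1000 years per cell.
`scale_design()` provides the desk-scale preset used by the package's own
verification: the acceptance workflow runs 500-year realisations with the
window over years 301–500 and 16 replicates per cell.  Two choices
deserve a note:

* **Window width.**  The full-scale convention is the final tenth of the
  run.  The coupled human–prey system approaches equilibrium through a
  damped oscillation with a period of a few hundred years; a 50-year window
  at desk scale samples an arbitrary phase of that oscillation and inflates
  between-run variance (and, worse, strategy-by-cost noise).  The desk-scale
  window therefore spans the final 200 of 500 years, averaging over the
  oscillation at no computational cost.  Both strategies always use the same
  scale, so comparisons are internally consistent.
* **Replicates.**  16 per cell keeps the whole 2 x 10 factorial within a
  desk-scale compute budget while leaving the headline contrasts (decline
  with cost, tolerant:avoidant ratio, extinction onset) resolvable; they are
  noisier than the full design, and the package's checks use the tolerance
  bands stated alongside each check rather than printed-precision equality.

### Summary statistics

`ratio_by_cost()` reports, per cost level, the per-pair ratio of tolerant to
avoidant mean population over pairs in which both members survived (with a
normal-approximation 95% CI), and the cell-mean ratio
mean(tolerant)/mean(avoidant) over surviving runs, which is the statistic
used for the interaction curves.  `two_way_anova()` fits the balanced
fixed-effects decomposition of mean population on cost x strategy (via
`stats::aov`; an independent brute-force decomposition from cell, marginal
and grand means backs it in the test suite) and reports both classical
($SS/SS_{tot}$) and partial ($SS/(SS + SS_{err})$) eta-squared.  The printed
effect sizes of the original analysis can only be partial eta-squared —
classical values cannot sum beyond 1 — so partial values are the ones to
compare.  p-values are reported but deliberately not leaned on: with
hundreds of cheap replicates everything is "significant".

## What the generator does and does not emulate

The synthetic world captures the mechanisms the question needs: local
resource depletion with regrowth, distance-structured random encounters,
group-level food pooling with hard fission/dissolution thresholds, and
age-structured demography under a food-gated birth process.  It does not
emulate heritable or mixed strategies (every run is all-tolerant or
all-avoidant), cultural transmission, memory or directed movement,
seasonality within years, or any spatial heterogeneity in carrying capacity.
Passing checks therefore demonstrate internal consistency of this model and
the direction of its comparative statics — not that real Palaeolithic
populations behaved quantitatively like this.

## Numerical and degenerate-input choices

* Continuous prey counts meet discrete removals: a hunt can only succeed in
  a cell holding at least one whole animal, keeping the one-animal-per-food
  accounting exact and cells non-negative.
* Positions live on a torus; all distances are toroidal, so there are no
  edge artefacts to interpret.
* Starvation victims, fission assignments and birth order are uniform over
  the eligible individuals; ties never need breaking by index.
* A fission draw that leaves one daughter empty is redrawn (the group simply
  re-enters the queue), which keeps daughter invariants simple; the event
  has probability $2^{-49}$ per split at the threshold.
* An extinct state is a fixed point: `step_year()` returns an all-zero
  record and mutates nothing.
* `two_way_anova()` refuses unbalanced designs rather than silently
  switching to a sum-of-squares convention; the factorial runner only
  produces balanced tables.  A constant response reports zero sums of
  squares and zero effect sizes.

## Known limitations

* Absolute population sizes are not calibrated to any empirical census; only
  the comparative structure across strategies and costs is meaningful.
* The coupled system's damped oscillation makes short measurement windows
  phase-sensitive; desk-scale results use wide windows, and single short
  runs should not be over-read.
* Near the extinction boundary the surviving-run statistics are conditioned
  on survival; with few replicates the avoidant survivors are a
  luck-selected subset and per-cost ratios there carry wide uncertainty.
* The interaction budget (3 uniform pairs per group-year) is a calibrated
  default, not an estimate from ethnographic contact rates.
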