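Package: tolsim
Title: Spatial Agent-Based Simulation of Intergroup Tolerance in Forager Populations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A spatially explicit, individual-based model of hunter-gatherer
    groups foraging on a dynamic prey landscape, used to compare 'tolerant'
    (food-sharing) and 'avoidant' intergroup strategies across a gradient of
    environmental harshness expressed as the food cost of reproduction.
    Provides the annual simulation cycle (foraging forays with local prey
    depletion, distance-dependent intergroup encounters with surplus-to-deficit
    food transfers, per-capita maintenance with starvation, age-structured
    mortality and food-limited births, group fission and dissolution, logistic
    prey regrowth), a factorial experiment runner with deterministic replicate
    seeding, paired tolerant/avoidant population-size ratios, and a two-way
    fixed-effects ANOVA with classical and partial eta-squared effect sizes.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
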