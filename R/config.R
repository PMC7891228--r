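#' Default age-specific mortality schedule
#'
#' Piecewise-constant annual death probabilities with the U-shaped profile
#' characteristic of hunter-gatherer life tables: elevated infant and juvenile
#' mortality, a low plateau through the prime adult ages, and senescent rise to
#' a closed terminal age at which death is certain.  The exact values are a
#' package default intended to give a realistic crude death rate (roughly
#' 2.5--3\% per year in a stationary population); they are swappable through
#' the \code{mortality_schedule} field of \code{\link{sim_config}}.
#'
#' @param terminal_age age (years) at and beyond which annual death
#'   probability is 1.
#' @return numeric vector of annual death probabilities indexed by age
#'   \code{0:terminal_age} (element \code{i} is the probability at age
#'   \code{i - 1}).
#' @export
#' @examples
#' sched <- default_mortality_schedule()
#' sched[1]    # infant mortality (age 0)
#' sched[86]   # terminal age: certain death
default_mortality_schedule <- function(terminal_age = 85) {
    stopifnot(terminal_age >= 1)
    p <- numeric(terminal_age + 1)
    age <- 0:terminal_age
    p[age == 0] <- 0.20
    p[age >= 1 & age <= 4] <- 0.045
    p[age >= 5 & age <= 9] <- 0.012
    p[age >= 10 & age <= 14] <- 0.006
    p[age >= 15 & age <= 19] <- 0.008
    p[age >= 20 & age <= 39] <- 0.010
    p[age >= 40 & age <= 49] <- 0.014
    p[age >= 50 & age <= 59] <- 0.022
    p[age >= 60 & age <= 69] <- 0.045
    p[age >= 70 & age <= 79] <- 0.110
    p[age >= 80 & age < terminal_age] <- 0.250
    p[terminal_age + 1] <- 1.0
    p
}

#' Simulation configuration
#'
#' Builds the immutable configuration of one model realisation.  Defaults are
#' the published model constants (100 x 100 landscape, 160 initial groups,
#' 3000 individuals, initial ages 1--50, initial prey 1--100 per cell, fission
#' at 50 members, dissolution below 4, hunting above age 10, fertility at ages
#' 16--39, one food unit of maintenance per person per year, birth costs
#' varied over 26--35, interannual cost perturbations uniform on -7..7);
#' mechanism constants the published description leaves open (foray length,
#' capture half-saturation, logistic prey parameters, encounter kernel, camp
#' and fission relocation radii, mortality table) are package defaults, all
#' configurable here.
#'
#' @param grid_side landscape cells per side.
#' @param n_groups_init number of initial group foci.
#' @param n_individuals_init initial number of individuals.
#' @param init_age_range integer interval of initial ages.
#' @param init_animal_range integer interval of initial per-cell prey counts.
#' @param cost_of_reproduction food units a group pays per birth (the
#'   environmental "harshness" knob; varied 26--35 in the experiments).
#' @param variable_environment if \code{TRUE}, the realised cost is perturbed
#'   each year by a uniform integer on
#'   \code{[-variability_halfwidth, variability_halfwidth]}.
#' @param variability_halfwidth half-width of the annual cost perturbation.
#' @param tolerant strategy of every group in the run: \code{TRUE} for
#'   tolerant (food sharing on encounters), \code{FALSE} for avoidant.
#' @param n_years years to simulate.
#' @param measure_window year interval over which mean population is reported.
#' @param fission_threshold group size at and above which a group splits.
#' @param dissolution_threshold group size below which a group is lost.
#' @param hunting_min_age exclusive age bound for hunters (older than this).
#' @param fertile_age_range inclusive female fertile age interval.
#' @param maintenance_per_capita food units per person per year.
#' @param foray_steps steps per hunter foray per year.
#' @param step_length distance (grid units) per foray step.
#' @param capture_halfsat prey count at which a hunt attempt succeeds with
#'   probability one half.
#' @param prey_growth_rate per-year logistic growth rate r.
#' @param prey_capacity per-cell carrying capacity K.
#' @param encounter_pairs_per_year group pairs drawn per year; \code{NA}
#'   (default) means three times the current number of groups.
#' @param encounter_scale e-folding distance (grid units) of the encounter
#'   probability kernel \code{exp(-d / scale)}.
#' @param fission_relocation_radius radius (grid units) within which a
#'   daughter group's new focus is placed.
#' @param camp_relocation_radius radius (grid units) of the annual camp move;
#'   0 keeps camps fixed.
#' @param mortality_schedule numeric vector of annual death probabilities
#'   indexed by age 0..terminal (last entry 1).
#' @param seed RNG seed of the realisation.
#' @return a validated list of class \code{sim_config}.
#' @seealso \code{\link{init_state}}, \code{\link{run_realisation}}
#' @export
#' @examples
#' cfg <- sim_config(cost_of_reproduction = 30, tolerant = TRUE, seed = 1)
#' cfg$grid_side
sim_config <- function(grid_side = 100,
                       n_groups_init = 160,
                       n_individuals_init = 3000,
                       init_age_range = c(1L, 50L),
                       init_animal_range = c(1L, 100L),
                       cost_of_reproduction = 30,
                       variable_environment = FALSE,
                       variability_halfwidth = 7,
                       tolerant = FALSE,
                       n_years = 1000,
                       measure_window = c(901L, 1000L),
                       fission_threshold = 50,
                       dissolution_threshold = 4,
                       hunting_min_age = 10,
                       fertile_age_range = c(16L, 39L),
                       maintenance_per_capita = 1,
                       foray_steps = 4,
                       step_length = 1.0,
                       capture_halfsat = 25,
                       prey_growth_rate = 0.06,
                       prey_capacity = 100,
                       encounter_pairs_per_year = NA,
                       encounter_scale = 15,
                       fission_relocation_radius = 10,
                       camp_relocation_radius = 5,
                       mortality_schedule = default_mortality_schedule(),
                       seed = 1L) {
    cfg <- list(
        grid_side = as.integer(grid_side),
        n_groups_init = as.integer(n_groups_init),
        n_individuals_init = as.integer(n_individuals_init),
        init_age_range = as.integer(init_age_range),
        init_animal_range = as.integer(init_animal_range),
        cost_of_reproduction = as.numeric(cost_of_reproduction),
        variable_environment = isTRUE(as.logical(variable_environment)),
        variability_halfwidth = as.integer(variability_halfwidth),
        tolerant = isTRUE(as.logical(tolerant)),
        n_years = as.integer(n_years),
        measure_window = as.integer(measure_window),
        fission_threshold = as.integer(fission_threshold),
        dissolution_threshold = as.integer(dissolution_threshold),
        hunting_min_age = as.numeric(hunting_min_age),
        fertile_age_range = as.integer(fertile_age_range),
        maintenance_per_capita = as.numeric(maintenance_per_capita),
        foray_steps = as.integer(foray_steps),
        step_length = as.numeric(step_length),
        capture_halfsat = as.numeric(capture_halfsat),
        prey_growth_rate = as.numeric(prey_growth_rate),
        prey_capacity = as.numeric(prey_capacity),
        encounter_pairs_per_year =
            if (is.null(encounter_pairs_per_year) ||
                    is.na(encounter_pairs_per_year)) NA_integer_
            else as.integer(encounter_pairs_per_year),
        encounter_scale = as.numeric(encounter_scale),
        fission_relocation_radius = as.numeric(fission_relocation_radius),
        camp_relocation_radius = as.numeric(camp_relocation_radius),
        mortality_schedule = as.numeric(mortality_schedule),
        seed = as.integer(seed)
    )
    class(cfg) <- "sim_config"
    validate_config(cfg)
    cfg
}

#' Validate a simulation configuration
#'
#' Checks every structural invariant of a \code{\link{sim_config}} and stops,
#' naming the offending field, on the first violation.
#'
#' @param config a \code{sim_config}.
#' @return the configuration, invisibly, if valid.
#' @export
validate_config <- function(config) {
    chk <- function(ok, field, why) {
        if (!isTRUE(ok)) {
            stop("invalid configuration: field '", field, "' ", why,
                 call. = FALSE)
        }
    }
    chk(config$grid_side >= 1, "grid_side", "must be >= 1")
    chk(config$n_groups_init >= 0, "n_groups_init", "must be >= 0")
    chk(config$n_individuals_init >= 0, "n_individuals_init", "must be >= 0")
    chk(length(config$init_age_range) == 2 &&
            config$init_age_range[1] <= config$init_age_range[2] &&
            config$init_age_range[1] >= 0,
        "init_age_range", "must be a non-empty non-negative interval")
    chk(length(config$init_animal_range) == 2 &&
            config$init_animal_range[1] <= config$init_animal_range[2] &&
            config$init_animal_range[1] >= 0,
        "init_animal_range", "must be a non-empty non-negative interval")
    chk(config$cost_of_reproduction >= 0, "cost_of_reproduction",
        "must be >= 0")
    chk(config$variability_halfwidth >= 0, "variability_halfwidth",
        "must be >= 0")
    chk(config$n_years >= 1, "n_years", "must be >= 1")
    chk(length(config$measure_window) == 2 &&
            config$measure_window[1] <= config$measure_window[2] &&
            config$measure_window[1] >= 1 &&
            config$measure_window[2] <= config$n_years,
        "measure_window", "must be a non-empty interval within [1, n_years]")
    chk(config$fission_threshold > config$dissolution_threshold,
        "fission_threshold", "must exceed dissolution_threshold")
    chk(config$dissolution_threshold >= 1, "dissolution_threshold",
        "must be >= 1")
    chk(config$hunting_min_age >= 0, "hunting_min_age", "must be >= 0")
    chk(length(config$fertile_age_range) == 2 &&
            config$fertile_age_range[1] <= config$fertile_age_range[2],
        "fertile_age_range", "must be a non-empty interval")
    chk(config$maintenance_per_capita >= 0, "maintenance_per_capita",
        "must be >= 0")
    chk(config$foray_steps >= 0, "foray_steps", "must be >= 0")
    chk(config$step_length >= 0, "step_length", "must be >= 0")
    chk(config$capture_halfsat > 0, "capture_halfsat", "must be > 0")
    chk(config$prey_capacity > 0, "prey_capacity", "must be > 0")
    chk(is.na(config$encounter_pairs_per_year) ||
            config$encounter_pairs_per_year >= 0,
        "encounter_pairs_per_year", "must be >= 0 or NA")
    chk(config$encounter_scale > 0, "encounter_scale", "must be > 0")
    chk(config$fission_relocation_radius >= 0, "fission_relocation_radius",
        "must be >= 0")
    chk(config$camp_relocation_radius >= 0, "camp_relocation_radius",
        "must be >= 0")
    chk(length(config$mortality_schedule) >= 2 &&
            all(config$mortality_schedule >= 0) &&
            all(config$mortality_schedule <= 1),
        "mortality_schedule", "probabilities must lie in [0, 1]")
    chk(config$mortality_schedule[length(config$mortality_schedule)] == 1,
        "mortality_schedule", "must end with probability 1 (closed table)")
    invisible(config)
}

#' @export
print.sim_config <- function(x, ...) {
    cat("Simulation configuration (sim_config)\n")
    cat(sprintf("  landscape: %d x %d cells, prey K = %g, r = %g\n",
                x$grid_side, x$grid_side, x$prey_capacity,
                x$prey_growth_rate))
    cat(sprintf("  population: %d individuals in %d groups\n",
                x$n_individuals_init, x$n_groups_init))
    cat(sprintf("  strategy: %s | cost of reproduction: %g%s\n",
                if (x$tolerant) "tolerant" else "avoidant",
                x$cost_of_reproduction,
                if (x$variable_environment)
                    sprintf(" (+/- %d annually)", x$variability_halfwidth)
                else ""))
    cat(sprintf("  years: %d (measured %d-%d) | seed: %d\n",
                x$n_years, x$measure_window[1], x$measure_window[2], x$seed))
    invisible(x)
}
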