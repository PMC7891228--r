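#' Realised annual cost of reproduction
#'
#' In a constant environment the realised cost equals the base cost.  With
#' interannual variability a uniform integer perturbation on
#' \code{[-halfwidth, halfwidth]} (mean 0, drawn independently each year, no
#' temporal autocorrelation) is added; the result is floored at 0.
#'
#' @param base_cost non-negative base cost of reproduction.
#' @param variable logical; perturb this year's cost?
#' @param halfwidth perturbation half-width (default 7).
#' @return realised integer cost for the year.
#' @export
#' @examples
#' sample_annual_cost(30, FALSE)       # 30
#' set.seed(1); sample_annual_cost(30, TRUE)  # in 23..37
sample_annual_cost <- function(base_cost, variable, halfwidth = 7) {
    if (base_cost < 0) stop("base_cost must be >= 0", call. = FALSE)
    if (!isTRUE(variable)) return(base_cost)
    delta <- sample.int(2L * halfwidth + 1L, 1L) - halfwidth - 1L
    max(0, base_cost + delta)
}

#' Logistic prey update
#'
#' One year of discrete logistic growth, \code{n + r n (1 - n/K)}, floored at
#' 0.  Vectorised over \code{n}.
#'
#' @param n current animal count(s), >= 0.
#' @param r per-year growth rate.
#' @param k carrying capacity, > 0.
#' @return updated animal count(s).
#' @export
#' @examples
#' logistic_update(50, 0.2, 100)   # 55
#' logistic_update(100, 0.2, 100)  # 100: at capacity
logistic_update <- function(n, r, k) {
    if (any(k <= 0)) stop("carrying capacity k must be > 0", call. = FALSE)
    out <- n + r * n * (1 - n / k)
    out[out < 0] <- 0  # preserves dim, unlike pmax(0, .)
    out
}

#' Distance-dependent encounter probability
#'
#' Probability that a randomly drawn pair of groups actually meets, as a
#' function of the toroidal distance between their foci:
#' \code{exp(-distance / scale)}.  Equals 1 at distance 0 and decreases
#' strictly with distance, so nearby groups interact more often.
#'
#' @param distance toroidal distance(s) between foci, >= 0.
#' @param scale e-folding distance of the kernel, > 0.
#' @return probability in (0, 1].
#' @export
#' @examples
#' interaction_probability(0, 10)   # 1
#' interaction_probability(10, 10)  # exp(-1)
interaction_probability <- function(distance, scale) {
    if (any(scale <= 0)) stop("encounter scale must be > 0", call. = FALSE)
    if (any(distance < 0)) stop("distance must be >= 0", call. = FALSE)
    exp(-distance / scale)
}

#' Food transferred at a tolerant encounter
#'
#' The sharing rule: the donor gives the smaller of its surplus and the
#' recipient's deficit.  Surplus and deficit are measured against each
#' group's annual reserve — its maintenance need (member count times
#' per-capita maintenance) plus the year's realised cost of reproduction —
#' so transfers can both avert starvation and fund a birth in the receiving
#' group, while donors never give away food they need to subsist and
#' reproduce themselves.  Pure function.
#'
#' @param donor_surplus donor's food above its maintenance need, >= 0.
#' @param recipient_deficit recipient's shortfall below its need, >= 0.
#' @return food units transferred.
#' @export
#' @examples
#' attempt_transfer(10, 4)  # 4
#' attempt_transfer(3, 8)   # 3
attempt_transfer <- function(donor_surplus, recipient_deficit) {
    if (donor_surplus < 0 || recipient_deficit < 0) {
        stop("surplus and deficit must be >= 0", call. = FALSE)
    }
    min(donor_surplus, recipient_deficit)
}

#' Annual death probability at a given age
#'
#' Looks an age up in a closed mortality table (annual probabilities indexed
#' by age 0..terminal, final entry 1); ages beyond the table's end return 1.
#'
#' @param age age(s) in years, >= 0.
#' @param schedule numeric probability vector as in
#'   \code{\link{default_mortality_schedule}}.
#' @return annual death probability in [0, 1], vectorised over \code{age}.
#' @export
#' @examples
#' death_probability(90, default_mortality_schedule())  # 1
death_probability <- function(age, schedule = default_mortality_schedule()) {
    if (any(age < 0)) stop("age must be >= 0", call. = FALSE)
    schedule[pmin(age, length(schedule) - 1L) + 1L]
}

#' One forager's annual foray
#'
#' Runs a single random-walk foray from \code{start}: \code{foray_steps}
#' steps of \code{step_length} grid units in uniform random directions
#' (toroidal wrap), with a hunt attempt at the end of each step.  An attempt
#' in a cell with \code{n} animals succeeds with probability
#' \code{n / (n + capture_halfsat)} (possible only while the cell holds at
#' least one animal); each success removes one animal from the cell and
#' yields one food unit.  Mutates \code{state$cells}; the forager's position
#' is transient and returned, not stored.
#'
#' @param state a \code{sim_state}.
#' @param start numeric (x, y) start position, normally a group focus.
#' @return list with \code{harvest} (food units), and the end position
#'   \code{x}, \code{y}.
#' @export
foray <- function(state, start) {
    cfg <- state$config
    state$cells <- state$cells + 0  # unshare before in-place mutation
    res <- foray_cpp(state$cells, start[1], start[2], cfg$foray_steps,
                     cfg$step_length, cfg$capture_halfsat)
    res
}

#' Hunting phase
#'
#' Every individual strictly older than \code{hunting_min_age} starts at its
#' group's focus and performs one \code{\link{foray}}; successes add food to
#' the hunter's group stock and remove animals from the landscape one for
#' one.  Hunter end positions are kept on the state (for snapshots only).
#'
#' @param state a \code{sim_state}; mutated in place.
#' @return invisibly, a list with \code{harvested} (total food units).
#' @export
hunting_phase <- function(state) {
    cfg <- state$config
    eligible <- which(state$i_age > cfg$hunting_min_age)
    if (length(eligible) == 0L || length(state$g_id) == 0L) {
        state$forager_x <- numeric(0)
        state$forager_y <- numeric(0)
        return(invisible(list(harvested = 0)))
    }
    gidx <- match(state$i_gid[eligible], state$g_id)
    state$cells <- state$cells + 0  # unshare before in-place mutation
    res <- hunt_cpp(state$cells, state$g_x, state$g_y, gidx,
                    cfg$foray_steps, cfg$step_length, cfg$capture_halfsat)
    state$g_stock <- state$g_stock + res$harvest
    state$forager_x <- res$x
    state$forager_y <- res$y
    invisible(list(harvested = sum(res$harvest)))
}

#' Intergroup interaction phase
#'
#' Draws \code{encounter_pairs_per_year} unordered pairs of distinct groups
#' uniformly at random (default: three times the current number of groups);
#' each pair meets with probability
#' \code{\link{interaction_probability}} of the toroidal distance between
#' their foci.  In a tolerant run a meeting transfers
#' \code{\link{attempt_transfer}} food units from the group with a surplus to
#' the one with a deficit, both relative to the group's reserve of
#' maintenance need plus the year's realised cost of reproduction; in an
#' avoidant run meetings have no effect.  Total group food is conserved.
#'
#' @param state a \code{sim_state}; mutated in place.
#' @return invisibly, a list with \code{transferred} (food units) and
#'   \code{meetings} (realised encounters).
#' @export
interaction_phase <- function(state) {
    cfg <- state$config
    ng <- length(state$g_id)
    if (ng < 2L) return(invisible(list(transferred = 0, meetings = 0L)))
    n_pairs <- if (is.na(cfg$encounter_pairs_per_year)) 3L * ng
               else cfg$encounter_pairs_per_year
    if (n_pairs == 0L) return(invisible(list(transferred = 0, meetings = 0L)))
    # reserve: subsistence for every member plus one birth at this year's cost
    need <- group_sizes(state) * cfg$maintenance_per_capita + state$last_cost
    # draw all pairs at once: ordered uniform pairs of distinct groups
    i <- sample.int(ng, n_pairs, replace = TRUE)
    j <- sample.int(ng, n_pairs, replace = TRUE)
    repeat {
        dup <- i == j
        if (!any(dup)) break
        j[dup] <- sample.int(ng, sum(dup), replace = TRUE)
    }
    d <- toroidal_distance(state$g_x[i], state$g_y[i],
                           state$g_x[j], state$g_y[j], cfg$grid_side)
    meets <- stats::runif(n_pairs) <
        interaction_probability(d, cfg$encounter_scale)
    meetings <- sum(meets)
    transferred <- 0
    if (cfg$tolerant && meetings > 0L) {
        # transfers are sequential: each meeting sees the stocks as left by
        # the previous one
        for (p in which(meets)) {
            gi <- i[p]; gj <- j[p]
            bal_i <- state$g_stock[gi] - need[gi]
            bal_j <- state$g_stock[gj] - need[gj]
            if (bal_i > 0 && bal_j < 0) {
                amt <- attempt_transfer(bal_i, -bal_j)
                state$g_stock[gi] <- state$g_stock[gi] - amt
                state$g_stock[gj] <- state$g_stock[gj] + amt
                transferred <- transferred + amt
            } else if (bal_j > 0 && bal_i < 0) {
                amt <- attempt_transfer(bal_j, -bal_i)
                state$g_stock[gj] <- state$g_stock[gj] - amt
                state$g_stock[gi] <- state$g_stock[gi] + amt
                transferred <- transferred + amt
            }
        }
    }
    invisible(list(transferred = transferred, meetings = meetings))
}

#' Maintenance and starvation phase
#'
#' Each group pays one unit of food per member (times
#' \code{maintenance_per_capita}).  A group that cannot cover the need sets
#' its stock to zero and loses \code{ceiling(shortfall / per-capita)} members
#' to starvation, chosen uniformly at random.
#'
#' @param state a \code{sim_state}; mutated in place.
#' @return invisibly, a list with \code{starved} (death count).
#' @export
maintenance_phase <- function(state) {
    cfg <- state$config
    ng <- length(state$g_id)
    if (ng == 0L) return(invisible(list(starved = 0L)))
    sizes <- group_sizes(state)
    need <- sizes * cfg$maintenance_per_capita
    fed <- state$g_stock >= need
    state$g_stock[fed] <- state$g_stock[fed] - need[fed]
    starved_total <- 0L
    short_g <- which(!fed)
    if (length(short_g) > 0L && cfg$maintenance_per_capita > 0) {
        members_of <- split(seq_along(state$i_gid),
                            factor(state$i_gid,
                                   levels = state$g_id[short_g]))
        kill <- integer(0)
        for (s in seq_along(short_g)) {
            g <- short_g[s]
            if (sizes[g] == 0L) { state$g_stock[g] <- 0; next }
            shortfall <- need[g] - state$g_stock[g]
            state$g_stock[g] <- 0
            k <- min(sizes[g],
                     ceiling(shortfall / cfg$maintenance_per_capita))
            members <- members_of[[s]]
            kill <- c(kill, members[sample.int(length(members), k)])
            starved_total <- starved_total + k
        }
        if (length(kill) > 0L) remove_individuals(state, kill)
    } else {
        state$g_stock[!fed] <- 0
    }
    invisible(list(starved = starved_total))
}

#' Ageing, death and birth phase
#'
#' Survivors of maintenance age by one year; each then dies independently
#' with the age-specific probability of the mortality table.  Births follow:
#' within each group, every fertile female (age within
#' \code{fertile_age_range}) can produce at most one offspring, and offspring
#' are produced while the group's remaining stock covers the year's realised
#' cost of reproduction, debiting the stock per birth.  Because fertile
#' females are interchangeable, the number of births in a group is
#' \code{min(n_fertile, floor(stock / cost))}.  Newborns enter at age 0 with
#' even-chance sex.
#'
#' @param state a \code{sim_state}; mutated in place.
#' @param cost this year's realised cost of reproduction (defaults to the
#'   state's last sampled cost).
#' @return invisibly, a list with \code{births} and \code{deaths_age}.
#' @export
demography_phase <- function(state, cost = state$last_cost) {
    cfg <- state$config
    n <- length(state$i_id)
    if (n == 0L) return(invisible(list(births = 0L, deaths_age = 0L)))
    state$i_age <- state$i_age + 1L
    p <- death_probability(state$i_age, cfg$mortality_schedule)
    dies <- stats::runif(n) < p
    deaths_age <- sum(dies)
    if (deaths_age > 0L) remove_individuals(state, which(dies))

    births_total <- 0L
    ng <- length(state$g_id)
    if (ng > 0L && length(state$i_id) > 0L) {
        fertile <- state$i_sex == 0L &
            state$i_age >= cfg$fertile_age_range[1] &
            state$i_age <= cfg$fertile_age_range[2]
        n_fert <- tabulate(match(state$i_gid[fertile], state$g_id),
                           nbins = ng)
        max_afford <- if (cost > 0) floor(state$g_stock / cost)
                      else n_fert
        births <- pmin(n_fert, pmax(0, max_afford))
        births_total <- as.integer(sum(births))
        if (births_total > 0L) {
            state$g_stock <- state$g_stock - births * cost
            new_gid <- rep(state$g_id, births)
            new_ids <- seq.int(state$next_iid,
                               length.out = births_total)
            state$next_iid <- state$next_iid + births_total
            state$i_id <- c(state$i_id, new_ids)
            state$i_age <- c(state$i_age, integer(births_total))
            state$i_sex <- c(state$i_sex,
                             as.integer(stats::runif(births_total) < 0.5))
            state$i_gid <- c(state$i_gid, new_gid)
        }
    }
    invisible(list(births = births_total, deaths_age = deaths_age))
}

#' Group fission and loss phase
#'
#' Groups at or above \code{fission_threshold} members split repeatedly:
#' members are assigned to the two daughters with even chance, one daughter
#' keeps the parent focus, the other's focus is placed uniformly at random
#' within \code{fission_relocation_radius} (toroidal), and the parent stock
#' is divided in proportion to daughter sizes.  Afterwards every group below
#' \code{dissolution_threshold} members is dissolved and its remaining
#' members die, so surviving group sizes end the phase in
#' \code{[dissolution_threshold, fission_threshold - 1]}.
#'
#' @param state a \code{sim_state}; mutated in place.
#' @return invisibly, a list with \code{fissions} and \code{dissolutions}.
#' @export
fission_loss_phase <- function(state) {
    cfg <- state$config
    fissions <- 0L
    sizes <- group_sizes(state)
    repeat {
        big <- which(sizes >= cfg$fission_threshold)
        if (length(big) == 0L) break
        g <- big[1]
        members <- which(state$i_gid == state$g_id[g])
        to_new <- stats::runif(length(members)) < 0.5
        n_new <- sum(to_new)
        fissions <- fissions + 1L
        if (n_new == 0L || n_new == length(members)) next
        new_id <- state$next_gid
        state$next_gid <- state$next_gid + 1L
        new_focus <- disc_jitter(state$g_x[g], state$g_y[g],
                                 cfg$fission_relocation_radius,
                                 cfg$grid_side)
        frac <- n_new / length(members)
        new_stock <- state$g_stock[g] * frac
        state$g_stock[g] <- state$g_stock[g] - new_stock
        state$g_id <- c(state$g_id, new_id)
        state$g_x <- c(state$g_x, new_focus[1])
        state$g_y <- c(state$g_y, new_focus[2])
        state$g_stock <- c(state$g_stock, new_stock)
        state$i_gid[members[to_new]] <- new_id
        sizes[g] <- sizes[g] - n_new
        sizes <- c(sizes, n_new)
    }
    small <- which(sizes < cfg$dissolution_threshold)
    dissolutions <- length(small)
    if (dissolutions > 0L) {
        doomed_ids <- state$g_id[small]
        victims <- which(state$i_gid %in% doomed_ids)
        if (length(victims) > 0L) remove_individuals(state, victims)
        keep <- -small
        state$g_id <- state$g_id[keep]
        state$g_x <- state$g_x[keep]
        state$g_y <- state$g_y[keep]
        state$g_stock <- state$g_stock[keep]
    }
    invisible(list(fissions = fissions, dissolutions = dissolutions))
}

#' Prey regrowth phase
#'
#' Updates every landscape cell independently by one year of logistic growth
#' with \code{prey_growth_rate} and \code{prey_capacity}.
#'
#' @param state a \code{sim_state}; mutated in place.
#' @return the state, invisibly.
#' @export
animal_growth_phase <- function(state) {
    cfg <- state$config
    state$cells <- logistic_update(state$cells, cfg$prey_growth_rate,
                                   cfg$prey_capacity)
    invisible(state)
}

# Drop individuals by position index, keeping all parallel vectors in step.
remove_individuals <- function(state, idx) {
    keep <- -idx
    state$i_id <- state$i_id[keep]
    state$i_age <- state$i_age[keep]
    state$i_sex <- state$i_sex[keep]
    state$i_gid <- state$i_gid[keep]
    invisible(state)
}

#' Advance the simulation by one year
#'
#' Executes the annual cycle in order: camp relocation (uniform move within
#' \code{camp_relocation_radius}; radius 0 keeps camps fixed), reset of all
#' food stocks (no storage between years), sampling of the realised cost of
#' reproduction, hunting, intergroup interactions, maintenance/starvation,
#' ageing-death-birth, group fission and loss, and prey regrowth.  Increments
#' the year and marks the state extinct when the population reaches zero.
#' Extinction is absorbing: called on an extinct state, the function returns
#' an all-zero record (at the unchanged year) without mutating anything.
#'
#' @param state a \code{sim_state}; mutated in place.
#' @return a one-row data.frame audit record with columns \code{year},
#'   \code{total_population}, \code{n_groups}, \code{total_food_harvested},
#'   \code{total_food_transferred}, \code{n_births}, \code{n_deaths_age},
#'   \code{n_deaths_starvation}, \code{n_fissions}, \code{n_dissolutions},
#'   \code{annual_cost_of_reproduction}.
#' @export
step_year <- function(state) {
    as.data.frame(step_year_core(state))
}

# Fast path used by run_realisation: same cycle, record as a plain list.
step_year_core <- function(state) {
    cfg <- state$config
    if (!state$alive) {
        return(year_record(state$year, 0L, 0L, 0, 0, 0L, 0L, 0L, 0L, 0L, 0))
    }
    ng <- length(state$g_id)
    if (cfg$camp_relocation_radius > 0 && ng > 0L) {
        rad <- cfg$camp_relocation_radius * sqrt(stats::runif(ng))
        ang <- 2 * pi * stats::runif(ng)
        state$g_x <- (state$g_x + rad * cos(ang)) %% cfg$grid_side
        state$g_y <- (state$g_y + rad * sin(ang)) %% cfg$grid_side
    }
    state$g_stock[] <- 0
    cost <- sample_annual_cost(cfg$cost_of_reproduction,
                               cfg$variable_environment,
                               cfg$variability_halfwidth)
    state$last_cost <- cost
    hunt <- hunting_phase(state)
    inter <- interaction_phase(state)
    maint <- maintenance_phase(state)
    demo <- demography_phase(state, cost)
    fiss <- fission_loss_phase(state)
    animal_growth_phase(state)
    state$year <- state$year + 1L
    pop <- population_size(state)
    if (pop == 0L) state$alive <- FALSE
    year_record(state$year, pop, length(state$g_id), hunt$harvested,
                inter$transferred, demo$births, demo$deaths_age,
                maint$starved, fiss$fissions, fiss$dissolutions, cost)
}

year_record <- function(year, pop, ngroups, harvested, transferred, births,
                        deaths_age, starved, fissions, dissolutions, cost) {
    list(year = year,
               total_population = pop,
               n_groups = ngroups,
               total_food_harvested = harvested,
               total_food_transferred = transferred,
               n_births = births,
               n_deaths_age = deaths_age,
               n_deaths_starvation = starved,
               n_fissions = fissions,
               n_dissolutions = dissolutions,
               annual_cost_of_reproduction = cost)
}
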