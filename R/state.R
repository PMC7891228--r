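#' Initialise the simulation world
#'
#' Seeds the RNG from \code{config$seed} and builds the year-0 state: group
#' foci uniform in continuous space, individuals assigned to groups uniformly
#' at random with uniform integer ages and even-chance sex, and independent
#' per-cell prey populations drawn as uniform integers.  All group food
#' stocks start at zero (there is no storage between years).
#'
#' The state is an environment (reference semantics): phase functions mutate
#' it in place and a state is never shared between runs.
#'
#' @param config a \code{\link{sim_config}}.
#' @return an environment of class \code{sim_state} with fields
#'   \code{config}, \code{year}, \code{cells} (grid_side x grid_side numeric
#'   matrix of prey), group vectors (\code{g_id}, \code{g_x}, \code{g_y},
#'   \code{g_stock}), individual vectors (\code{i_id}, \code{i_age},
#'   \code{i_sex} with 0 = female / 1 = male, \code{i_gid}), counters and the
#'   \code{alive} flag.
#' @export
#' @examples
#' st <- init_state(sim_config(n_years = 10, measure_window = c(1, 10)))
#' population_size(st)
init_state <- function(config) {
    validate_config(config)
    set.seed(config$seed)
    st <- new.env(parent = emptyenv())
    st$config <- config
    st$year <- 0L
    side <- config$grid_side
    ncell <- side * side
    st$cells <- matrix(
        as.numeric(sample.int(
            config$init_animal_range[2] - config$init_animal_range[1] + 1L,
            ncell, replace = TRUE) + config$init_animal_range[1] - 1L),
        nrow = side, ncol = side)

    ng <- config$n_groups_init
    st$g_id <- seq_len(ng)
    st$g_x <- stats::runif(ng, 0, side)
    st$g_y <- stats::runif(ng, 0, side)
    st$g_stock <- numeric(ng)

    ni <- config$n_individuals_init
    st$i_id <- seq_len(ni)
    ages <- config$init_age_range
    st$i_age <- as.integer(sample.int(ages[2] - ages[1] + 1L, ni,
                                      replace = TRUE) + ages[1] - 1L)
    st$i_sex <- as.integer(stats::runif(ni) < 0.5)  # 0 = female, 1 = male
    st$i_gid <- if (ng > 0) sample.int(ng, ni, replace = TRUE) else integer(0)

    st$next_gid <- ng + 1L
    st$next_iid <- ni + 1L
    st$forager_x <- numeric(0)
    st$forager_y <- numeric(0)
    st$last_cost <- config$cost_of_reproduction
    st$alive <- ni > 0L
    class(st) <- "sim_state"
    st
}

#' Total living population of a state
#' @param state a \code{sim_state}.
#' @return integer count of living individuals.
#' @export
population_size <- function(state) length(state$i_id)

#' Group sizes of a state
#' @param state a \code{sim_state}.
#' @return integer vector of member counts, one per living group (in the
#'   order of the state's group vectors).
#' @export
group_sizes <- function(state) {
    tabulate(match(state$i_gid, state$g_id), nbins = length(state$g_id))
}

#' @export
print.sim_state <- function(x, ...) {
    cat("Simulation state (sim_state)\n")
    cat(sprintf("  year %d | %d individuals in %d groups | %s\n",
                x$year, population_size(x), length(x$g_id),
                if (x$alive) "alive" else "extinct"))
    cat(sprintf("  prey: total %.0f animals on %d x %d cells\n",
                sum(x$cells), nrow(x$cells), ncol(x$cells)))
    invisible(x)
}

#' Toroidal distance
#'
#' Euclidean distance between points on the \code{[0, side) x [0, side)}
#' torus (the landscape has no edges).  Vectorised.
#'
#' @param x1,y1,x2,y2 coordinates.
#' @param side torus side length.
#' @return distance(s) in grid units.
#' @export
toroidal_distance <- function(x1, y1, x2, y2, side) {
    dx <- abs(x1 - x2)
    dx <- pmin(dx, side - dx)
    dy <- abs(y1 - y2)
    dy <- pmin(dy, side - dy)
    sqrt(dx * dx + dy * dy)
}

# Uniform point in a disc of radius r around (x, y), wrapped onto the torus.
disc_jitter <- function(x, y, r, side) {
    rad <- r * sqrt(stats::runif(1))
    ang <- stats::runif(1) * 2 * pi
    c((x + rad * cos(ang)) %% side, (y + rad * sin(ang)) %% side)
}
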