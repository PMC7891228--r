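# Shared fixtures: all worlds are generated in code at test time.

# A small, fast world for property-style tests.
tiny_config <- function(...) {
    defaults <- list(grid_side = 20, n_groups_init = 8,
                     n_individuals_init = 160, n_years = 20,
                     measure_window = c(11, 20), seed = 42)
    do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# A state whose groups/individuals are overwritten to an exact scenario.
# `sizes` gives member counts per group; all individuals share `age`/`sex`
# unless vectors are supplied.  Foci and stocks positional.
scripted_state <- function(sizes, stocks = NULL, foci_x = NULL,
                           foci_y = NULL, age = 25L, sex = 0L, ...) {
    ng <- length(sizes)
    n <- sum(sizes)
    cfg <- sim_config(grid_side = 5, n_groups_init = ng,
                      n_individuals_init = max(n, 1), n_years = 10,
                      measure_window = c(1, 10), camp_relocation_radius = 0,
                      seed = 1, ...)
    st <- init_state(cfg)
    st$g_id <- seq_len(ng)
    st$g_x <- if (is.null(foci_x)) rep(2.5, ng) else foci_x
    st$g_y <- if (is.null(foci_y)) rep(2.5, ng) else foci_y
    st$g_stock <- if (is.null(stocks)) numeric(ng) else as.numeric(stocks)
    st$i_id <- seq_len(n)
    st$i_age <- rep_len(as.integer(age), n)
    st$i_sex <- rep_len(as.integer(sex), n)
    st$i_gid <- rep(seq_len(ng), times = sizes)
    st$next_gid <- ng + 1L
    st$next_iid <- n + 1L
    st$alive <- n > 0
    st
}

# A mortality schedule with no death before the terminal age: isolates
# food-driven dynamics in phase tests.
no_death_schedule <- function(terminal_age = 200) {
    c(rep(0, terminal_age), 1)
}

# Independent brute-force two-way ANOVA from cell/marginal/grand means,
# used as the oracle for the stats module.
brute_force_anova <- function(d, response = "y") {
    y <- d[[response]]
    a <- factor(d$cost)
    b <- factor(d$strategy)
    gm <- mean(y)
    am <- tapply(y, a, mean)
    bm <- tapply(y, b, mean)
    cm <- tapply(y, list(a, b), mean)
    ss_a <- sum(table(a) * (am - gm)^2)
    ss_b <- sum(table(b) * (bm - gm)^2)
    ss_cells <- sum(table(a, b) * (cm - gm)^2)
    ss_ab <- ss_cells - ss_a - ss_b
    ss_tot <- sum((y - gm)^2)
    ss_err <- ss_tot - ss_cells
    list(cost = ss_a, tolerance = ss_b, interaction = ss_ab,
         error = ss_err, total = ss_tot)
}

# Random balanced factorial data set for oracle-equivalence checks.
random_balanced_design <- function(n_a, n_b, reps) {
    d <- expand.grid(cost = seq_len(n_a) + 25,
                     strategy = paste0("s", seq_len(n_b)),
                     replicate = seq_len(reps))
    d$y <- stats::rnorm(nrow(d), mean = 10 * as.integer(factor(d$cost)) +
                            3 * as.integer(factor(d$strategy)), sd = 2)
    d
}
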