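#' Run one complete realisation
#'
#' Initialises a world from \code{config} (seeding the RNG from
#' \code{config$seed}) and advances it year by year to \code{n_years} or to
#' extinction.  The headline output is the mean total population over the
#' measurement window (years after extinction count as population 0, which
#' keeps the mean defined for every run) together with a survival flag
#' (population above zero at the final year).
#'
#' @param config a \code{\link{sim_config}}.
#' @param keep_series keep the per-year audit table (\code{years}) and the
#'   population series on the summary?  Default \code{TRUE}; the factorial
#'   runner switches it off to save memory.
#' @param replicate optional replicate index recorded on the summary.
#' @return a list of class \code{realisation_summary} with fields
#'   \code{strategy}, \code{cost_base}, \code{variable_environment},
#'   \code{replicate}, \code{seed}, \code{mean_population}, \code{survived},
#'   \code{extinction_year} (\code{NA} if the run persisted),
#'   \code{final_state} omitted; plus \code{population_series} and
#'   \code{years} when \code{keep_series = TRUE}.
#' @export
#' @examples
#' cfg <- sim_config(grid_side = 12, n_groups_init = 4,
#'                   n_individuals_init = 60, n_years = 5,
#'                   measure_window = c(4, 5), seed = 7)
#' run_realisation(cfg)$mean_population
run_realisation <- function(config, keep_series = TRUE, replicate = NA_integer_) {
    validate_config(config)
    state <- init_state(config)
    ny <- config$n_years
    rec_names <- names(year_record(0L, 0L, 0L, 0, 0, 0L, 0L, 0L, 0L, 0L, 0))
    recs <- matrix(0, nrow = ny, ncol = length(rec_names),
                   dimnames = list(NULL, rec_names))
    for (t in seq_len(ny)) {
        r <- step_year_core(state)
        r$year <- t  # post-extinction padding keeps the series aligned
        recs[t, ] <- unlist(r, use.names = FALSE)
    }
    pop <- unname(recs[, "total_population"])
    win <- config$measure_window
    mean_pop <- mean(pop[win[1]:win[2]])
    survived <- pop[ny] > 0
    ext <- if (survived) NA_integer_ else as.integer(which(pop == 0)[1])
    out <- list(
        strategy = if (config$tolerant) "tolerant" else "avoidant",
        cost_base = config$cost_of_reproduction,
        variable_environment = config$variable_environment,
        replicate = replicate,
        seed = config$seed,
        mean_population = mean_pop,
        survived = survived,
        extinction_year = ext
    )
    if (keep_series) {
        out$population_series <- pop
        out$years <- as.data.frame(recs)
    }
    class(out) <- "realisation_summary"
    out
}

#' @export
print.realisation_summary <- function(x, ...) {
    cat(sprintf(
        "Realisation: %s, cost %g%s, seed %d\n  mean population %.1f | %s\n",
        x$strategy, x$cost_base,
        if (x$variable_environment) " (variable)" else "",
        x$seed, x$mean_population,
        if (x$survived) "survived"
        else sprintf("extinct in year %d", x$extinction_year)))
    invisible(x)
}

#' Deterministic per-realisation seed
#'
#' Mixes the master seed, cost level, replicate index and strategy into a
#' 31-bit seed with a multiplicative-congruential hash, so a factorial sweep
#' is a pure function of its design and master seed, and paired
#' tolerant/avoidant replicates are identified by their shared replicate
#' index (not by a shared random stream).
#'
#' @param master_seed integer master seed.
#' @param tolerant logical strategy flag.
#' @param cost cost-of-reproduction level.
#' @param replicate replicate index (1-based).
#' @param variable variable-environment flag.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master_seed, tolerant, cost, replicate,
                        variable = FALSE) {
    m <- 2147483647  # 2^31 - 1, prime
    s <- as.numeric(master_seed) %% m
    for (k in c(cost + 1, replicate + 1,
                as.integer(tolerant) + 1, as.integer(variable) + 1)) {
        s <- (s * 69069 + k) %% m
    }
    as.integer(s %% (m - 1)) + 1L
}

#' Run the factorial simulation experiment
#'
#' One realisation per (strategy, cost, replicate) cell, with per-realisation
#' seeds derived deterministically from the master seed
#' (\code{\link{derive_seed}}).  Tolerant and avoidant runs sharing a
#' replicate index form a pair for the population-size ratio analysis.
#'
#' @param base_config the configuration shared by all runs (its
#'   \code{tolerant}, \code{cost_of_reproduction},
#'   \code{variable_environment} and \code{seed} fields are overridden per
#'   cell).
#' @param costs integer vector of cost-of-reproduction levels (the published
#'   gradient is 26:35).
#' @param strategies character subset of \code{c("avoidant", "tolerant")}.
#' @param n_reps replicates per cell (200 at full scale).
#' @param variable run the variable-environment arm?
#' @param master_seed integer master seed for the whole sweep.
#' @param progress print a line per completed cell?
#' @return a data.frame of class \code{result_table}: one row per realisation
#'   with columns \code{strategy}, \code{cost}, \code{variable},
#'   \code{replicate}, \code{seed}, \code{mean_population}, \code{survived},
#'   \code{extinction_year}.
#' @export
run_factorial <- function(base_config, costs = 26:35,
                          strategies = c("avoidant", "tolerant"),
                          n_reps = 200, variable = FALSE,
                          master_seed = 1, progress = FALSE) {
    stopifnot(length(costs) >= 1, n_reps >= 1,
              all(strategies %in% c("avoidant", "tolerant")))
    rows <- vector("list", length(strategies) * length(costs) * n_reps)
    k <- 0L
    for (strat in strategies) {
        tol <- strat == "tolerant"
        for (cost in costs) {
            for (rep_i in seq_len(n_reps)) {
                seed <- derive_seed(master_seed, tol, cost, rep_i, variable)
                cfg <- base_config
                cfg$tolerant <- tol
                cfg$cost_of_reproduction <- as.numeric(cost)
                cfg$variable_environment <- variable
                cfg$seed <- seed
                s <- run_realisation(cfg, keep_series = FALSE,
                                     replicate = rep_i)
                k <- k + 1L
                rows[[k]] <- data.frame(
                    strategy = strat, cost = cost, variable = variable,
                    replicate = rep_i, seed = seed,
                    mean_population = s$mean_population,
                    survived = s$survived,
                    extinction_year = if (is.na(s$extinction_year))
                        NA_integer_ else s$extinction_year)
            }
            if (progress) {
                message(sprintf("  %s cost %d done (%d runs)", strat, cost,
                                n_reps))
            }
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("result_table", "data.frame")
    out
}

#' Proportion of replicates surviving in one design cell
#'
#' @param table a \code{result_table}.
#' @param strategy \code{"avoidant"} or \code{"tolerant"}.
#' @param cost cost-of-reproduction level.
#' @return fraction of replicates with population above zero at the end.
#' @export
survival_proportion <- function(table, strategy, cost) {
    rows <- table$strategy == strategy & table$cost == cost
    if (!any(rows)) {
        stop("no replicates for strategy '", strategy, "' at cost ", cost,
             call. = FALSE)
    }
    mean(table$survived[rows])
}

#' Paired tolerant/avoidant population ratio at one cost level
#'
#' Pairs tolerant and avoidant replicates by replicate index.  Per-pair
#' ratios (tolerant mean population / avoidant mean population) are computed
#' only for pairs in which both members persisted to the end; the summary
#' reports their mean with a normal-approximation 95\% confidence interval.
#' The cell-mean ratio (mean over surviving tolerant runs divided by mean
#' over surviving avoidant runs) is reported alongside, as used for the
#' interaction curves.
#'
#' @param table a \code{result_table} holding both strategies at \code{cost}.
#' @param cost cost-of-reproduction level.
#' @return a list with \code{cost}, \code{ratios} (per surviving pair),
#'   \code{n_pairs}, \code{mean_ratio}, \code{ci} (length-2), and
#'   \code{cell_mean_ratio}; all-\code{NA} summary values (and a zero-length
#'   \code{ratios}) if no pair survived.
#' @export
paired_ratio <- function(table, cost) {
    tol <- table[table$strategy == "tolerant" & table$cost == cost, ]
    avo <- table[table$strategy == "avoidant" & table$cost == cost, ]
    m <- merge(tol, avo, by = "replicate", suffixes = c("_tol", "_avo"))
    both <- m$survived_tol & m$survived_avo
    ratios <- m$mean_population_tol[both] / m$mean_population_avo[both]
    n <- length(ratios)
    if (n == 0L) {
        return(list(cost = cost, ratios = numeric(0), n_pairs = 0L,
                    mean_ratio = NA_real_, ci = c(NA_real_, NA_real_),
                    cell_mean_ratio = NA_real_))
    }
    mr <- mean(ratios)
    se <- if (n > 1) stats::sd(ratios) / sqrt(n) else NA_real_
    ci <- if (n > 1) mr + c(-1.96, 1.96) * se else c(NA_real_, NA_real_)
    cell <- mean(tol$mean_population[tol$survived]) /
        mean(avo$mean_population[avo$survived])
    list(cost = cost, ratios = ratios, n_pairs = n, mean_ratio = mr,
         ci = ci, cell_mean_ratio = cell)
}

#' Ratio curve across the cost gradient
#'
#' Applies \code{\link{paired_ratio}} at every cost level present in the
#' table and stacks the summaries.
#'
#' @param table a \code{result_table} holding both strategies.
#' @return data.frame with one row per cost: \code{cost}, \code{n_pairs},
#'   \code{mean_pair_ratio}, \code{ci_lo}, \code{ci_hi},
#'   \code{cell_mean_ratio}.
#' @export
ratio_by_cost <- function(table) {
    costs <- sort(unique(table$cost))
    do.call(rbind, lapply(costs, function(cc) {
        pr <- paired_ratio(table, cc)
        data.frame(cost = cc, n_pairs = pr$n_pairs,
                   mean_pair_ratio = pr$mean_ratio,
                   ci_lo = pr$ci[1], ci_hi = pr$ci[2],
                   cell_mean_ratio = pr$cell_mean_ratio)
    }))
}

#' Mean population by design cell
#'
#' Convenience summary of a \code{result_table}: mean population per
#' (strategy, cost), both inclusive (extinct runs count their window mean,
#' typically 0) and over surviving runs only.
#'
#' @param table a \code{result_table}.
#' @return data.frame with columns \code{strategy}, \code{cost}, \code{n},
#'   \code{mean_population} (inclusive), \code{mean_population_surviving},
#'   \code{survival}.
#' @export
cell_means <- function(table) {
    sp <- split(table, list(table$strategy, table$cost), drop = TRUE)
    out <- do.call(rbind, lapply(sp, function(d) {
        data.frame(strategy = d$strategy[1], cost = d$cost[1], n = nrow(d),
                   mean_population = mean(d$mean_population),
                   mean_population_surviving =
                       if (any(d$survived))
                           mean(d$mean_population[d$survived])
                       else NA_real_,
                   survival = mean(d$survived))
    }))
    out <- out[order(out$cost, out$strategy), ]
    rownames(out) <- NULL
    out
}
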