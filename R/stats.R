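#' Two-way fixed-effects ANOVA of the factorial experiment
#'
#' Decomposes the response (mean population size by default) over the two
#' crossed factors of the design — cost of reproduction and tolerance
#' strategy — into main effects, their interaction, and error.  The design
#' must be balanced (equal replicates per cell), as the factorial runner
#' produces; with balance the sequential decomposition is unique, and
#' SS_total = SS_cost + SS_tolerance + SS_interaction + SS_error.  The fit is
#' delegated to \code{stats::aov}.  Classical
#' (\eqn{SS_{effect}/SS_{total}}) and partial
#' (\eqn{SS_{effect}/(SS_{effect}+SS_{error})}) eta-squared effect sizes are
#' attached per effect; for a constant response all sums of squares and
#' effect sizes are 0 by convention.
#'
#' P-values are reported for completeness, but effect sizes are the
#' meaningful summary here: with hundreds of cheap replicates of a
#' simulation, essentially any effect is "significant".
#'
#' @param table a \code{result_table} (or any data.frame with columns
#'   \code{cost}, \code{strategy} and the response).
#' @param response name of the response column.
#' @param surviving_only drop runs that went extinct before fitting?  The
#'   resulting design is then usually unbalanced and is balanced by
#'   subsampling is \emph{not} attempted: an error asks the caller to
#'   balance.  Default \code{FALSE} (extinct runs keep their window mean).
#' @return an object of class \code{tolsim_anova}: a list with \code{table}
#'   (data.frame with one row per term: \code{term}, \code{df}, \code{ss},
#'   \code{ms}, \code{f}, \code{p}, \code{classical_eta2},
#'   \code{partial_eta2}) and \code{ss_total}.
#' @export
#' @examples
#' d <- expand.grid(cost = c(26, 27), strategy = c("avoidant", "tolerant"),
#'                  replicate = 1:2)
#' d$mean_population <- c(10, 12, 20, 22, 30, 32, 40, 42)
#' two_way_anova(d)
two_way_anova <- function(table, response = "mean_population",
                          surviving_only = FALSE) {
    stopifnot(all(c("cost", "strategy", response) %in% names(table)))
    if (surviving_only) table <- table[table$survived, ]
    f_cost <- factor(table$cost)
    f_tol <- factor(table$strategy)
    if (nlevels(f_cost) < 2 || nlevels(f_tol) < 2) {
        stop("need at least 2 levels of each factor", call. = FALSE)
    }
    counts <- table(f_cost, f_tol)
    if (any(counts < 2)) {
        stop("need at least 2 replicates in every design cell",
             call. = FALSE)
    }
    if (length(unique(as.vector(counts))) != 1) {
        stop("unbalanced design: equal cell counts are required; ",
             "drop replicates to the minimum cell count before fitting",
             call. = FALSE)
    }
    y <- table[[response]]
    fit <- stats::aov(y ~ f_cost * f_tol)
    a <- summary(fit)[[1]]
    ss <- a[["Sum Sq"]]
    df <- a[["Df"]]
    # order: f_cost, f_tol, f_cost:f_tol, Residuals
    terms <- c("cost", "tolerance", "interaction", "error")
    ss_total <- sum(ss)
    ss_err <- ss[4]
    ms <- ss / df
    fval <- c(ms[1:3] / ms[4], NA_real_)
    pval <- c(stats::pf(fval[1:3], df[1:3], df[4], lower.tail = FALSE),
              NA_real_)
    # constant response: sums of squares are numerical noise around zero
    degenerate <- ss_total <= 1e-10 * nrow(table) * (1 + mean(y)^2)
    if (degenerate) {
        classical <- partial <- c(0, 0, 0, NA_real_)
        fval[] <- NA_real_
        pval[] <- NA_real_
    } else {
        classical <- c(ss[1:3] / ss_total, NA_real_)
        partial <- c(ifelse(ss[1:3] + ss_err > 0,
                            ss[1:3] / (ss[1:3] + ss_err), 0), NA_real_)
    }
    out <- list(
        table = data.frame(term = terms, df = df, ss = ss, ms = ms,
                           f = fval, p = pval,
                           classical_eta2 = classical,
                           partial_eta2 = partial),
        ss_total = ss_total,
        response = response,
        n = nrow(table)
    )
    class(out) <- "tolsim_anova"
    out
}

#' Eta-squared effect sizes of a fitted ANOVA
#'
#' @param anova a \code{\link{two_way_anova}} result.
#' @return data.frame with one row per effect (\code{cost},
#'   \code{tolerance}, \code{interaction}) and columns \code{classical} and
#'   \code{partial}.
#' @export
#' @examples
#' d <- expand.grid(cost = c(26, 27), strategy = c("avoidant", "tolerant"),
#'                  replicate = 1:2)
#' d$mean_population <- c(10, 12, 20, 22, 30, 32, 40, 42)
#' eta_squared(two_way_anova(d))
eta_squared <- function(anova) {
    stopifnot(inherits(anova, "tolsim_anova"))
    tab <- anova$table[anova$table$term != "error", ]
    data.frame(effect = tab$term,
               classical = tab$classical_eta2,
               partial = tab$partial_eta2,
               row.names = NULL)
}

#' @export
print.tolsim_anova <- function(x, ...) {
    cat(sprintf("Two-way ANOVA of %s (n = %d)\n", x$response, x$n))
    tab <- x$table
    tab$ss <- signif(tab$ss, 6)
    tab$ms <- signif(tab$ms, 6)
    tab$f <- signif(tab$f, 5)
    tab$p <- signif(tab$p, 3)
    tab$classical_eta2 <- round(tab$classical_eta2, 4)
    tab$partial_eta2 <- round(tab$partial_eta2, 4)
    print(tab, row.names = FALSE)
    invisible(x)
}
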