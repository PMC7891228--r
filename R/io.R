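#' Load a simulation configuration from YAML or JSON
#'
#' The document is a single flat mapping whose keys mirror the
#' \code{\link{sim_config}} field names exactly.  Absent fields take the
#' package defaults; unknown fields are an error (no silent typos).  The
#' result is validated before being returned.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return a validated \code{sim_config}.
#' @export
load_config <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    ext <- tolower(tools::file_ext(path))
    raw <- if (ext %in% c("yaml", "yml")) {
        yaml::read_yaml(path)
    } else if (ext == "json") {
        jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
        stop("unsupported config format '", ext, "' (use yaml or json)",
             call. = FALSE)
    }
    if (is.null(raw)) raw <- list()
    known <- names(formals(sim_config))
    unknown <- setdiff(names(raw), known)
    if (length(unknown) > 0) {
        stop("unknown configuration field(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
    }
    do.call(sim_config, raw)
}

#' Save a simulation configuration
#'
#' Writes the configuration as a flat YAML or JSON mapping (chosen by file
#' extension) that \code{\link{load_config}} reads back identically.
#'
#' @param config a \code{sim_config}.
#' @param path output path ending in \code{.yaml}/\code{.yml} or
#'   \code{.json}.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(config, path) {
    x <- unclass(config)
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("yaml", "yml")) {
        yaml::write_yaml(x, path)
    } else if (ext == "json") {
        jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, na = "null")
    } else {
        stop("unsupported config format '", ext, "' (use yaml or json)",
             call. = FALSE)
    }
    invisible(path)
}

#' Write per-run outputs
#'
#' Writes \code{years.csv} (one row per annual audit record) and
#' \code{summary.json} (the realisation summary) into \code{dir}.
#'
#' @param summary a \code{\link{run_realisation}} result with
#'   \code{keep_series = TRUE}.
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_realisation <- function(summary, dir) {
    if (is.null(summary$years)) {
        stop("summary has no per-year table; rerun with keep_series = TRUE",
             call. = FALSE)
    }
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    years_path <- file.path(dir, "years.csv")
    utils::write.csv(format_floats(summary$years), years_path,
                     row.names = FALSE, quote = FALSE)
    js <- summary[c("strategy", "cost_base", "variable_environment",
                    "replicate", "seed", "mean_population", "survived",
                    "extinction_year")]
    json_path <- file.path(dir, "summary.json")
    jsonlite::write_json(js, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    invisible(c(years_path, json_path))
}

# CSV dialect: '.' decimal, floats at 10 significant digits.
format_floats <- function(df) {
    for (j in seq_along(df)) {
        if (is.double(df[[j]])) {
            df[[j]] <- ifelse(is.na(df[[j]]), NA,
                              format(signif(df[[j]], 10), trim = TRUE,
                                     scientific = FALSE))
        }
    }
    df
}

#' Export a landscape snapshot
#'
#' Writes the state of the world for plotting: the per-cell prey matrix as
#' CSV (\code{<prefix>_cells.csv}; row i / column j holds the cell whose
#' continuous coordinates satisfy \code{floor(x) == i - 1},
#' \code{floor(y) == j - 1}), the group foci and (if a hunting phase has
#' run) the forager end positions as a points CSV
#' (\code{<prefix>_points.csv} with columns \code{kind,x,y}), and optionally
#' an ASCII PGM greyscale image of the prey matrix scaled from 0 (black) to
#' the carrying capacity (white).
#'
#' @param state a \code{sim_state}.
#' @param prefix output path prefix.
#' @param image also write \code{<prefix>.pgm}?
#' @return character vector of files written, invisibly.
#' @export
render_snapshot <- function(state, prefix, image = FALSE) {
    dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
    cells_path <- paste0(prefix, "_cells.csv")
    utils::write.table(format(signif(state$cells, 10), trim = TRUE,
                              scientific = FALSE),
                       cells_path, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    pts <- data.frame(
        kind = c(rep("focus", length(state$g_id)),
                 rep("forager", length(state$forager_x))),
        x = c(state$g_x, state$forager_x),
        y = c(state$g_y, state$forager_y))
    points_path <- paste0(prefix, "_points.csv")
    utils::write.csv(format_floats(pts), points_path, row.names = FALSE,
                     quote = FALSE)
    files <- c(cells_path, points_path)
    if (isTRUE(image)) {
        pgm_path <- paste0(prefix, ".pgm")
        k <- state$config$prey_capacity
        g <- round(255 * pmin(pmax(state$cells / k, 0), 1))
        con <- file(pgm_path, "w")
        writeLines(c("P2", paste(ncol(g), nrow(g)), "255"), con)
        utils::write.table(g, con, sep = " ", row.names = FALSE,
                           col.names = FALSE)
        close(con)
        files <- c(files, pgm_path)
    }
    invisible(files)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-exactly: the package
#' version, the full configuration, the master seed and any derived
#' per-realisation seeds, and the output file inventory.
#'
#' @param path output JSON path.
#' @param config the run's \code{sim_config}.
#' @param master_seed master seed of the invocation.
#' @param seeds named or plain vector of derived seeds (may be empty).
#' @param files character vector of output files written.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(path, config, master_seed, seeds = integer(0),
                           files = character(0)) {
    manifest <- list(
        package = "tolsim",
        version = as.character(utils::packageVersion("tolsim")),
        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        master_seed = master_seed,
        derived_seeds = seeds,
        config = unclass(config),
        files = files)
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    invisible(path)
}

#' Write factorial experiment results
#'
#' @param table a \code{result_table}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_experiment <- function(table, path) {
    utils::write.csv(format_floats(as.data.frame(table)), path,
                     row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read factorial experiment results
#'
#' @param path CSV written by \code{\link{write_experiment}}.
#' @return a \code{result_table}.
#' @export
read_experiment <- function(path) {
    out <- utils::read.csv(path, stringsAsFactors = FALSE)
    class(out) <- c("result_table", "data.frame")
    out
}

#' Write ANOVA outputs
#'
#' Writes \code{anova.json} (the full decomposition) and \code{effects.csv}
#' (one row per effect) into \code{dir}.
#'
#' @param anova a \code{\link{two_way_anova}} result.
#' @param dir output directory (created if needed).
#' @return files written, invisibly.
#' @export
write_anova <- function(anova, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    json_path <- file.path(dir, "anova.json")
    jsonlite::write_json(list(response = anova$response, n = anova$n,
                              ss_total = anova$ss_total,
                              table = anova$table),
                         json_path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    eff <- anova$table[anova$table$term != "error",
                       c("term", "ss", "df", "f", "p",
                         "classical_eta2", "partial_eta2")]
    names(eff)[1] <- "effect"
    csv_path <- file.path(dir, "effects.csv")
    utils::write.csv(format_floats(eff), csv_path, row.names = FALSE,
                     quote = FALSE)
    invisible(c(json_path, csv_path))
}
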