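#' Export / import a trajectory as delimited text
#'
#' Writes one CSV matrix per field (rows = output times with a leading
#' `tau` column, columns = chi nodes, header row of chi values) plus a JSON
#' manifest (`manifest.json`) recording the scenario, resolved parameters,
#' seed, numerics and solver statistics — enough to re-run the simulation
#' bit-identically on one platform.
#'
#' @param traj an `eso_trajectory`.
#' @param dir output directory (created if missing).
#' @param fields fields to export.
#' @return `write_trajectory` returns `dir` invisibly; `read_trajectory`
#'   returns an `eso_trajectory` rebuilt from the files.
#' @export
write_trajectory <- function(traj, dir,
                             fields = c("alpha", "U", "E", "I", "theta",
                                        "p")) {
  stopifnot(inherits(traj, "eso_trajectory"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in fields) {
    M <- traj[[f]]
    df <- data.frame(tau = traj$times, M, check.names = FALSE)
    names(df) <- c("tau", formatC(traj$chi, format = "g", digits = 15))
    utils::write.csv(df, file.path(dir, paste0(f, ".csv")),
                     row.names = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("esoflip")),
    scenario = scenario_to_list(traj$scenario),
    parameters = unclass(traj$params),
    numerics = unclass(traj$numerics),
    seed = traj$seed,
    fields = fields,
    solver_stats = lapply(traj$stats, as.list)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_trajectory
#' @param dir directory previously written by [write_trajectory()].
#' @export
read_trajectory <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  fields <- man$fields
  read_one <- function(f) {
    df <- utils::read.csv(file.path(dir, paste0(f, ".csv")),
                          check.names = FALSE)
    as.matrix(df[, -1, drop = FALSE])
  }
  mats <- lapply(fields, read_one)
  names(mats) <- fields
  df1 <- utils::read.csv(file.path(dir, paste0(fields[1], ".csv")),
                         check.names = FALSE)
  chi <- as.numeric(names(df1)[-1])
  mats <- lapply(mats, function(m) { dimnames(m) <- NULL; m })
  params <- do.call(eso_parameters, man$parameters[names(eso_parameters())])
  params <- validate_parameters(params, eso_grid(params$N))
  structure(c(
    list(times = df1$tau, chi = chi),
    mats,
    list(params = params,
         scenario = scenario_from_list(man$scenario),
         numerics = do.call(eso_numerics,
                            man$numerics[!vapply(man$numerics, is.null,
                                                 TRUE)]),
         seed = man$seed, stats = man$solver_stats)
  ), class = "eso_trajectory")
}

scenario_to_list <- function(sc) {
  out <- unclass(sc)
  if (!is.null(out$bag) && is.infinite(out$bag$t_deflate)) {
    out$bag$t_deflate <- "Inf"
  }
  out
}

scenario_from_list <- function(x) {
  if (!is.null(x$bag)) {
    x$bag$t_deflate <- as.numeric(x$bag$t_deflate)
    x$bag <- as.list(x$bag)
  }
  if (!is.null(x$stimulus)) x$stimulus <- as.list(x$stimulus)
  if (!is.null(x$heterogeneity)) x$heterogeneity <- as.list(x$heterogeneity)
  if (!is.null(x$overrides)) x$overrides <- as.list(x$overrides)
  sc <- structure(x, class = "eso_scenario")
  validate_scenario(sc)
}

#' Write a pattern report as JSON (+ events as CSV)
#'
#' @param pattern an `eso_pattern` from [classify_pattern()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(pattern, dir) {
  stopifnot(inherits(pattern, "eso_pattern"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(as.list(glance.eso_pattern(pattern)),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(pattern$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Run a scenario end to end
#'
#' `make scenario -> simulate -> classify`, optionally writing all exports
#' (field CSVs, manifest, report) to a directory.
#'
#' @param scenario scenario name or [eso_scenario()] object.
#' @param overrides named list of parameter overrides.
#' @param out_dir optional output directory for exports.
#' @param seed integer seed for heterogeneity draws.
#' @param numerics an [eso_numerics()].
#' @param thresholds a [classification_thresholds()].
#' @return A list with `trajectory` (`eso_trajectory`) and `pattern`
#'   (`eso_pattern`), invisibly if `out_dir` is written.
#' @export
run_scenario <- function(scenario, overrides = list(), out_dir = NULL,
                         seed = NULL, numerics = eso_numerics(),
                         thresholds = classification_thresholds()) {
  if (is.character(scenario)) {
    scenario <- eso_scenario(scenario, overrides = overrides)
  } else if (length(overrides)) {
    scenario$overrides[names(overrides)] <- overrides
  }
  traj <- eso_simulate(scenario, numerics = numerics, seed = seed)
  pat <- classify_pattern(traj, thresholds = thresholds)
  res <- list(trajectory = traj, pattern = pat)
  if (!is.null(out_dir)) {
    write_trajectory(traj, out_dir)
    write_report(pat, out_dir)
    return(invisible(res))
  }
  res
}

#' Parameter sweep
#'
#' Runs one scenario repeatedly while varying a single parameter (explicit
#' `values`) or drawing per-segment Gaussian heterogeneity (`mean`, `sd`,
#' one run per seed in `seeds`), and aggregates the pattern summaries.
#'
#' @param scenario scenario name or [eso_scenario()] object.
#' @param param parameter name to vary.
#' @param values numeric vector of scalar values to sweep over.
#' @param mean,sd,seeds Gaussian heterogeneity specification (used when
#'   `values` is `NULL`).
#' @param numerics an [eso_numerics()].
#' @param thresholds a [classification_thresholds()].
#' @return A tibble with one row per run: the swept value (or seed) plus
#'   the [glance.eso_pattern()] columns.
#' @export
sweep_parameter <- function(scenario, param, values = NULL,
                            mean = NULL, sd = NULL, seeds = NULL,
                            numerics = eso_numerics(),
                            thresholds = classification_thresholds()) {
  if (is.character(scenario)) scenario <- eso_scenario(scenario)
  if (!param %in% names(eso_parameters())) {
    stop("unknown parameter '", param, "'", call. = FALSE)
  }
  if (!is.null(values)) {
    if (!length(values)) stop("empty value list", call. = FALSE)
    rows <- lapply(values, function(v) {
      sc <- scenario
      sc$overrides[[param]] <- v
      pat <- classify_pattern(eso_simulate(sc, numerics = numerics),
                              thresholds = thresholds)
      cbind(tibble::tibble(param = param, value = v, seed = NA_integer_),
            glance.eso_pattern(pat))
    })
  } else {
    if (is.null(mean) || is.null(sd) || is.null(seeds) || !length(seeds)) {
      stop("give either `values` or all of `mean`, `sd`, `seeds`",
           call. = FALSE)
    }
    rows <- lapply(seeds, function(s) {
      sc <- scenario
      sc$heterogeneity <- list(param = param, mean = mean, sd = sd)
      sc$seed <- as.integer(s)
      pat <- classify_pattern(eso_simulate(sc, numerics = numerics),
                              thresholds = thresholds)
      cbind(tibble::tibble(param = param, value = mean,
                           seed = as.integer(s)),
            glance.eso_pattern(pat))
    })
  }
  do.call(rbind, rows)
}
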