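#' Named scenario library
#'
#' Builds a scenario specification: a named preset (parameter overrides,
#' distension mode, timed events, sensory variant, heterogeneity) merged
#' with user overrides. The library covers the baseline distension response
#' and the perturbations that reproduce the disorder-like patterns:
#'
#' \describe{
#'   \item{baseline_flip}{full coupled tube, uniform sustained distension
#'     (`S_IC = 2`); normal repetitive antegrade contractions.}
#'   \item{absent_response}{mechanosensory excitation removed (`w_E = 0`);
#'     the organ stays quiescent. Raising `alpha_hat` to 10 is an
#'     equivalent alternative (`overrides = list(alpha_hat = 10, w_E = 1.6)`).}
#'   \item{transient_stimulus}{mechanoreceptors disabled (`alpha_hat = 10`)
#'     plus a brief rostral excitatory pulse; a single peristaltic wave.}
#'   \item{no_intersegmental_coupling}{`b = d = 0`; repetitive but
#'     synchronous (non-propagating) contractions.}
#'   \item{overlapping_reduced_d}{`d` halved; longer excitation, overlapping
#'     contractions.}
#'   \item{overlapping_low_phiE}{`phi_E` lowered to 3; early excitatory
#'     spikes, overlapping contractions.}
#'   \item{local_inhibition_bag}{short-bag prescribed distension with the
#'     windowed (local) inhibitory kernel, so descending inhibition acts
#'     only near the bag and contractions escape caudally.}
#'   \item{short_bag_sustained}{prescribed distension confined to
#'     `chi` in (0.2, 0.4); repetitive contractions only near the bag.}
#'   \item{short_bag_deflate}{as above with abrupt deflation at
#'     `tau = 50`; a single wave then travels the full length.}
#'   \item{disordered_e}{per-segment Gaussian heterogeneity in `e`
#'     (mean 12, sd 3): the excitatory/inhibitory balance breaks and the
#'     pattern becomes spastic/disordered.}
#'   \item{sustained_pan}{excitation of the inhibitory population reduced
#'     (`c = 5`), so inhibitory activity stays too low to terminate the
#'     excitatory phase anywhere along the chain; the whole organ locks
#'     into sustained contraction with persistently elevated bag
#'     pressure.}
#'   \item{retrograde}{mechanosensory drive to inhibitory populations
#'     removed (`w_I = 0`); the phase gradient reverses and contractions
#'     appear retrograde.}
#' }
#'
#' Presets whose exact magnitudes are not fixed by the baseline parameter
#' table (`absent_response`, `overlapping_*`, `sustained_pan`,
#' `disordered_e`, `retrograde`) use documented defaults chosen to realize
#' the described phenotype; all are overridable.
#'
#' @param name scenario name (see above), or `list_scenarios()` for the set.
#' @param overrides named list of parameter overrides applied on top of the
#'   preset (scenario preset > user override of other fields > defaults).
#' @param ... further `eso_scenario` fields to override (e.g. `bag`,
#'   `stimulus`, `heterogeneity`, `betaI_windowed`, `seed`).
#' @return An `eso_scenario` object: fields `name`, `mode` ("coupled" or
#'   "prescribed"), `overrides`, `bag` (x1, x2, level, t_deflate),
#'   `stimulus` (amp, x_end, t0, t1) or NULL, `betaI_windowed`,
#'   `heterogeneity` (param, mean, sd) or NULL, `seed`.
#' @examples
#' eso_scenario("baseline_flip")
#' eso_scenario("retrograde")$overrides
#' @export
eso_scenario <- function(name, overrides = list(), ...) {
  lib <- scenario_presets()
  if (!name %in% names(lib)) {
    stop("unknown scenario '", name, "'; available: ",
         paste(names(lib), collapse = ", "), call. = FALSE)
  }
  sc <- lib[[name]]
  if (length(overrides)) {
    stopifnot(is.list(overrides), !is.null(names(overrides)))
    sc$overrides[names(overrides)] <- overrides
  }
  extra <- list(...)
  if (length(extra)) {
    unknown <- setdiff(names(extra), names(sc))
    if (length(unknown)) {
      stop("unknown scenario field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    sc[names(extra)] <- extra
  }
  validate_scenario(sc)
}

#' @rdname eso_scenario
#' @export
list_scenarios <- function() names(scenario_presets())

scenario_presets <- function() {
  base <- structure(list(
    name = "baseline_flip", mode = "coupled", overrides = list(),
    bag = NULL, stimulus = NULL, betaI_windowed = FALSE,
    heterogeneity = NULL, seed = NULL
  ), class = "eso_scenario")
  mk <- function(...) {
    sc <- base
    mods <- list(...)
    sc[names(mods)] <- mods
    sc
  }
  bag_default <- list(x1 = 0.2, x2 = 0.4, level = 0.5, t_deflate = Inf)
  list(
    baseline_flip = base,
    absent_response = mk(name = "absent_response",
                         overrides = list(w_E = 0)),
    transient_stimulus = mk(name = "transient_stimulus",
                            overrides = list(alpha_hat = 10),
                            stimulus = list(amp = 1.6, x_end = 0.1,
                                            t0 = 0, t1 = 2)),
    no_intersegmental_coupling = mk(name = "no_intersegmental_coupling",
                                    overrides = list(b = 0, d = 0)),
    overlapping_reduced_d = mk(name = "overlapping_reduced_d",
                               overrides = list(d = 10)),
    overlapping_low_phiE = mk(name = "overlapping_low_phiE",
                              overrides = list(phi_E = 3)),
    local_inhibition_bag = mk(name = "local_inhibition_bag",
                              mode = "prescribed", bag = bag_default,
                              betaI_windowed = TRUE),
    short_bag_sustained = mk(name = "short_bag_sustained",
                             mode = "prescribed", bag = bag_default),
    short_bag_deflate = mk(name = "short_bag_deflate", mode = "prescribed",
                           bag = within_list(bag_default, t_deflate = 50)),
    disordered_e = mk(name = "disordered_e",
                      heterogeneity = list(param = "e", mean = 12, sd = 3),
                      seed = 1L),
    sustained_pan = mk(name = "sustained_pan", overrides = list(c = 5)),
    retrograde = mk(name = "retrograde", overrides = list(w_I = 0))
  )
}

within_list <- function(x, ...) {
  mods <- list(...)
  x[names(mods)] <- mods
  x
}

validate_scenario <- function(sc) {
  stopifnot(sc$mode %in% c("coupled", "prescribed"))
  if (!is.null(sc$bag)) {
    stopifnot(sc$bag$x1 >= 0, sc$bag$x2 <= 1, sc$bag$x1 < sc$bag$x2,
              sc$bag$level >= 0, sc$bag$t_deflate > 0)
  }
  if (sc$mode == "prescribed" && is.null(sc$bag)) {
    stop("prescribed-distension mode needs a bag specification",
         call. = FALSE)
  }
  if (!is.null(sc$stimulus)) {
    stopifnot(sc$stimulus$amp > 0, sc$stimulus$t0 < sc$stimulus$t1,
              sc$stimulus$x_end >= 0, sc$stimulus$x_end <= 1)
  }
  if (!is.null(sc$heterogeneity)) {
    stopifnot(sc$heterogeneity$param %in% HETERO_PARAMS,
              sc$heterogeneity$sd >= 0)
  }
  if (length(sc$overrides)) {
    unknown <- setdiff(names(sc$overrides), names(eso_parameters()))
    if (length(unknown)) {
      stop("override(s) for unknown parameter(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  sc
}

#' @export
print.eso_scenario <- function(x, ...) {
  cat("<eso_scenario>", x$name, "| mode:", x$mode, "\n")
  if (length(x$overrides)) {
    cat("  overrides:",
        paste(names(x$overrides),
              vapply(x$overrides, function(v) paste(signif(v, 4),
                                                    collapse = ","), ""),
              sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$bag)) {
    cat(sprintf("  bag: chi in (%.2g, %.2g), level %.3g, deflate at %.4g\n",
                x$bag$x1, x$bag$x2, x$bag$level, x$bag$t_deflate))
  }
  if (!is.null(x$stimulus)) {
    cat(sprintf("  stimulus: amp %.3g on chi <= %.2g, tau in [%.3g, %.3g)\n",
                x$stimulus$amp, x$stimulus$x_end, x$stimulus$t0,
                x$stimulus$t1))
  }
  if (!is.null(x$heterogeneity)) {
    cat(sprintf("  heterogeneity: %s ~ N(%.3g, %.3g), seed %s\n",
                x$heterogeneity$param, x$heterogeneity$mean,
                x$heterogeneity$sd, x$seed %||% "unset"))
  }
  invisible(x)
}

#' Per-segment Gaussian parameter heterogeneity
#'
#' Replaces one heterogeneity-capable parameter with N independent Gaussian
#' draws (clamped at 0 from below: negative synaptic weights would invert
#' the sign semantics of the circuit), seeded for reproducibility.
#'
#' @param params an [eso_parameters()] object.
#' @param param parameter name (one of `a`, `b`, `c`, `d`, `e`, `f`,
#'   `w_E`, `w_I`, `phi_E`, `alpha_hat`).
#' @param mean,sd Gaussian mean and standard deviation (`sd >= 0`).
#' @param seed integer seed.
#' @return The parameter set with `param` installed as a length-N vector.
#' @examples
#' p <- perturb_parameters(eso_parameters(), "e", mean = 15, sd = 1, seed = 7)
#' length(p$e)
#' @export
perturb_parameters <- function(params, param, mean, sd, seed) {
  stopifnot(inherits(params, "eso_parameters"), sd >= 0)
  if (!param %in% HETERO_PARAMS) {
    stop("parameter '", param, "' does not support per-segment values; ",
         "choose one of: ", paste(HETERO_PARAMS, collapse = ", "),
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  v <- pmax(stats::rnorm(params$N, mean, sd), 0)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  params[[param]] <- v
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a
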