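#' Tidy a simulated trajectory
#'
#' @param x an `eso_trajectory`.
#' @param fields which fields to pivot (`alpha`, `U`, `E`, `I`, `theta`,
#'   `p`).
#' @param ... unused.
#' @return A long tibble with columns `tau`, `chi`, `field`, `value`.
#' @export
tidy.eso_trajectory <- function(x, fields = c("alpha", "U", "E", "I",
                                              "theta", "p"), ...) {
  fields <- match.arg(fields, several.ok = TRUE)
  parts <- lapply(fields, function(f) {
    M <- x[[f]]
    tibble::tibble(
      tau = rep(x$times, times = length(x$chi)),
      chi = rep(x$chi, each = length(x$times)),
      field = f,
      value = as.vector(M)
    )
  })
  do.call(rbind, parts)
}

#' One-row summary of a simulated trajectory
#'
#' @param x an `eso_trajectory`.
#' @param ... unused.
#' @return A one-row tibble: scenario, mode, grid size, snapshot count,
#'   final time, activation extrema, volume drift, and solver work.
#' @export
glance.eso_trajectory <- function(x, ...) {
  st <- if (length(x$stats)) Reduce(`+`, x$stats) else c(steps = 0,
                                                         rhs_evals = 0)
  tibble::tibble(
    scenario = x$scenario$name, mode = x$scenario$mode,
    n_nodes = length(x$chi), n_snapshots = length(x$times),
    tau_end = max(x$times),
    theta_min = min(x$theta), max_depth = 1 - min(x$theta),
    volume_drift = if (x$scenario$mode == "coupled") volume_drift(x)
                   else NA_real_,
    steps = unname(st["steps"]), rhs_evals = unname(st["rhs_evals"])
  )
}

#' @rdname tidy.eso_pattern
#' @export
glance.eso_pattern <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario, label = x$label,
    n_events = nrow(x$events), med_events = x$med_events,
    frequency = x$frequency,
    slope = if (nrow(x$profile)) stats::median(x$profile$slope) else NA_real_,
    delay_rsd = if (nrow(x$profile)) {
      stats::median(x$profile$delay_rsd, na.rm = TRUE)
    } else {
      NA_real_
    },
    overlap = x$overlap, max_depth = x$max_depth,
    sustained_seg_frac = x$sustained_seg_frac
  )
}

#' Tidy a pattern report
#'
#' `tidy()` returns the per-segment contraction events; `glance()` the
#' one-row summary (label, frequency, onset slope, overlap, depth).
#'
#' @param x an `eso_pattern` from [classify_pattern()].
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.eso_pattern <- function(x, ...) x$events

#' Spatiotemporal topography of a trajectory field
#'
#' Colour-coded map in the panometry orientation: position chi on the
#' vertical axis (rostral end at the top), time tau horizontal.
#'
#' @param object an `eso_trajectory`.
#' @param field one of `alpha`, `U`, `E`, `I`, `theta`, `p`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.eso_trajectory <- function(object, field = "alpha", ...) {
  d <- tidy.eso_trajectory(object, fields = field)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tau, y = .data$chi,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::scale_fill_viridis_c(name = field) +
    ggplot2::labs(
      x = expression(tau), y = expression(chi),
      title = sprintf("%s topography: %s", field, object$scenario$name)
    )
}

#' @rdname autoplot.eso_trajectory
#' @param traj an `eso_trajectory`.
#' @export
plot_topography <- function(traj, field = "alpha", ...) {
  autoplot.eso_trajectory(traj, field = field, ...)
}

#' @importFrom ggplot2 .data
NULL
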