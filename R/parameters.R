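#' Default model parameters
#'
#' Returns the non-dimensional parameter set of the baseline model: the two
#' fluid groups (`psi`, `beta`), the initial distension ratio `S_IC`, the
#' mechanoreceptor threshold `alpha_hat`, the neural synaptic weights
#' (`a`, `b`, `c`, `d`, `e`, `f`), sensory feedback strengths (`w_E`, `w_I`),
#' sigmoid shapes (`phi_E`, `phi_I`, `lambda_E`, `lambda_I`), gains
#' (`g_S`, `g_E`, `g_theta`), the muscle parameters (`tau_theta`, `theta_o`,
#' `E_hat`), the sensory kernel shift `x_s`, the inhibitory time-constant
#' ratio `tau_I`, and the number of grid nodes / oscillators `N`.
#'
#' `b` and `d` are the unidirectional intersegmental weights (each oscillator
#' reads only its rostral neighbour); `a`, `e`, `c`, `f` are intrasegmental.
#' All quantities are dimensionless; time is in units of the excitatory time
#' constant, length in units of esophageal length, area in units of the rest
#' reference area.
#'
#' @param ... named overrides of individual defaults, e.g. `w_E = 0`.
#'   A subset of parameters (see [validate_parameters()]) may be given as
#'   length-`N` vectors for per-segment heterogeneity.
#' @return An object of class `eso_parameters` (a named list).
#' @examples
#' p <- eso_parameters()
#' p$psi
#' eso_parameters(b = 0, d = 0)$b
#' @export
eso_parameters <- function(...) {
  p <- list(
    psi = 3000, beta = 100, theta_o = 0.05,
    S_IC = 2, alpha_hat = 1.5, x_s = 0.1,
    tau_theta = 0.2, tau_I = 4,
    a = 16, b = 20, c = 12, d = 40, e = 15, f = 3,
    w_E = 1.6, w_I = 1.35,
    phi_E = 4, phi_I = 3.7, lambda_E = 1.3, lambda_I = 2,
    g_S = 1000, g_E = 1000, g_theta = 5,
    E_hat = 0.3, N = 70
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(!nzchar(names(ov)))) {
      stop("parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(ov)] <- ov
  }
  structure(p, class = "eso_parameters")
}

# parameters that may carry per-segment (length-N) heterogeneity
HETERO_PARAMS <- c("a", "b", "c", "d", "e", "f",
                   "w_E", "w_I", "phi_E", "alpha_hat")

#' Validate a parameter set against a grid
#'
#' Checks positivity and range constraints, broadcasts scalar values of the
#' heterogeneity-capable parameters (`a`, `b`, `c`, `d`, `e`, `f`, `w_E`,
#' `w_I`, `phi_E`, `alpha_hat`) to per-segment length-`N` vectors, and
#' rejects vectors whose length does not match the grid.
#'
#' @param params an [eso_parameters()] object.
#' @param grid an [eso_grid()]; defaults to `eso_grid(params$N)`.
#' @return The checked parameter set with heterogeneity-capable fields as
#'   length-`N` vectors and attribute `validated = TRUE`.
#' @export
validate_parameters <- function(params, grid = eso_grid(params$N)) {
  stopifnot(inherits(params, "eso_parameters"))
  N <- grid$N
  if (!is.numeric(params$N) || length(params$N) != 1 || params$N < 3) {
    stop("N must be >= 3", call. = FALSE)
  }
  if (params$N != N) stop("grid size does not match params$N", call. = FALSE)

  pos <- c("psi", "beta", "tau_theta", "tau_I",
           "g_S", "g_E", "g_theta", "lambda_E", "lambda_I", "S_IC")
  for (nm in pos) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop(nm, " must be a strictly positive scalar", call. = FALSE)
    }
  }
  if (params$theta_o <= 0 || params$theta_o >= 1) {
    stop("theta_o must lie in (0, 1)", call. = FALSE)
  }
  if (params$x_s < 0 || params$x_s > 1) {
    stop("x_s must lie in [0, 1]", call. = FALSE)
  }
  for (nm in setdiff(names(params), c(HETERO_PARAMS, "N"))) {
    if (length(params[[nm]]) != 1) {
      stop(nm, " must be scalar (per-segment values are not supported for it)",
           call. = FALSE)
    }
  }
  for (nm in HETERO_PARAMS) {
    v <- params[[nm]]
    if (!is.numeric(v) || !all(is.finite(v))) {
      stop(nm, " must be finite numeric", call. = FALSE)
    }
    if (length(v) == 1) {
      v <- rep(v, N)
    } else if (length(v) != N) {
      stop(nm, " has length ", length(v), " but N = ", N, call. = FALSE)
    }
    params[[nm]] <- v
  }
  attr(params, "validated") <- TRUE
  params
}

#' Uniform spatial grid on the unit interval
#'
#' @param N number of nodes (>= 3); one oscillator sits at each node.
#' @return An `eso_grid` object with fields `N`, `chi` (node positions on
#'   `[0, 1]`) and `d_chi` (spacing `1/(N-1)`).
#' @examples
#' eso_grid(3)$chi
#' @export
eso_grid <- function(N = 70) {
  if (!is.numeric(N) || length(N) != 1 || !is.finite(N) || N < 3 ||
      N != round(N)) {
    stop("N must be an integer >= 3", call. = FALSE)
  }
  N <- as.integer(N)
  structure(list(N = N, chi = seq(0, 1, length.out = N), d_chi = 1 / (N - 1)),
            class = "eso_grid")
}

#' Numerical settings for the time integrator
#'
#' Defaults resolve the steep (`g = 1000`) sigmoids of the sensory pathway:
#' relative tolerance `1e-6`, absolute tolerance `1e-8`, final time
#' `tau_end = 100` (time in units of the excitatory time constant), and a
#' snapshot every `output_d_tau = 0.1`.
#'
#' @param rel_tol,abs_tol integrator tolerances (> 0).
#' @param tau_end final non-dimensional time (> 0).
#' @param output_d_tau sampling interval of stored snapshots (> 0).
#' @param max_step optional cap on the internal step size.
#' @return An `eso_numerics` object.
#' @export
eso_numerics <- function(rel_tol = 1e-6, abs_tol = 1e-8,
                         tau_end = 100, output_d_tau = 0.1,
                         max_step = NULL) {
  stopifnot(rel_tol > 0, abs_tol > 0, tau_end >= 0, output_d_tau > 0)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, tau_end = tau_end,
                 output_d_tau = output_d_tau, max_step = max_step),
            class = "eso_numerics")
}

#' Write / read a parameter set as JSON
#'
#' Round-trips exactly: `read_parameters(write_parameters(p, f))` is
#' value-identical to `p`.
#'
#' @param params an [eso_parameters()] object.
#' @param path file path.
#' @return `write_parameters` returns `path` invisibly; `read_parameters`
#'   returns an `eso_parameters` object.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "eso_parameters"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(eso_parameters, raw)
}

#' @export
print.eso_parameters <- function(x, ...) {
  cat("<eso_parameters> N =", x$N, "\n")
  show <- function(nm) {
    v <- x[[nm]]
    if (length(v) > 1) sprintf("%s = <per-segment, mean %.4g>", nm, mean(v))
    else sprintf("%s = %.4g", nm, v)
  }
  cat(" ", paste(vapply(setdiff(names(x), "N"), show, ""), collapse = ", "),
      "\n")
  invisible(x)
}
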