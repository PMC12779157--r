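#' Initial state of the coupled system
#'
#' Fluid at rest with uniform (or prescribed) distension, neural circuit at
#' rest: `U = 0`, `E = 0`, `I = 0`, `theta = 1`, and
#' `alpha = distension_profile * theta`.
#'
#' @param params validated [eso_parameters()].
#' @param grid matching [eso_grid()].
#' @param distension_profile scalar or length-N positive vector; defaults
#'   to the uniform initial distension ratio `S_IC`.
#' @return Named list of length-N vectors `alpha`, `U`, `E`, `I`, `theta`.
#' @export
initial_state <- function(params, grid, distension_profile = params$S_IC) {
  params <- ensure_validated(params, grid)
  N <- grid$N
  prof <- if (length(distension_profile) == 1) {
    rep(distension_profile, N)
  } else {
    distension_profile
  }
  stopifnot(length(prof) == N, all(prof > 0))
  theta <- rep(1, N)
  list(alpha = prof * theta, U = numeric(N), E = numeric(N), I = numeric(N),
       theta = theta)
}

#' Full coupled time derivative (reference implementation)
#'
#' Composes, in order: mechanosensory inputs from the current `(alpha,
#' theta)` (or from a prescribed strain-excess field in
#' prescribed-distension mode), the oscillator-chain derivatives, the
#' muscle-activation derivative, and the tube derivatives. This pure-R
#' composition defines the model; [eso_simulate()] integrates an equivalent
#' compiled version of it and the two are cross-checked in the test suite.
#'
#' @param tau current time (enters only through scenario events).
#' @param state named list with `alpha`, `U`, `E`, `I`, `theta`.
#' @param scenario an [eso_scenario()].
#' @param params validated [eso_parameters()].
#' @param grid matching [eso_grid()].
#' @return Named list of derivatives `dalpha`, `dU`, `dE`, `dI`, `dtheta`.
#' @export
coupled_rhs <- function(tau, state, scenario, params, grid) {
  params <- ensure_validated(params, grid)
  h <- NULL
  if (scenario$mode == "prescribed") {
    bag <- scenario$bag
    inside <- grid$chi > bag$x1 & grid$chi < bag$x2
    h <- ifelse(inside & tau < bag$t_deflate, bag$level, 0)
  }
  S <- sensory_inputs(state$alpha, state$theta, params, grid, h = h,
                      betaI_windowed = scenario$betaI_windowed)
  st <- scenario$stimulus
  if (!is.null(st) && tau >= st$t0 && tau < st$t1) {
    S$S_E[grid$chi <= st$x_end] <- st$amp
  }
  nr <- neural_rhs(state$E, state$I, S$S_E, S$S_I, params)
  dtheta <- theta_rhs(state$theta, state$E, params)
  if (scenario$mode == "prescribed") {
    fl <- list(dalpha = numeric(grid$N), dU = numeric(grid$N))
  } else {
    fl <- fluid_rhs(state$alpha, state$U, state$theta, params, grid)
  }
  list(dalpha = fl$dalpha, dU = fl$dU, dE = nr$dE, dI = nr$dI,
       dtheta = dtheta)
}

#' Simulate a distension scenario
#'
#' Assembles the 5N-variable system (area, velocity, excitatory and
#' inhibitory activities, muscle activation on a shared uniform grid),
#' applies the scenario's initial conditions and parameter overrides, and
#' integrates with an adaptive embedded Runge-Kutta 4(5) pair
#' (Dormand-Prince). Timed events (stimulus offset, bag deflation) split
#' the integration so each leg sees a time-continuous right-hand side.
#'
#' @param scenario an [eso_scenario()] or a scenario name.
#' @param params base parameter set before scenario overrides.
#' @param numerics an [eso_numerics()] object.
#' @param seed integer seed used for heterogeneity draws when the scenario
#'   requests them but carries no seed of its own.
#' @return An `eso_trajectory`: list with `times`, `chi`, matrices
#'   `alpha`, `U`, `E`, `I`, `theta`, `p` (rows = output times, columns =
#'   nodes), the resolved `params`, `scenario`, `numerics`, `seed`, and
#'   `stats` (solver statistics per integration leg).
#' @examples
#' \donttest{
#' traj <- eso_simulate("baseline_flip", numerics = eso_numerics(tau_end = 30))
#' glance(traj)
#' }
#' @export
eso_simulate <- function(scenario = eso_scenario("baseline_flip"),
                         params = eso_parameters(),
                         numerics = eso_numerics(), seed = NULL) {
  if (is.character(scenario)) scenario <- eso_scenario(scenario)
  stopifnot(inherits(scenario, "eso_scenario"),
            inherits(numerics, "eso_numerics"))
  if (length(scenario$overrides)) params[names(scenario$overrides)] <-
      scenario$overrides
  used_seed <- scenario$seed %||% seed
  if (!is.null(scenario$heterogeneity)) {
    if (is.null(used_seed)) {
      stop("scenario requests heterogeneity but no seed is set",
           call. = FALSE)
    }
    het <- scenario$heterogeneity
    params <- perturb_parameters(params, het$param, het$mean, het$sd,
                                 seed = used_seed)
  }
  grid <- eso_grid(params$N)
  params <- validate_parameters(params, grid)
  state0 <- initial_state(params, grid)
  y0 <- unlist(state0, use.names = FALSE)

  times <- seq(0, numerics$tau_end, by = numerics$output_d_tau)
  if (times[length(times)] < numerics$tau_end) {
    times <- c(times, numerics$tau_end)
  }
  if (numerics$tau_end == 0) {
    return(build_trajectory(matrix(c(0, y0), nrow = 1), grid, params,
                            scenario, numerics, used_seed, list()))
  }

  events <- numeric(0)
  if (!is.null(scenario$stimulus)) {
    events <- c(events, scenario$stimulus$t0, scenario$stimulus$t1)
  }
  if (!is.null(scenario$bag)) events <- c(events, scenario$bag$t_deflate)
  events <- sort(unique(events[events > 0 & events < numerics$tau_end]))
  bounds <- c(0, events, numerics$tau_end)

  parms <- pack_parms(params, grid, scenario)
  out_rows <- matrix(numeric(0), ncol = 5 * grid$N + 1)
  stats <- list()
  y <- y0
  for (leg in seq_len(length(bounds) - 1)) {
    lo <- bounds[leg]; hi <- bounds[leg + 1]
    leg_times <- unique(c(lo, times[times > lo & times < hi], hi))
    sol <- deSolve::ode(
      y = y, times = leg_times, func = "eso_derivs", parms = parms,
      dllname = "esoflip", initfunc = "eso_init",
      method = deSolve::rkMethod("rk45ck"),
      rtol = numerics$rel_tol, atol = numerics$abs_tol,
      hmax = numerics$max_step %||% (hi - lo), maxsteps = 1e6
    )
    if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol))) {
      stop("integration failed in tau ∈ [", signif(lo, 6), ", ",
           signif(hi, 6), "]; last valid tau = ",
           signif(max(sol[stats::complete.cases(sol), 1]), 6),
           call. = FALSE)
    }
    stats[[leg]] <- c(steps = unname(attr(sol, "istate")[2]),
                      rhs_evals = unname(attr(sol, "istate")[3]))
    keep <- sol[, 1] %in% times
    if (leg > 1) keep[1] <- FALSE  # leg start already recorded
    out_rows <- rbind(out_rows, sol[keep, , drop = FALSE])
    y <- sol[nrow(sol), -1]
  }
  build_trajectory(out_rows, grid, params, scenario, numerics, used_seed,
                   stats)
}

build_trajectory <- function(rows, grid, params, scenario, numerics, seed,
                             stats) {
  N <- grid$N
  field <- function(j) {
    m <- rows[, 1 + (j - 1) * N + seq_len(N), drop = FALSE]
    dimnames(m) <- NULL
    m
  }
  alpha <- field(1); U <- field(2); E <- field(3); I <- field(4)
  theta <- field(5)
  if (any(alpha <= 0)) {
    stop("numerical state error: non-positive alpha in recorded trajectory",
         call. = FALSE)
  }
  structure(list(
    times = as.numeric(rows[, 1]), chi = grid$chi,
    alpha = alpha, U = U, E = E, I = I, theta = theta,
    p = alpha / theta - 1,
    params = params, scenario = scenario, numerics = numerics,
    seed = seed, stats = stats
  ), class = "eso_trajectory")
}

# pack parameters + scenario flags into the flat vector the C RHS reads;
# layout must stay in sync with src/esorhs.c
pack_parms <- function(params, grid, scenario) {
  N <- grid$N
  st <- scenario$stimulus %||% list(amp = 0, x_end = 0, t0 = 0, t1 = 0)
  bag <- scenario$bag %||% list(level = 0, x1 = 0, x2 = 0, t_deflate = Inf)
  head <- c(
    N, if (scenario$mode == "prescribed") 1 else 0,
    params$psi, params$beta, params$tau_theta, params$tau_I,
    params$theta_o, params$g_S, params$g_E, params$g_theta, params$x_s,
    params$lambda_E, params$lambda_I, params$E_hat, grid$d_chi,
    as.numeric(isTRUE(scenario$betaI_windowed)),
    st$amp, st$x_end, st$t0, st$t1,
    bag$level, bag$x1, bag$x2,
    if (is.finite(bag$t_deflate)) bag$t_deflate else 1e30
  )
  arrays <- c(params$alpha_hat, params$a, params$b, params$c, params$d,
              params$e, params$f, params$w_E, params$w_I,
              rep_len(params$phi_E, N), rep_len(params$phi_I, N))
  v <- c(head, arrays)
  if (length(v) > 6000) stop("N too large for the compiled backend (max ~540)",
                             call. = FALSE)
  c(v, numeric(6000 - length(v)))
}

#' @export
print.eso_trajectory <- function(x, ...) {
  cat("<eso_trajectory>", x$scenario$name, "| mode:", x$scenario$mode, "\n")
  cat(sprintf("  N = %d nodes, %d snapshots, tau in [%.3g, %.3g]\n",
              length(x$chi), length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  theta range [%.3g, %.3g], volume drift %.2e\n",
              min(x$theta), max(x$theta), volume_drift(x)))
  invisible(x)
}

#' Relative drift of total fluid volume over a trajectory
#'
#' @param traj an `eso_trajectory` from [eso_simulate()].
#' @return `max_t |V(t) - V(0)| / V(0)` using trapezoidal volumes.
#' @export
volume_drift <- function(traj) {
  grid <- eso_grid(length(traj$chi))
  V <- apply(traj$alpha, 1, total_volume, grid = grid)
  max(abs(V - V[1])) / V[1]
}
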