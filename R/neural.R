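#' Neural activation sigmoid
#'
#' The switching nonlinearity of the excitatory/inhibitory populations:
#' `1/(1 + exp(-lam*(x - phi))) - 1/(1 + exp(lam*phi))`. The subtracted
#' constant anchors the value to 0 at `x = 0`, so the rest state is a fixed
#' point of the circuit. Overflow-safe for arbitrarily large `|x|`.
#'
#' @param x input (any numeric vector).
#' @param lam activation speed (slope), > 0.
#' @param phi activation threshold (location of maximum slope).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' sigmoid_ei(0, 1.3, 4)       # exactly 0
#' sigmoid_ei(4, 1.3, 4)       # half-activation minus the floor
#' @export
sigmoid_ei <- function(x, lam, phi) {
  stopifnot(lam > 0)
  a <- pmin(-lam * (x - phi), 700)
  b <- min(lam * phi, 700)
  1 / (1 + exp(a)) - 1 / (1 + exp(b))
}

#' Excitatory sensory kernel
#'
#' Smoothed step `0.5 + 0.5*tanh(g_E*(x + x_s))` weighting how strongly a
#' mechanoreceptor at signed offset `x` (receptor position subtracted from
#' neuron position, in units of tube length) drives the excitatory
#' population. With the default gain the kernel is ~1 for receptors within
#' `x_s` caudal of the neuron and ~0 beyond, making distension-induced
#' excitation local to about 10% of esophageal length.
#'
#' @param x signed offset chi_neuron - chi_receptor.
#' @param g_E kernel gain.
#' @param x_s horizontal shift (kernel reach), fraction of tube length.
#' @return Weight in `[0, 1]`.
#' @export
sensory_kernel_E <- function(x, g_E, x_s) {
  0.5 + 0.5 * tanh(pmax(pmin(g_E * (x + x_s), 20), -20))
}

#' Mechanoreceptor strain excess
#'
#' Local distension signal `h_i = max(alpha_i/theta_i - alpha_hat, 0)`:
#' receptors fire when the lumen is stretched beyond `alpha_hat` relative to
#' the *active* reference area (`theta` rescales the rest area, so receptors
#' sense strain against the current muscle tone, not the rest tube).
#'
#' @param alpha non-dimensional cross-sectional area (length-N).
#' @param theta muscle activation field (length-N, > 0).
#' @param alpha_hat strain threshold (scalar or length-N).
#' @return Non-negative length-N vector.
#' @examples
#' strain_excess(2, 1, 1.5)  # 0.5, the baseline distension drive
#' @export
strain_excess <- function(alpha, theta, alpha_hat) {
  stopifnot(all(theta > 0))
  pmax(alpha / theta - alpha_hat, 0)
}

#' Mechanosensory inputs to the oscillator chain
#'
#' Discretized sensory source terms. The excitatory drive at node i sums
#' strain excess over nodes k >= i (receptors at and caudal to i), windowed
#' by [sensory_kernel_E()] so only receptors within ~`x_s` contribute; the
#' inhibitory-population drive sums over k <= i (receptors at and rostral to
#' i) with unit weight, realizing descending inhibition along the whole
#' caudal esophagus. Both sums are squashed by `tanh(g_S * .)` and scaled by
#' `w_E` / `w_I`.
#'
#' @param alpha,theta length-N state fields (or a prescribed strain excess,
#'   see `h`).
#' @param params validated [eso_parameters()].
#' @param grid matching [eso_grid()].
#' @param h optional prescribed strain-excess field overriding
#'   `strain_excess(alpha, theta, alpha_hat)`.
#' @param betaI_windowed if `TRUE`, the inhibitory sum uses the mirrored
#'   local window `0.5 + 0.5*tanh(g_E*(x_s - x))`, confining
#'   distension-induced inhibition to ~`x_s` caudal of the receptor (the
#'   "local inhibition" variant).
#' @return List with length-N vectors `S_E` and `S_I`.
#' @export
sensory_inputs <- function(alpha, theta, params, grid,
                           h = NULL, betaI_windowed = FALSE) {
  params <- ensure_validated(params, grid)
  N <- grid$N
  if (is.null(h)) h <- strain_excess(alpha, theta, params$alpha_hat)
  stopifnot(length(h) == N)
  dchi <- grid$d_chi
  chi <- grid$chi
  # offset matrix chi_i - chi_k (rows i = neurons, cols k = receptors)
  off <- outer(chi, chi, "-")
  KE <- sensory_kernel_E(off, params$g_E, params$x_s)
  KE[off > 0] <- 0                       # only k >= i contributes to S_E
  argE <- as.vector(KE %*% h) * dchi
  if (betaI_windowed) {
    KI <- sensory_kernel_E(-off, params$g_E, params$x_s)
  } else {
    KI <- matrix(1, N, N)
  }
  KI[off < 0] <- 0                       # only k <= i contributes to S_I
  argI <- as.vector(KI %*% h) * dchi
  list(S_E = params$w_E * tanh(pmin(params$g_S * argE, 20)),
       S_I = params$w_I * tanh(pmin(params$g_S * argI, 20)))
}

#' Time derivatives of the oscillator chain
#'
#' The unidirectionally coupled excitatory/inhibitory population equations:
#' each node i reads only its rostral neighbour i-1 (excitatory weight `b`,
#' inhibitory weight `d`); at the rostral-most node those terms are absent.
#' The inhibitory derivative carries the time-constant ratio `tau_I`.
#'
#' @param E,I length-N activity vectors.
#' @param S_E,S_I length-N sensory inputs (see [sensory_inputs()]).
#' @param params validated [eso_parameters()].
#' @return List with length-N vectors `dE` and `dI` (per unit tau).
#' @export
neural_rhs <- function(E, I, S_E, S_I, params) {
  params <- ensure_validated(params, eso_grid(length(E)))
  N <- length(E)
  stopifnot(length(I) == N, length(S_E) == N, length(S_I) == N)
  E_up <- c(0, E[-N])                    # rostral neighbour, 0 at node 1
  I_up <- c(0, I[-N])
  b <- params$b; d <- params$d
  b[1] <- 0; d[1] <- 0
  argE <- params$a * E + b * E_up - params$e * I - d * I_up + S_E
  argI <- params$c * E - params$f * I + S_I
  dE <- -E + (1 - E) * sigmoid_ei(argE, params$lambda_E, params$phi_E)
  dI <- (-I + (1 - I) * sigmoid_ei(argI, params$lambda_I, params$phi_I)) /
    params$tau_I
  list(dE = dE, dI = dI)
}

# broadcast heterogeneity-capable parameters if the caller passed a raw set
ensure_validated <- function(params, grid) {
  if (isTRUE(attr(params, "validated")) && length(params$a) == grid$N) {
    return(params)
  }
  if (params$N != grid$N) params$N <- grid$N
  validate_parameters(params, grid)
}

#' Integrate a single (uncoupled) oscillator
#'
#' Convenience integrator for one excitatory/inhibitory unit plus its muscle
#' activation under constant or time-varying sensory input, used to study
#' the rest, excitable, and limit-cycle regimes in isolation.
#'
#' @param S_E,S_I constants, or functions of tau returning the inputs.
#' @param params an [eso_parameters()] object (intersegmental weights are
#'   irrelevant here and forced to 0).
#' @param tau_end,output_d_tau time span and sampling interval.
#' @param rel_tol,abs_tol integrator tolerances.
#' @param state0 initial `c(E, I, theta)`.
#' @return A tibble with columns `tau`, `E`, `I`, `theta`.
#' @examples
#' osc <- single_oscillator(S_E = 1.6, S_I = 1.35, tau_end = 50)
#' range(osc$E)
#' @export
single_oscillator <- function(S_E = 0, S_I = 0, params = eso_parameters(),
                              tau_end = 50, output_d_tau = 0.05,
                              rel_tol = 1e-8, abs_tol = 1e-10,
                              state0 = c(E = 0, I = 0, theta = 1)) {
  fE <- if (is.function(S_E)) S_E else function(tau) S_E
  fI <- if (is.function(S_I)) S_I else function(tau) S_I
  p1 <- scalar_params(params)
  rhs <- function(tau, y, parms) {
    list(unlist(osc_rhs(y[1], y[2], y[3], fE(tau), fI(tau), p1)))
  }
  times <- seq(0, tau_end, by = output_d_tau)
  out <- deSolve::ode(y = state0, times = times, func = rhs, parms = NULL,
                      method = deSolve::rkMethod("ode45"),
                      rtol = rel_tol, atol = abs_tol)
  tibble::tibble(tau = out[, 1], E = out[, 2], I = out[, 3],
                 theta = out[, 4])
}

# single-unit derivative (b = d = 0); shared by the adaptive path and tests
osc_rhs <- function(E, I, theta, S_E, S_I, p) {
  dE <- -E + (1 - E) *
    sigmoid_ei(p$a * E - p$e * I + S_E, p$lambda_E, p$phi_E)
  dI <- (-I + (1 - I) *
           sigmoid_ei(p$c * E - p$f * I + S_I, p$lambda_I, p$phi_I)) / p$tau_I
  dth <- (1 - theta - sigma_theta(E - p$E_hat, p$g_theta, p$theta_o)) /
    p$tau_theta
  list(dE = dE, dI = dI, dtheta = dth)
}

# collapse per-segment vectors to their first element (single-unit use)
scalar_params <- function(params) {
  for (nm in HETERO_PARAMS) params[[nm]] <- params[[nm]][1]
  params
}
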