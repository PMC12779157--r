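#' Muscle activation sigmoid
#'
#' `sigma_theta(x) = 0.5*(1 - theta_o)*(1 + tanh(g_theta * x))`: the smooth
#' switch that converts supra-threshold excitatory activity into contraction
#' drive. Its range `(0, 1 - theta_o)` caps contraction so the activation
#' field can never fall below `theta_o`, the maximum contraction strength
#' (5% of rest area at the default).
#'
#' @param x input, typically `E - E_hat`.
#' @param g_theta gain.
#' @param theta_o maximum contraction strength, in `(0, 1)`.
#' @return Numeric vector in `(0, 1 - theta_o)`.
#' @examples
#' sigma_theta(0, 5, 0.05)    # 0.475
#' @export
sigma_theta <- function(x, g_theta, theta_o) {
  stopifnot(theta_o > 0, theta_o < 1)
  0.5 * (1 - theta_o) * (1 + tanh(pmax(pmin(g_theta * x, 20), -20)))
}

#' Time derivative of the muscle activation field
#'
#' `dtheta_i = (1 - theta_i - sigma_theta(E_i - E_hat)) / tau_theta`,
#' purely local in i. The excitatory population is the only input: with
#' sustained high `E` the field relaxes to `theta_o` (full contraction);
#' with `E = 0` it relaxes to near-rest tone `1 - sigma_theta(-E_hat)`.
#'
#' @param theta length-N activation field.
#' @param E length-N excitatory activity.
#' @param params validated [eso_parameters()].
#' @return Length-N vector `dtheta` per unit tau.
#' @export
theta_rhs <- function(theta, E, params) {
  stopifnot(length(theta) == length(E))
  (1 - theta - sigma_theta(E - params$E_hat, params$g_theta,
                           params$theta_o)) / params$tau_theta
}
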