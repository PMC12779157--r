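#' Non-dimensional tube pressure
#'
#' Linear tube law relative to the active reference area:
#' `p = alpha/theta - 1`. Pressure is zero when the lumen matches the
#' neurally set reference area `theta`, positive when distended beyond it.
#'
#' @param alpha non-dimensional cross-sectional area.
#' @param theta muscle activation field (> 0).
#' @return Vector `p` of the same length.
#' @examples
#' tube_pressure(2, 1)      # baseline distension pressure, 1
#' tube_pressure(0.1, 0.05) # ratio invariance: also 1
#' @export
tube_pressure <- function(alpha, theta) {
  stopifnot(all(theta > 0))
  alpha / theta - 1
}

#' Time derivatives of the 1D tube fields
#'
#' Mass and momentum balance for the fluid-filled closed flexible tube:
#' `dalpha/dtau = -d(alpha*U)/dchi` and
#' `dU/dtau = -U dU/dchi - psi dp/dchi - beta U/alpha`, with `p` from
#' [tube_pressure()]. Interior nodes use second-order central differences on
#' the co-located grid; the ends are closed (`U = 0`, so `dU = 0` there) and
#' continuity at the ends is closed with mirror ghost nodes consistent with
#' the wall condition `d(alpha/theta)/dchi = 0`, which makes the trapezoidal
#' total volume exactly conserved by the semi-discretization.
#'
#' @param alpha,U,theta length-N state fields (`alpha > 0`).
#' @param params validated [eso_parameters()] (only `psi`, `beta` used).
#' @param grid matching [eso_grid()].
#' @return List with length-N vectors `dalpha` and `dU` per unit tau.
#' @export
fluid_rhs <- function(alpha, U, theta, params, grid) {
  N <- grid$N
  stopifnot(length(alpha) == N, length(U) == N, length(theta) == N)
  if (any(alpha <= 0)) {
    stop("non-positive cross-sectional area: alpha_min = ",
         signif(min(alpha), 4), " at node ", which.min(alpha), call. = FALSE)
  }
  dchi <- grid$d_chi
  p <- tube_pressure(alpha, theta)
  Fv <- alpha * U
  i <- 2:(N - 1)
  dalpha <- numeric(N)
  dU <- numeric(N)
  dalpha[i] <- -(Fv[i + 1] - Fv[i - 1]) / (2 * dchi)
  dU[i] <- -U[i] * (U[i + 1] - U[i - 1]) / (2 * dchi) -
    params$psi * (p[i + 1] - p[i - 1]) / (2 * dchi) -
    params$beta * U[i] / alpha[i]
  dalpha[1] <- -Fv[2] / dchi
  dalpha[N] <- Fv[N - 1] / dchi
  list(dalpha = dalpha, dU = dU)
}

#' Total fluid volume
#'
#' Trapezoidal integral of `alpha` over `chi` in `[0, 1]`; the conservation
#' diagnostic for the closed tube.
#'
#' @param alpha length-N area field.
#' @param grid matching [eso_grid()].
#' @return Scalar volume (in units of rest reference area times length).
#' @export
total_volume <- function(alpha, grid) {
  stopifnot(length(alpha) == grid$N)
  sum((alpha[-1] + alpha[-grid$N]) / 2) * grid$d_chi
}
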