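# Build a minimal eso_trajectory around a supplied theta matrix so the
# diagnostics can be exercised on constructed inputs.
synthetic_trajectory <- function(theta, times, chi,
                                 mode = "prescribed", S_IC = 2) {
  N <- length(chi)
  params <- validate_parameters(eso_parameters(N = N), eso_grid(N))
  alpha <- matrix(S_IC, nrow(theta), N) * theta
  sc <- eso_scenario("short_bag_sustained")
  sc$mode <- mode
  structure(list(
    times = times, chi = chi,
    alpha = alpha, U = matrix(0, nrow(theta), N),
    E = matrix(0, nrow(theta), N), I = matrix(0, nrow(theta), N),
    theta = theta, p = alpha / theta - 1,
    params = params, scenario = sc, numerics = eso_numerics(
      tau_end = max(times), output_d_tau = diff(times[1:2])),
    seed = NULL, stats = list()
  ), class = "eso_trajectory")
}

# travelling contraction wave: one smooth dip per cycle, onset at
# tau0 + speed_inv * chi (+ k * period), depth 0.9
synthetic_wave_theta <- function(times, chi, tau0 = 5, speed_inv = 12,
                                 period = Inf, n_cycles = 1, width = 3,
                                 depth = 0.9) {
  theta <- matrix(1, length(times), length(chi))
  for (k in seq_len(n_cycles) - 1) {
    shift <- if (k == 0) 0 else k * period
    for (j in seq_along(chi)) {
      centre <- tau0 + speed_inv * chi[j] + shift + width / 2
      pulse <- depth * exp(-((times - centre) / (width / 3))^2)
      theta[, j] <- pmin(theta[, j], 1 - pulse)
    }
  }
  theta
}
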