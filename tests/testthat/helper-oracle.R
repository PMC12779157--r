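# Fixed-step classical 4th-order Runge-Kutta, independent of deSolve.
# f(t, y) returns dy/dt as a numeric vector.
rk4_integrate <- function(f, y0, tau_end, h, record_every = 1L) {
  n_steps <- round(tau_end / h)
  y <- y0
  t <- 0
  kept <- seq(0, n_steps, by = record_every)
  out <- matrix(NA_real_, length(kept), length(y0) + 1)
  out[1, ] <- c(0, y0)
  row <- 1L
  for (s in seq_len(n_steps)) {
    k1 <- f(t, y)
    k2 <- f(t + h / 2, y + h / 2 * k1)
    k3 <- f(t + h / 2, y + h / 2 * k2)
    k4 <- f(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- s * h
    if (s %% record_every == 0) {
      row <- row + 1L
      out[row, ] <- c(t, y)
    }
  }
  out
}

# single-unit derivative written out directly from the model equations
# (kept separate from the package's osc_rhs so the oracle is independent)
oracle_osc_rhs <- function(S_E, S_I, p) {
  sig <- function(x, lam, phi) {
    1 / (1 + exp(-lam * (x - phi))) - 1 / (1 + exp(lam * phi))
  }
  function(t, y) {
    E <- y[1]; I <- y[2]
    dE <- -E + (1 - E) * sig(p$a * E - p$e * I + S_E, p$lambda_E, p$phi_E)
    dI <- (-I + (1 - I) * sig(p$c * E - p$f * I + S_I,
                              p$lambda_I, p$phi_I)) / p$tau_I
    c(dE, dI)
  }
}
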