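test_that("activation sigmoid is anchored at zero and saturates safely", {
  expect_equal(sigmoid_ei(0, 1.3, 4), 0)
  expect_equal(sigmoid_ei(0, 2, 3.7), 0)
  # direct evaluation of the closed form at the half-activation point
  expect_equal(sigmoid_ei(4, 1.3, 4), 0.5 - 1 / (1 + exp(1.3 * 4)),
               tolerance = 1e-12)
  expect_equal(sigmoid_ei(4, 1.3, 4), 0.494514, tolerance = 1e-5)
  expect_equal(sigmoid_ei(1e6, 1.3, 4), 1 - 1 / (1 + exp(5.2)),
               tolerance = 1e-10)
  expect_equal(sigmoid_ei(1e6, 1.3, 4), 0.994514, tolerance = 1e-5)
  expect_true(is.finite(sigmoid_ei(-1e9, 1.3, 4)))
  x <- seq(-5, 10, by = 0.25)
  expect_true(all(diff(sigmoid_ei(x, 1.3, 4)) > 0))
  expect_error(sigmoid_ei(1, lam = -1, phi = 4))
})

test_that("excitatory sensory kernel is a local smooth step of reach x_s", {
  expect_equal(sensory_kernel_E(-0.1, 1000, 0.1), 0.5)
  expect_equal(sensory_kernel_E(0, 1000, 0.1), 1, tolerance = 1e-12)
  expect_equal(sensory_kernel_E(-0.2, 1000, 0.1), 0, tolerance = 1e-12)
  x <- seq(-0.3, 0.1, by = 0.01)
  expect_true(all(diff(sensory_kernel_E(x, 1000, 0.1)) >= 0))
})

test_that("strain excess clamps at the mechanoreceptor threshold", {
  expect_equal(strain_excess(2, 1, 1.5), 0.5)
  expect_equal(strain_excess(1.5, 1, 1.5), 0)
  expect_equal(strain_excess(rep(1, 5), rep(1, 5), 1.5), rep(0, 5))
  # senses strain relative to the active reference area: alpha/theta ratio
  expect_equal(strain_excess(1, 0.5, 1.5), 0.5)
  expect_error(strain_excess(1, 0, 1.5))
})

test_that("sensory inputs follow the windowed / prefix sum structure", {
  g <- eso_grid(70)
  p <- validate_parameters(eso_parameters(), g)
  S0 <- sensory_inputs(rep(1, 70), rep(1, 70), p, g)  # h = 0 everywhere
  expect_equal(S0$S_E, rep(0, 70))
  expect_equal(S0$S_I, rep(0, 70))
  # uniform baseline distension saturates both pathways in the interior
  S <- sensory_inputs(rep(2, 70), rep(1, 70), p, g)
  interior <- 2:69
  expect_equal(S$S_E[interior], rep(1.6, 68), tolerance = 1e-6)
  expect_equal(S$S_I[interior], rep(1.35, 68), tolerance = 1e-6)
  # point distension: S_I is a prefix sum, zero strictly rostral of the site
  h <- rep(0, 70); h[30] <- 0.5
  Sp <- sensory_inputs(rep(2, 70), rep(1, 70), p, g, h = h)
  expect_equal(Sp$S_I[1:29], rep(0, 29))
  expect_true(all(Sp$S_I[30:70] > 0))
  expect_equal(diff(Sp$S_I[30:70]), rep(0, 40), tolerance = 1e-12)
  # ... and S_E reaches only receptors within ~x_s rostral of the site
  expect_true(all(Sp$S_E[30 - 0:5] > 0))
  expect_equal(Sp$S_E[1:20], rep(0, 20), tolerance = 1e-12)
  expect_equal(Sp$S_E[40:70], rep(0, 31), tolerance = 1e-12)
})

test_that("sensory response is monotone in the strain field", {
  g <- eso_grid(40)
  p <- validate_parameters(eso_parameters(N = 40, g_S = 5), g)
  set.seed(7)
  h <- runif(40, 0, 0.5)
  S1 <- sensory_inputs(NULL, rep(1, 40), p, g, h = h)
  for (k in c(1, 17, 40)) {
    h2 <- h; h2[k] <- h2[k] + 0.3
    S2 <- sensory_inputs(NULL, rep(1, 40), p, g, h = h2)
    expect_true(all(S2$S_E >= S1$S_E - 1e-12))
    expect_true(all(S2$S_I >= S1$S_I - 1e-12))
  }
})

test_that("windowed inhibitory kernel confines S_I to the distended region", {
  g <- eso_grid(70)
  p <- validate_parameters(eso_parameters(), g)
  h <- ifelse(g$chi > 0.2 & g$chi < 0.4, 0.5, 0)
  Sw <- sensory_inputs(NULL, rep(1, 70), p, g, h = h, betaI_windowed = TRUE)
  Sd <- sensory_inputs(NULL, rep(1, 70), p, g, h = h)
  # default: descending inhibition covers everything caudal to the bag
  expect_true(all(Sd$S_I[g$chi > 0.5] > 1))
  # windowed: inhibition vanishes beyond ~x_s caudal of the bag
  expect_equal(Sw$S_I[g$chi > 0.55], rep(0, sum(g$chi > 0.55)),
               tolerance = 1e-9)
  expect_true(all(Sw$S_I[g$chi > 0.25 & g$chi < 0.4] > 1))
})

test_that("oscillator chain derivatives: fixed point, saturation, causality", {
  g <- eso_grid(20)
  p <- validate_parameters(eso_parameters(N = 20), g)
  z <- rep(0, 20)
  d0 <- neural_rhs(z, z, z, z, p)
  expect_equal(d0$dE, z)
  expect_equal(d0$dI, z)
  # E_i = 1 forces dE_i = -1 regardless of all inputs
  E <- z; E[7] <- 1
  d1 <- neural_rhs(E, runif(20), runif(20, 0, 1.6), runif(20, 0, 1.35), p)
  expect_equal(d1$dE[7], -1)
  # strict unidirectional coupling: perturbing node j reaches only j, j+1
  set.seed(1)
  E <- runif(20, 0, 0.5); I <- runif(20, 0, 0.5)
  SE <- runif(20, 0, 1.6); SI <- runif(20, 0, 1.35)
  base <- neural_rhs(E, I, SE, SI, p)
  for (j in c(1, 9, 20)) {
    E2 <- E; I2 <- I
    E2[j] <- E2[j] + 0.1; I2[j] <- I2[j] + 0.1
    d2 <- neural_rhs(E2, I2, SE, SI, p)
    changed <- which(abs(d2$dE - base$dE) + abs(d2$dI - base$dI) > 1e-12)
    expect_true(all(changed %in% c(j, j + 1)))
    expect_true(j %in% changed)
  }
})

test_that("single oscillator reproduces rest, limit-cycle and excitable regimes", {
  # rest: no input, stays at the origin
  rest <- single_oscillator(S_E = 0, S_I = 0, tau_end = 50)
  expect_lt(max(sqrt(rest$E^2 + rest$I^2)), 1e-6)
  # sustained input: stable limit cycle (non-decaying oscillation)
  osc <- single_oscillator(S_E = 1.6, S_I = 1.35, tau_end = 100)
  late <- osc[osc$tau >= 50, ]
  expect_gte(diff(range(late$E)), 0.2)
  peaks <- which(diff(sign(diff(osc$E))) == -2)
  peaks <- peaks[osc$E[peaks + 1] > 0.1]
  expect_gte(length(peaks), 4)
  # brief pulse: single excursion, then decay back to rest (excitable)
  pulse <- single_oscillator(
    S_E = function(tau) ifelse(tau < 2, 1.6, 0),
    S_I = function(tau) ifelse(tau < 2, 1.35, 0), tau_end = 50)
  expect_gt(max(pulse$E), 0.05)
  tail_state <- pulse[pulse$tau > 45, ]
  expect_lt(max(abs(tail_state$E)), 1e-3)
  expect_lt(max(abs(tail_state$I)), 1e-3)
  # activity bounds along all three trajectories
  for (tr in list(rest, osc, pulse)) {
    expect_true(all(tr$E >= -0.01 & tr$E <= 1))
    expect_true(all(tr$I >= -0.01 & tr$I <= 1))
  }
})

test_that("adaptive integration matches a fixed-step RK4 oracle", {
  p <- eso_parameters()
  adaptive <- single_oscillator(S_E = 1.6, S_I = 1.35, tau_end = 20,
                                output_d_tau = 0.01)
  oracle <- rk4_integrate(oracle_osc_rhs(1.6, 1.35, p), c(0, 0),
                          tau_end = 20, h = 1e-4, record_every = 100L)
  expect_equal(nrow(oracle), nrow(adaptive))
  expect_lt(max(abs(adaptive$E - oracle[, 2])), 1e-4)
  expect_lt(max(abs(adaptive$I - oracle[, 3])), 1e-4)
})
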