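# recover the exact RHS the compiled backend computes at one state via a
# single explicit Euler step of size h: f = (y(h) - y0) / h
compiled_rhs_at <- function(state, scenario, params, grid, tau = 0,
                            h = 1e-7) {
  parms <- esoflip:::pack_parms(params, grid, scenario)
  y0 <- unlist(state, use.names = FALSE)
  sol <- deSolve::ode(y0, c(tau, tau + h), func = "eso_derivs",
                      parms = parms, dllname = "esoflip",
                      initfunc = "eso_init",
                      method = deSolve::rkMethod("euler"), hini = h)
  unname((sol[2, -1] - y0) / h)
}

r_rhs_at <- function(state, scenario, params, grid, tau = 0) {
  d <- coupled_rhs(tau, state, scenario, params, grid)
  unlist(d, use.names = FALSE)
}

test_that("initial state matches the rest-and-uniform-distension conditions", {
  g <- eso_grid(70)
  p <- validate_parameters(eso_parameters(), g)
  s <- initial_state(p, g)
  expect_equal(s$alpha, rep(2, 70))
  expect_equal(s$U, rep(0, 70))
  expect_equal(s$E, rep(0, 70))
  expect_equal(s$I, rep(0, 70))
  expect_equal(s$theta, rep(1, 70))
  prof <- ifelse(g$chi > 0.2 & g$chi < 0.4, 2.5, 1)
  s2 <- initial_state(p, g, distension_profile = prof)
  expect_equal(s2$alpha, prof)
  expect_error(initial_state(p, g, distension_profile = -1))
})

test_that("compiled backend agrees with the R reference composition", {
  N <- 24
  g <- eso_grid(N)
  p <- validate_parameters(eso_parameters(N = N), g)
  set.seed(5)
  random_state <- function() {
    list(alpha = runif(N, 1, 3), U = c(0, runif(N - 2, -0.2, 0.2), 0),
         E = runif(N, 0, 0.6), I = runif(N, 0, 0.6),
         theta = runif(N, 0.3, 1))
  }
  cases <- list(
    list(sc = eso_scenario("baseline_flip"), tau = 0),
    list(sc = eso_scenario("short_bag_sustained"), tau = 1),
    list(sc = eso_scenario("short_bag_deflate"), tau = 60),  # post-deflation
    list(sc = eso_scenario("local_inhibition_bag"), tau = 3),
    list(sc = eso_scenario("transient_stimulus"), tau = 1),  # pulse active
    list(sc = eso_scenario("transient_stimulus"), tau = 10)  # pulse over
  )
  for (cs in cases) {
    pp <- p
    if (length(cs$sc$overrides)) pp[names(cs$sc$overrides)] <- cs$sc$overrides
    pp <- validate_parameters(pp, g)
    st <- random_state()
    f_c <- compiled_rhs_at(st, cs$sc, pp, g, tau = cs$tau)
    f_r <- r_rhs_at(st, cs$sc, pp, g, tau = cs$tau)
    expect_equal(f_c, f_r, tolerance = 1e-6,
                 label = paste("compiled rhs,", cs$sc$name, "tau", cs$tau))
  }
})

test_that("baseline rest composition: only theta relaxes, and distension excites", {
  g <- eso_grid(70)
  p <- validate_parameters(eso_parameters(), g)
  sc <- eso_scenario("baseline_flip")
  # sub-threshold distension: alpha/theta < alpha_hat everywhere
  st <- list(alpha = rep(1, 70), U = rep(0, 70), E = rep(0, 70),
             I = rep(0, 70), theta = rep(1, 70))
  d <- coupled_rhs(0, st, sc, p, g)
  expect_equal(d$dalpha, rep(0, 70))
  expect_equal(d$dU, rep(0, 70))
  expect_equal(d$dE, rep(0, 70))
  expect_equal(d$dI, rep(0, 70))
  expect_true(all(d$dtheta < 0))  # relaxing from 1 toward the E = 0 tone
  # baseline distension: saturated excitatory drive, excitation begins
  s0 <- initial_state(p, g)
  S <- sensory_inputs(s0$alpha, s0$theta, p, g)
  expect_equal(S$S_E[2:69], rep(1.6, 68), tolerance = 1e-6)
  d0 <- coupled_rhs(0, s0, sc, p, g)
  expect_true(all(d0$dE[2:69] > 0))
  expect_equal(d0$dE[35], sigmoid_ei(1.6, 1.3, 4), tolerance = 1e-6)
})

test_that("trajectories are deterministic and respect mode contracts", {
  num <- eso_numerics(tau_end = 2, output_d_tau = 0.5)
  t1 <- eso_simulate("baseline_flip", numerics = num)
  t2 <- eso_simulate("baseline_flip", numerics = num)
  expect_identical(t1$alpha, t2$alpha)
  expect_identical(t1$E, t2$E)
  # neural-only mode: fluid fields frozen at their initial values
  nb <- eso_simulate("short_bag_sustained",
                     numerics = eso_numerics(tau_end = 30))
  expect_true(all(nb$alpha == matrix(nb$alpha[1, ], nrow(nb$alpha), 70,
                                     byrow = TRUE)))
  expect_true(all(nb$U == 0))
  expect_gt(max(1 - nb$theta), 0.5)  # but the muscle does contract
  # prescribed strain of zero level: nothing ever moves
  sc0 <- eso_scenario("short_bag_sustained")
  sc0$bag$level <- 0
  quiet <- eso_simulate(sc0, numerics = eso_numerics(tau_end = 10))
  expect_lt(max(abs(quiet$E)), 1e-9)
  expect_lt(max(1 - quiet$theta), 0.0452)  # at most the rest-tone depth
})

test_that("zero-length integration returns exactly the initial snapshot", {
  tr <- eso_simulate("baseline_flip",
                     numerics = eso_numerics(tau_end = 0))
  expect_equal(length(tr$times), 1)
  expect_equal(tr$times, 0)
  expect_equal(tr$alpha[1, ], rep(2, 70))
  expect_equal(tr$theta[1, ], rep(1, 70))
})

test_that("state is continuous across the deflation event", {
  sc <- eso_scenario("short_bag_deflate")
  sc$bag$t_deflate <- 5
  tr <- eso_simulate(sc, numerics = eso_numerics(tau_end = 10,
                                                 output_d_tau = 0.05))
  i_ev <- which.min(abs(tr$times - 5))
  for (f in c("E", "I", "theta")) {
    jumps <- abs(tr[[f]][i_ev + 1, ] - tr[[f]][i_ev, ])
    typical <- max(abs(diff(tr[[f]])))
    expect_lt(max(jumps), typical + 1e-8)
  }
})

test_that("doubling the grid changes the baseline cycle period by < 5%", {
  period_at_mid <- function(N) {
    tr <- eso_simulate(
      eso_scenario("baseline_flip", overrides = list(N = N)),
      numerics = eso_numerics(tau_end = 60))
    ev <- detect_contractions(tr)
    1 / contraction_frequency(ev, segment = which.min(abs(tr$chi - 0.5)))
  }
  p70 <- period_at_mid(70)
  p140 <- period_at_mid(140)
  expect_lt(abs(p140 - p70) / p70, 0.05)
})
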