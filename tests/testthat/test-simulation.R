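test_that("spike detection interpolates crossings and honours the guards", {
  ev <- detect_spikes(-10, 10, threshold = 0, t = 100, dt = 0.05)
  expect_equal(ev$time, 100.025)
  expect_equal(ev$neuron, 1L)
  expect_equal(nrow(detect_spikes(-10, -5, 0, t = 0, dt = 0.05)), 0)
  # plateau exactly at threshold is not a crossing
  expect_equal(nrow(detect_spikes(0, 0, 0, t = 0, dt = 0.05)), 0)
  expect_equal(nrow(detect_spikes(0, 10, 0, t = 0, dt = 0.05)), 0)
  # refractory guard drops a too-early second crossing
  ev2 <- detect_spikes(c(-10, -10), c(10, 10), 0, t = 100, dt = 0.05,
                       last_spike = c(99, 90), refractory = 2)
  expect_equal(ev2$neuron, 2L)
})

test_that("firing rates count spikes per window", {
  sp <- data.frame(neuron = rep(1L, 71), time = seq(0, 999, length.out = 71))
  fr <- firing_rates(sp, c(0, 1000), N = 2)
  expect_equal(fr$rates, c(71, 0))
  expect_equal(fr$mean, 35.5)
  expect_error(firing_rates(sp, c(5, 5), N = 2), "empty")
})

test_that("uncoupled neurons match an adaptive-step reference solution", {
  skip_if_not_installed("deSolve")
  p <- network_params(N = 2, sigma_I = 0, mu_c = 0, sigma_c = 0)
  # smooth initial state (near resting values): no settling needed
  st <- init_network(p, seed = 1)
  st$V[] <- c(-65, -60)
  st$m[] <- 0.05; st$h[] <- 0.6; st$n[] <- 0.32; st$s[] <- 0
  cfg <- integration_config(dt = 0.01, settle_duration = 0)
  hh_ode <- function(t, y, parms) {
    V <- y[1:2]; m <- y[3:4]; h <- y[5:6]; n <- y[7:8]; s <- y[9:10]
    r <- hh_rates(V)
    dV <- (11 - 120 * m^3 * h * (V - 50) - 36 * n^4 * (V + 77)
           - 0.3 * (V + 54.4))
    list(c(dV,
           r$alpha_m * (1 - m) - r$beta_m * m,
           r$alpha_h * (1 - h) - r$beta_h * h,
           r$alpha_n * (1 - n) - r$beta_n * n,
           psp_derivative(pmin(pmax(s, 0), 1), V)))
  }
  y0 <- c(st$V, st$m, st$h, st$n, st$s)
  times <- seq(0, 100, by = 5)
  ref <- deSolve::lsoda(y0, times, hh_ode, NULL, rtol = 1e-10, atol = 1e-10)
  state <- st
  err <- 0
  for (k in 2:length(times)) {
    r <- run_protocol(p, protocol = NULL,
                      schedule = protocol_schedule(5, 0, 0, 0), cfg = cfg,
                      seed = 1, init_state = state, measure = FALSE)
    state <- r$state
    err <- max(err, abs(state$V - ref[k, 2:3]))
  }
  expect_lt(err, 0.5)
})

test_that("a zero-intensity protocol is bitwise identical to no stimulation", {
  p <- small_params()
  warm <- run_protocol(p, protocol = NULL,
                       schedule = protocol_schedule(300, 200, 0, 0),
                       seed = 6, measure = FALSE)
  sched <- protocol_schedule(0, 0, 300, 0)
  withK0 <- run_protocol(p, protocol = small_protocol(K = 0),
                         schedule = sched, seed = 6,
                         init_state = warm$state, measure = FALSE)
  noStim <- run_protocol(p, protocol = NULL, schedule = sched, seed = 6,
                         init_state = warm$state, measure = FALSE)
  expect_identical(withK0$state$V, noStim$state$V)
  expect_identical(withK0$state$c, noStim$state$c)
  expect_identical(withK0$spikes, noStim$spikes)
  expect_identical(withK0$series$C_av, noStim$series$C_av)
})

test_that("halving the step leaves the mean weight essentially unchanged", {
  p <- small_params()
  out <- lapply(c(0.05, 0.025), function(dtv) {
    run_protocol(p, protocol = NULL, cfg = integration_config(dt = dtv),
                 schedule = protocol_schedule(200, 800, 0, 0),
                 seed = 10, measure = FALSE)
  })
  c1 <- tail(out[[1]]$series$C_av, 1)
  c2 <- tail(out[[2]]$series$C_av, 1)
  expect_lt(abs(c1 - c2), 1e-3)
  # spike counts agree closely as well
  expect_lt(abs(nrow(out[[1]]$spikes) - nrow(out[[2]]$spikes)) /
              nrow(out[[1]]$spikes), 0.01)
})

test_that("identical seeds give identical results; phases keep their contracts", {
  p <- small_params()
  proto <- small_protocol()
  sch <- short_schedule()
  a <- run_protocol(p, protocol = proto, schedule = sch, seed = 3)
  b <- run_protocol(p, protocol = proto, schedule = sch, seed = 3)
  expect_identical(a$state, b$state)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$series, b$series)
  # STDP is frozen during equilibration
  expect_identical(a$snapshots$post_equilibration, a$snapshots$initial)
  # ... and active during kindling
  expect_false(identical(a$snapshots$post_kindling,
                         a$snapshots$post_equilibration))
  # state invariants hold at the end
  expect_true(all(a$state$m >= 0 & a$state$m <= 1))
  expect_true(all(a$state$s >= 0 & a$state$s <= 1))
  expect_true(all(a$state$c >= 0 & a$state$c <= 1))
  expect_identical(unname(diag(a$state$c)), rep(0, p$N))
  expect_true(all(diff(a$series$time) > 0))
  Rv <- a$series$R[!is.na(a$series$R)]
  expect_true(all(Rv >= 0 & Rv <= 1 + 1e-12))
})

test_that("with the active conductances off, V relaxes to the leak/drive fixed point", {
  p <- network_params(N = 4, g_Na = 1e-12, g_K = 1e-12,
                      sigma_I = 0, mu_c = 0, sigma_c = 0)
  res <- run_protocol(p, protocol = NULL,
                      schedule = protocol_schedule(200, 0, 0, 0),
                      seed = 2, measure = FALSE)
  expect_equal(res$state$V, rep(-54.4 + 11 / 0.3, 4), tolerance = 1e-3)
})

test_that("dynamics are equivariant under ring rotation of the initial conditions", {
  p <- small_params(sigma_I = 0, sigma_c = 0)
  st <- init_network(p, seed = 12)
  st$m[] <- 0.05; st$h[] <- 0.6; st$n[] <- 0.32; st$s[] <- 0  # smooth start
  rot <- function(x, r) x[((seq_along(x) - 1 + r) %% length(x)) + 1]
  r <- 7
  st2 <- st
  for (f in c("V", "m", "h", "n", "s", "I")) st2[[f]] <- rot(st[[f]], r)
  cfg <- integration_config(settle_duration = 0)
  sch <- protocol_schedule(0, 100, 0, 0)
  a <- run_protocol(p, protocol = NULL, schedule = sch, cfg = cfg,
                    seed = 1, init_state = st, measure = FALSE)
  b <- run_protocol(p, protocol = NULL, schedule = sch, cfg = cfg,
                    seed = 1, init_state = st2, measure = FALSE)
  expect_equal(rot(a$state$V, r), b$state$V, tolerance = 1e-6)
  expect_equal(rot(a$state$s, r), b$state$s, tolerance = 1e-6)
})

test_that("an all-zero schedule returns the initial snapshots only", {
  p <- small_params()
  res <- run_protocol(p, protocol = NULL,
                      schedule = protocol_schedule(0, 0, 0, 0),
                      seed = 1)
  expect_equal(nrow(res$spikes), 0)
  expect_identical(res$snapshots$post_cr_off, res$snapshots$initial)
  expect_length(res$endpoints, 0)
})

test_that("a blown-up trajectory aborts with a diagnostic", {
  p <- network_params(N = 4, I_0 = 1e5, sigma_I = 0)
  expect_error(
    run_protocol(p, protocol = NULL,
                 schedule = protocol_schedule(50, 0, 0, 0), seed = 1,
                 cfg = integration_config(settle_duration = 0)),
    "instability")
})
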