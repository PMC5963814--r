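test_that("RVS stream draws uniform permutations, reproducibly", {
  s <- rvs_stream(seed = 1, N_s = 4, count = 2000)
  expect_equal(dim(s), c(2000, 4))
  expect_true(all(apply(s, 1, function(r) setequal(r, 1:4))))
  keys <- apply(s, 1, paste, collapse = "")
  expect_equal(length(unique(keys)), 24)  # full support of S_4
  # uniformity over the 24 permutations
  s10k <- rvs_stream(seed = 2, N_s = 4, count = 10000)
  counts <- table(apply(s10k, 1, paste, collapse = ""))
  expect_equal(length(counts), 24)
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.01)
  expect_identical(rvs_stream(seed = 1, N_s = 4, count = 2000), s)
  # the caller's RNG is untouched
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(rvs_stream(seed = 9, N_s = 4, count = 10))
  expect_identical(stats::runif(1), before)
})

test_that("SVS-l streams repeat each sequence exactly l times", {
  for (l in c(1, 4, 100)) {
    s <- svs_stream(seed = 3, N_s = 4, l = l, count = 350)
    keys <- apply(s, 1, paste, collapse = "")
    change <- which(keys[-1] != keys[-length(keys)])
    expect_true(all(change %% l == 0))  # switches only at block boundaries
    expect_true(all(keys[1:min(l, 350)] == keys[1]))
  }
  # within-block constancy for SVS-100
  s100 <- svs_stream(seed = 5, N_s = 4, l = 100, count = 300)
  expect_equal(length(unique(apply(s100[1:100, ], 1, paste, collapse = ""))), 1)
  # l = 1 with the same seed is the RVS stream
  expect_identical(svs_stream(7, 4, 1, 50), rvs_stream(7, 4, 50))
})

test_that("ON-OFF cycling is (m+n)*T_s periodic with ON-ordinal bookkeeping", {
  d <- onoff_cycle(c(25, 35), T_s = 10)
  expect_identical(d$on, c(TRUE, FALSE))
  expect_identical(d$on_cycle[1], 2L)
  # periodicity
  t <- seq(0, 499, by = 0.5)
  a <- onoff_cycle(t, T_s = 10)
  b <- onoff_cycle(t + 5 * 10, T_s = 10)
  expect_identical(a$on, b$on)
  # ON fraction is m/(m+n)
  expect_equal(mean(a$on), 3 / 5, tolerance = 0.01)
})

test_that("exactly one site is active during ON, none during OFF", {
  proto <- cr_protocol(T_s = 10, K = 0.2, mode = "rvs", seed = 1)
  stream <- rvs_stream(1, 4, count = 60)
  t_on <- seq(0.05, 29.9, by = 0.37)   # inside the first ON block
  t_off <- seq(30.05, 49.9, by = 0.37) # inside the first OFF block
  tot_on <- Reduce(`+`, lapply(1:4, function(k)
    cr_indicator(t_on, k, proto, stream)))
  tot_off <- Reduce(`+`, lapply(1:4, function(k)
    cr_indicator(t_off, k, proto, stream)))
  expect_true(all(tot_on == 1))
  expect_true(all(tot_off == 0))
  # each site active exactly once per ON cycle, for T_s/N_s
  tt <- seq(0, 10 - 1e-9, by = 0.01)
  for (k in 1:4) {
    ind <- cr_indicator(tt, k, proto, stream)
    expect_equal(sum(ind) * 0.01, 10 / 4, tolerance = 0.02)
    expect_equal(sum(diff(ind) == 1) + (ind[1] == 1), 1)  # one activation
  }
})

test_that("stimulus conductance is an alpha function with the printed time-to-peak", {
  expect_equal(gstim(5, t_k = 5, tau_stim = 0.4), 0)
  expect_equal(gstim(5.4, t_k = 5, tau_stim = 0.4), exp(-1))
  expect_error(gstim(4, t_k = 5, tau_stim = 0.4), "onset")
  expect_equal(cr_protocol(T_s = 10)$tau_stim, 10 / 24)
  expect_equal(cr_protocol(T_s = 10)$tau_stim, 0.41667, tolerance = 1e-4)
  # the peak is the maximum over the activation
  u <- seq(0, 2.5, by = 1e-3)
  g <- gstim(u, 0, 0.41667)
  expect_equal(max(g), exp(-1), tolerance = 1e-6)
  expect_equal(u[which.max(g)], 0.41667, tolerance = 1e-3)
})

test_that("spatial decay profile: unity on site, symmetric, hand value", {
  d <- 10 / 199
  expect_equal(spatial_profile(25, 25, d), 1)
  expect_equal(spatial_profile(25 + 16, 25, d, 0.8), 0.497494,
               tolerance = 1e-6)
  expect_equal(spatial_profile(25 + 16, 25, d, 0.8),
               1 / (1 + d^2 * 256 / 0.64), tolerance = 1e-12)
  i <- 1:200
  expect_equal(spatial_profile(i, 75, d), spatial_profile(2 * 75 - i, 75, d))
})

test_that("total stimulation current vanishes at K = 0 and at the reversal potential", {
  p <- network_params()
  proto <- cr_protocol(T_s = 10, K = 0.2, mode = "rvs", seed = 2)
  stream <- rvs_stream(2, 4, count = 10)
  st <- init_network(p, seed = 1)
  proto0 <- cr_protocol(T_s = 10, K = 0, mode = "rvs", seed = 2)
  expect_equal(stimulation_current(st, 1.3, proto0, stream, p), rep(0, 200))
  st20 <- st
  st20$V[] <- 20
  expect_equal(stimulation_current(st20, 1.3, proto, stream, p), rep(0, 200))
  # during an ON slot the active site's neuron receives the largest drive
  st$V[] <- -65
  f <- stimulation_current(st, 1.3, proto, stream, p)
  active <- proto$site_positions[stream[1, floor(1.3 / 2.5) + 1]]
  expect_equal(which.max(abs(f)), active)
  expect_true(all(f >= 0))   # excitatory below the reversal potential
  # OFF cycle: nothing
  expect_equal(stimulation_current(st, 31.0, proto, stream, p), rep(0, 200))
})

test_that("activation timeline: slot spacing T_s/N_s, equidistant sites, truncation", {
  proto <- cr_protocol(T_s = 10, K = 0.2, mode = "rvs", seed = 4)
  expect_equal(diff(proto$site_positions), rep(50, 3))
  tl <- export_stimulus_csv(proto, duration = 128, tempfile(fileext = ".csv"))
  expect_true(all(tl$onset < 128))
  # within each ON cycle the four onsets are spaced exactly T_s/N_s
  by_cycle <- split(tl$onset, tl$on_cycle)
  expect_true(all(vapply(by_cycle, function(o) all(diff(o) == 2.5), TRUE)))
  # ON cycles 0,1,2 start the first block; cycle 3 starts after the OFF gap
  starts <- vapply(by_cycle, min, numeric(1))
  expect_equal(unname(starts[1:4]), c(0, 10, 20, 50))
})
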