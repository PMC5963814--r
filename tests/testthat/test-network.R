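test_that("ring distance wraps around and is symmetric", {
  expect_identical(ring_distance(7, 7, N = 200), 0)
  expect_equal(ring_distance(1, 200, N = 200), 10 / 199)
  expect_equal(ring_distance(25, 75, N = 200), 10 / 199 * 50)
  # symmetry and translation invariance on random pairs
  set.seed(3)
  i <- sample(200, 25, replace = TRUE)
  j <- sample(200, 25, replace = TRUE)
  expect_equal(ring_distance(i, j, 200), ring_distance(j, i, 200))
  r <- ((i + 36 - 1) %% 200) + 1
  s <- ((j + 36 - 1) %% 200) + 1
  expect_equal(ring_distance(r, s, 200), ring_distance(i, j, 200))
  expect_error(ring_distance(0, 5, N = 200), "indices")
})

test_that("Mexican hat is positive short range, zero at sigma_1, negative beyond", {
  expect_identical(mexican_hat(0), 1)
  expect_equal(mexican_hat(3.5), 0)
  expect_equal(mexican_hat(2.0), (1 - 4 / 12.25) * exp(-0.5), tolerance = 1e-12)
  expect_equal(mexican_hat(2.0), 0.408480, tolerance = 1e-6)
  expect_true(all(mexican_hat(seq(0, 3.4, 0.1)) > 0))
  expect_true(all(mexican_hat(seq(3.6, 6, 0.1)) < 0))
})

test_that("coupling profile: symmetric, banded excitation up to 69 steps, class reversal potentials", {
  prof <- build_coupling(network_params())
  expect_equal(max(abs(prof$M - t(prof$M))), 0)
  expect_equal(unname(diag(prof$M)), rep(1, 200))
  # M_ij > 0 exactly for ring steps <= 69 (d * 69.65 = sigma_1)
  steps <- abs(outer(1:200, 1:200, "-"))
  steps <- pmin(steps, 200 - steps)
  expect_true(all(prof$M[steps <= 69] > 0))
  expect_true(all(prof$M[steps >= 70] < 0))
  expect_true(all(prof$V_r[prof$sgn > 0] == 20))
  expect_true(all(prof$V_r[prof$sgn < 0] == -40))
})

test_that("gating rate functions match their analytic limits and closed forms", {
  expect_equal(hh_rates(-40)$alpha_m, 1)
  expect_equal(hh_rates(-55)$alpha_n, 0.1)
  expect_equal(hh_rates(-35)$beta_h, 0.5)
  # limits are approached continuously
  expect_equal(hh_rates(-40 + 1e-6)$alpha_m, 1, tolerance = 1e-6)
  expect_equal(hh_rates(-55 - 1e-6)$alpha_n, 0.1, tolerance = 1e-6)
  r <- hh_rates(-65)
  expect_equal(r$beta_m, 4)
  expect_equal(r$alpha_h, 0.07)
  expect_equal(r$beta_n, 0.125)
  expect_error(hh_rates(NaN), "finite")
})

test_that("PSP derivative keeps s inside the unit interval", {
  expect_equal(psp_derivative(1, 30), -2)
  expect_equal(psp_derivative(1, -80), -2)
  expect_equal(psp_derivative(0, -5), 0.25)
  expect_lt(psp_derivative(0, -1e3), 1e-10)
  s <- seq(0, 1, 0.25)
  expect_true(all(psp_derivative(rep(0, 5), seq(-80, 40, 30)) >= 0))
  expect_true(all(psp_derivative(rep(1, 5), seq(-80, 40, 30)) <= 0))
})

test_that("synaptic input follows the reversal-potential driving force", {
  # hand-built two-neuron system: one active excitatory connection
  prof <- list(M = matrix(c(1, 0.4, 0.4, 1), 2), sgn = matrix(1, 2, 2),
               abs_M = matrix(c(1, 0.4, 0.4, 1), 2),
               V_r = matrix(20, 2, 2))
  st <- list(V = c(-65, 0), s = c(0, 1),
             c = matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(synaptic_input(st, prof)[1], (20 + 65) * 0.5 * 0.4 / 2)
  st$s <- c(0, 0)
  expect_equal(synaptic_input(st, prof), c(0, 0))
  # agreement with the naive double sum on a random instance
  set.seed(11)
  pr <- random_profile(15)
  st <- init_network(small_params(15), seed = 2)
  S <- synaptic_input(st, pr)
  S_ref <- sapply(1:15, function(i)
    sum((pr$V_r[i, ] - st$V[i]) * st$c[i, ] * pr$abs_M[i, ] * st$s) / 15)
  expect_equal(S, S_ref, tolerance = 1e-12)
})

test_that("random initialization honours the stated distributions and is reproducible", {
  p <- network_params()
  st <- init_network(p, seed = 42)
  expect_true(all(st$I >= 10.55 & st$I <= 11.45))
  expect_true(all(st$V >= -65 & st$V <= 5))
  expect_true(all(st$m >= 0 & st$m <= 1))
  expect_true(all(st$c >= 0 & st$c <= 1))
  expect_identical(unname(diag(st$c)), rep(0, 200))
  # weights concentrated near mu_c
  off <- st$c[row(st$c) != col(st$c)]
  expect_equal(mean(off), 0.5, tolerance = 0.005)
  expect_equal(sd(off), 0.01, tolerance = 0.05)
  st2 <- init_network(p, seed = 42)
  expect_identical(st, st2)
  expect_false(identical(init_network(p, seed = 43)$V, st$V))
})

test_that("a single uncoupled neuron fires periodically at the stated drive", {
  p <- network_params(N = 2, sigma_I = 0, mu_c = 0, sigma_c = 0)
  res <- run_protocol(p, protocol = NULL,
                      schedule = protocol_schedule(1500, 0, 0, 0),
                      seed = 5, measure = FALSE)
  tr <- res$spikes$time[res$spikes$neuron == 1]
  tr <- tr[tr > 300]   # drop the transient
  isi <- diff(tr)
  expect_gt(length(isi), 50)
  expect_lt(sd(isi) / mean(isi), 0.01)
  # I = 11 drives roughly the network's intrinsic ~71 Hz rhythm
  expect_equal(1000 / mean(isi), 71, tolerance = 0.05)
})

test_that("state save/load round-trips and the weight CSV export matches", {
  st <- init_network(small_params(), seed = 9)
  f <- tempfile(fileext = ".rds")
  save_network_state(st, f, params = small_params(), seed = 9)
  back <- load_network_state(f)
  expect_identical(back$state, st)
  expect_identical(back$seed, 9)
  fc <- tempfile(fileext = ".csv")
  export_weights_csv(st, fc)
  c_back <- as.matrix(utils::read.csv(fc, header = FALSE))
  expect_equal(unname(c_back), unname(st$c), tolerance = 1e-12)
  unlink(c(f, fc))
})
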