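#' Ring distance between neurons
#'
#' Neurons sit on a lattice of chain length `d_0`; the spacing between
#' neighbours is `d = d_0 / (N - 1)`.  Distances wrap around the ring:
#' `d * min(|i - j|, N - |i - j|)`, applied uniformly to all pairs so the
#' metric is symmetric and free of boundary effects.
#'
#' @param i,j Neuron indices (1..N, vectorized).
#' @param N Neuron count.
#' @param d_0 Chain length.
#' @return Distance(s), dimensionless length units.
#' @export
#' @examples
#' ring_distance(1, 200, N = 200, d_0 = 10)  # one wrap-around step
ring_distance <- function(i, j, N, d_0 = 10) {
  if (any(i < 1 | i > N) || any(j < 1 | j > N))
    stop("neuron indices must lie in 1..N")
  steps <- abs(i - j)
  d_0 / (N - 1) * pmin(steps, N - steps)
}

#' Mexican-hat coupling profile value
#'
#' `(1 - dist^2 / sigma_1^2) * exp(-dist^2 / (2 sigma_2^2))`: positive
#' (excitatory) below the zero crossing `sigma_1`, negative (inhibitory)
#' beyond it, with a Gaussian envelope of width `sigma_2`.
#'
#' @param dist Ring distance(s), >= 0.
#' @param sigma_1 Zero crossing of the profile.
#' @param sigma_2 Width of the Gaussian envelope.
#' @return Signed coupling weight(s).
#' @export
mexican_hat <- function(dist, sigma_1 = 3.5, sigma_2 = 2.0) {
  stopifnot(all(dist >= 0))
  (1 - dist^2 / sigma_1^2) * exp(-dist^2 / (2 * sigma_2^2))
}

#' Build the spatial coupling profile of the ring network
#'
#' Evaluates the Mexican hat on the ring distances of all neuron pairs and
#' classifies every connection as excitatory (`M_ij > 0`, synaptic reversal
#' `V_r_exc`) or inhibitory (`M_ij < 0`, reversal `V_r_inh`).  The
#' classification is fixed for the run.  The diagonal of the profile is 1
#' (distance zero) but never enters the dynamics because self-weights
#' `c_ii` are pinned to zero.
#'
#' @param params A [network_params()] object.
#' @return An object of class `"coupling_profile"`: list with the signed
#'   profile `M`, `abs_M`, the sign matrix `sgn`, and the per-connection
#'   reversal-potential matrix `V_r`.
#' @export
build_coupling <- function(params) {
  stopifnot(inherits(params, "network_params"))
  N <- params$N
  idx <- seq_len(N)
  steps <- abs(outer(idx, idx, "-"))
  dist <- params$d_0 / (N - 1) * pmin(steps, N - steps)
  M <- mexican_hat(dist, params$sigma_1, params$sigma_2)
  sgn <- sign(M)
  V_r <- matrix(0, N, N)
  V_r[sgn > 0] <- params$V_r_exc
  V_r[sgn < 0] <- params$V_r_inh
  structure(list(M = M, abs_M = abs(M), sgn = sgn, V_r = V_r),
            class = "coupling_profile")
}

#' Hodgkin-Huxley gating rate functions
#'
#' The six voltage-dependent transition rates of the m, h and n gates (in
#' 1/ms).  The removable singularities of `alpha_m` at V = -40 mV and
#' `alpha_n` at V = -55 mV are replaced by their analytic limits (1 and
#' 0.1) within 1e-7 mV of the singular voltage.
#'
#' @param V Membrane potential(s), mV; must be finite.
#' @return A list with numeric components `alpha_m`, `beta_m`, `alpha_h`,
#'   `beta_h`, `alpha_n`, `beta_n`, each the length of `V`.
#' @export
#' @examples
#' hh_rates(-40)$alpha_m  # analytic limit, 1
hh_rates <- function(V) {
  if (!all(is.finite(V))) stop("membrane potential must be finite")
  u_m <- 0.1 * V + 4
  alpha_m <- ifelse(abs(V + 40) < 1e-7, 1, u_m / (1 - exp(-u_m)))
  u_n <- 0.01 * V + 0.55
  alpha_n <- ifelse(abs(V + 55) < 1e-7, 0.1, u_n / (1 - exp(-10 * u_n)))
  list(alpha_m = alpha_m,
       beta_m  = 4 * exp(-(V + 65) / 18),
       alpha_h = 0.07 * exp(-(V + 65) / 20),
       beta_h  = 1 / (1 + exp(-0.1 * V - 3.5)),
       alpha_n = alpha_n,
       beta_n  = 0.125 * exp(-(V + 65) / 80))
}

#' Postsynaptic-potential derivative
#'
#' `ds/dt = 0.5 (1 - s) / (1 + exp(-(V + 5)/12)) - 2 s`.  The rise term is
#' gated by a sigmoid of the presynaptic potential, so `s` is driven
#' towards 1 while the presynaptic neuron spikes and decays with rate 2/ms
#' otherwise; the flow maps `[0, 1]` into itself.
#'
#' @param s PSP variable(s) in `[0, 1]`.
#' @param V Presynaptic membrane potential(s), mV.
#' @return `ds/dt` in 1/ms.
#' @export
psp_derivative <- function(s, V) {
  stopifnot(all(s >= 0 & s <= 1))
  0.5 * (1 - s) / (1 + exp(-(V + 5) / 12)) - 2 * s
}

#' Synaptic input currents
#'
#' The population-averaged postsynaptic current into each neuron:
#' \deqn{S_i = N^{-1} \sum_j (V_{r,j} - V_i)\, c_{ij} |M_{ij}|\, s_j,}
#' with the connection's reversal potential `V_r` set by its
#' excitatory/inhibitory class.  Self-terms vanish because `c_ii = 0`.
#'
#' @param state A `"network_state"` (see [init_network()]).
#' @param profile A `"coupling_profile"` (see [build_coupling()]).
#' @return Numeric vector of per-neuron currents `S_i`.
#' @export
synaptic_input <- function(state, profile) {
  N <- length(state$V)
  if (!all(dim(profile$M) == N) || !all(dim(state$c) == N))
    stop("state/profile dimension mismatch")
  A <- state$c * profile$abs_M
  drop(((profile$V_r * A) %*% state$s) - state$V * (A %*% state$s)) / N
}

#' Initialize a random network state
#'
#' Draws the initial conditions that define one "network": per-neuron
#' drive currents uniform on `[I_0 - sigma_I, I_0 + sigma_I]`, membrane
#' potentials uniform on `[-65, 5]` mV, gating and PSP variables uniform
#' on `[0, 1]`, and synaptic weights `c_ij ~ Normal(mu_c, sigma_c)`
#' clipped to `[0, 1]` with a zero diagonal (no self-connections).
#' Reproducible: the same seed yields a bitwise-identical state.  The
#' caller's RNG state is left untouched.
#'
#' @param params A [network_params()] object.
#' @param seed Integer RNG seed.
#' @return An object of class `"network_state"`: list with `V`, `m`, `h`,
#'   `n`, `s`, `I`, weight matrix `c`, `last_spike` (NA until a neuron has
#'   spiked), and current time `t` (ms).
#' @export
init_network <- function(params, seed) {
  stopifnot(inherits(params, "network_params"))
  N <- params$N
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  st <- list(V = stats::runif(N, -65, 5),
             m = stats::runif(N),
             h = stats::runif(N),
             n = stats::runif(N),
             s = stats::runif(N),
             I = stats::runif(N, params$I_0 - params$sigma_I,
                              params$I_0 + params$sigma_I),
             c = matrix(pmin(pmax(stats::rnorm(N * N, params$mu_c,
                                               params$sigma_c), 0), 1),
                        N, N),
             last_spike = rep(NA_real_, N),
             t = 0)
  diag(st$c) <- 0
  structure(st, class = "network_state")
}

#' Save / load a network state
#'
#' Serializes a `"network_state"` together with its parameters and seed
#' provenance to a single-file RDS container; the weight matrix can also
#' be exported as plain CSV.
#'
#' @param state A `"network_state"`.
#' @param file Path to write to / read from.
#' @param params Optional [network_params()] stored alongside the state.
#' @param seed Optional seed stored alongside the state.
#' @return `load_network_state()` returns the saved list with elements
#'   `state`, `params`, `seed`; the writers return `file` invisibly.
#' @export
save_network_state <- function(state, file, params = NULL, seed = NULL) {
  stopifnot(inherits(state, "network_state"))
  saveRDS(list(state = state, params = params, seed = seed), file)
  invisible(file)
}

#' @rdname save_network_state
#' @export
load_network_state <- function(file) readRDS(file)

#' @rdname save_network_state
#' @export
export_weights_csv <- function(state, file) {
  utils::write.table(state$c, file, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}
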