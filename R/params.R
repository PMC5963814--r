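#' Network model parameters
#'
#' Constants of the Hodgkin-Huxley ring network: membrane conductances and
#' reversal potentials, the per-neuron constant drive current distribution,
#' the initial synaptic-weight distribution, and the Mexican-hat spatial
#' coupling profile.  Defaults are the reference parameter set of the model:
#' `N = 200` neurons on a ring of chain length `d_0 = 10`, short-range
#' excitation up to ring distance `sigma_1 = 3.5` and weak long-range
#' inhibition beyond it, drive currents uniform on
#' `[I_0 - sigma_I, I_0 + sigma_I]` so neurons are non-identical.
#'
#' Neurons are indexed 1..N in every public function (site positions
#' 25/75/125/175 refer to these indices); internal storage uses the same
#' 1-based convention.
#'
#' @param N Number of neurons (>= 2).
#' @param g_Na,g_K,g_l Maximal sodium/potassium/leak conductances (mS/cm^2).
#' @param V_Na,V_K,V_l Sodium/potassium/leak reversal potentials (mV).
#' @param C_m Membrane capacitance (uF/cm^2).
#' @param I_0,sigma_I Center and half-width of the uniform per-neuron
#'   constant drive current (uA/cm^2); `sigma_I < I_0`.
#' @param mu_c,sigma_c Mean and sd of the normal distribution the initial
#'   synaptic weights are drawn from (clipped to `[0, 1]`).
#' @param d_0 Length of the neuronal chain; the lattice spacing is
#'   `d = d_0 / (N - 1)`.
#' @param sigma_1,sigma_2 Mexican-hat parameters: zero crossing of the
#'   profile and width of its Gaussian envelope (`sigma_1 > sigma_2 > 0`).
#' @param V_r_exc,V_r_inh Synaptic reversal potentials (mV) used for
#'   excitatory (profile > 0) and inhibitory (profile < 0) connections.
#'
#' @return An object of class `"network_params"` (named list).
#' @export
#' @examples
#' p <- network_params(N = 20)
#' p$sigma_1
network_params <- function(N = 200,
                           g_Na = 120, g_K = 36, g_l = 0.3,
                           V_Na = 50, V_K = -77, V_l = -54.4,
                           C_m = 1,
                           I_0 = 11.0, sigma_I = 0.45,
                           mu_c = 0.5, sigma_c = 0.01,
                           d_0 = 10, sigma_1 = 3.5, sigma_2 = 2.0,
                           V_r_exc = 20, V_r_inh = -40) {
  stopifnot(N >= 2, N == as.integer(N))
  if (!(g_Na > 0 && g_K > 0 && g_l > 0))
    stop("all conductances must be positive")
  if (!(sigma_1 > sigma_2 && sigma_2 > 0))
    stop("Mexican-hat parameters require sigma_1 > sigma_2 > 0")
  if (!(sigma_I >= 0 && sigma_I < I_0))
    stop("drive half-width sigma_I must lie in [0, I_0)")
  if (sigma_c < 0) stop("sigma_c must be non-negative")
  structure(list(N = as.integer(N),
                 g_Na = g_Na, g_K = g_K, g_l = g_l,
                 V_Na = V_Na, V_K = V_K, V_l = V_l, C_m = C_m,
                 I_0 = I_0, sigma_I = sigma_I,
                 mu_c = mu_c, sigma_c = sigma_c,
                 d_0 = d_0, sigma_1 = sigma_1, sigma_2 = sigma_2,
                 V_r_exc = V_r_exc, V_r_inh = V_r_inh),
            class = "network_params")
}

#' STDP parameters
#'
#' Parameters of the asymmetric spike-timing-dependent plasticity kernel
#' \deqn{\Delta c(\Delta t) = \beta_1 e^{-\Delta t/(\gamma_1\tau)}
#'   \;(\Delta t \ge 0), \qquad
#'   \beta_2 \frac{\Delta t}{\tau} e^{\Delta t/(\gamma_2\tau)}
#'   \;(\Delta t < 0),}
#' with \eqn{\Delta t} the post-minus-pre spike-time difference in ms.
#' Every kernel value is scaled by the learning rate `delta` before being
#' added to (excitatory) or subtracted from (inhibitory) a weight, and
#' weights are clipped to `[c_min, c_max]`.
#'
#' @param beta_1,beta_2 Potentiation/depression amplitudes.
#' @param gamma_1,gamma_2 Potentiation/depression width factors (the decay
#'   scales are `gamma_1 * tau` and `gamma_2 * tau`).
#' @param tau Plasticity time scale (ms).
#' @param delta Learning rate (>= 0; 0 freezes the weights, recovering the
#'   plasticity-free model).
#' @param c_min,c_max Weight bounds (mS/cm^2).
#'
#' @details Pairing is nearest-spike: every spike pairs with the partner
#'   neuron's most recent spike only, in both directions.  This keeps the
#'   per-spike state bounded (one last-spike time per neuron) and makes
#'   the event stream exactly reproducible.
#'
#' @return An object of class `"stdp_params"`.
#' @export
stdp_params <- function(beta_1 = 1, beta_2 = 16,
                        gamma_1 = 0.12, gamma_2 = 0.15,
                        tau = 14, delta = 0.002,
                        c_min = 0, c_max = 1) {
  stopifnot(tau > 0, delta >= 0, c_min < c_max)
  structure(list(beta_1 = beta_1, beta_2 = beta_2,
                 gamma_1 = gamma_1, gamma_2 = gamma_2,
                 tau = tau, delta = delta,
                 c_min = c_min, c_max = c_max),
            class = "stdp_params")
}

#' Coordinated Reset stimulation protocol
#'
#' Describes one CR protocol: `N_s` equidistant stimulation sites on the
#' ring, a cycle period `T_s` during which each site is activated exactly
#' once for `T_s/N_s`, an intensity `K`, an `m:n` ON-OFF cycling scheme,
#' and the site-sequence mode -- `"rvs"` draws a fresh random permutation
#' of the sites every ON cycle, `"svs"` repeats each random permutation
#' `l` times before switching.
#'
#' The stimulus conductance of an activation is the alpha function
#' `G(t) = (t/tau_stim) exp(-t/tau_stim)` with time-to-peak
#' `tau_stim = T_s / (6 N_s)`; its spatial spread is the quadratic decay
#' profile `D(i, x_k) = 1 / (1 + d^2 (i - x_k)^2 / sigma_d^2)`.
#'
#' @param T_s Cycle period (ms, > 0).
#' @param K Stimulation intensity (dimensionless, >= 0).
#' @param mode Sequence mode, `"rvs"` or `"svs"`.
#' @param l Repetitions per sequence in SVS mode (>= 1).
#' @param N_s Number of stimulation sites.
#' @param site_positions Neuron indices of the sites (distinct, in 1..N).
#' @param m,n ON and OFF cycles per ON-OFF block (default 3:2).
#' @param V_r_stim Stimulation reversal potential (mV).
#' @param sigma_d Spatial decay rate of the stimulation current.
#' @param seed Seed of the sequence stream RNG (integer, or `NULL` to
#'   derive from the master seed at run time).
#'
#' @return An object of class `"cr_protocol"`.
#' @export
#' @examples
#' cr_protocol(T_s = 10, K = 0.2, mode = "rvs", seed = 1)
cr_protocol <- function(T_s = 16, K = 0.2, mode = c("rvs", "svs"), l = 100,
                        N_s = 4, site_positions = c(25, 75, 125, 175),
                        m = 3, n = 2, V_r_stim = 20, sigma_d = 0.8,
                        seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(T_s > 0, K >= 0, m >= 0, n >= 0, l >= 1, N_s >= 1)
  site_positions <- as.integer(site_positions)
  if (length(site_positions) != N_s || anyDuplicated(site_positions))
    stop("site_positions must be ", N_s, " distinct neuron indices")
  structure(list(T_s = T_s, K = K, mode = mode, l = as.integer(l),
                 N_s = as.integer(N_s), site_positions = site_positions,
                 m = as.integer(m), n = as.integer(n),
                 V_r_stim = V_r_stim, sigma_d = sigma_d,
                 tau_stim = T_s / (6 * N_s), seed = seed),
            class = "cr_protocol")
}

#' Phase durations of the stimulation experiment
#'
#' The four-phase protocol: an equilibration phase with neither STDP nor
#' stimulation, a kindling phase in which STDP alone rewires the network
#' into a strongly coupled synchronized state, a CR-on phase with both
#' STDP and stimulation, and a stimulation-free CR-off phase probing the
#' persistence of the induced changes.
#'
#' @param equilibration,kindling,cr_on,cr_off Durations in ms (>= 0).
#'   Defaults: 2 s, 60 s, 128 s, 128 s.
#' @param stdp_during_equilibration Keep plasticity on during the
#'   equilibration phase (default `FALSE`).
#' @return An object of class `"protocol_schedule"`.
#' @export
protocol_schedule <- function(equilibration = 2000, kindling = 60000,
                              cr_on = 128000, cr_off = 128000,
                              stdp_during_equilibration = FALSE) {
  stopifnot(equilibration >= 0, kindling >= 0, cr_on >= 0, cr_off >= 0)
  structure(list(equilibration = equilibration, kindling = kindling,
                 cr_on = cr_on, cr_off = cr_off,
                 stdp_during_equilibration = stdp_during_equilibration),
            class = "protocol_schedule")
}

#' Integration configuration
#'
#' The system is advanced with a fixed-step classical Runge-Kutta (RK4)
#' scheme.  Spikes are detected as strict upward crossings of
#' `spike_threshold` with linear interpolation of the crossing time inside
#' the step and a 2 ms refractory guard; weight changes are applied after
#' the step in which the spike was detected.
#'
#' @param dt Step size (ms).  The default 0.05 ms resolves the ~1 ms HH
#'   spike upstroke; 0.01 ms is available for convergence checks.
#' @param spike_threshold Crossing threshold (mV).
#' @param record_stride Steps between recorded measure samples.
#' @param refractory Minimal separation of detected spikes per neuron (ms).
#' @param settle_duration,settle_dt Freshly drawn initial conditions put
#'   the gating variables arbitrarily far from their nullclines, so the
#'   first moments of a run are much stiffer than the running dynamics;
#'   the first `settle_duration` ms of a run started from a raw state
#'   (one without spike history) are integrated at the finer step
#'   `settle_dt` before switching to `dt`.
#' @return An object of class `"integration_config"`.
#' @export
integration_config <- function(dt = 0.05, spike_threshold = 0,
                               record_stride = 20, refractory = 2,
                               settle_duration = 20, settle_dt = 0.001) {
  stopifnot(dt > 0, record_stride >= 1, refractory >= 0,
            settle_duration >= 0, settle_dt > 0)
  structure(list(dt = dt, method = "rk4",
                 spike_threshold = spike_threshold,
                 record_stride = as.integer(record_stride),
                 refractory = refractory,
                 settle_duration = settle_duration, settle_dt = settle_dt),
            class = "integration_config")
}
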