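# Miniature networks for fast tests.  The 20-neuron ring keeps the model
# geometry (Mexican-hat band, four equidistant sites) at a tenth of the
# study size; runs of a few hundred ms finish in well under a second.

small_params <- function(N = 20, ...) network_params(N = N, ...)

# sites every N/4 neurons, centered like the full-scale 25/75/125/175
small_protocol <- function(T_s = 10, K = 0.2, mode = "rvs", N = 20, ...) {
  spacing <- N %/% 4
  cr_protocol(T_s = T_s, K = K, mode = mode,
              site_positions = (0:3) * spacing + ceiling(spacing / 2),
              seed = 7, ...)
}

short_schedule <- function(equilibration = 200, kindling = 200,
                           cr_on = 200, cr_off = 200) {
  protocol_schedule(equilibration, kindling, cr_on, cr_off)
}

# random sparse spike trains for STDP oracle comparisons
random_trains <- function(N, n_spikes, t_max = 100) {
  ev <- data.frame(neuron = sample.int(N, n_spikes, replace = TRUE),
                   time = round(stats::runif(n_spikes, 0, t_max), 3))
  ev <- ev[!duplicated(ev[c("neuron", "time")]), ]
  lapply(seq_len(N), function(j) sort(ev$time[ev$neuron == j]))
}

random_profile <- function(N) {
  build_coupling(network_params(N = N))
}
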