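#' Sign-weighted mean synaptic weight
#'
#' The macroscopic connectivity measure
#' \deqn{C_{av} = N^{-2} \sum_{i,j} \mathrm{sgn}(M_{ij})\, c_{ij},}
#' i.e. excitatory weights count positively and inhibitory weights
#' negatively.  The diagonal contributes nothing because `c_ii = 0`.
#' Values lie in `[-1, 1]`; kindled networks sit near the excitatory end,
#' anti-kindled networks near or below zero.
#'
#' @param c Weight matrix (N x N, zero diagonal).
#' @param sgn Sign matrix of the coupling profile (`profile$sgn`).
#' @return Scalar `C_av`.
#' @export
mean_synaptic_weight <- function(c, sgn) {
  if (!all(dim(c) == dim(sgn))) stop("dimension mismatch")
  sum(sgn * c) / nrow(c)^2
}

#' Linearly interpolated spike phase
#'
#' Between consecutive spikes at `t_m <= t < t_{m+1}` the phase of a
#' neuron grows linearly from 0 to 2*pi:
#' `phi(t) = 2 pi (t - t_m) / (t_{m+1} - t_m)`.  Undefined (NA) when `t`
#' is not bracketed by two spikes.
#'
#' @param spikes Sorted spike times of one neuron (ms).
#' @param t Evaluation time(s), ms.
#' @return Phase(s) in `[0, 2 pi)`, NA where unbracketed.
#' @export
#' @examples
#' linear_phase(c(0, 8), 6)  # 3 pi / 2
linear_phase <- function(spikes, t) {
  out <- rep(NA_real_, length(t))
  if (length(spikes) < 2) return(out)
  m <- findInterval(t, spikes)
  ok <- m >= 1 & m < length(spikes) & t >= spikes[1]
  out[ok] <- 2 * pi * (t[ok] - spikes[m[ok]]) /
    (spikes[m[ok] + 1] - spikes[m[ok]])
  out
}

#' Kuramoto order parameter
#'
#' Modulus of the population-mean unit phasor,
#' `R = |mean(exp(i phi_j))|`, in `[0, 1]`: 0 for phases spread evenly on
#' the circle, 1 for perfect in-phase synchrony.  NA phases (neurons
#' without a bracketing spike pair) are excluded from the mean.
#'
#' @param phases Per-neuron phase values (radians); may contain NA.
#' @return Scalar `R`, or NA if no valid phase is available.
#' @export
order_parameter <- function(phases) {
  phases <- phases[!is.na(phases)]
  if (!length(phases)) return(NA_real_)
  Mod(mean(exp(1i * phases)))
}

#' Order-parameter time series from spike trains
#'
#' Evaluates [linear_phase()] for every neuron on a sample-time grid and
#' reduces each sample to the order parameter.  Neurons lacking a
#' bracketing spike pair at a sample (silent neurons) are excluded from
#' that sample's phasor mean; `n_valid` records how many entered.
#'
#' @param spikes Data frame with columns `neuron` and `time` (ms), or a
#'   list of per-neuron spike-time vectors.
#' @param times Sample times (ms).
#' @param N Number of neurons.
#' @return Data frame with columns `time`, `R`, `n_valid`.
#' @export
order_parameter_series <- function(spikes, times, N) {
  trains <- if (is.data.frame(spikes)) {
    split(spikes$time, factor(spikes$neuron, levels = seq_len(N)))
  } else spikes
  acc <- complex(length(times))
  nv <- integer(length(times))
  for (j in seq_len(N)) {
    ph <- linear_phase(trains[[j]], times)
    ok <- !is.na(ph)
    acc[ok] <- acc[ok] + exp(1i * ph[ok])
    nv <- nv + ok
  }
  data.frame(time = times,
             R = ifelse(nv > 0, Mod(acc) / pmax(nv, 1), NA_real_),
             n_valid = nv)
}

#' Endpoint average of the order parameter
#'
#' Arithmetic mean of the `R` samples inside the window
#' `[t_end - 100 T_s, t_end]`, the standard endpoint summary of a
#' stimulation epoch.
#'
#' @param series Data frame with columns `time` and `R`.
#' @param T_s Cycle period (ms).
#' @param t_end Window end (ms); default: last sample time.
#' @return Scalar `R_av`.
#' @export
r_av <- function(series, T_s, t_end = max(series$time)) {
  lo <- t_end - 100 * T_s
  if (min(series$time) > lo)
    stop("series does not cover the last 100 * T_s window")
  sel <- series$time >= lo & series$time <= t_end
  mean(series$R[sel], na.rm = TRUE)
}

#' Moving average of the order parameter
#'
#' Centered moving mean with window `400 * T_s`, the smoothing used when
#' plotting `R(t)` against time (raw `R` fluctuates strongly); window
#' edges are truncated to the available samples.
#'
#' @param series Data frame with columns `time` and `R`.
#' @param T_s Cycle period (ms).
#' @param window Window length (ms), default `400 * T_s`.
#' @return The series with an extra column `R_ma`.
#' @export
moving_average_R <- function(series, T_s, window = 400 * T_s) {
  t <- series$time
  R <- series$R
  half <- window / 2
  lo <- findInterval(t - half, t, left.open = TRUE) + 1L
  hi <- findInterval(t + half, t)
  cs <- cumsum(ifelse(is.na(R), 0, R))
  cn <- cumsum(!is.na(R))
  n <- cn[hi] - ifelse(lo > 1, cn[lo - 1], 0)
  s <- cs[hi] - ifelse(lo > 1, cs[lo - 1], 0)
  series$R_ma <- ifelse(n > 0, s / n, NA_real_)
  series
}

#' Sub-population order parameters
#'
#' Splits the ring into `N_s` contiguous blocks of `N / N_s` neurons
#' centered on the stimulation sites (for the default geometry: neurons
#' 1-50, 51-100, 101-150, 151-200 around sites 25/75/125/175) and
#' computes the order parameter per block.  A cluster state shows
#' per-block values near 1 with a small global `R`.
#'
#' @param phases Per-neuron phases (length N, NA allowed).
#' @param site_positions Site neuron indices (length `N_s`).
#' @param N Number of neurons; must be divisible by `N_s`.
#' @return Numeric vector of `N_s` block order parameters.
#' @export
subpopulation_order_parameters <- function(phases, site_positions, N) {
  N_s <- length(site_positions)
  if (N %% N_s != 0) stop("N must be divisible by the number of sites")
  bs <- N %/% N_s
  vapply(seq_len(N_s), function(b) {
    order_parameter(phases[((b - 1) * bs + 1):(b * bs)])
  }, numeric(1))
}
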