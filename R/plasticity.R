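#' STDP kernel value
#'
#' Asymmetric spike-timing-dependent plasticity kernel as a function of
#' the post-minus-pre spike-time difference `dt` (ms):
#' potentiation branch `beta_1 * exp(-dt / (gamma_1 tau))` for `dt >= 0`
#' (simultaneous spikes included), depression branch
#' `beta_2 * (dt / tau) * exp(dt / (gamma_2 tau))` for `dt < 0`.  With the
#' default parameters depression dominates at moderate lags, which is what
#' lets uncorrelated firing unlearn strong weights.
#'
#' @param dt Spike-time difference(s) t_post - t_pre, ms; finite.
#' @param p An [stdp_params()] object.
#' @return Kernel value(s) `Delta c` (unscaled by the learning rate).
#' @export
#' @examples
#' p <- stdp_params()
#' stdp_increment(0, p)                    # beta_1
#' stdp_increment(p$gamma_1 * p$tau, p)    # exp(-1)
stdp_increment <- function(dt, p = stdp_params()) {
  if (!all(is.finite(dt))) stop("spike-time difference must be finite")
  ifelse(dt >= 0,
         p$beta_1 * exp(-dt / (p$gamma_1 * p$tau)),
         p$beta_2 * (dt / p$tau) * exp(dt / (p$gamma_2 * p$tau)))
}

# Single-event update rule of the event-driven stream: neuron k spiked at
# time t_sp; partner last-spike times are in `last` (NA = never).
# Excitatory connections add delta * Dc, inhibitory connections subtract
# it; weights are clipped and the diagonal is untouched.
.stdp_apply_one <- function(c_mat, sgn, k, t_sp, last, p) {
  N <- nrow(c_mat)
  j <- which(!is.na(last))
  j <- j[j != k]
  if (length(j)) {
    # incoming k <- j : dt = t_sp - t_j >= 0 (potentiation branch)
    dc_in <- stdp_increment(t_sp - last[j], p)
    upd <- c_mat[k, j] + p$delta * dc_in * sgn[k, j]
    c_mat[k, j] <- pmin(pmax(upd, p$c_min), p$c_max)
    # outgoing i <- k : dt = t_i,last - t_sp <= 0
    dc_out <- stdp_increment(last[j] - t_sp, p)
    upd <- c_mat[j, k] + p$delta * dc_out * sgn[j, k]
    c_mat[j, k] <- pmin(pmax(upd, p$c_min), p$c_max)
  }
  c_mat
}

#' Apply the event-driven STDP update for one spike
#'
#' When neuron `k` spikes at time `t`, every incoming connection `k <- j`
#' is updated with `dt = t - t_j` (last spike of `j`, hence `dt >= 0`,
#' potentiation branch) and every outgoing connection `i <- k` with
#' `dt = t_i - t < 0` (depression branch), using nearest-spike pairing:
#' only the partner's most recent spike participates.  The signed kernel
#' value scaled by the learning rate is added on excitatory connections
#' and subtracted on inhibitory ones, results are clipped to
#' `[c_min, c_max]`, and the diagonal stays zero.  The state's spike
#' history is advanced.
#'
#' @param event List with `neuron` (index) and `time` (ms).
#' @param state A `"network_state"`.
#' @param profile A `"coupling_profile"`.
#' @param p An [stdp_params()] object.
#' @return The updated `"network_state"`.
#' @export
apply_spike_update <- function(event, state, profile, p = stdp_params()) {
  k <- event$neuron
  t_sp <- event$time
  if (!is.na(state$last_spike[k]) && t_sp < state$last_spike[k])
    stop("non-causal update: event precedes recorded spike history")
  state$c <- .stdp_apply_one(state$c, profile$sgn, k, t_sp,
                             state$last_spike, p)
  state$last_spike[k] <- t_sp
  state
}

#' Brute-force STDP replay oracle
#'
#' Replays complete spike trains in global time order and applies the
#' nearest-spike pairing rule, recomputing every pairing from the raw
#' trains rather than from an incremental history structure.  Intended as
#' an independent reference for testing the event-driven stream; not used
#' by the simulator.
#'
#' @param spike_trains List of numeric vectors, one sorted spike-time
#'   train per neuron (ms).
#' @param c0 Initial weight matrix (zero diagonal).
#' @param profile A `"coupling_profile"`.
#' @param p An [stdp_params()] object.
#' @return Final weight matrix.
#' @export
stdp_oracle <- function(spike_trains, c0, profile, p = stdp_params()) {
  N <- nrow(c0)
  stopifnot(length(spike_trains) == N)
  ev <- data.frame(
    neuron = rep(seq_len(N), lengths(spike_trains)),
    time = unlist(spike_trains, use.names = FALSE))
  ev <- ev[order(ev$time, ev$neuron), , drop = FALSE]
  # kernel written out longhand, independent of stdp_increment()
  kern <- function(dt) {
    if (dt >= 0) p$beta_1 * exp(-dt / (p$gamma_1 * p$tau))
    else p$beta_2 * (dt / p$tau) * exp(dt / (p$gamma_2 * p$tau))
  }
  c_mat <- c0
  for (r in seq_len(nrow(ev))) {
    k <- ev$neuron[r]
    t_sp <- ev$time[r]
    for (j in seq_len(N)) {
      if (j == k) next
      # partner's most recent spike before (or tied with, lower index
      # first) this event, recomputed from the raw trains every time
      prev <- spike_trains[[j]]
      prev <- prev[prev < t_sp | (prev == t_sp & j < k)]
      if (!length(prev)) next
      t_j <- max(prev)
      w <- c_mat[k, j] + p$delta * kern(t_sp - t_j) * profile$sgn[k, j]
      c_mat[k, j] <- min(max(w, p$c_min), p$c_max)
      w <- c_mat[j, k] + p$delta * kern(t_j - t_sp) * profile$sgn[j, k]
      c_mat[j, k] <- min(max(w, p$c_min), p$c_max)
    }
  }
  c_mat
}
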