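#' Detect spikes from a pair of consecutive membrane-potential samples
#'
#' A spike is a strict upward crossing of `threshold` between two
#' consecutive samples; its time is interpolated linearly within the
#' step.  A plateau sitting exactly at the threshold is not a crossing.
#' Crossings closer than `refractory` ms to a neuron's previous spike are
#' discarded.
#'
#' @param V_prev,V_now Membrane potentials at `t` and `t + dt` (mV).
#' @param threshold Crossing threshold (mV).
#' @param t Time of the earlier sample (ms).
#' @param dt Step (ms).
#' @param last_spike Per-neuron previous spike times (NA = none).
#' @param refractory Guard interval (ms).
#' @return Data frame with columns `neuron`, `time`, sorted by `time`.
#' @export
#' @examples
#' detect_spikes(-10, 10, threshold = 0, t = 100, dt = 0.05)
detect_spikes <- function(V_prev, V_now, threshold = 0, t, dt,
                          last_spike = rep(NA_real_, length(V_prev)),
                          refractory = 2) {
  stopifnot(length(V_prev) == length(V_now))
  hit <- which(V_prev < threshold & V_now > threshold)
  ts <- t + dt * (threshold - V_prev[hit]) / (V_now[hit] - V_prev[hit])
  ok <- is.na(last_spike[hit]) | (ts - last_spike[hit] >= refractory)
  out <- data.frame(neuron = hit[ok], time = ts[ok])
  out[order(out$time, out$neuron), , drop = FALSE]
}

#' Per-neuron firing rates over a time window
#'
#' Spike count divided by window length, per neuron, plus the network
#' mean and dispersion.
#'
#' @param spikes Data frame with columns `neuron`, `time` (ms).
#' @param window Length-2 numeric, `c(t_from, t_to)` in ms.
#' @param N Number of neurons.
#' @return List with `rates` (Hz, length N), `mean` and `sd` (Hz).
#' @export
firing_rates <- function(spikes, window, N) {
  if (diff(window) <= 0) stop("empty window")
  sel <- spikes$time >= window[1] & spikes$time < window[2]
  counts <- tabulate(spikes$neuron[sel], nbins = N)
  rates <- counts / diff(window) * 1000
  list(rates = rates, mean = mean(rates), sd = stats::sd(rates))
}

# Advance one protocol phase through the compiled core.
.sim_phase <- function(state, profile, params, stdp, cfg, duration,
                       stdp_on, stim = NULL) {
  n_steps <- as.integer(round(duration / cfg$dt))
  if (is.null(stim)) {
    stim <- list(on = FALSE, onset = numeric(0), site = integer(0),
                 slot_len = 1, tau_stim = 1, K = 0, V_r = 0, t0 = 0,
                 D = matrix(0, params$N, 1))
  }
  # widest ring band with positive (excitatory) profile, in steps
  kstar <- sum(params$d_0 / (params$N - 1) * seq_len(params$N %/% 2) <
                 params$sigma_1)
  res <- cpp_simulate_phase(
    state$V, state$m, state$h, state$n, state$s, state$I,
    state$c, profile$abs_M, profile$sgn, kstar,
    params$V_r_exc, params$V_r_inh,
    params[c("g_Na", "g_K", "g_l", "V_Na", "V_K", "V_l", "C_m")],
    cfg$dt, n_steps, state$t,
    stdp_on, stdp, cfg$spike_threshold, cfg$refractory, state$last_spike,
    stim$on, stim$onset, stim$site, stim$slot_len, stim$tau_stim,
    stim$K, stim$V_r, stim$D, stim$t0, cfg$record_stride)
  new_state <- structure(
    list(V = as.numeric(res$V), m = as.numeric(res$m),
         h = as.numeric(res$h), n = as.numeric(res$n),
         s = as.numeric(res$s), I = state$I, c = res$c,
         last_spike = res$last_spike, t = res$t),
    class = "network_state")
  list(state = new_state,
       spikes = data.frame(neuron = res$spike_neuron,
                           time = res$spike_time),
       series = data.frame(time = res$rec_time, C_av = res$rec_cav))
}

#' Run the four-phase stimulation experiment
#'
#' Executes equilibration (no STDP, no stimulation), kindling (STDP only;
#' the network rewires into a strongly coupled synchronized state), CR-on
#' (STDP + CR stimulation with the protocol's m:n ON-OFF cycling), and
#' CR-off (STDP only again, probing persistence).  Time runs continuously
#' from 0 at the start of equilibration; the CR-on start time is reported
#' in `boundaries` so results can be re-zeroed to stimulation onset.
#' Fully reproducible: the network seed fixes the initial state and
#' `protocol$seed` (default `seed + 10007`) fixes the sequence stream.
#'
#' @param params A [network_params()] object.
#' @param stdp An [stdp_params()] object.
#' @param protocol A [cr_protocol()] object, or `NULL` for a
#'   stimulation-free run.
#' @param schedule A [protocol_schedule()] object.
#' @param cfg An [integration_config()] object.
#' @param seed Master seed (integer) for the network initialization.
#' @param init_state Optional `"network_state"` to start from (e.g. a
#'   kindled snapshot); skips `init_network()`.
#' @param profile Optional precomputed `"coupling_profile"`.
#' @param measure Compute the order-parameter series (default `TRUE`).
#' @return An object of class `"cr_sim_result"`: list with `series`
#'   (time, C_av, R, n_valid, phase), `spikes`, `endpoints`
#'   (C_av/R_av at the ends of CR-on and CR-off, firing rates),
#'   `snapshots` (weight matrices at phase boundaries), `boundaries`,
#'   `state` (final), and `provenance`.
#' @export
run_protocol <- function(params = network_params(),
                         stdp = stdp_params(),
                         protocol = cr_protocol(),
                         schedule = protocol_schedule(),
                         cfg = integration_config(),
                         seed = 1, init_state = NULL, profile = NULL,
                         measure = TRUE) {
  if (is.null(profile)) profile <- build_coupling(params)
  state <- if (is.null(init_state)) init_network(params, seed) else init_state

  if (!is.null(protocol) && schedule$cr_on > 0) {
    slot_len <- protocol$T_s / protocol$N_s
    k <- slot_len / cfg$dt
    if (abs(k - round(k)) > 1e-9 * k)
      stop("dt must divide T_s / N_s so slot boundaries land on the grid")
  }

  spikes <- list()
  series <- list()
  snapshots <- list(initial = state$c)
  boundaries <- c(start = state$t)

  advance <- function(label, duration, stdp_on, stim = NULL) {
    if (duration <= 0) return(invisible(NULL))
    # a raw state (no spike history yet) needs a fine-step settling
    # window before the production step size takes over
    if (all(is.na(state$last_spike)) && cfg$settle_duration > 0) {
      settle <- min(cfg$settle_duration, duration)
      fine <- cfg
      fine$dt <- cfg$settle_dt
      fine$record_stride <- as.integer(round(settle / cfg$settle_dt))
      ph0 <- .sim_phase(state, profile, params, stdp, fine, settle,
                        stdp_on, stim)
      state <<- ph0$state
      if (nrow(ph0$spikes)) spikes[[paste0(label, "_settle")]] <<- ph0$spikes
      duration <- duration - settle
      if (duration <= 0) {
        ph0$series$phase <- label
        series[[label]] <<- ph0$series
        return(invisible(NULL))
      }
    }
    ph <- .sim_phase(state, profile, params, stdp, cfg, duration,
                     stdp_on, stim)
    state <<- ph$state
    if (nrow(ph$spikes)) spikes[[label]] <<- ph$spikes
    ph$series$phase <- label
    series[[label]] <<- ph$series
    invisible(NULL)
  }

  advance("equilibration", schedule$equilibration,
          schedule$stdp_during_equilibration)
  boundaries["equilibration_end"] <- state$t
  snapshots$post_equilibration <- state$c

  advance("kindling", schedule$kindling, TRUE)
  boundaries["kindling_end"] <- state$t
  snapshots$post_kindling <- state$c

  stream_seed <- NULL
  if (!is.null(protocol) && schedule$cr_on > 0) {
    stream_seed <- if (is.null(protocol$seed)) seed + 10007L else protocol$seed
    count <- n_on_cycles(protocol, schedule$cr_on)
    stream <- svs_stream(stream_seed, protocol$N_s,
                         if (protocol$mode == "svs") protocol$l else 1L,
                         count)
    tl <- stimulus_timeline(protocol, stream, schedule$cr_on)
    d <- params$d_0 / (params$N - 1)
    D <- vapply(protocol$site_positions, function(x)
      spatial_profile(seq_len(params$N), x, d, protocol$sigma_d),
      numeric(params$N))
    stim <- list(on = TRUE, onset = tl$onset, site = tl$site,
                 slot_len = protocol$T_s / protocol$N_s,
                 tau_stim = protocol$tau_stim, K = protocol$K,
                 V_r = protocol$V_r_stim, D = D, t0 = state$t)
    advance("cr_on", schedule$cr_on, TRUE, stim)
  } else {
    advance("cr_on", schedule$cr_on, TRUE)
  }
  boundaries["cr_on_end"] <- state$t
  snapshots$post_cr_on <- state$c

  advance("cr_off", schedule$cr_off, TRUE)
  boundaries["cr_off_end"] <- state$t
  snapshots$post_cr_off <- state$c

  spikes <- if (length(spikes)) do.call(rbind, unname(spikes))
            else data.frame(neuron = integer(0), time = numeric(0))
  series <- if (length(series)) do.call(rbind, unname(series))
            else data.frame(time = numeric(0), C_av = numeric(0),
                            phase = character(0))
  # phase boundaries are sampled twice (end of one phase, start of the
  # next); keep the first occurrence
  series <- series[!duplicated(series$time), , drop = FALSE]
  rownames(series) <- NULL

  if (measure && nrow(series)) {
    os <- order_parameter_series(spikes, series$time, params$N)
    series$R <- os$R
    series$n_valid <- os$n_valid
  }

  T_s <- if (!is.null(protocol)) protocol$T_s else NA_real_
  endpoints <- list()
  cav_at <- function(tt) series$C_av[which.min(abs(series$time - tt))]
  if (schedule$kindling > 0) {
    w <- c(max(boundaries["kindling_end"] - 5000, boundaries["equilibration_end"]),
           boundaries["kindling_end"])
    endpoints$mean_rate_kindling <- firing_rates(spikes, w, params$N)$mean
    endpoints$C_av_kindling_end <- cav_at(boundaries["kindling_end"])
  }
  # endpoint window is 100 * T_s; short (scaled-down) epochs that do not
  # cover it report NA rather than fail
  r_av_safe <- function(tt) tryCatch(unname(r_av(series, T_s, tt)),
                                     error = function(e) NA_real_)
  if (schedule$cr_on > 0 && !is.na(T_s)) {
    endpoints$C_av_on_end <- cav_at(boundaries["cr_on_end"])
    if (measure)
      endpoints$R_av_on_end <- r_av_safe(boundaries["cr_on_end"])
  }
  if (schedule$cr_off > 0 && !is.na(T_s)) {
    endpoints$C_av_off_end <- cav_at(boundaries["cr_off_end"])
    if (measure)
      endpoints$R_av_off_end <- r_av_safe(boundaries["cr_off_end"])
    endpoints$mean_rate_end <- firing_rates(
      spikes, c(boundaries["cr_off_end"] - min(5000, schedule$cr_off),
                boundaries["cr_off_end"]), params$N)$mean
  }

  structure(list(series = series, spikes = spikes, endpoints = endpoints,
                 snapshots = snapshots, boundaries = boundaries,
                 state = state,
                 provenance = list(params = params, stdp = stdp,
                                   protocol = protocol, schedule = schedule,
                                   cfg = cfg, seed = seed,
                                   stream_seed = stream_seed)),
            class = "cr_sim_result")
}

#' @export
print.cr_sim_result <- function(x, ...) {
  b <- x$boundaries
  cat("<cr_sim_result> ", length(unique(x$series$phase)), " phases, t = ",
      b[["start"]], " .. ", x$state$t, " ms, ",
      nrow(x$spikes), " spikes\n", sep = "")
  if (length(x$endpoints)) {
    ep <- vapply(x$endpoints, function(v) sprintf("%.4f", v), character(1))
    cat("endpoints: ", paste(names(ep), ep, sep = " = ", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Export spikes as a two-column CSV
#'
#' @param spikes Data frame with columns `neuron`, `time`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
export_spikes_csv <- function(spikes, file) {
  utils::write.csv(spikes[, c("neuron", "time")], file, row.names = FALSE)
  invisible(file)
}
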