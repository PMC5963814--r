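#' Random site-sequence streams
#'
#' A CR *sequence* is the order in which the `N_s` sites are activated
#' exactly once within one ON cycle.  `rvs_stream()` draws an independent
#' uniform random permutation of `1..N_s` for every ON cycle (Rapidly
#' Varying Sequences).  `svs_stream()` draws a permutation and repeats it
#' for `l` consecutive ON cycles before switching (Slowly Varying
#' Sequences, SVS-l); `l = 1` is distributionally identical to RVS.
#' Both are reproducible per seed and leave the caller's RNG untouched.
#'
#' @param seed Integer RNG seed of the sequence stream.
#' @param N_s Number of sites.
#' @param count Number of ON cycles to cover.
#' @param l Repetitions per sequence (SVS).
#' @return Integer matrix `count x N_s`; row `g` is the permutation used
#'   in global ON cycle `g` (1-based ordinal).
#' @export
#' @examples
#' rvs_stream(seed = 1, N_s = 4, count = 3)
rvs_stream <- function(seed, N_s = 4, count) {
  svs_stream(seed, N_s = N_s, l = 1, count = count)
}

#' @rdname rvs_stream
#' @export
svs_stream <- function(seed, N_s = 4, l = 100, count) {
  stopifnot(N_s >= 1, l >= 1, count >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  n_blocks <- ceiling(count / l)
  out <- matrix(0L, nrow = count, ncol = N_s)
  for (b in seq_len(n_blocks)) {
    perm <- sample.int(N_s)
    rows <- ((b - 1L) * l + 1L):min(b * l, count)
    out[rows, ] <- matrix(perm, nrow = length(rows), ncol = N_s,
                          byrow = TRUE)
  }
  out
}

#' ON/OFF phase of the CR cycling scheme at a time point
#'
#' Stimulation cycles of length `T_s` are grouped into blocks of `m` ON
#' cycles followed by `n` OFF cycles; the pattern is `(m + n) * T_s`
#' periodic.  The global ON-cycle ordinal counts ON cycles only (OFF
#' cycles do not consume sequences from the stream).
#'
#' @param t Time(s) since the start of CR stimulation (ms, >= 0).
#' @param T_s Cycle period (ms).
#' @param m,n ON and OFF cycles per block.
#' @return Data frame with columns `on` (logical) and `on_cycle` (0-based
#'   global ON-cycle ordinal; for OFF instants, the ordinal the next ON
#'   cycle will have).
#' @export
#' @examples
#' onoff_cycle(c(25, 35), T_s = 10)
onoff_cycle <- function(t, T_s, m = 3, n = 2) {
  stopifnot(all(t >= 0), T_s > 0)
  block <- T_s * (m + n)
  b <- floor(t / block)
  within_cyc <- floor((t %% block) / T_s)   # 0..m+n-1
  on <- within_cyc < m
  data.frame(on = on,
             on_cycle = as.integer(b * m + pmin(within_cyc, m)))
}

#' Site activation indicator
#'
#' During ON cycle `g` with sequence `seq_g`, the site occupying slot `p`
#' (0-based) of the sequence is active exactly on the half-open window
#' `[p T_s/N_s, (p+1) T_s/N_s)` within the cycle, so exactly one site is
#' active at every ON instant and none during OFF cycles.
#'
#' @param t Time(s) since CR start (ms).
#' @param site Site index in `1..N_s`.
#' @param protocol A [cr_protocol()] object.
#' @param stream Sequence matrix from [rvs_stream()] / [svs_stream()].
#' @return 0/1 vector, the indicator of `site` at `t`.
#' @export
cr_indicator <- function(t, site, protocol, stream) {
  ph <- onoff_cycle(t, protocol$T_s, protocol$m, protocol$n)
  slot_len <- protocol$T_s / protocol$N_s
  slot <- floor((t %% protocol$T_s) / slot_len)  # 0-based within cycle
  out <- integer(length(t))
  idx <- which(ph$on)
  if (length(idx)) {
    g <- ph$on_cycle[idx] + 1L
    if (any(g > nrow(stream))) stop("sequence stream exhausted")
    active_site <- stream[cbind(g, slot[idx] + 1L)]
    out[idx] <- as.integer(active_site == site)
  }
  out
}

#' Alpha-function stimulus conductance
#'
#' Normalized conductance evoked by a site activation with onset `t_k`:
#' `G(t) = ((t - t_k)/tau_stim) * exp(-(t - t_k)/tau_stim)`, zero at the
#' onset and maximal (`exp(-1)`) at `t = t_k + tau_stim`, where the
#' time-to-peak is `tau_stim = T_s / (6 N_s)`.  Each activation is only
#' evaluated within its validity window (up to the next activation), so
#' pulses do not overlap.
#'
#' @param t Evaluation time(s), ms, `>= t_k`.
#' @param t_k Activation onset (ms).
#' @param tau_stim Time-to-peak (ms).
#' @return Conductance value(s).
#' @export
gstim <- function(t, t_k, tau_stim) {
  if (any(t < t_k)) stop("gstim evaluated before the activation onset")
  u <- (t - t_k) / tau_stim
  u * exp(-u)
}

#' Spatial decay profile of the stimulation current
#'
#' Quadratic decay around the stimulated neuron:
#' `D(i, x_k) = 1 / (1 + d^2 (i - x_k)^2 / sigma_d^2)` with `d` the
#' lattice spacing; equals 1 at the site and is symmetric in `i - x_k`.
#' Note the decay uses the plain index difference (each site drives its
#' local neighbourhood), not the ring metric.
#'
#' @param i Neuron index (vectorized).
#' @param x_k Site neuron index.
#' @param d Lattice spacing `d_0 / (N - 1)`.
#' @param sigma_d Spatial decay rate.
#' @return Decay factor(s) in `(0, 1]`.
#' @export
spatial_profile <- function(i, x_k, d, sigma_d = 0.8) {
  1 / (1 + d^2 * (i - x_k)^2 / sigma_d^2)
}

#' Total CR stimulation current
#'
#' `F_i = (V_r - V_i) * K * sum_k D(i, x_k) rho_k(t) G_stim(t)`: at most
#' one indicator is non-zero at a time, so during an ON slot the current
#' is the alpha-function conductance of the active site, spatially
#' weighted by `D` and driven by the excitatory reversal potential; zero
#' during OFF cycles or at `K = 0`.
#'
#' @param state A `"network_state"`.
#' @param t Time since CR start (ms, scalar).
#' @param protocol A [cr_protocol()] object.
#' @param stream Sequence matrix covering the ON cycle at `t`.
#' @param params A [network_params()] object (for `N`, `d_0`).
#' @return Numeric vector of per-neuron currents `F_i`.
#' @export
stimulation_current <- function(state, t, protocol, stream, params) {
  N <- length(state$V)
  F_i <- numeric(N)
  if (protocol$K == 0) return(F_i)
  ph <- onoff_cycle(t, protocol$T_s, protocol$m, protocol$n)
  if (!ph$on) return(F_i)
  slot_len <- protocol$T_s / protocol$N_s
  slot <- floor((t %% protocol$T_s) / slot_len)
  g <- ph$on_cycle + 1L
  if (g > nrow(stream)) stop("sequence stream exhausted")
  site <- stream[g, slot + 1L]
  onset <- floor(t / slot_len) * slot_len
  d <- params$d_0 / (params$N - 1)
  D <- spatial_profile(seq_len(N), protocol$site_positions[site], d,
                       protocol$sigma_d)
  (protocol$V_r_stim - state$V) * protocol$K * D *
    gstim(t, onset, protocol$tau_stim)
}

# Expand a protocol + stream into the activation timeline of one CR-on
# epoch: one row per site activation (slot), truncated at the epoch end.
# Onsets are relative to the epoch start.
stimulus_timeline <- function(protocol, stream, duration) {
  T_s <- protocol$T_s
  N_s <- protocol$N_s
  slot_len <- T_s / N_s
  block <- T_s * (protocol$m + protocol$n)
  n_on <- nrow(stream)
  g <- seq_len(n_on) - 1L                      # 0-based ON ordinal
  cycle_start <- (g %/% protocol$m) * block + (g %% protocol$m) * T_s
  onset <- rep(cycle_start, each = N_s) +
    rep(seq_len(N_s) - 1L, times = n_on) * slot_len
  df <- data.frame(
    onset = onset,
    site = as.integer(t(stream)),
    slot = rep(seq_len(N_s) - 1L, times = n_on),
    on_cycle = rep(g, each = N_s),
    sequence_id = rep(if (protocol$mode == "svs") g %/% protocol$l else g,
                      each = N_s))
  df[df$onset < duration, , drop = FALSE]
}

# Number of ON cycles whose start lies inside a CR-on epoch of `duration`
# ms (partial trailing cycles are kept and truncated at the epoch end).
n_on_cycles <- function(protocol, duration) {
  block <- protocol$T_s * (protocol$m + protocol$n)
  full <- floor(duration / block)
  rest <- duration - full * block
  extra <- min(ceiling(rest / protocol$T_s), protocol$m)
  as.integer(full * protocol$m + extra)
}

#' Export a stimulus timeline as CSV
#'
#' One row per site activation: onset (ms, relative to CR start), site,
#' slot within the cycle, global ON-cycle ordinal, and sequence id.
#'
#' @param protocol A [cr_protocol()] object with a `seed`.
#' @param duration CR-on duration (ms).
#' @param file Output path.
#' @return The timeline data frame, invisibly.
#' @export
export_stimulus_csv <- function(protocol, duration, file) {
  count <- n_on_cycles(protocol, duration)
  stream <- svs_stream(protocol$seed, protocol$N_s,
                       if (protocol$mode == "svs") protocol$l else 1L,
                       count)
  tl <- stimulus_timeline(protocol, stream, duration)
  utils::write.csv(tl, file, row.names = FALSE)
  invisible(tl)
}
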