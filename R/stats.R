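#' Conversion between stimulation period and frequency ratio
#'
#' `ratio_for_period()` expresses a cycle period `T_s` (ms) as the
#' percentage of a reference frequency, `(1000 / T_s) / f_ref * 100`,
#' rounded to the nearest integer percent.  `period_for_ratio()` is the
#' inverse design mapping: the integer period (ms) closest to the one
#' realizing a requested percentage, `round(1000 / (f_ref * r / 100))`.
#' Two references are in routine use: the reference stimulation frequency
#' `f_0 = 62.5` Hz (16 ms) and the intrinsic firing rate of the kindled
#' network, `f_int = 1000/14` Hz (~71.4 Hz).  Because periods are rounded
#' to integer milliseconds, forward conversion of a rounded period does
#' not always land back on the design percentage (e.g. 85% -> 19 ms ->
#' 84%); the period values are the authoritative grid.
#'
#' @param T_s Cycle period(s), ms, > 0.
#' @param ratio Frequency ratio(s) in percent, > 0.
#' @param f_ref Reference frequency (Hz).
#' @return Integer percent (forward) or integer period in ms (inverse).
#' @export
#' @examples
#' ratio_for_period(16, f_ref = 62.5)        # 100
#' ratio_for_period(9, f_ref = 1000 / 14)    # 156
#' period_for_ratio(145, f_ref = 62.5)       # 11
ratio_for_period <- function(T_s, f_ref = 62.5) {
  stopifnot(all(T_s > 0), f_ref > 0)
  as.integer(round((1000 / T_s) / f_ref * 100))
}

#' @rdname ratio_for_period
#' @export
period_for_ratio <- function(ratio, f_ref = 62.5) {
  stopifnot(all(ratio > 0), f_ref > 0)
  as.integer(round(1000 / (f_ref * ratio / 100)))
}

#' Parameter-sweep specification
#'
#' The grid of stimulation intensities and periods explored per protocol
#' mode, the number of replicate networks, and an optional duration scale
#' applied to the CR-on and CR-off epochs (equilibration and kindling
#' keep their full lengths so every cell starts from the same kindled
#' baseline).  Defaults are the full study grid: `K` from 0.20 to 0.50 in
#' steps of 0.05, the 11 periods of the frequency-ratio table, 11
#' replicate networks.
#'
#' @param K Intensity values (>= 0).
#' @param T_s Period values (ms, > 0).
#' @param modes Character vector from `c("rvs", "svs")`.
#' @param l SVS repetitions per sequence.
#' @param replicates Number of replicate networks.
#' @param duration_scale Factor multiplying the CR-on/CR-off durations.
#' @return An object of class `"sweep_spec"`.
#' @export
sweep_spec <- function(K = seq(0.20, 0.50, by = 0.05),
                       T_s = c(64, 40, 29, 23, 19, 16, 14, 12, 11, 10, 9),
                       modes = "rvs", l = 100, replicates = 11,
                       duration_scale = 1) {
  stopifnot(all(K >= 0), all(T_s > 0), replicates >= 1,
            all(modes %in% c("rvs", "svs")), duration_scale > 0)
  structure(list(K = K, T_s = T_s, modes = modes, l = as.integer(l),
                 replicates = as.integer(replicates),
                 duration_scale = duration_scale),
            class = "sweep_spec")
}

#' Run a (K, T_s) stimulation-parameter sweep
#'
#' For each replicate network the pre-stimulation history (equilibration
#' + kindling) is simulated once from seed `seed + network id` and the
#' kindled snapshot is reused for every grid cell, mirroring the design
#' of stimulating the same networks across the whole grid.  Each cell
#' then runs CR-on/CR-off from that snapshot with a cell-specific
#' sequence-stream seed.  Deterministic per `seed`; with `cache_dir` set,
#' completed records are written as RDS files and skipped on rerun, so an
#' interrupted sweep resumes and a completed sweep is idempotent.
#' Failures of individual runs are recorded (`NA` endpoints, message in
#' `error`) and the sweep continues.
#'
#' @param spec A [sweep_spec()] object.
#' @param params,stdp,schedule,cfg Shared run configuration (see
#'   [run_protocol()]).
#' @param seed Master seed of the seed table.
#' @param cache_dir Optional directory for resumable per-record caching.
#' @param protocol_defaults A [cr_protocol()] supplying the non-swept
#'   protocol fields (sites, m:n, sigma_d, ...).
#' @param verbose Print one line per record.
#' @return A data frame of class `"sweep_table"`, one row per
#'   (mode, K, T_s, network) with endpoint columns `C_av_on_end`,
#'   `R_av_on_end`, `C_av_off_end`, `R_av_off_end`, `mean_rate`.
#' @export
run_sweep <- function(spec = sweep_spec(),
                      params = network_params(),
                      stdp = stdp_params(),
                      schedule = protocol_schedule(),
                      cfg = integration_config(),
                      seed = 1, cache_dir = NULL,
                      protocol_defaults = cr_protocol(),
                      verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)
  profile <- build_coupling(params)
  kindle_sched <- protocol_schedule(schedule$equilibration,
                                    schedule$kindling, 0, 0)
  cr_sched <- protocol_schedule(0, 0,
                                schedule$cr_on * spec$duration_scale,
                                schedule$cr_off * spec$duration_scale)
  grid <- expand.grid(mode = spec$modes, K = spec$K, T_s = spec$T_s,
                      network = seq_len(spec$replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  kindled <- NULL
  kindled_id <- NA
  for (net in unique(grid$network)) {
    cells <- which(grid$network == net)
    for (ci in seq_along(cells)) {
      g <- grid[cells[ci], ]
      tag <- sprintf("%s_K%.2f_Ts%g_net%d", g$mode, g$K, g$T_s, g$network)
      cache_file <- if (!is.null(cache_dir))
        file.path(cache_dir, paste0(tag, ".rds")) else NULL
      if (!is.null(cache_file) && file.exists(cache_file)) {
        rows[[cells[ci]]] <- readRDS(cache_file)
        next
      }
      if (!identical(kindled_id, net)) {
        kindled <- run_protocol(params, stdp, protocol = NULL,
                                schedule = kindle_sched, cfg = cfg,
                                seed = seed + net, profile = profile,
                                measure = FALSE)
        kindled_id <- net
      }
      rec <- tryCatch({
        proto <- cr_protocol(T_s = g$T_s, K = g$K, mode = g$mode,
                             l = spec$l,
                             N_s = protocol_defaults$N_s,
                             site_positions = protocol_defaults$site_positions,
                             m = protocol_defaults$m, n = protocol_defaults$n,
                             V_r_stim = protocol_defaults$V_r_stim,
                             sigma_d = protocol_defaults$sigma_d,
                             seed = seed + 1000L * net + 7L * ci)
        res <- run_protocol(params, stdp, proto, cr_sched, cfg,
                            seed = seed + net,
                            init_state = kindled$state, profile = profile)
        ep <- res$endpoints
        data.frame(mode = g$mode, K = g$K, T_s = g$T_s, network = g$network,
                   C_av_kindled = kindled$endpoints$C_av_kindling_end,
                   rate_kindled = kindled$endpoints$mean_rate_kindling,
                   C_av_on_end = ep$C_av_on_end,
                   R_av_on_end = ep$R_av_on_end,
                   C_av_off_end = ep$C_av_off_end,
                   R_av_off_end = ep$R_av_off_end,
                   mean_rate = ep$mean_rate_end,
                   error = NA_character_)
      }, error = function(e) {
        data.frame(mode = g$mode, K = g$K, T_s = g$T_s, network = g$network,
                   C_av_kindled = NA_real_, rate_kindled = NA_real_,
                   C_av_on_end = NA_real_, R_av_on_end = NA_real_,
                   C_av_off_end = NA_real_, R_av_off_end = NA_real_,
                   mean_rate = NA_real_, error = conditionMessage(e))
      })
      if (verbose)
        message(tag, ": C_av_off_end = ",
                signif(rec$C_av_off_end, 4))
      if (!is.null(cache_file)) saveRDS(rec, cache_file)
      rows[[cells[ci]]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Boxplot summary statistics
#'
#' Median, quartiles (type-7 linear interpolation between order
#' statistics), inter-quartile range, the 1.5 IQR fences, and the
#' observations falling outside them.
#'
#' @param values Numeric vector (n >= 1).
#' @return An object of class `"boxplot_stats"`: list with `median`,
#'   `q1`, `q3`, `iqr`, `fence_lower`, `fence_upper`, `outliers`, `n`.
#' @export
#' @examples
#' boxplot_stats(1:11)
boxplot_stats <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no non-missing values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  fl <- q[1] - 1.5 * iqr
  fu <- q[3] + 1.5 * iqr
  structure(list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
                 fence_lower = fl, fence_upper = fu,
                 outliers = values[values < fl | values > fu],
                 n = length(values)),
            class = "boxplot_stats")
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Thin wrapper around [stats::wilcox.test()]: the exact small-sample
#' null distribution is used when both samples have at most 12
#' observations and there are no ties, the normal approximation
#' otherwise.  Degenerate all-tied input is flagged.
#'
#' @param a,b Numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List with `statistic` (rank-sum W), `p_value`, `method`.
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(10, 11, 12))$p_value  # exact, 0.1
rank_sum_test <- function(a, b,
                          alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  if (length(unique(c(a, b))) == 1)
    warning("degenerate input: all observations tied")
  exact <- length(a) <= 12 && length(b) <= 12 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                       correct = !exact))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Sample-size estimate for a two-sided location test
#'
#' First-pass estimate `n = ceil((x_{1-a/2} + x_{1-b})^2 (sd / delta)^2)`
#' of the number of replicates needed to detect a shift `delta` at
#' significance `alpha_s` with power `1 - beta_s`, given dispersion `sd`.
#' Quantiles are standard normal by default; with `quantiles = "t"` the
#' Student-t quantiles are iterated to a fixed point of `df = n - 1`.
#' The result is floored at 1.
#'
#' @param alpha_s Two-sided significance level in (0, 1).
#' @param beta_s Type-II error risk in (0, 1).
#' @param sd Anticipated standard deviation (> 0).
#' @param delta_s Shift to detect (> 0).
#' @param quantiles `"normal"` (default) or `"t"`.
#' @return Integer sample size.
#' @export
#' @examples
#' sample_size_estimate(0.05, 0.10, sd = 1, delta_s = 1)  # 11
sample_size_estimate <- function(alpha_s = 0.05, beta_s = 0.10,
                                 sd, delta_s,
                                 quantiles = c("normal", "t")) {
  quantiles <- match.arg(quantiles)
  stopifnot(alpha_s > 0, alpha_s < 1, beta_s > 0, beta_s < 1,
            sd > 0, delta_s > 0)
  ratio2 <- (sd / delta_s)^2
  n <- ceiling((stats::qnorm(1 - alpha_s / 2) +
                  stats::qnorm(1 - beta_s))^2 * ratio2)
  n <- max(n, 1)
  if (quantiles == "t") {
    repeat {
      df <- max(n - 1, 1)
      n2 <- max(ceiling((stats::qt(1 - alpha_s / 2, df) +
                           stats::qt(1 - beta_s, df))^2 * ratio2), 1)
      if (n2 == n) break
      n <- n2
    }
  }
  as.integer(n)
}

#' Summarize a sweep table with boxplot statistics
#'
#' Groups a [run_sweep()] table by (mode, K, T_s) and returns the median
#' and IQR of a chosen endpoint across replicate networks.
#'
#' @param table A `"sweep_table"`.
#' @param outcome Endpoint column name, default `"C_av_off_end"`.
#' @return Data frame with one row per (mode, K, T_s): `median`, `iqr`,
#'   `n_outliers`, `n`.
#' @export
sweep_summary <- function(table, outcome = "C_av_off_end") {
  stopifnot(outcome %in% names(table))
  keys <- unique(table[, c("mode", "K", "T_s")])
  rows <- lapply(seq_len(nrow(keys)), function(r) {
    sel <- table$mode == keys$mode[r] & table$K == keys$K[r] &
      table$T_s == keys$T_s[r]
    bs <- boxplot_stats(table[[outcome]][sel])
    cbind(keys[r, ], data.frame(median = bs$median, iqr = bs$iqr,
                                n_outliers = length(bs$outliers),
                                n = bs$n))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
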