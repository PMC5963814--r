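#' Heatmap of a sweep endpoint over intensity and period
#'
#' Renders the median (or IQR) of an endpoint across replicate networks as
#' a `K` by `T_s` colour map, one panel per protocol mode, mirroring the
#' overview figures of stimulation-parameter studies.  Periods are placed
#' on the axis in decreasing order so stimulation frequency increases to
#' the right.
#'
#' @param table A `"sweep_table"` from [run_sweep()].
#' @param outcome Endpoint column, default `"C_av_off_end"`.
#' @param stat `"median"` or `"iqr"`.
#' @param file Optional PNG path; when given, the plot is written there.
#' @return The plotted matrix (rows `K`, columns `T_s`), invisibly.
#' @export
plot_sweep_heatmap <- function(table, outcome = "C_av_off_end",
                               stat = c("median", "iqr"), file = NULL) {
  stat <- match.arg(stat)
  sm <- sweep_summary(table, outcome)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 420 * length(unique(sm$mode)))
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  modes <- unique(sm$mode)
  graphics::par(mfrow = c(length(modes), 1), mar = c(4, 4, 3, 6))
  out <- list()
  for (md in modes) {
    d <- sm[sm$mode == md, ]
    Ks <- sort(unique(d$K))
    Ts <- sort(unique(d$T_s), decreasing = TRUE)
    z <- matrix(NA_real_, length(Ks), length(Ts),
                dimnames = list(Ks, Ts))
    for (r in seq_len(nrow(d)))
      z[as.character(d$K[r]), as.character(d$T_s[r])] <-
        if (stat == "median") d$median[r] else d$iqr[r]
    graphics::image(seq_along(Ts), seq_along(Ks), t(z),
                    col = grDevices::hcl.colors(64, "viridis"),
                    axes = FALSE, xlab = "T_s (ms)", ylab = "K",
                    main = sprintf("%s of %s (%s)", stat, outcome,
                                   toupper(md)))
    graphics::axis(1, seq_along(Ts), Ts)
    graphics::axis(2, seq_along(Ks), Ks)
    graphics::box()
    out[[md]] <- z
  }
  invisible(if (length(out) == 1) out[[1]] else out)
}

#' Boxplots of a sweep endpoint per period
#'
#' One box per `T_s` value (within one mode and intensity) across the
#' replicate networks, with the interpolated-quartile convention of
#' [boxplot_stats()] and 1.5 IQR whisker fences.
#'
#' @param table A `"sweep_table"`.
#' @param outcome Endpoint column, default `"C_av_off_end"`.
#' @param mode,K Protocol mode and intensity to display (defaults: first
#'   present in the table).
#' @param file Optional PNG path.
#' @return The list of per-period value vectors, invisibly.
#' @export
plot_sweep_boxplots <- function(table, outcome = "C_av_off_end",
                                mode = table$mode[1], K = table$K[1],
                                file = NULL) {
  d <- table[table$mode == mode & table$K == K, ]
  if (!nrow(d)) stop("no records for the requested mode/K")
  Ts <- sort(unique(d$T_s), decreasing = TRUE)
  values <- lapply(Ts, function(ts) d[[outcome]][d$T_s == ts])
  names(values) <- Ts
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 480)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  graphics::boxplot(values, range = 1.5, xlab = "T_s (ms)",
                    ylab = outcome,
                    main = sprintf("%s, K = %.2f (%s)", outcome, K,
                                   toupper(mode)))
  invisible(values)
}
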