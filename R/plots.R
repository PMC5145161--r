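#' Temperature-map diagnostic plot
#'
#' Cluster sizes as a function of temperature for one block's sweep,
#' with the automatically selected (temperature, cluster) pairs
#' marked — the standard diagnostic for judging whether the selection
#' picked up the stable clusters.
#'
#' @param spc a `bs_spc` from [spc_run()].
#' @param trace optional selection trace from [select_clusters()];
#'   selected clusters are drawn as filled points.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the matrix of plotted sizes.
#' @export
plot_temperatures <- function(spc, trace = NULL, ...) {
  n_show <- max(lengths(spc$sizes))
  m <- t(vapply(spc$sizes, function(s) {
    length(s) <- n_show
    s
  }, numeric(n_show)))
  graphics::matplot(spc$temperatures, m, type = "l", lty = 1,
                    log = "y", xlab = "temperature",
                    ylab = "cluster size (spikes)", ...)
  if (!is.null(trace) && nrow(trace))
    graphics::points(trace$temperature, trace$size, pch = 19)
  invisible(m)
}

#' Unit diagnostic panel
#'
#' Standard per-unit quality plots for one merged group: spike-density
#' image of all waveforms, mean waveforms of the member clusters,
#' inter-spike-interval histogram, cumulative spike count over time,
#' and spike maxima over time (drift diagnostic).
#'
#' @param spikes the [spike_set()] that was sorted.
#' @param sorting the matching [sorting_result()].
#' @param group group id to plot.
#' @return invisibly, the indices of the group's spikes.
#' @export
plot_unit <- function(spikes, sorting, group) {
  cl <- sorting$clusters
  ids <- cl$cluster_id[!is.na(cl$group_id) & cl$group_id == group]
  idx <- which(sorting$spikes$cluster_id %in% ids)
  if (!length(idx)) stop("group ", group, " has no spikes")
  wf <- spikes$waveforms[idx, , drop = FALSE]
  tm <- spikes$times[idx]
  k <- ncol(wf)
  t_ms <- (seq_len(k) - 1) / (spikes$rate_eff %||% 24000) * 1000

  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))

  nshow <- min(nrow(wf), 500)
  pick <- round(seq(1, nrow(wf), length.out = nshow))
  graphics::matplot(t_ms, t(wf[pick, , drop = FALSE]), type = "l",
                    lty = 1, col = grDevices::adjustcolor(1, 0.05),
                    xlab = "time (ms)", ylab = "amplitude (uV)",
                    main = sprintf("group %d: %d spikes", group,
                                   length(idx)))
  for (id in ids)
    graphics::lines(t_ms, sorting$templates[id, ], col = 2, lwd = 2)

  isi <- diff(sort(tm))
  isi <- isi[isi < 100]
  if (length(isi))
    graphics::hist(isi, breaks = 50, main = "ISI (< 100 ms)",
                   xlab = "inter-spike interval (ms)")
  else graphics::plot.new()

  graphics::plot(sort(tm) / 60000, seq_along(tm), type = "s",
                 xlab = "time (min)", ylab = "cumulative spikes",
                 main = "spike count over time")

  graphics::plot(tm / 60000, apply(wf, 1, max), pch = ".",
                 xlab = "time (min)", ylab = "spike maximum (uV)",
                 main = "maxima over time")
  invisible(idx)
}
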