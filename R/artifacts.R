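# Overlapping-bin bookkeeping shared by the rate and concurrency
# criteria. Bins of width `bin` start every `hop` ms, anchored at the
# recording start (t = 0); each event is covered by every bin
# [start, start + bin) containing it.
covering_bins <- function(times, bin, hop) {
  lo <- floor((times - bin) / hop) + 1
  hi <- floor(times / hop)
  lo[lo < 0] <- 0
  Map(seq.int, lo, hi)
}

#' Firing-rate artifact criterion
#'
#' Events are counted in overlapping time bins (500 ms wide, 250 ms
#' hop by default); every event inside a bin whose count exceeds
#' `rate_max_events` is removed. The inequality is strict: a bin with
#' exactly the limit is kept. An event is removed if *any* bin covering
#' it exceeds the limit.
#'
#' @param times sorted event times (ms) of one channel.
#' @param p an [artifact_params()] object.
#' @return logical keep-mask over events.
#' @export
mask_high_rate <- function(times, p = artifact_params()) {
  n <- length(times)
  if (!n) return(logical(0))
  hop <- p$rate_bin - p$rate_overlap
  covers <- covering_bins(times, p$rate_bin, hop)
  all_bins <- unlist(covers)
  counts <- table(all_bins)
  bad <- as.numeric(names(counts))[counts > p$rate_max_events]
  if (!length(bad)) return(rep(TRUE, n))
  !vapply(covers, function(b) any(b %in% bad), logical(1))
}

#' Amplitude artifact criterion
#'
#' Removes every event whose absolute extremum exceeds `amp_limit`
#' (1 mV by default). Strict inequality: an event at exactly the limit
#' is kept.
#'
#' @param waveforms spike waveform matrix (uV), one row per event.
#' @param p an [artifact_params()] object.
#' @return logical keep-mask over events.
#' @export
mask_high_amplitude <- function(waveforms, p = artifact_params()) {
  if (!nrow(waveforms)) return(logical(0))
  apply(abs(waveforms), 1, max) <= p$amp_limit
}

#' Resolve double detections
#'
#' Spike detection imposes no refractory period, so two detections can
#' fall within one extraction window (sinusoidal noise, or two neurons
#' firing with a very short lag). Within every pair of detections
#' closer than `double_window` ms, the waveform with the smaller
#' maximum is discarded. Chains are resolved by a single deterministic
#' left-to-right sweep that compares the current survivor with the next
#' event.
#'
#' @param times sorted event times (ms).
#' @param waveforms aligned waveform matrix (uV), same order.
#' @param p an [artifact_params()] object.
#' @return logical keep-mask over events.
#' @export
resolve_double_detections <- function(times, waveforms,
                                      p = artifact_params()) {
  n <- length(times)
  if (!n) return(logical(0))
  if (nrow(waveforms) != n)
    stop("times and waveforms disagree in length")
  maxima <- apply(waveforms, 1, max)
  keep <- rep(TRUE, n)
  cur <- 1L
  for (i in seq_len(n)[-1]) {
    if (times[i] - times[cur] < p$double_window) {
      if (maxima[i] > maxima[cur]) {
        keep[cur] <- FALSE
        cur <- i
      } else {
        keep[i] <- FALSE
      }
    } else {
      cur <- i
    }
  }
  keep
}

#' Concurrent-event artifact criterion
#'
#' Movement artifacts and electrical noise typically hit many channels
#' at once, whereas an action potential is seen on one channel only.
#' Event times from all channels are partitioned into overlapping bins
#' (3 ms wide, 1.5 ms hop); a bin containing an event on at least
#' `conc_frac` of the channels is excluded, i.e. every event of every
#' channel inside it is removed. The criterion is disabled (all events
#' kept) when fewer than `min_channels_concurrent` channels are
#' supplied, because with few channels the rule would delete genuine
#' coincident firing.
#'
#' @param times_by_channel list of sorted event-time vectors (ms), one
#'   per recording channel.
#' @param p an [artifact_params()] object.
#' @return list of logical keep-masks, one per channel.
#' @export
mask_concurrent <- function(times_by_channel, p = artifact_params()) {
  nch <- length(times_by_channel)
  masks <- lapply(times_by_channel, function(t) rep(TRUE, length(t)))
  if (nch < p$min_channels_concurrent) return(masks)
  hop <- p$conc_bin - p$conc_overlap
  covers <- lapply(times_by_channel, covering_bins,
                   bin = p$conc_bin, hop = hop)
  per_ch_bins <- lapply(covers, function(cv) unique(unlist(cv)))
  counts <- table(unlist(per_ch_bins))
  bad <- as.numeric(names(counts))[counts / nch >= p$conc_frac]
  if (!length(bad)) return(masks)
  for (ci in seq_len(nch))
    masks[[ci]] <- !vapply(covers[[ci]],
                           function(b) any(b %in% bad), logical(1))
  masks
}

#' Pre-sorting artifact rejection
#'
#' Applies the event-level criteria to one channel's spike set: (1)
#' excessive firing rate, (2) amplitude above 1 mV, (3) double
#' detections, and — when event times from all recording channels are
#' supplied — (4) events concurrent on half the channels. Criteria
#' (1)-(3) depend only on the channel itself; (4) is the only
#' cross-channel rule. Every criterion is evaluated on the original
#' event set and the final keep-mask is their conjunction, so surviving
#' spikes keep their original order.
#'
#' @param spikes a [spike_set()].
#' @param times_by_channel optional list of event times for all
#'   recording channels (ms); element `channel_index` must correspond
#'   to `spikes`. When omitted, the concurrency criterion is skipped.
#' @param channel_index index of `spikes`' channel inside
#'   `times_by_channel`.
#' @param p an [artifact_params()] object.
#' @return a list with elements `spikes` (the cleaned [spike_set()])
#'   and `report` (a `bs_rejection` with per-criterion masks and
#'   counts).
#' @export
reject_artifacts <- function(spikes, times_by_channel = NULL,
                             channel_index = 1,
                             p = artifact_params()) {
  n <- n_spikes(spikes)
  masks <- list(
    rate = mask_high_rate(spikes$times, p),
    amplitude = mask_high_amplitude(spikes$waveforms, p),
    double = resolve_double_detections(spikes$times, spikes$waveforms,
                                       p))
  if (!is.null(times_by_channel)) {
    conc <- mask_concurrent(times_by_channel, p)[[channel_index]]
    if (length(conc) != n)
      stop("times_by_channel[[channel_index]] does not match spikes")
    masks$concurrent <- conc
  }
  keep <- Reduce(`&`, masks, rep(TRUE, n))
  report <- structure(
    list(masks = masks, keep = keep, n = n,
         removed = vapply(masks, function(m) sum(!m), integer(1)),
         removed_total = sum(!keep),
         fraction_removed = if (n) sum(!keep) / n else 0),
    class = "bs_rejection")
  list(spikes = subset_spikes(spikes, keep), report = report)
}

#' @export
print.bs_rejection <- function(x, ...) {
  cat(sprintf("<bs_rejection> %d events, %d removed (%.2f%%)\n",
              x$n, x$removed_total, 100 * x$fraction_removed))
  for (nm in names(x$removed))
    cat(sprintf("  %-10s %6d (%.2f%%)\n", nm, x$removed[nm],
                if (x$n) 100 * x$removed[nm] / x$n else 0))
  invisible(x)
}

# Strict interior local maxima of a vector: sign change of the first
# difference from positive to negative. Optional moving-average
# smoothing of width w.
local_maxima <- function(m, w = 0) {
  if (w > 1) {
    kern <- rep(1 / w, w)
    m <- as.numeric(stats::filter(m, kern, sides = 2))
    m[is.na(m)] <- 0
  }
  d <- diff(m)
  idx <- which(d[-length(d)] > 0 & d[-1] < 0) + 1L
  list(idx = idx, height = m[idx])
}

#' Post-sorting artifact criteria for one cluster
#'
#' Flags a cluster as non-neural if any of the following holds for its
#' mean waveform: (a) more than `max_local_maxima` local maxima (e.g.
#' sinusoidal electrical noise); (b) the ratio of the largest to the
#' second-largest local maximum is below `peak_ratio_min`, counting
#' only maxima separated by at least `peak_sep` ms; (c) the amplitude
#' range covered in the second half of the mean waveform exceeds the
#' global maximum; or (d) the per-sample standard error of the mean,
#' averaged over samples, exceeds `sem_limit` uV. For a single-spike
#' cluster the SEM is undefined and criterion (d) is skipped with a
#' warning.
#'
#' @param cluster_waveforms waveform matrix (uV) of the cluster's
#'   spikes.
#' @param rate_eff waveform sampling rate (Hz), needed to convert
#'   `peak_sep` into samples.
#' @param p an [artifact_params()] object.
#' @return list with `artifact` (logical) and `criteria` (character
#'   vector naming the fired criteria among `"n_maxima"`,
#'   `"peak_ratio"`, `"tail_range"`, `"sem"`).
#' @export
flag_artifact_cluster <- function(cluster_waveforms, rate_eff,
                                  p = artifact_params()) {
  wf <- as.matrix(cluster_waveforms)
  if (!nrow(wf)) stop("cluster must contain at least one waveform")
  m <- colMeans(wf)
  k <- length(m)
  fired <- character(0)

  lm <- local_maxima(m, p$smooth_w)
  if (length(lm$idx) > p$max_local_maxima)
    fired <- c(fired, "n_maxima")

  sep_samp <- p$peak_sep * rate_eff / 1000
  if (length(lm$idx) >= 2L) {
    ord <- order(lm$height, decreasing = TRUE)
    kept <- integer(0)
    for (i in ord)
      if (!length(kept) ||
          all(abs(lm$idx[i] - lm$idx[kept]) >= sep_samp))
        kept <- c(kept, i)
    if (length(kept) >= 2L) {
      h <- sort(lm$height[kept], decreasing = TRUE)
      if (h[2] > 0 && h[1] / h[2] < p$peak_ratio_min)
        fired <- c(fired, "peak_ratio")
    }
  }

  second <- m[(floor(k / 2) + 1L):k]
  if (max(second) - min(second) > max(m))
    fired <- c(fired, "tail_range")

  if (nrow(wf) >= 2L) {
    sem <- apply(wf, 2, sd) / sqrt(nrow(wf))
    if (mean(sem) > p$sem_limit) fired <- c(fired, "sem")
  } else {
    warning("single-spike cluster: SEM criterion skipped")
  }

  list(artifact = length(fired) > 0, criteria = fired)
}
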