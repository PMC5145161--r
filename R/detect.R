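#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (zero phase, so spike shapes are not skewed) to every channel.
#'
#' @param rec a `bs_recording`.
#' @param band passband in Hz; must lie strictly inside the Nyquist
#'   interval.
#' @param order filter order (of the analogue prototype; the effective
#'   order doubles under forward-backward filtering).
#' @return the filtered `bs_recording`, same length and rate.
#' @export
bandpass_filter <- function(rec, band = c(300, 1000), order = 4) {
  band <- as.numeric(band)
  nyq <- rec$rate / 2
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= nyq)
    stop("passband must satisfy 0 < low < high < rate/2 (Nyquist ",
         nyq, " Hz)")
  bf <- signal::butter(order, band / nyq, type = "pass")
  rec$samples <- lapply(rec$samples, function(x)
    as.numeric(signal::filtfilt(bf, x)))
  rec
}

#' Robust noise scale
#'
#' The standard robust estimate of the noise standard deviation,
#' `median(|x|) / 0.6745`, insensitive to the spikes riding on the
#' noise.
#'
#' @param x numeric vector (a filtered trace).
#' @return estimated noise SD in the units of `x`.
#' @export
noise_scale <- function(x) median(abs(x)) / 0.6745

#' Detect spikes by amplitude threshold
#'
#' Detects threshold crossings of the filtered trace and returns, per
#' channel, the times of the sign-appropriate local extrema following
#' each crossing. The threshold is `thr_mult` times the robust noise
#' scale, estimated per channel. No artificial refractory period is
#' imposed: overlapping detections are left for the artifact-rejection
#' stage to resolve.
#'
#' @param filtered a band-pass filtered `bs_recording`.
#' @param params a [detect_params()] object.
#' @return a list, one element per channel, each a data frame with
#'   columns `time` (ms from recording start), `sign` (`"positive"` or
#'   `"negative"`) and `sample` (1-based peak sample index). The
#'   per-channel thresholds are attached as attribute `"thresholds"`.
#' @export
detect_spikes <- function(filtered, params = detect_params()) {
  win <- max(1L, round(params$window_ms * filtered$rate / 1000))
  signs <- switch(params$sign, both = c("positive", "negative"),
                  positive = "positive", negative = "negative")
  thresholds <- numeric(length(filtered$samples))
  out <- vector("list", length(filtered$samples))
  for (ci in seq_along(filtered$samples)) {
    x <- filtered$samples[[ci]]
    thr <- params$thr_mult * noise_scale(x)
    thresholds[ci] <- thr
    res <- list()
    for (sg in signs) {
      y <- if (sg == "positive") x else -x
      pk <- find_peaks_above(y, thr, win)
      if (length(pk))
        res[[sg]] <- data.frame(time = (pk - 1) / filtered$rate * 1000,
                                sign = sg, sample = pk)
    }
    ev <- if (length(res)) do.call(rbind, res) else
      data.frame(time = numeric(0), sign = character(0),
                 sample = integer(0))
    ev <- ev[order(ev$time), , drop = FALSE]
    rownames(ev) <- NULL
    out[[ci]] <- ev
  }
  names(out) <- filtered$channel_ids
  attr(out, "thresholds") <- thresholds
  out
}

# Peak sample index for every upward crossing of `thr` in y: the
# largest value within `win` samples after the crossing.
find_peaks_above <- function(y, thr, win) {
  n <- length(y)
  if (n < 2L) return(integer(0))
  up <- which(y[-1] >= thr & y[-n] < thr) + 1L
  if (!length(up)) return(integer(0))
  pk <- vapply(up, function(i) {
    j <- min(n, i + win - 1L)
    i - 1L + which.max(y[i:j])
  }, integer(1))
  unique(pk)
}

#' Extract and align spike waveforms
#'
#' Cuts a window of `round(window_ms * rate / 1000)` samples around
#' every event, with `pre_frac` of the window before the peak, and
#' aligns each waveform so the peak sits exactly at the alignment
#' index: the segment is upsampled by cubic-spline interpolation,
#' re-centred on the interpolated extremum, and decimated back to the
#' original rate. Events too close to the recording edges are dropped;
#' the dropped count is attached as attribute `"dropped"`.
#'
#' Negative-polarity events are sign-flipped before alignment so that
#' all downstream stages see positive peaks.
#'
#' @param filtered a band-pass filtered `bs_recording`.
#' @param times event times in ms (one polarity stream), as returned by
#'   [detect_spikes()].
#' @param params a [detect_params()] object.
#' @param channel channel index to extract from.
#' @param sign polarity of the stream being extracted.
#' @return a [spike_set()] (attribute `"dropped"` holds the number of
#'   edge-dropped events).
#' @export
extract_align <- function(filtered, times, params = detect_params(),
                          channel = 1, sign = "positive") {
  x <- filtered$samples[[channel]]
  if (sign == "negative") x <- -x
  rate <- filtered$rate
  k <- max(2L, round(params$window_ms * rate / 1000))
  pre <- max(1L, round(params$pre_frac * k))
  u <- params$upsample
  margin <- 3L
  n <- length(x)
  peaks <- round(times * rate / 1000) + 1L
  lo <- peaks - (pre - 1L) - margin
  hi <- peaks + (k - pre) + margin
  ok <- lo >= 1L & hi <= n
  dropped <- sum(!ok)
  peaks <- peaks[ok]
  wf <- matrix(numeric(0), 0L, k)
  kept_times <- numeric(0)
  if (length(peaks)) {
    wf <- t(vapply(peaks, function(p) {
      seg <- x[(p - pre + 1L - margin):(p + k - pre + margin)]
      m <- length(seg)
      if (u > 1L) {
        su <- spline(seq_len(m), seg, n = (m - 1L) * u + 1L)$y
        ctr <- (margin + pre - 1L) * u + 1L
        rng <- max(1L, ctr - margin * u):min(length(su), ctr + margin * u)
        pk_u <- rng[which.max(su[rng])]
        idx <- pk_u + (seq_len(k) - pre) * u
        if (idx[1] < 1L || idx[k] > length(su))
          idx <- ctr + (seq_len(k) - pre) * u
        su[idx]
      } else {
        rng <- max(1L, margin + pre - margin):min(m, margin + pre + margin)
        pk <- rng[which.max(seg[rng])]
        if (pk - pre + 1L < 1L || pk + k - pre > m) pk <- margin + pre
        seg[(pk - pre + 1L):(pk + k - pre)]
      }
    }, numeric(k)))
    kept_times <- (peaks - 1L) / rate * 1000
  }
  out <- spike_set(wf, kept_times,
                   channel_id = filtered$channel_ids[channel],
                   rate_eff = rate, sign = sign)
  attr(out, "dropped") <- dropped
  out
}

#' Detect and extract one channel
#'
#' Convenience wrapper: band-pass filter, detect, and extract aligned
#' waveforms for every polarity stream of one channel.
#'
#' @param rec a raw `bs_recording`.
#' @param channel channel index.
#' @param params a [detect_params()] object.
#' @param filtered set to `TRUE` if `rec` is already band-pass
#'   filtered.
#' @return a named list of [spike_set()]s, one per polarity stream
#'   (`"positive"`, `"negative"`).
#' @export
extract_channel <- function(rec, channel = 1, params = detect_params(),
                            filtered = FALSE) {
  if (!filtered) rec <- bandpass_filter(rec, params$band)
  ev <- detect_spikes(rec, params)[[channel]]
  out <- list()
  for (sg in unique(ev$sign)) {
    tms <- ev$time[ev$sign == sg]
    out[[sg]] <- extract_align(rec, tms, params, channel = channel,
                               sign = sg)
  }
  out
}
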