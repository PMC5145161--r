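# One-to-one matching of sorted spike times to ground-truth spike
# times: walking both in time order, each sorted spike takes the
# nearest still-unmatched truth spike within tol_ms (earlier spike
# wins ties). Returns the truth row index per sorted spike (NA when
# unmatched).
match_times <- function(sorted_times, truth_times, tol_ms = 0.5) {
  ns <- length(sorted_times)
  nt <- length(truth_times)
  out <- rep(NA_integer_, ns)
  if (!ns || !nt) return(out)
  ord <- order(sorted_times)
  taken <- logical(nt)
  j <- 1L
  for (oi in ord) {
    t <- sorted_times[oi]
    while (j <= nt && (taken[j] || truth_times[j] < t - tol_ms))
      j <- j + 1L
    best <- NA_integer_
    bd <- tol_ms
    jj <- j
    while (jj <= nt && truth_times[jj] <= t + tol_ms) {
      if (!taken[jj]) {
        d <- abs(truth_times[jj] - t)
        if (d < bd || (d == bd && is.na(best))) {
          bd <- d
          best <- jj
        }
      }
      jj <- jj + 1L
    }
    if (!is.na(best)) {
      taken[best] <- TRUE
      out[oi] <- best
    }
  }
  out
}

#' Score sorted units against ground truth
#'
#' Matches sorted spikes to ground-truth spikes by time (one-to-one,
#' nearest neighbour within `tol_ms`) and evaluates every sorted unit
#' (merged group) against its plurality neuron: *purity* is the
#' fraction of the unit's spikes coming from that neuron,
#' *completeness* the fraction of that neuron's spikes captured by the
#' unit. A unit is a *hit* when both reach at least 50%.
#'
#' @param sorting a [sorting_result()].
#' @param truth a `bs_ground_truth` from [make_dataset()].
#' @param tol_ms time-matching tolerance (ms).
#' @param by `"group"` (default: merged groups are the units) or
#'   `"cluster"` (each cluster is a unit).
#' @return an object of class `bs_hit_report`: list with `units` (data
#'   frame: unit id, size, matched neuron, purity, completeness, hit)
#'   and `summary` (`n_hits`, `n_neurons`, `hit_fraction`).
#' @export
score_hits <- function(sorting, truth, tol_ms = 0.5,
                       by = c("group", "cluster")) {
  by <- match.arg(by)
  sp <- sorting$spikes
  cl <- sorting$clusters
  if (by == "group") {
    map <- cl$group_id[match(sp$cluster_id, cl$cluster_id)]
    unit <- ifelse(sp$cluster_id == 0, NA_integer_, map)
  } else {
    unit <- ifelse(sp$cluster_id == 0, NA_integer_, sp$cluster_id)
  }
  matched <- match_times(sp$time, truth$spikes$time, tol_ms)
  neuron <- truth$spikes$neuron[matched]       # NA when unmatched
  neuron_totals <- if (nrow(truth$spikes))
    table(truth$spikes$neuron) else table(integer(0))

  units <- sort(unique(unit[!is.na(unit)]))
  rows <- lapply(units, function(u) {
    in_u <- which(!is.na(unit) & unit == u)
    nu <- neuron[in_u]
    size <- length(in_u)
    tab <- table(nu[!is.na(nu)])
    if (!length(tab))
      return(data.frame(unit = u, size = size,
                        neuron = NA_integer_, purity = 0,
                        completeness = 0, hit = FALSE))
    best <- names(tab)[which.max(tab)]
    n_best <- max(tab)
    total <- as.integer(neuron_totals[best])
    purity <- n_best / size
    completeness <- n_best / total
    data.frame(unit = u, size = size, neuron = as.integer(best),
               purity = purity, completeness = completeness,
               hit = purity >= 0.5 && completeness >= 0.5)
  })
  units_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit = integer(0), size = integer(0),
               neuron = integer(0), purity = numeric(0),
               completeness = numeric(0), hit = logical(0))
  n_hits <- sum(units_df$hit)
  n_neurons <- truth$n_neurons
  structure(list(units = units_df,
                 summary = list(n_hits = n_hits,
                                n_neurons = n_neurons,
                                hit_fraction = if (n_neurons)
                                  n_hits / n_neurons else NA_real_)),
            class = "bs_hit_report")
}

#' @export
print.bs_hit_report <- function(x, ...) {
  cat(sprintf("<bs_hit_report> %d unit(s), %d hit(s) of %d neuron(s)",
              nrow(x$units), x$summary$n_hits, x$summary$n_neurons))
  if (!is.na(x$summary$hit_fraction))
    cat(sprintf(" (%.1f%%)", 100 * x$summary$hit_fraction))
  cat("\n")
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate,
#' returned in the original order. Values outside `[0, 1]` are an
#' error.
#'
#' @param pvalues numeric vector of p-values.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Stimulus-response score
#'
#' The screening-analysis score for one (unit, stimulus) pair: spike
#' counts of every presentation are computed in `n_bins` overlapping
#' post-onset bins (100 ms wide, 50 ms hop, covering the 1 s
#' stimulus-on period); each bin's counts are compared with the
#' baseline count distribution (all pre-onset intervals of the session,
#' tiled into bins of the same width) by a one-sided Mann-Whitney U
#' test; the resulting p-values are Benjamini-Hochberg adjusted and the
#' score is their minimum. The pair is a *response* when the score is
#' below `alpha` *and* the unit fired during at least
#' `min_presentations` presentation windows.
#'
#' @param spike_times spike times of the unit (ms).
#' @param stim_onsets onset times (ms) of the presentations of this
#'   stimulus.
#' @param rp a [response_params()] object.
#' @param baseline_onsets onset times of *all* presentations in the
#'   session, used for the pooled baseline; defaults to `stim_onsets`.
#' @return list with `score` (minimum adjusted p-value), `is_response`,
#'   `n_fired` (presentations with at least one spike in the 1 s
#'   window), `p_adj` and `p_raw` (per-bin values).
#' @export
response_score <- function(spike_times, stim_onsets,
                           rp = response_params(),
                           baseline_onsets = NULL) {
  if (!length(stim_onsets)) stop("need at least one stimulus onset")
  if (is.null(baseline_onsets)) baseline_onsets <- stim_onsets
  spike_times <- sort(spike_times)
  count_in <- function(lo, hi)
    sum(spike_times >= lo & spike_times < hi)

  n_base_sub <- floor(rp$baseline_ms / rp$bin_ms)
  baseline <- as.numeric(vapply(baseline_onsets, function(on)
    vapply(seq_len(n_base_sub), function(b)
      count_in(on - rp$baseline_ms + (b - 1) * rp$bin_ms,
               on - rp$baseline_ms + b * rp$bin_ms), numeric(1)),
    numeric(n_base_sub)))

  window_ms <- rp$hop_ms * (rp$n_bins - 1) + rp$bin_ms
  p_raw <- vapply(seq_len(rp$n_bins), function(b) {
    starts <- stim_onsets + (b - 1) * rp$hop_ms
    counts <- vapply(starts, function(s)
      count_in(s, s + rp$bin_ms), numeric(1))
    if (all(counts == 0) && all(baseline == 0)) return(1)
    suppressWarnings(
      wilcox.test(counts, baseline, alternative = "greater",
                  exact = FALSE)$p.value)
  }, numeric(1))
  p_adj <- bh_adjust(p_raw)
  score <- min(p_adj)
  n_fired <- sum(vapply(stim_onsets, function(on)
    count_in(on, on + window_ms) > 0, logical(1)))
  list(score = score,
       is_response = score < rp$alpha &&
         n_fired >= rp$min_presentations,
       n_fired = n_fired, p_adj = p_adj, p_raw = p_raw)
}
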