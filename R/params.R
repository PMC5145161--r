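#' Sorting parameters
#'
#' Parameters controlling block segmentation, multi-temperature cluster
#' selection, iterative re-clustering, template matching and cluster
#' merging. Defaults are the framework's standard values.
#'
#' @param N_block number of spikes per sorting block.
#' @param C_max maximum number of clusters selected at one temperature.
#' @param S_min minimum number of spikes in a cluster. Values < 1 are
#'   interpreted as a fraction of the block size.
#' @param R_min minimum cluster size for iterative re-clustering
#'   (splitting of large clusters).
#' @param N_rep number of clustering iterations per block.
#' @param f1 radius for within-block template matching, in units of a
#'   cluster's variability measure `s`.
#' @param f2 radius for across-block template matching (same units).
#' @param C_stop threshold at which hierarchical merging of clusters
#'   stops (normalized mean-waveform distance).
#' @param n_T number of temperatures for the superparamagnetic sweep.
#' @param T_range temperature interval, swept with `n_T` equally spaced
#'   values.
#' @param merge_metric `"normalized"` (Euclidean distance between group
#'   means divided by the pooled variability `s`) or `"raw"` (plain
#'   Euclidean distance in microvolts).
#'
#' @return An object of class `bs_sort_params` (a validated list).
#' @export
sort_params <- function(N_block = 20000, C_max = 5, S_min = 15,
                        R_min = 2000, N_rep = 1, f1 = 0.75, f2 = 3,
                        C_stop = 1.8, n_T = 21, T_range = c(0, 0.2),
                        merge_metric = c("normalized", "raw")) {
  merge_metric <- match.arg(merge_metric)
  p <- list(N_block = N_block, C_max = C_max, S_min = S_min,
            R_min = R_min, N_rep = N_rep, f1 = f1, f2 = f2,
            C_stop = C_stop, n_T = n_T, T_range = as.numeric(T_range),
            merge_metric = merge_metric)
  stopifnot(N_block >= 1, C_max >= 1, S_min > 0, R_min >= 1,
            N_rep >= 1, f1 > 0, f2 > 0, C_stop > 0, n_T >= 3,
            length(p$T_range) == 2L, p$T_range[1] >= 0,
            p$T_range[2] > p$T_range[1])
  structure(p, class = "bs_sort_params")
}

#' Artifact-rejection parameters
#'
#' Thresholds for the four pre-sorting event-level criteria (firing
#' rate, amplitude, double detection, concurrency) and the post-sorting
#' cluster-level criteria. All times are in milliseconds, voltages in
#' microvolts.
#'
#' @param rate_bin width of firing-rate bins (ms).
#' @param rate_overlap overlap of consecutive rate bins (ms); the hop is
#'   `rate_bin - rate_overlap`.
#' @param rate_max_events events allowed per rate bin; bins with *more*
#'   events are excluded.
#' @param amp_limit absolute amplitude limit (uV); events exceeding it
#'   are excluded.
#' @param double_window two detections closer than this (ms) count as a
#'   double detection; the one with the smaller maximum is dropped.
#' @param conc_bin,conc_overlap bin width and overlap (ms) for the
#'   cross-channel concurrency criterion.
#' @param conc_frac a concurrency bin is excluded when at least this
#'   fraction of channels contains an event in it.
#' @param min_channels_concurrent the concurrency criterion is disabled
#'   when fewer channels than this are available (with few channels the
#'   rule would delete genuine coincident firing).
#' @param max_local_maxima a mean waveform with more local maxima than
#'   this flags the cluster as an artifact.
#' @param peak_ratio_min minimum ratio of largest to second-largest
#'   local maximum of the mean waveform (maxima closer than `peak_sep`
#'   ms are not counted separately).
#' @param peak_sep minimum separation (ms) between local maxima counted
#'   for the peak-ratio criterion.
#' @param sem_limit a cluster whose per-sample standard error of the
#'   mean averages more than this (uV) is flagged as an artifact.
#' @param smooth_w width (samples) of a moving-average smoother applied
#'   to the mean waveform before counting local maxima; 0 disables
#'   smoothing.
#'
#' @return An object of class `bs_artifact_params`.
#' @export
artifact_params <- function(rate_bin = 500, rate_overlap = 250,
                            rate_max_events = 100, amp_limit = 1000,
                            double_window = 1.5, conc_bin = 3,
                            conc_overlap = 1.5, conc_frac = 0.5,
                            min_channels_concurrent = 10,
                            max_local_maxima = 5, peak_ratio_min = 2,
                            peak_sep = 0.3, sem_limit = 2,
                            smooth_w = 0) {
  stopifnot(rate_bin > 0, rate_overlap >= 0, rate_overlap < rate_bin,
            rate_max_events > 0, amp_limit > 0, double_window > 0,
            conc_bin > 0, conc_overlap >= 0, conc_overlap < conc_bin,
            conc_frac > 0, conc_frac <= 1, max_local_maxima >= 1,
            peak_ratio_min > 0, peak_sep >= 0, sem_limit > 0,
            smooth_w >= 0)
  structure(list(rate_bin = rate_bin, rate_overlap = rate_overlap,
                 rate_max_events = rate_max_events,
                 amp_limit = amp_limit, double_window = double_window,
                 conc_bin = conc_bin, conc_overlap = conc_overlap,
                 conc_frac = conc_frac,
                 min_channels_concurrent = min_channels_concurrent,
                 max_local_maxima = max_local_maxima,
                 peak_ratio_min = peak_ratio_min, peak_sep = peak_sep,
                 sem_limit = sem_limit, smooth_w = smooth_w),
            class = "bs_artifact_params")
}

#' Spike detection and extraction parameters
#'
#' @param band passband of the zero-phase Butterworth band-pass filter
#'   (Hz).
#' @param thr_mult detection threshold in units of the robust noise
#'   scale `median(|x|)/0.6745`.
#' @param window_ms extraction window length (ms).
#' @param pre_frac fraction of the window placed before the aligned
#'   peak.
#' @param upsample interpolation factor used for sub-sample peak
#'   alignment.
#' @param sign polarity of detection: `"positive"`, `"negative"` or
#'   `"both"` (positive and negative events are extracted as separate
#'   streams; negative streams are sign-flipped so downstream stages
#'   always see positive peaks).
#'
#' @return An object of class `bs_detect_params`.
#' @export
detect_params <- function(band = c(300, 1000), thr_mult = 5,
                          window_ms = 2, pre_frac = 0.25, upsample = 3,
                          sign = c("both", "positive", "negative")) {
  sign <- match.arg(sign)
  band <- as.numeric(band)
  stopifnot(length(band) == 2L, band[1] > 0, band[2] > band[1],
            thr_mult > 0, window_ms > 0, pre_frac > 0, pre_frac < 1,
            upsample >= 1)
  structure(list(band = band, thr_mult = thr_mult,
                 window_ms = window_ms, pre_frac = pre_frac,
                 upsample = as.integer(upsample), sign = sign),
            class = "bs_detect_params")
}

#' Superparamagnetic clustering hyper-parameters
#'
#' Internals of the Potts-model Swendsen-Wang simulation. The
#' temperature grid itself lives in [sort_params()] (`n_T`, `T_range`).
#'
#' @param q number of Potts spin states.
#' @param k_nn number of nearest neighbours in the interaction graph
#'   (the graph is the union of all k-nearest-neighbour links and a
#'   minimum spanning tree, so it is always connected).
#' @param sweeps Monte-Carlo sweeps per temperature used for the
#'   correlation estimate.
#' @param burnin additional sweeps discarded before measuring.
#' @param corr_thresh spin-spin correlation above which two neighbouring
#'   points are linked into the same cluster.
#' @param seed integer seed for the (self-contained) simulation RNG.
#'
#' @return An object of class `bs_spc_hyper`.
#' @export
spc_hyper <- function(q = 20, k_nn = 11, sweeps = 300, burnin = 100,
                      corr_thresh = 0.5, seed = 42) {
  stopifnot(q >= 2, k_nn >= 1, sweeps >= 1, burnin >= 0,
            corr_thresh > 0, corr_thresh < 1)
  structure(list(q = as.integer(q), k_nn = as.integer(k_nn),
                 sweeps = as.integer(sweeps),
                 burnin = as.integer(burnin),
                 corr_thresh = corr_thresh, seed = as.integer(seed)),
            class = "bs_spc_hyper")
}

#' Response-score parameters
#'
#' Parameters of the stimulus-response score used to identify
#' responsive units in picture-presentation screening sessions.
#'
#' @param n_bins number of overlapping post-onset bins.
#' @param bin_ms bin duration (ms).
#' @param hop_ms hop between bin onsets (ms); the default gives 50%
#'   overlap.
#' @param baseline_ms length of the pre-onset baseline interval (ms),
#'   tiled into `bin_ms` sub-bins for the baseline count distribution.
#' @param alpha significance level on the adjusted score.
#' @param min_presentations a unit must fire during at least this many
#'   presentation windows to count as responsive.
#' @param n_reps presentations per stimulus.
#'
#' @return An object of class `bs_response_params`.
#' @export
response_params <- function(n_bins = 19, bin_ms = 100, hop_ms = 50,
                            baseline_ms = 500, alpha = 0.001,
                            min_presentations = 4, n_reps = 6) {
  stopifnot(n_bins >= 1, bin_ms > 0, hop_ms > 0, baseline_ms >= bin_ms,
            alpha > 0, alpha < 1, min_presentations >= 1, n_reps >= 1)
  structure(list(n_bins = as.integer(n_bins), bin_ms = bin_ms,
                 hop_ms = hop_ms, baseline_ms = baseline_ms,
                 alpha = alpha,
                 min_presentations = as.integer(min_presentations),
                 n_reps = as.integer(n_reps)),
            class = "bs_response_params")
}

#' Read a declarative configuration file
#'
#' A single YAML file mirrors the parameter constructors: top-level
#' sections `sort`, `artifact`, `detect`, `spc`, `response`, each
#' holding fields named exactly as the corresponding constructor
#' arguments. Unknown sections or keys are an error, never silently
#' ignored.
#'
#' @param path path to a YAML configuration file.
#' @return A named list of parameter objects (`sort`, `artifact`,
#'   `detect`, `spc`, `response`), defaults filled in for absent
#'   sections.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  ctors <- list(sort = sort_params, artifact = artifact_params,
                detect = detect_params, spc = spc_hyper,
                response = response_params)
  unknown <- setdiff(names(cfg), names(ctors))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  out <- list()
  for (sec in names(ctors)) {
    fields <- if (is.null(cfg[[sec]])) list() else cfg[[sec]]
    bad <- setdiff(names(fields), names(formals(ctors[[sec]])))
    if (length(bad))
      stop("unknown key(s) in config section '", sec, "': ",
           paste(bad, collapse = ", "))
    out[[sec]] <- do.call(ctors[[sec]], fields)
  }
  out
}
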