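#' Construct a spike set
#'
#' A spike set is the unit of data passed between extraction, artifact
#' rejection and sorting: a matrix of extracted waveforms together with
#' the event times.
#'
#' @param waveforms numeric matrix, one row per spike, `k` samples per
#'   row, in microvolts. Negative-polarity streams are stored
#'   sign-flipped so that every waveform has a positive peak.
#' @param times event times in milliseconds from recording start,
#'   monotonically non-decreasing.
#' @param channel_id label of the source channel.
#' @param rate_eff sampling rate of the waveforms (Hz) after any
#'   resampling.
#' @param sign detection polarity of the stream, `"positive"` or
#'   `"negative"`.
#'
#' @return An object of class `bs_spikes`.
#' @export
spike_set <- function(waveforms, times, channel_id = "ch1",
                      rate_eff = NULL, sign = "positive") {
  waveforms <- as.matrix(waveforms)
  times <- as.numeric(times)
  if (nrow(waveforms) != length(times))
    stop("waveform row count (", nrow(waveforms),
         ") does not equal number of times (", length(times), ")")
  if (is.unsorted(times)) stop("times must be non-decreasing")
  if (!sign %in% c("positive", "negative"))
    stop("sign must be 'positive' or 'negative'")
  structure(list(waveforms = waveforms, times = times,
                 channel_id = as.character(channel_id),
                 rate_eff = rate_eff, sign = sign),
            class = "bs_spikes")
}

#' @export
print.bs_spikes <- function(x, ...) {
  cat(sprintf("<bs_spikes> %d spikes x %d samples, channel %s (%s)\n",
              nrow(x$waveforms), ncol(x$waveforms), x$channel_id,
              x$sign))
  invisible(x)
}

#' Number of spikes in a spike set
#' @param spikes a `bs_spikes`.
#' @return integer spike count.
#' @export
n_spikes <- function(spikes) nrow(spikes$waveforms)

#' Subset a spike set
#' @param spikes a `bs_spikes`.
#' @param idx integer or logical index over spikes.
#' @return the subset `bs_spikes`.
#' @export
subset_spikes <- function(spikes, idx) {
  spike_set(spikes$waveforms[idx, , drop = FALSE], spikes$times[idx],
            channel_id = spikes$channel_id, rate_eff = spikes$rate_eff,
            sign = spikes$sign)
}

#' Write / read a spike-set container
#'
#' Directory container: `waveforms.csv` (one row per spike),
#' `times.csv` and a `meta.json` sidecar. The round trip is lossless up
#' to double-precision text representation.
#'
#' @param spikes a `bs_spikes`.
#' @param path container directory.
#' @return `path` invisibly for the writer; a `bs_spikes` for the
#'   reader.
#' @export
write_spikes <- function(spikes, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(data.table::as.data.table(spikes$waveforms),
                     file.path(path, "waveforms.csv"))
  data.table::fwrite(data.table::data.table(time = spikes$times),
                     file.path(path, "times.csv"))
  meta <- list(container = "bs_spikes", version = 1L,
               channel_id = spikes$channel_id,
               rate_eff = spikes$rate_eff, sign = spikes$sign,
               n = n_spikes(spikes), k = ncol(spikes$waveforms))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path))
    stop("not a spike container (missing meta.json): ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$container, "bs_spikes"))
    stop("unknown container format: ", meta$container)
  wf <- as.matrix(data.table::fread(file.path(path, "waveforms.csv")))
  dimnames(wf) <- NULL
  if (meta$n == 0L)
    wf <- matrix(numeric(0), 0L, meta$k)
  tm <- data.table::fread(file.path(path, "times.csv"))$time
  if (is.null(tm)) tm <- numeric(0)
  spike_set(wf, tm, channel_id = meta$channel_id,
            rate_eff = meta$rate_eff, sign = meta$sign)
}

sorting_spike_cols <- c("time", "cluster_id", "original_cluster_id",
                        "block_index", "assign_stage")
sorting_cluster_cols <- c("cluster_id", "block_index", "size",
                          "artifact", "criteria", "group_id")

#' Construct a sorting result
#'
#' Holds the per-spike assignment (cluster id 0 is the residual
#' cluster), the per-cluster table (artifact flags and merged group
#' ids) and the cluster template waveforms. Merging never overwrites
#' `original_cluster_id`, so any grouping can be undone exactly.
#'
#' @param spikes data frame with columns `time`, `cluster_id`,
#'   `original_cluster_id`, `block_index`, `assign_stage`.
#' @param clusters data frame with columns `cluster_id`, `block_index`,
#'   `size`, `artifact`, `criteria`, `group_id`.
#' @param templates numeric matrix of cluster mean waveforms, one row
#'   per cluster in `clusters` order (may have zero rows).
#' @param channel_id source channel label.
#' @param rate_eff waveform sampling rate (Hz), used by diagnostics.
#'
#' @return An object of class `bs_sorting`.
#' @export
sorting_result <- function(spikes, clusters, templates = NULL,
                           channel_id = "ch1", rate_eff = NULL) {
  spikes <- as.data.frame(spikes)
  clusters <- as.data.frame(clusters)
  miss <- setdiff(sorting_spike_cols, names(spikes))
  if (length(miss))
    stop("sorting spike table missing column(s): ",
         paste(miss, collapse = ", "))
  miss <- setdiff(sorting_cluster_cols, names(clusters))
  if (length(miss))
    stop("sorting cluster table missing column(s): ",
         paste(miss, collapse = ", "))
  stages <- c("SPC", "TM_within", "TM_across", "residual")
  if (!all(spikes$assign_stage %in% stages))
    stop("invalid assign_stage value(s)")
  if (any(spikes$cluster_id != 0 &
          !spikes$cluster_id %in% clusters$cluster_id))
    stop("spike assigned to a cluster absent from the cluster table")
  if (is.null(templates))
    templates <- matrix(numeric(0), 0L, 0L)
  structure(list(spikes = spikes, clusters = clusters,
                 templates = as.matrix(templates),
                 channel_id = as.character(channel_id),
                 rate_eff = rate_eff),
            class = "bs_sorting")
}

#' @export
print.bs_sorting <- function(x, ...) {
  n <- nrow(x$spikes)
  resid <- sum(x$spikes$cluster_id == 0)
  na <- sum(!x$clusters$artifact)
  cat(sprintf(paste0(
    "<bs_sorting> channel %s: %d spikes, %d clusters",
    " (%d non-artifact, %d groups), %d residual (%.1f%%)\n"),
    x$channel_id, n, nrow(x$clusters), na,
    length(unique(stats::na.omit(x$clusters$group_id))), resid,
    if (n) 100 * resid / n else 0))
  invisible(x)
}

#' Write / read a sorting container
#'
#' Directory container with `spikes.csv`, `clusters.csv`,
#' `templates.csv` and a `meta.json` sidecar. Reading validates the
#' schema: a container missing a required column (for example
#' `assign_stage`) is an error, never silently defaulted.
#'
#' @param sorting a `bs_sorting`.
#' @param path container directory.
#' @return `path` invisibly for the writer; a `bs_sorting` for the
#'   reader.
#' @export
write_sorting <- function(sorting, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(sorting$spikes, file.path(path, "spikes.csv"))
  data.table::fwrite(sorting$clusters, file.path(path, "clusters.csv"))
  data.table::fwrite(data.table::as.data.table(sorting$templates),
                     file.path(path, "templates.csv"))
  meta <- list(container = "bs_sorting", version = 1L,
               channel_id = sorting$channel_id,
               rate_eff = sorting$rate_eff,
               n_spikes = nrow(sorting$spikes),
               n_clusters = nrow(sorting$clusters),
               k = ncol(sorting$templates))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sorting
#' @export
read_sorting <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path))
    stop("not a sorting container (missing meta.json): ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$container, "bs_sorting"))
    stop("unknown container format: ", meta$container)
  sp <- as.data.frame(data.table::fread(file.path(path, "spikes.csv")))
  cl <- as.data.frame(
    data.table::fread(file.path(path, "clusters.csv")))
  if (meta$n_spikes == 0L)
    sp <- empty_spike_table()
  if (meta$n_clusters == 0L)
    cl <- empty_cluster_table()
  tp <- as.matrix(data.table::fread(file.path(path, "templates.csv")))
  dimnames(tp) <- NULL
  if (meta$n_clusters == 0L) tp <- matrix(numeric(0), 0L, meta$k)
  if (!is.null(cl$criteria)) {
    cl$criteria <- as.character(cl$criteria)
    cl$criteria[is.na(cl$criteria)] <- ""
  }
  sorting_result(sp, cl, tp, channel_id = meta$channel_id,
                 rate_eff = meta$rate_eff)
}

empty_spike_table <- function() {
  data.frame(time = numeric(0), cluster_id = integer(0),
             original_cluster_id = integer(0), block_index = integer(0),
             assign_stage = character(0))
}

empty_cluster_table <- function() {
  data.frame(cluster_id = integer(0), block_index = integer(0),
             size = integer(0), artifact = logical(0),
             criteria = character(0), group_id = integer(0))
}

#' Undo cluster grouping
#'
#' Reverts hierarchical merging: every cluster becomes its own group
#' again. Spike-level assignments are untouched because merging only
#' ever edits the cluster table.
#'
#' @param sorting a `bs_sorting`.
#' @return the `bs_sorting` with `group_id` reset to `cluster_id` for
#'   non-artifact clusters.
#' @export
ungroup_sorting <- function(sorting) {
  gid <- sorting$clusters$cluster_id
  gid[sorting$clusters$artifact] <- NA_integer_
  sorting$clusters$group_id <- gid
  sorting
}
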