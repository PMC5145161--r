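#' Segment a spike set into sorting blocks
#'
#' Blocks are consecutive, non-overlapping runs of `N_block` spikes in
#' time order; the final block holds the remainder. Block-wise sorting
#' confines periods of signal contamination to few blocks and lets
#' blocks be sorted in parallel.
#'
#' @param spikes a [spike_set()] (or anything with a spike count via
#'   `n`).
#' @param N_block spikes per block.
#' @param n alternative to `spikes`: the spike count itself.
#' @return list of integer index vectors, one per block.
#' @export
segment_blocks <- function(spikes = NULL, N_block = 20000, n = NULL) {
  if (is.null(n)) n <- n_spikes(spikes)
  if (n == 0) return(list())
  n_blocks <- max(1L, (n %/% N_block) + as.integer(n %% N_block > 0))
  starts <- (seq_len(n_blocks) - 1L) * N_block + 1L
  lapply(seq_len(n_blocks), function(b)
    seq.int(starts[b], min(n, starts[b] + N_block - 1L)))
}

#' Select clusters across temperatures
#'
#' Iterates over the temperatures of an SPC sweep from low to high,
#' starting at the second temperature (where a local maximum is first
#' defined) and stopping before the last. At temperature `T_j` the
#' clusters are ranked by size; the `i`-th largest is selected when it
#' is strictly larger than the `i`-th largest at both surrounding
#' temperatures `T_{j-1}` and `T_{j+1}` — a local maximum of cluster
#' size as a function of temperature — or when one of three
#' deterministic stability clauses fires on the same rank-wise size
#' sequence: the start of an exactly flat run (equal size at
#' `T_{j+1}`, different at `T_{j-1}`); a material rise that persists
#' (`prev <= 0.9 s` and `next >= 0.75 s`, a cluster born at this
#' rank); or a split-drop that persists (`s <= 0.9 prev` and
#' `next >= 0.75 s`, the largest child left after the cluster above
#' it broke apart). The extra clauses cover the degenerate limits of
#' the stability signal: a compact cluster's size is near-constant
#' across the frozen phase and the largest child of a split inherits a
#' monotone-decreasing curve, so neither ever shows a strict local
#' maximum; on gradually fluctuating size tables the clauses never
#' fire and the selection is exactly the local-maximum rule. At most
#' `C_max` clusters are selected per temperature and a cluster must
#' hold at least `S_min` spikes. Spikes claimed at a lower temperature
#' are never reassigned at a higher one.
#'
#' @param spc a `bs_spc` from [spc_run()].
#' @param C_max maximum selections per temperature.
#' @param S_min minimum cluster size (absolute count).
#' @return list with `assignment` (integer per spike; 0 = unassigned,
#'   clusters numbered in selection order) and `trace` (data frame of
#'   the selected (temperature, cluster) pairs with their static sizes
#'   and claimed counts, for temperature-map diagnostics).
#' @export
select_clusters <- function(spc, C_max = 5, S_min = 15) {
  labels <- spc$labels
  n_T <- nrow(labels)
  n <- ncol(labels)
  assigned <- integer(n)
  trace <- list()
  next_id <- 1L
  if (n_T >= 3) {
    sizes <- lapply(seq_len(n_T), function(j)
      sort(tabulate(labels[j, ]), decreasing = TRUE))
    for (j in 2:(n_T - 1)) {
      sz <- sizes[[j]]
      n_sel <- 0L
      for (i in seq_along(sz)) {
        if (n_sel >= C_max) break
        if (sz[i] < S_min) break
        prev_i <- if (i <= length(sizes[[j - 1]]))
          sizes[[j - 1]][i] else 0L
        next_i <- if (i <= length(sizes[[j + 1]]))
          sizes[[j + 1]][i] else 0L
        # the still-undifferentiated root (a cluster holding nearly
        # all of the input) is never a selection candidate — selecting
        # it would freeze the whole subset into one cluster and defeat
        # the later splitting stage; the stability clauses use a
        # stricter bound than the strict local-max rule
        not_root <- sz[i] <= 0.9 * n
        eligible <- sz[i] <= 0.5 * n
        local_max <- not_root && sz[i] > prev_i && sz[i] > next_i
        flat_start <- eligible && sz[i] == next_i && sz[i] != prev_i
        persists <- next_i >= 0.75 * sz[i]
        rise <- eligible && prev_i <= 0.9 * sz[i] && sz[i] > prev_i &&
          persists
        drop <- eligible && sz[i] <= 0.9 * prev_i && persists
        if (local_max || flat_start || rise || drop) {
          n_sel <- n_sel + 1L
          # label of the i-th largest cluster at T_j (ties resolved
          # towards the lower label, which tabulate ordering gives)
          tab <- tabulate(labels[j, ])
          lab_order <- order(-tab, seq_along(tab))
          lab <- lab_order[i]
          members <- which(labels[j, ] == lab & assigned == 0L)
          if (length(members)) {
            assigned[members] <- next_id
            trace[[length(trace) + 1L]] <- data.frame(
              temp_index = j, temperature = spc$temperatures[j],
              label = lab, size = sz[i], cluster_id = next_id,
              n_claimed = length(members))
            next_id <- next_id + 1L
          } else {
            trace[[length(trace) + 1L]] <- data.frame(
              temp_index = j, temperature = spc$temperatures[j],
              label = lab, size = sz[i], cluster_id = NA_integer_,
              n_claimed = 0L)
          }
        }
      }
    }
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(temp_index = integer(0), temperature = numeric(0),
               label = integer(0), size = integer(0),
               cluster_id = integer(0), n_claimed = integer(0))
  list(assignment = assigned, trace = trace)
}

#' Per-cluster waveform statistics
#'
#' Mean waveform and the variability measure
#' `s = sqrt(sum_i var(x_i))` (the square root of the summed
#' per-sample variances, in uV), which makes the template-matching
#' radius `f * s` commensurable with a Euclidean distance in waveform
#' space.
#'
#' @param waveforms waveform matrix of the cluster's spikes.
#' @return list with `mean_wave`, `ss` (per-sample sums of squared
#'   deviations), `s`, `size` and `sem_mean`.
#' @export
cluster_stats <- function(waveforms) {
  wf <- as.matrix(waveforms)
  nr <- nrow(wf)
  if (!nr) stop("empty cluster")
  m <- colMeans(wf)
  ss <- colSums(sweep(wf, 2, m)^2)
  v <- if (nr > 1) ss / (nr - 1) else rep(0, ncol(wf))
  list(mean_wave = m, ss = ss, s = sqrt(sum(v)), size = nr,
       sem_mean = mean(sqrt(v / nr)))
}

#' Template matching
#'
#' Assigns spikes to the nearest admissible cluster: the Euclidean
#' distance in waveform space between each spike and every cluster
#' mean is computed, a cluster admits a spike when the distance is
#' below `f * s` (its own variability radius), and the spike joins the
#' nearest admitting cluster. Spikes admitted by no cluster remain
#' unassigned.
#'
#' @param waveforms waveform matrix of the spikes to assign.
#' @param clusters list of [cluster_stats()] objects.
#' @param f match radius in units of each cluster's `s`.
#' @return integer vector: index into `clusters` per spike, 0 when
#'   unassigned.
#' @export
template_match <- function(waveforms, clusters, f) {
  wf <- as.matrix(waveforms)
  nw <- nrow(wf)
  if (!length(clusters) || !nw) return(integer(nw))
  means <- t(vapply(clusters, `[[`, numeric(ncol(wf)), "mean_wave"))
  radius <- f * vapply(clusters, `[[`, numeric(1), "s")
  d2 <- outer(rowSums(wf^2), rep(1, nrow(means))) +
    outer(rep(1, nw), rowSums(means^2)) - 2 * wf %*% t(means)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  admissible <- sweep(d, 2, radius, `<`)
  d[!admissible] <- Inf
  best <- max.col(-d, ties.method = "first")
  best[!is.finite(d[cbind(seq_len(nw), best)])] <- 0L
  as.integer(best)
}

#' Split large clusters by re-clustering
#'
#' Every cluster containing at least `R_min` spikes is re-clustered on
#' its own members (feature selection and the temperature sweep are
#' re-run on the subset); when at least two subclusters emerge *and*
#' they jointly claim at least half of the parent, they replace it,
#' and the procedure recurses into subclusters until none qualifies
#' or no split occurs. The coverage condition keeps a homogeneous
#' cluster intact when the sub-run only chips transition-region
#' slivers off it. This counteracts under-clustering, where spikes of
#' several neurons share one cluster.
#'
#' @param assignment integer cluster id per spike (0 = unassigned).
#' @param coeffs full wavelet-coefficient matrix of the same spikes.
#' @param R_min minimum cluster size for re-clustering.
#' @param params a [sort_params()] object.
#' @param hyper a [spc_hyper()] object; sub-runs derive their seeds
#'   from `hyper$seed`.
#' @param S_min minimum subcluster size (absolute count).
#' @return the updated assignment vector (members of a split parent
#'   that no subcluster claims become unassigned).
#' @export
split_large <- function(assignment, coeffs, R_min = 2000,
                        params = sort_params(), hyper = spc_hyper(),
                        S_min = 15) {
  assignment <- as.integer(assignment)
  queue <- unique(assignment[assignment > 0])
  counter <- 0L
  while (length(queue)) {
    cid <- queue[1]
    queue <- queue[-1]
    members <- which(assignment == cid)
    if (length(members) < R_min) next
    counter <- counter + 1L
    feats <- select_features_ks(coeffs[members, , drop = FALSE])
    hy <- hyper
    hy$seed <- as.integer((hyper$seed + 104729 * counter) %% .Machine$integer.max)
    spc <- spc_run(feats, params, hy)
    sel <- select_clusters(spc, params$C_max, S_min)
    sub_ids <- unique(sel$assignment[sel$assignment > 0])
    # a genuine split must both produce >= 2 subclusters and explain
    # the bulk of the parent; transition-region slivers on a
    # homogeneous cluster do not dissolve it
    coverage <- mean(sel$assignment > 0)
    if (length(sub_ids) >= 2 && coverage >= 0.5) {
      base <- max(assignment)
      new_ids <- base + seq_along(sub_ids)
      remap <- integer(max(sub_ids))
      remap[sub_ids] <- new_ids
      assignment[members] <- 0L
      claimed <- sel$assignment > 0
      assignment[members[claimed]] <- remap[sel$assignment[claimed]]
      big <- new_ids[tabulate(assignment)[new_ids] >= R_min]
      queue <- c(queue, big)
    }
  }
  assignment
}

#' Sort one block of spikes
#'
#' The per-block pipeline: Haar wavelet features, KS feature selection,
#' superparamagnetic temperature sweep, multi-temperature cluster
#' selection, splitting of large clusters, then template matching with
#' radius `f1` to assign leftover spikes to the new clusters. When
#' `N_rep > 1` the whole pipeline is re-applied to the spikes still
#' unassigned after the previous pass.
#'
#' @param spikes a [spike_set()] (one block), or a waveform matrix.
#' @param params a [sort_params()] object.
#' @param hyper a [spc_hyper()] object.
#' @param block_seed seed for this block's simulations (defaults to
#'   `hyper$seed`); parallel channel sorting derives one per block so
#'   results are independent of worker scheduling.
#' @return list with `assignment` (integer cluster id per spike, 0 =
#'   unassigned; ids are local to the block), `stage` (character per
#'   spike: `"SPC"`, `"TM_within"` or `"residual"`), `trace` (selection
#'   trace rows from all passes) and `n_clusters`.
#' @export
sort_block <- function(spikes, params = sort_params(),
                       hyper = spc_hyper(), block_seed = NULL) {
  wf <- if (inherits(spikes, "bs_spikes")) spikes$waveforms else
    as.matrix(spikes)
  n <- nrow(wf)
  if (is.null(block_seed)) block_seed <- hyper$seed
  S_min_abs <- if (params$S_min < 1)
    max(1, round(params$S_min * n)) else params$S_min
  assignment <- integer(n)
  stage <- rep("residual", n)
  traces <- list()
  if (n < 2 * S_min_abs) {
    warning("block of ", n, " spikes is below the minimum clusterable",
            " size; returning a single pass-through cluster")
    return(list(assignment = rep(1L, n), stage = rep("SPC", n),
                trace = data.frame(), n_clusters = if (n) 1L else 0L))
  }
  for (rep_i in seq_len(params$N_rep)) {
    un <- which(assignment == 0L)
    if (length(un) < 2 * S_min_abs) break
    coeffs <- wavelet_features(wf[un, , drop = FALSE])
    feats <- select_features_ks(coeffs)
    hy <- hyper
    hy$seed <- as.integer((block_seed + (rep_i - 1)) %%
                            .Machine$integer.max)
    spc <- spc_run(feats, params, hy)
    sel <- select_clusters(spc, params$C_max, S_min_abs)
    if (!any(sel$assignment > 0)) break
    local <- split_large(sel$assignment, coeffs, params$R_min, params,
                         hy, S_min_abs)
    offset <- max(assignment)
    claimed <- local > 0
    # split_large numbers subclusters above the originals; compact ids
    local[claimed] <- match(local[claimed], sort(unique(local[claimed])))
    assignment[un[claimed]] <- local[claimed] + offset
    stage[un[claimed]] <- "SPC"
    sel$trace$pass <- rep_i
    traces[[rep_i]] <- sel$trace
    # within-block template matching on everything still unassigned
    un2 <- which(assignment == 0L)
    ids <- sort(unique(assignment[assignment > 0]))
    if (length(un2) && length(ids)) {
      stats <- lapply(ids, function(id)
        cluster_stats(wf[assignment == id, , drop = FALSE]))
      tm <- template_match(wf[un2, , drop = FALSE], stats, params$f1)
      hit <- tm > 0
      assignment[un2[hit]] <- ids[tm[hit]]
      stage[un2[hit]] <- "TM_within"
    }
  }
  list(assignment = assignment, stage = stage,
       trace = if (length(traces)) do.call(rbind, traces) else
         data.frame(),
       n_clusters = length(unique(assignment[assignment > 0])))
}

#' Merge clusters into groups
#'
#' Agglomerative merging of clusters, within and across blocks
#' simultaneously: the pair of groups with the smallest distance
#' between mean waveforms is merged, the merged group's mean is
#' recomputed (spike-count weighted, exactly), and merging stops once
#' the minimal distance exceeds `C_stop`. With the default
#' `"normalized"` metric the distance is the Euclidean distance between
#' group means divided by the pooled variability `s` of the pair, so
#' `C_stop` is on the same scale as the template-matching radii.
#'
#' @param clusters list of [cluster_stats()] objects (non-artifact
#'   clusters).
#' @param C_stop merge-stop threshold.
#' @param metric `"normalized"` or `"raw"` (plain uV distance).
#' @return list with `group` (integer group index per input cluster,
#'   numbered by first member), `history` (data frame of merge steps)
#'   and `stats` (list of merged-group [cluster_stats()]).
#' @export
merge_groups <- function(clusters, C_stop = 1.8,
                         metric = c("normalized", "raw")) {
  metric <- match.arg(metric)
  nc <- length(clusters)
  if (!nc) return(list(group = integer(0), history = data.frame(),
                       stats = list()))
  groups <- clusters
  member <- as.list(seq_len(nc))
  active <- rep(TRUE, nc)
  history <- list()
  pair_dist <- function(g1, g2) {
    dmu <- sqrt(sum((g1$mean_wave - g2$mean_wave)^2))
    if (metric == "raw") return(dmu)
    n1 <- g1$size; n2 <- g2$size
    v1 <- if (n1 > 1) g1$ss / (n1 - 1) else g1$ss * 0
    v2 <- if (n2 > 1) g2$ss / (n2 - 1) else g2$ss * 0
    spool <- sqrt((n1 * sum(v1) + n2 * sum(v2)) / (n1 + n2))
    if (spool == 0) return(if (dmu == 0) 0 else Inf)
    dmu / spool
  }
  combine <- function(g1, g2) {
    n <- g1$size + g2$size
    m <- (g1$size * g1$mean_wave + g2$size * g2$mean_wave) / n
    ss <- g1$ss + g2$ss +
      g1$size * g2$size / n * (g1$mean_wave - g2$mean_wave)^2
    v <- if (n > 1) ss / (n - 1) else ss * 0
    list(mean_wave = m, ss = ss, s = sqrt(sum(v)), size = n,
         sem_mean = mean(sqrt(v / n)))
  }
  repeat {
    act <- which(active)
    if (length(act) < 2) break
    best <- c(NA, NA)
    dmin <- Inf
    for (a in seq_along(act)[-length(act)])
      for (b in (a + 1):length(act)) {
        dd <- pair_dist(groups[[act[a]]], groups[[act[b]]])
        if (dd < dmin) {
          dmin <- dd
          best <- c(act[a], act[b])
        }
      }
    if (dmin > C_stop) break
    i <- best[1]; j <- best[2]
    groups[[i]] <- combine(groups[[i]], groups[[j]])
    member[[i]] <- c(member[[i]], member[[j]])
    active[j] <- FALSE
    history[[length(history) + 1L]] <-
      data.frame(into = i, from = j, distance = dmin)
  }
  group <- integer(nc)
  act <- which(active)
  for (gi in seq_along(act))
    group[member[[act[gi]]]] <- gi
  list(group = group,
       history = if (length(history)) do.call(rbind, history) else
         data.frame(into = integer(0), from = integer(0),
                    distance = numeric(0)),
       stats = groups[act])
}

#' Sort a whole channel
#'
#' The complete pipeline for one channel's spike set (after pre-sorting
#' artifact rejection): segmentation into blocks, independent per-block
#' sorting (optionally in parallel), template matching across blocks
#' with radius `f2` to place spikes no block claimed, post-sorting
#' artifact flagging of every cluster, and hierarchical merging of all
#' non-artifact clusters into groups. Spikes never assigned end up in
#' the residual cluster (id 0). Merging only edits the cluster table:
#' each spike's original cluster identity is preserved, so grouping can
#' be undone exactly with [ungroup_sorting()].
#'
#' @param spikes a [spike_set()].
#' @param params a [sort_params()] object.
#' @param hyper a [spc_hyper()] object; block `b` runs with seed
#'   `hyper$seed + b`, making the result independent of worker count.
#' @param ap an [artifact_params()] object for post-sorting flagging.
#' @param n_workers parallel workers for block sorting (forked;
#'   results are bitwise identical for any worker count).
#' @param flag_artifacts apply the post-sorting artifact criteria to
#'   every cluster (default). Disable for data known to contain no
#'   artifacts, e.g. clean simulations, where the absolute SEM
#'   criterion would otherwise flag genuine clusters.
#' @return a [sorting_result()].
#' @export
sort_channel <- function(spikes, params = sort_params(),
                         hyper = spc_hyper(), ap = artifact_params(),
                         n_workers = 1, flag_artifacts = TRUE) {
  wf <- spikes$waveforms
  n <- nrow(wf)
  if (!n)
    return(sorting_result(empty_spike_table(), empty_cluster_table(),
                          matrix(numeric(0), 0, ncol(wf)),
                          channel_id = spikes$channel_id,
                          rate_eff = spikes$rate_eff))
  blocks <- segment_blocks(spikes, params$N_block)
  run_block <- function(b) {
    sort_block(wf[blocks[[b]], , drop = FALSE], params, hyper,
               block_seed = as.integer((hyper$seed + b) %%
                                         .Machine$integer.max))
  }
  results <- if (n_workers > 1)
    parallel::mclapply(seq_along(blocks), run_block,
                       mc.cores = n_workers, mc.preschedule = TRUE)
  else lapply(seq_along(blocks), run_block)

  assignment <- integer(n)
  stage <- rep("residual", n)
  block_index <- integer(n)
  offset <- 0L
  cluster_block <- integer(0)
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    res <- results[[b]]
    block_index[idx] <- b
    claimed <- res$assignment > 0
    assignment[idx[claimed]] <- res$assignment[claimed] + offset
    stage[idx] <- ifelse(claimed, res$stage, "residual")
    cluster_block <- c(cluster_block, rep(b, res$n_clusters))
    offset <- offset + res$n_clusters
  }
  # compact cluster ids into 1..C in (block, local id) order
  ids <- sort(unique(assignment[assignment > 0]))
  assignment[assignment > 0] <- match(assignment[assignment > 0], ids)
  n_clusters <- length(ids)
  cluster_block <- cluster_block[seq_len(n_clusters)]

  stats <- lapply(seq_len(n_clusters), function(id)
    cluster_stats(wf[assignment == id, , drop = FALSE]))

  un <- which(assignment == 0L)
  if (length(un) && n_clusters) {
    tm <- template_match(wf[un, , drop = FALSE], stats, params$f2)
    hit <- tm > 0
    assignment[un[hit]] <- tm[hit]
    stage[un[hit]] <- "TM_across"
    stats <- lapply(seq_len(n_clusters), function(id)
      cluster_stats(wf[assignment == id, , drop = FALSE]))
  }

  if (flag_artifacts) {
    flags <- lapply(seq_len(n_clusters), function(id)
      flag_artifact_cluster(wf[assignment == id, , drop = FALSE],
                            spikes$rate_eff %||% 24000, ap))
    artifact <- vapply(flags, `[[`, logical(1), "artifact")
    criteria <- vapply(flags, function(f)
      paste(f$criteria, collapse = ";"), character(1))
  } else {
    artifact <- rep(FALSE, n_clusters)
    criteria <- rep("", n_clusters)
  }

  group_id <- rep(NA_integer_, n_clusters)
  keep <- which(!artifact)
  if (length(keep)) {
    mg <- merge_groups(stats[keep], params$C_stop,
                       params$merge_metric)
    group_id[keep] <- mg$group
  }

  sizes <- vapply(seq_len(n_clusters), function(id)
    sum(assignment == id), integer(1))
  clusters <- data.frame(cluster_id = seq_len(n_clusters),
                         block_index = cluster_block, size = sizes,
                         artifact = artifact, criteria = criteria,
                         group_id = group_id)
  sp <- data.frame(time = spikes$times, cluster_id = assignment,
                   original_cluster_id = assignment,
                   block_index = block_index, assign_stage = stage)
  templates <- if (n_clusters)
    t(vapply(stats, `[[`, numeric(ncol(wf)), "mean_wave")) else
      matrix(numeric(0), 0, ncol(wf))
  sorting_result(sp, clusters, templates,
                 channel_id = spikes$channel_id,
                 rate_eff = spikes$rate_eff)
}
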