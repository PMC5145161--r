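# Independent brute-force oracles. These deliberately re-derive each
# rule from its plain-language statement with naive loops, so they
# share no code path with the package implementation they check.

# Overlapping-bin rate criterion: enumerate every bin start that could
# contain an event, count events per bin with an explicit loop, and
# remove the events of every over-full bin.
oracle_mask_high_rate <- function(times, bin, hop, max_events) {
  keep <- rep(TRUE, length(times))
  if (!length(times)) return(keep)
  m_max <- floor(max(times) / hop)
  for (m in 0:m_max) {
    lo <- m * hop
    inside <- times >= lo & times < lo + bin
    if (sum(inside) > max_events) keep[inside] <- FALSE
  }
  keep
}

# Cross-channel concurrency: per candidate bin, count channels holding
# at least one event; excluded bins empty every channel.
oracle_mask_concurrent <- function(times_by_channel, bin, hop, frac) {
  nch <- length(times_by_channel)
  keeps <- lapply(times_by_channel, function(t) rep(TRUE, length(t)))
  all_t <- unlist(times_by_channel)
  if (!length(all_t)) return(keeps)
  m_max <- floor(max(all_t) / hop)
  for (m in 0:m_max) {
    lo <- m * hop
    n_with <- sum(vapply(times_by_channel, function(t)
      any(t >= lo & t < lo + bin), logical(1)))
    if (n_with / nch >= frac)
      for (ci in seq_len(nch)) {
        t <- times_by_channel[[ci]]
        keeps[[ci]][t >= lo & t < lo + bin] <- FALSE
      }
  }
  keeps
}

# Greedy double-detection sweep, written as the rule reads: walk left
# to right, compare the current survivor with the next event.
oracle_double <- function(times, maxima, window) {
  n <- length(times)
  keep <- rep(TRUE, n)
  if (n < 2) return(keep)
  cur <- 1
  for (i in 2:n) {
    if (times[i] - times[cur] < window) {
      if (maxima[i] > maxima[cur]) {
        keep[cur] <- FALSE
        cur <- i
      } else keep[i] <- FALSE
    } else cur <- i
  }
  keep
}

# Multi-temperature cluster selection over a table of per-temperature
# cluster-size vectors: returns the selected (temperature, rank)
# pairs. Works purely on sizes, never on labels. Implements the
# documented rule: strict local maximum of the rank-i size over
# temperature, the first temperature of an exactly flat run, or a
# persistent material rise / split-drop.
oracle_select_table <- function(size_table, C_max, S_min) {
  n_T <- length(size_table)
  n_pts <- sum(size_table[[1]])
  picks <- list()
  if (n_T < 3) return(picks)
  for (j in 2:(n_T - 1)) {
    sizes <- sort(size_table[[j]], decreasing = TRUE)
    prev <- sort(size_table[[j - 1]], decreasing = TRUE)
    nxt <- sort(size_table[[j + 1]], decreasing = TRUE)
    n_sel <- 0
    for (i in seq_along(sizes)) {
      if (n_sel >= C_max) break
      if (sizes[i] < S_min) break
      p <- if (i <= length(prev)) prev[i] else 0
      q <- if (i <= length(nxt)) nxt[i] else 0
      s <- sizes[i]
      not_root <- s <= 0.9 * n_pts
      elig <- s <= 0.5 * n_pts
      if ((not_root && s > p && s > q) ||
          (elig && s == q && s != p) ||
          (elig && p <= 0.9 * s && s > p && q >= 0.75 * s) ||
          (elig && s <= 0.9 * p && q >= 0.75 * s)) {
        n_sel <- n_sel + 1
        picks[[length(picks) + 1]] <- c(temp = j, rank = i,
                                        size = sizes[i])
      }
    }
  }
  picks
}

# Exhaustive min-pair agglomeration computing every group's statistics
# directly from the pooled raw waveforms at every step.
oracle_merge <- function(waveform_list, C_stop) {
  groups <- lapply(seq_along(waveform_list), identity)
  gdist <- function(ga, gb) {
    wa <- do.call(rbind, waveform_list[ga])
    wb <- do.call(rbind, waveform_list[gb])
    ma <- colMeans(wa)
    mb <- colMeans(wb)
    dmu <- sqrt(sum((ma - mb)^2))
    va <- if (nrow(wa) > 1) apply(wa, 2, var) else 0 * ma
    vb <- if (nrow(wb) > 1) apply(wb, 2, var) else 0 * mb
    spool <- sqrt((nrow(wa) * sum(va) + nrow(wb) * sum(vb)) /
                    (nrow(wa) + nrow(wb)))
    if (spool == 0) {
      if (dmu == 0) 0 else Inf
    } else dmu / spool
  }
  repeat {
    if (length(groups) < 2) break
    dmin <- Inf
    best <- NULL
    for (a in 1:(length(groups) - 1))
      for (b in (a + 1):length(groups)) {
        dd <- gdist(groups[[a]], groups[[b]])
        if (dd < dmin) {
          dmin <- dd
          best <- c(a, b)
        }
      }
    if (dmin > C_stop) break
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  # partition as a group label per input cluster
  lab <- integer(length(waveform_list))
  for (g in seq_along(groups)) lab[groups[[g]]] <- g
  lab
}

# Purity / completeness / hit straight from a contingency table.
oracle_hits <- function(unit_labels, neuron_labels, n_neurons) {
  units <- sort(unique(unit_labels[unit_labels > 0]))
  hits <- 0
  for (u in units) {
    in_u <- unit_labels == u
    nu <- neuron_labels[in_u]
    nu <- nu[nu > 0]
    if (!length(nu)) next
    tab <- table(nu)
    best <- as.integer(names(tab)[which.max(tab)])
    purity <- max(tab) / sum(in_u)
    completeness <- max(tab) / sum(neuron_labels == best)
    if (purity >= 0.5 && completeness >= 0.5) hits <- hits + 1
  }
  list(n_hits = hits, fraction = if (n_neurons) hits / n_neurons else NA)
}

# Closed-form step-up adjustment:
# adj_i = min over { j : p_(j) >= p_(i) } of m * p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  vapply(seq_len(m), function(i) {
    js <- which(ps >= p[i] - 1e-15)
    min(1, min(m * ps[js] / js))
  }, numeric(1))
}

# Build an SPC-like label structure from a prescribed size table so
# selection can be exercised on known inputs.
labels_from_sizes <- function(size_table) {
  n <- sum(size_table[[1]])
  stopifnot(all(vapply(size_table, sum, numeric(1)) == n))
  labels <- t(vapply(size_table, function(sz)
    rep(seq_along(sz), sz), integer(n)))
  structure(list(temperatures = seq(0, 0.2,
                                    length.out = length(size_table)),
                 labels = labels,
                 sizes = lapply(size_table, sort, decreasing = TRUE)),
            class = "bs_spc")
}

# A random partition of n points into parts of size >= 1.
random_size_table <- function(n, n_T, max_clusters, rng) {
  lapply(seq_len(n_T), function(j) {
    kc <- sample(seq_len(max_clusters), 1)
    cuts <- sort(sample(seq_len(n - 1), kc - 1))
    diff(c(0, cuts, n))
  })
}
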