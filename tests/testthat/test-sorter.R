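test_that("block segmentation counts match integer arithmetic", {
  expect_length(segment_blocks(n = 350000, N_block = 20000), 18)
  b <- segment_blocks(n = 60000, N_block = 20000)
  expect_length(b, 3)
  expect_true(all(lengths(b) == 20000))
  b <- segment_blocks(n = 5000, N_block = 20000)
  expect_length(b, 1)
  expect_length(b[[1]], 5000)
  expect_equal(unlist(segment_blocks(n = 41, N_block = 20)), 1:41)
  expect_length(segment_blocks(n = 0), 0)
})

test_that("cluster selection picks local size maxima over temperature", {
  # constructed 5-temperature table with one clear bump at T3
  tbl <- list(c(100), c(60, 40), c(55, 30, 15), c(70, 20, 10),
              c(50, 30, 20))
  spc <- labels_from_sizes(tbl)
  sel <- select_clusters(spc, C_max = 5, S_min = 10)
  got <- Map(c, sel$trace$temp_index, sel$trace$size)
  want <- lapply(oracle_select_table(tbl, 5, 10),
                 function(p) unname(c(p["temp"], p["size"])))
  expect_setequal(lapply(got, as.numeric), want)
  # spikes claimed once are never reassigned
  expect_true(all(table(sel$assignment[sel$assignment > 0]) > 0))
})

test_that("selection matches the table oracle on random tables", {
  for (case in 1:150) {
    set.seed(case)
    n_T <- sample(4:8, 1)
    tbl <- random_size_table(200, n_T, 6)
    C_max <- sample(2:5, 1)
    S_min <- sample(c(5, 15, 30), 1)
    sel <- select_clusters(labels_from_sizes(tbl), C_max, S_min)
    got <- sort(vapply(seq_len(nrow(sel$trace)), function(r)
      sel$trace$temp_index[r] * 1000 + sel$trace$size[r], numeric(1)))
    want <- sort(vapply(oracle_select_table(tbl, C_max, S_min),
                        function(p) p["temp"] * 1000 + p["size"],
                        numeric(1)))
    expect_equal(got, unname(want), info = paste("case", case))
  }
})

test_that("selection respects C_max and S_min edge cases", {
  # everything below S_min -> nothing selected
  tbl <- list(c(5, 5), c(6, 4), c(7, 3), c(4, 6))
  sel <- select_clusters(labels_from_sizes(tbl), C_max = 5, S_min = 15)
  expect_equal(nrow(sel$trace), 0L)
  expect_true(all(sel$assignment == 0L))
  # many qualifying maxima at one temperature, capped at C_max
  base <- rep(10, 9)
  tbl <- list(rep(10, 9) + c(rep(0, 9)),
              20:12,           # all nine larger than neighbours
              rep(10, 9) + 8,  # 18 each
              rep(10, 9))
  tbl <- lapply(tbl, function(s) c(s, 200 - sum(s)))
  tbl <- lapply(tbl, sort, decreasing = TRUE)
  sel <- select_clusters(labels_from_sizes(tbl), C_max = 5, S_min = 5)
  expect_lte(max(table(sel$trace$temp_index)), 5)
})

test_that("claimed spikes stay with their low-temperature cluster", {
  # same big cluster is a local maximum twice; the second selection
  # must not steal the first one's members
  tbl <- list(c(90, 10), c(60, 40), c(50, 30, 20), c(80, 20),
              c(55, 45))
  spc <- labels_from_sizes(tbl)
  sel <- select_clusters(spc, C_max = 5, S_min = 10)
  first_members <- which(sel$assignment == 1L)
  # re-run selection: deterministic
  sel2 <- select_clusters(spc, C_max = 5, S_min = 10)
  expect_identical(sel$assignment, sel2$assignment)
  # a spike belongs to exactly one cluster
  expect_true(all(tabulate(sel$assignment[sel$assignment > 0]) >= 1))
  expect_gt(length(first_members), 0)
})

test_that("template matching assigns nearest admissible cluster", {
  set.seed(6)
  k <- 16
  mA <- c(rep(0, 4), 50, 80, 50, rep(0, 9))
  mB <- c(rep(0, 9), 60, 90, 60, rep(0, 4))
  clA <- cluster_stats(matrix(rep(mA, 30), 30, k, byrow = TRUE) +
                         rnorm(30 * k, sd = 4))
  clB <- cluster_stats(matrix(rep(mB, 30), 30, k, byrow = TRUE) +
                         rnorm(30 * k, sd = 4))
  # a spike equal to cluster A's mean: distance 0 -> assigned to A
  got <- template_match(matrix(clA$mean_wave, 1), list(clA, clB),
                        f = 0.75)
  expect_equal(got, 1L)
  # spike at distance 0.8 s from its only cluster with f = 0.75:
  # stays unassigned
  dirv <- rnorm(k)
  dirv <- dirv / sqrt(sum(dirv^2))
  spike <- clA$mean_wave + 0.8 * clA$s * dirv
  expect_equal(template_match(matrix(spike, 1), list(clA), 0.75), 0L)
  expect_equal(template_match(matrix(spike, 1), list(clA), 1.0), 1L)
  # within radius of both but nearer B -> B
  mid <- 0.45 * clA$mean_wave + 0.55 * clB$mean_wave
  far <- sqrt(sum((mid - clA$mean_wave)^2))
  near <- sqrt(sum((mid - clB$mean_wave)^2))
  f_big <- 1.05 * max(far / clA$s, near / clB$s)
  expect_equal(template_match(matrix(mid, 1), list(clA, clB), f_big),
               2L)
  # zero clusters: identity
  expect_equal(template_match(matrix(mid, 1), list(), 3), 0L)
})

test_that("template matching equals a brute-force nearest-admissible oracle", {
  set.seed(13)
  k <- 12
  for (case in 1:25) {
    stats <- lapply(1:4, function(i)
      cluster_stats(matrix(rnorm(20 * k, mean = i), 20, k)))
    spikes <- matrix(rnorm(30 * k, mean = runif(1, 0, 5)), 30, k)
    got <- template_match(spikes, stats, f = 1.5)
    for (si in seq_len(nrow(spikes))) {
      d <- vapply(stats, function(cs)
        sqrt(sum((spikes[si, ] - cs$mean_wave)^2)), numeric(1))
      ok <- which(d < 1.5 * vapply(stats, `[[`, numeric(1), "s"))
      want <- if (length(ok)) ok[which.min(d[ok])] else 0L
      expect_equal(got[si], as.integer(want))
    }
  }
})

test_that("cluster variability s is the root of summed variances", {
  set.seed(4)
  wf <- matrix(rnorm(50 * 8, sd = 3), 50, 8)
  cs <- cluster_stats(wf)
  expect_equal(cs$s, sqrt(sum(apply(wf, 2, var))))
  expect_equal(cs$mean_wave, colMeans(wf))
  expect_equal(cs$size, 50)
  one <- cluster_stats(wf[1, , drop = FALSE])
  expect_equal(one$s, 0)
})

test_that("merging follows the exhaustive min-pair oracle", {
  set.seed(17)
  k <- 8
  for (case in 1:20) {
    centers <- matrix(rnorm(4 * k, sd = 3), 4, k)
    wfs <- lapply(1:4, function(i)
      matrix(rep(centers[i, ], 25), 25, k, byrow = TRUE) +
        matrix(rnorm(25 * k, sd = 1.2), 25, k))
    stats <- lapply(wfs, cluster_stats)
    for (C_stop in c(1.2, 1.8, 3)) {
      got <- merge_groups(stats, C_stop)$group
      want <- oracle_merge(wfs, C_stop)
      # same partition (group numbering may differ)
      expect_equal(length(unique(got)), length(unique(want)))
      expect_true(all(got[want == want[1]] == got[1]))
      for (g in unique(want))
        expect_equal(length(unique(got[want == g])), 1L)
    }
  }
})

test_that("merge examples: identical means merge, distant ones do not", {
  k <- 8
  base <- matrix(rep(c(0, 10, 40, 10, 0, -5, 0, 0), 20), 20, k,
                 byrow = TRUE)
  set.seed(2)
  a <- cluster_stats(base + rnorm(20 * k))
  b <- cluster_stats(base + rnorm(20 * k))
  expect_equal(length(unique(merge_groups(list(a, b), 1.8)$group)), 1L)

  # displace b's waveforms along one axis so the normalized
  # mean-to-mean distance is exactly 2.0
  wf_b <- base + rnorm(20 * k)
  cs_b0 <- cluster_stats(wf_b)
  pool <- function(x, y) sqrt((x$size * x$s^2 + y$size * y$s^2) /
                                (x$size + y$size))
  delta <- 2.0 * pool(a, cs_b0)
  dvec <- cs_b0$mean_wave - a$mean_wave
  rest2 <- sum(dvec[-1]^2)
  wf_b_far <- wf_b
  wf_b_far[, 1] <- wf_b_far[, 1] +
    (sqrt(delta^2 - rest2) - dvec[1])
  cs_far <- cluster_stats(wf_b_far)
  d <- sqrt(sum((cs_far$mean_wave - a$mean_wave)^2)) / pool(a, cs_far)
  expect_equal(d, 2.0, tolerance = 1e-6)
  expect_equal(length(unique(merge_groups(list(a, cs_far),
                                          1.8)$group)), 2L)
  # a single cluster is a single group
  expect_equal(merge_groups(list(a), 1.8)$group, 1L)
})

test_that("lowering C_stop never lowers the group count", {
  set.seed(23)
  k <- 10
  stats <- lapply(1:6, function(i)
    cluster_stats(matrix(rnorm(30 * k, mean = i * 0.8, sd = 1.5),
                         30, k)))
  counts <- vapply(c(1.2, 1.4, 1.6, 1.8), function(cs)
    length(unique(merge_groups(stats, cs)$group)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("splitting separates a merged two-template blob", {
  fx <- sim_spikes_fixture("two_templates")
  wf <- fx$spikes$waveforms
  truth <- fx$lab                     # 0 = noise/hash detections
  coeffs <- wavelet_features(wf)
  assignment <- rep(1L, nrow(wf))     # everything lumped together
  out <- split_large(assignment, coeffs, R_min = 2000, sort_params(),
                     spc_hyper(seed = 3), S_min = 15)
  ids <- unique(out[out > 0])
  expect_gte(length(ids), 2)
  big <- ids[vapply(ids, function(i) sum(out == i), numeric(1)) >= 100]
  expect_gte(length(big), 2)
  # among ground-truth spikes, every big subcluster is pure, and both
  # neurons dominate some subcluster
  doms <- integer(0)
  for (i in big) {
    matched <- truth[out == i]
    matched <- matched[matched > 0]
    if (!length(matched)) next
    expect_gt(purity_of(matched), 0.9)
    doms <- c(doms, as.integer(names(which.max(table(matched)))))
  }
  expect_setequal(unique(doms), 1:2)

  # clusters below R_min stay untouched
  small <- rep(1L, 400)
  expect_identical(split_large(small, coeffs[1:400, ], R_min = 2000,
                               sort_params(), spc_hyper(seed = 3),
                               S_min = 15),
                   small)

  # homogeneous single-template cluster: no effective split
  one <- which(truth == 2)
  a1 <- split_large(rep(1L, length(one)),
                    coeffs[one, , drop = FALSE],
                    R_min = 1000, sort_params(), spc_hyper(seed = 5),
                    S_min = 15)
  big1 <- unique(a1[a1 > 0])
  sizes <- vapply(big1, function(i) sum(a1 == i), numeric(1))
  expect_gte(max(sizes) / length(one), 0.8)
})

test_that("sort_block conserves spikes and finds planted templates", {
  fx <- sim_spikes_fixture("three_neurons")
  sp <- fx$spikes
  truth <- fx$lab
  n <- n_spikes(sp)
  res <- sort_block(sp, sort_params(R_min = 1000),
                    spc_hyper(seed = 21))
  expect_length(res$assignment, n)
  expect_true(all(res$assignment >= 0))
  # conservation: every spike is clustered or unassigned
  expect_equal(sum(res$assignment > 0) + sum(res$assignment == 0), n)
  expect_true(all(res$stage[res$assignment == 0] == "residual"))
  # at least 3 clusters
  ids <- unique(res$assignment[res$assignment > 0])
  expect_gte(length(ids), 3)
  # each planted neuron is dominated by one cluster, and that
  # cluster is pure for it
  for (tr in 1:3) {
    members <- res$assignment[truth == tr]
    members <- members[members > 0]
    dom <- as.integer(names(which.max(table(members))))
    expect_gt(max(table(members)) / sum(truth == tr), 0.5)
    expect_gt(purity_of(truth[res$assignment == dom]), 0.9)
  }
})

test_that("a tiny block becomes a single pass-through cluster", {
  sp <- make_toy_spikes(10)
  expect_warning(res <- sort_block(sp, sort_params(S_min = 15),
                                   spc_hyper(seed = 1)),
                 "pass-through")
  expect_equal(res$assignment, rep(1L, 10))
})

test_that("a second clustering pass only ever shrinks the residual", {
  fx <- sim_spikes_fixture("two_templates")
  sp <- fx$spikes
  p1 <- sort_params(S_min = 15, N_rep = 1, R_min = 2000)
  p2 <- sort_params(S_min = 15, N_rep = 2, R_min = 2000)
  r1 <- sort_block(sp, p1, spc_hyper(seed = 61))
  r2 <- sort_block(sp, p2, spc_hyper(seed = 61))
  # pass 1 of both runs is identical; pass 2 can only assign more
  expect_lte(sum(r2$assignment == 0), sum(r1$assignment == 0))
  expect_equal(length(r2$assignment), n_spikes(sp))
  # spikes assigned in pass 1 keep their cluster in the N_rep = 2 run
  expect_true(all(r2$assignment[r1$assignment > 0] > 0))
})
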