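make_sorting <- function(times, cluster, group = NULL) {
  ids <- sort(unique(cluster[cluster > 0]))
  if (!length(ids)) {
    sp <- data.frame(time = times, cluster_id = cluster,
                     original_cluster_id = cluster, block_index = 1L,
                     assign_stage = "residual")
    return(sorting_result(sp, blocksort:::empty_cluster_table(),
                          matrix(numeric(0), 0, 8)))
  }
  if (is.null(group)) group <- ids
  cl <- data.frame(cluster_id = ids, block_index = 1L,
                   size = as.integer(table(factor(cluster,
                                                  levels = ids))),
                   artifact = FALSE, criteria = "",
                   group_id = group)
  sp <- data.frame(time = times, cluster_id = cluster,
                   original_cluster_id = cluster, block_index = 1L,
                   assign_stage = ifelse(cluster > 0, "SPC",
                                         "residual"))
  sorting_result(sp, cl, matrix(0, length(ids), 8))
}

make_truth <- function(times, neuron) {
  structure(list(spikes = data.frame(neuron = neuron, time = times),
                 duration_ms = max(times) + 1,
                 n_neurons = length(unique(neuron))),
            class = "bs_ground_truth")
}

test_that("hit rule: 50% purity and 50% completeness, both required", {
  # a unit capturing 38012 of a 40200-spike neuron plus 399 strays is
  # a hit with purity ~0.99 and completeness ~0.95 (scaled down 1:100)
  n_in <- 380
  n_stray <- 4
  n_missed <- 22
  t_unit <- seq_len(n_in + n_stray)
  t_missed <- n_in + n_stray + seq_len(n_missed)
  truth <- make_truth(c(t_unit[1:n_in], t_missed,
                        t_unit[n_in + 1:n_stray] + 0.4),
                      c(rep(1L, n_in + n_missed), rep(2L, n_stray)))
  srt <- make_sorting(c(t_unit, t_missed),
                      c(rep(1L, n_in + n_stray), rep(0L, n_missed)))
  rep <- score_hits(srt, truth)
  u <- rep$units[rep$units$unit == 1, ]
  expect_equal(u$neuron, 1L)
  expect_equal(u$purity, n_in / (n_in + n_stray))
  expect_equal(u$completeness, n_in / (n_in + n_missed))
  expect_true(u$hit)

  # perfect sorting of n neurons: n hits, fraction 1
  truth2 <- make_truth(1:60, rep(1:3, each = 20))
  srt2 <- make_sorting(1:60, rep(1:3, each = 20))
  rep2 <- score_hits(srt2, truth2)
  expect_equal(rep2$summary$n_hits, 3L)
  expect_equal(rep2$summary$hit_fraction, 1)

  # 49% purity is not a hit: 49 spikes from the unit's best neuron,
  # 51 unmatched noise events
  truth3 <- make_truth(1:49, rep(1L, 49))
  srt3 <- make_sorting(c(1:49, 1000 + 1:51), rep(1L, 100))
  u3 <- score_hits(srt3, truth3)$units
  expect_equal(u3$purity[1], 0.49)
  expect_false(u3$hit[1])

  # empty sorting: defined report with zero hits
  srt4 <- make_sorting(1:10, rep(0L, 10))
  rep4 <- score_hits(srt4, truth2)
  expect_equal(rep4$summary$n_hits, 0L)
})

test_that("hit scoring agrees with the contingency-table oracle", {
  # exhaustive over all label assignments of 6 spikes to 2 units and
  # 2 neurons (units may also leave spikes unassigned)
  grid <- expand.grid(rep(list(0:2), 3))
  for (ui in seq_len(nrow(grid))) {
    unit_lab <- c(as.integer(grid[ui, ]), 1L, 2L, 2L)
    for (ni in 1:8) {
      set.seed(ni)
      neuron_lab <- sample(1:2, 6, replace = TRUE)
      srt <- make_sorting(1:6, unit_lab)
      truth <- make_truth(1:6, neuron_lab)
      got <- score_hits(srt, truth)$summary
      want <- oracle_hits(unit_lab, neuron_lab, 2)
      expect_equal(got$n_hits, want$n_hits,
                   info = paste("grid", ui, "labels", ni))
    }
  }
})

test_that("time matching tolerates jitter and is one-to-one", {
  truth <- make_truth(c(10, 20, 30), c(1L, 1L, 1L))
  # sorted spikes jittered by 0.3 ms still match; 0.8 ms does not
  srt <- make_sorting(c(10.3, 20.8, 30.1), c(1L, 1L, 1L))
  rep <- score_hits(srt, truth, tol_ms = 0.5)
  expect_equal(rep$units$purity, 2 / 3)
  # two sorted spikes cannot claim the same truth spike
  srt2 <- make_sorting(c(10.1, 10.2), c(1L, 1L))
  rep2 <- score_hits(srt2, make_truth(10, 1L), tol_ms = 0.5)
  expect_equal(rep2$units$purity, 1 / 2)
})

test_that("BH adjustment equals the closed-form step-up", {
  expect_equal(bh_adjust(rep(0.03, 7)), rep(0.03, 7))
  p <- c(0.01, 0.02, 0.03, 0.04)
  # hand-computed step-up: m * p_(j) / j minimized over j >= rank
  expect_equal(bh_adjust(p), c(0.04, 0.04, 0.04, 0.04))
  set.seed(12)
  for (case in 1:30) {
    p <- runif(sample(3:25, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), info = paste("case", case))
    expect_true(all(adj >= p - 1e-12))
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.1, -0.2)), "0, 1")
})

test_that("response score flags strong responses and not null firing", {
  rp <- response_params()
  onsets <- seq(5000, by = 5000, length.out = 6)
  set.seed(4)
  # null: homogeneous 5 Hz Poisson firing throughout
  null_spikes <- sort(runif(200, 0, 40000))
  r0 <- response_score(null_spikes, onsets, rp)
  expect_false(r0$is_response)
  expect_length(r0$p_adj, 19)

  # strong: 2 Hz baseline with a 20 Hz burst in every presentation
  base <- sort(runif(80, 0, 40000))
  burst <- unlist(lapply(onsets, function(on)
    on + sort(runif(20, 0, 1000))))
  r1 <- response_score(sort(c(base, burst)), onsets, rp)
  expect_true(r1$is_response)
  expect_lt(r1$score, 0.001)

  # firing in only 3 of 6 presentations is never a response
  burst3 <- unlist(lapply(onsets[1:3], function(on)
    on + sort(runif(40, 0, 1000))))
  r3 <- response_score(sort(burst3), onsets, rp)
  expect_equal(r3$n_fired, 3L)
  expect_false(r3$is_response)
})

test_that("the null false-positive rate of the response score is low", {
  rp <- response_params()
  onsets <- seq(3000, by = 3000, length.out = 6)
  set.seed(99)
  n_sim <- 1000
  fp <- 0
  for (i in seq_len(n_sim)) {
    spikes <- sort(runif(rpois(1, 60), 0, 21000))
    if (response_score(spikes, onsets, rp)$is_response)
      fp <- fp + 1
  }
  expect_lt(fp / n_sim, 0.005)
})
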