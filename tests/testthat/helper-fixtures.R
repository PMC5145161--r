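# Shared fixtures, generated in code at test time.

# Two well-separated spherical Gaussian blobs in d dimensions.
make_blobs <- function(n_per = 500, d = 10, sep = 10, seed = 7) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d), ncol = d),
             matrix(rnorm(n_per * d, mean = sep), ncol = d))
  list(x = x, truth = rep(1:2, each = n_per))
}

# A tiny spike set with known waveforms: scaled copies of a smooth
# biphasic template plus noise.
make_toy_spikes <- function(n = 60, k = 48, amp = 80, noise = 2,
                            seed = 1, t_start = 0, spacing = 20) {
  set.seed(seed)
  tpl <- make_templates(1, rate = 24000, peak_uv = amp, dur_ms = 2,
                        peak_ms = 0.5, seed = seed)[1, seq_len(k)]
  wf <- matrix(rep(tpl, each = n), n, k) +
    matrix(rnorm(n * k, sd = noise), n, k)
  spike_set(wf, t_start + spacing * (seq_len(n) - 1),
            rate_eff = 24000)
}

# Simulation-derived spike fixtures, built once per test run. Each is
# a small ground-truth recording pushed through filtering, detection,
# extraction and pre-sorting artifact rejection, with every surviving
# spike labelled by its nearest ground-truth spike (0 = unmatched,
# i.e. noise/hash detections).
.fixture_cache <- new.env(parent = emptyenv())

sim_spikes_fixture <- function(name) {
  if (!is.null(.fixture_cache[[name]])) return(.fixture_cache[[name]])
  cfg <- switch(name,
    three_neurons = sim_config(n_neurons = 3, rates = c(1.5, 2.5, 3.5),
                               peak_uv = c(60, 85, 110),
                               duration = 240, mua_rate = 10,
                               seed = 77),
    two_templates = sim_config(n_neurons = 2, rates = c(5, 5),
                               peak_uv = c(70, 100), duration = 300,
                               mua_rate = 15, seed = 9),
    stop("unknown fixture ", name))
  ds <- make_dataset(cfg)
  sp <- extract_channel(ds$recording, 1,
                        detect_params(sign = "positive"))$positive
  rej <- reject_artifacts(sp)
  sp <- rej$spikes
  m <- blocksort:::match_times(sp$times, ds$truth$spikes$time, 0.5)
  lab <- ifelse(is.na(m), 0L, ds$truth$spikes$neuron[m])
  out <- list(ds = ds, spikes = sp, lab = lab)
  .fixture_cache[[name]] <- out
  out
}

# Cluster purity against known labels.
purity_of <- function(members_truth) {
  if (!length(members_truth)) return(NA_real_)
  max(table(members_truth)) / length(members_truth)
}
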