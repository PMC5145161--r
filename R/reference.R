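#' Reference study configurations
#'
#' The package ships two fixed, documented reference configurations
#' used by its validation suite and by `scripts/acceptance.R`. They
#' are part of the package's contract: the methods vignette discusses
#' every choice.
#'
#' `ref_recording_config()` describes a screening-style single
#' channel: five template neurons (peak amplitudes 60-110 uV over a
#' 10 uV broadband noise floor, firing at 0.5-3 Hz) recorded for ten
#' minutes at 24 kHz with multi-unit hash, plus injected artifacts —
#' sinusoidal 900 Hz line-noise bursts (inside the analysis band, so
#' they survive filtering and form stereotyped artifact clusters) and
#' 3 mV transients (above the 1 mV amplitude-exclusion criterion
#' after filtering).
#'
#' `ref_concurrent_config()` describes a short 16-channel recording
#' whose channels share simultaneous moderate-amplitude transients on
#' half the array — the situation the cross-channel concurrency
#' criterion exists for.
#'
#' `ref_multihour_base()` describes the base recording for the
#' multi-hour tracking protocol: the protocol's smallest instance, two
#' well-separated template neurons (distinct widths, trough delays and
#' depths; peaks 110 and 140 uV) firing at 2-2.5 Hz for three minutes.
#' Amplitudes are deliberately similar and large: the protocol adds
#' waveform noise proportional to the *maximum* value attained, so a
#' small-amplitude unit is drowned by the noise of a large one, and
#' templates must differ by shape.
#'
#' @param seed integer seed controlling the simulated recording.
#' @return a [sim_config()].
#' @export
ref_recording_config <- function(seed = 1) {
  sim_config(n_neurons = 5, duration = 600, seed = seed,
             artifact_spec = list(
               line_noise = list(n = 20, freq = 900, amp = 80,
                                 dur_ms = 50),
               transients = list(n = 30, amp = 3000)))
}

#' @rdname ref_recording_config
#' @export
ref_concurrent_config <- function(seed = 1) {
  sim_config(n_neurons = 3, duration = 60, n_channels = 16,
             seed = seed,
             artifact_spec = list(
               concurrent = list(n = 30, amp = 500, frac = 0.5)))
}

#' @rdname ref_recording_config
#' @export
ref_multihour_base <- function(seed = 1) {
  tpl <- make_templates(2, 24000, peak_uv = c(110, 140),
                        shape = list(w1 = c(0.20, 0.35),
                                     d = c(0.35, 0.70),
                                     w2 = c(0.30, 0.55),
                                     r = c(0.45, 0.30),
                                     pre = c(0.25, 0)))
  sim_config(n_neurons = 2, rates = c(2, 2.5), peak_uv = c(110, 140),
             mua_rate = 5, mua_peak_uv = 15, duration = 180,
             templates = tpl, seed = seed)
}

#' Reference sorting parameters
#'
#' `ref_sort_params()` are the settings used for short simulated
#' recordings with many clusters (more clusters per temperature,
#' aggressive re-clustering, a second clustering pass, and a strict
#' merge threshold). `ref_multihour_params()` additionally shrinks the
#' block size so that one block spans little amplitude drift, which is
#' the premise of block-wise tracking: at the reference scale one
#' block corresponds roughly to one concatenated repetition.
#'
#' @return a [sort_params()].
#' @export
ref_sort_params <- function() {
  sort_params(C_max = 7, R_min = 500, N_rep = 2, C_stop = 1.2)
}

#' @rdname ref_sort_params
#' @export
ref_multihour_params <- function() {
  sort_params(N_block = 2500, C_max = 7, R_min = 500, N_rep = 1,
              C_stop = 1.4)
}
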