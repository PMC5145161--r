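#' Orthonormal Haar wavelet decomposition
#'
#' Multi-level discrete Haar transform of one waveform. Coefficients
#' are returned as `c(approximation, detail_L, ..., detail_1)` with the
#' coarsest coefficients first. The transform is orthonormal, so the
#' sum of squared coefficients equals the sum of squared samples. A
#' waveform whose length is not divisible by `2^levels` is zero-padded
#' (with a warning) to the next multiple.
#'
#' @param x numeric vector of samples.
#' @param levels decomposition depth.
#' @return numeric coefficient vector (length = padded input length).
#' @export
haar_decompose <- function(x, levels = 4) {
  block <- 2^levels
  if (length(x) %% block != 0) {
    pad <- block - length(x) %% block
    warning("length ", length(x), " not divisible by ", block,
            "; zero-padding ", pad, " samples")
    x <- c(x, numeric(pad))
  }
  s <- x
  details <- vector("list", levels)
  for (l in seq_len(levels)) {
    odd <- s[seq(1, length(s), by = 2)]
    even <- s[seq(2, length(s), by = 2)]
    details[[l]] <- (odd - even) / sqrt(2)
    s <- (odd + even) / sqrt(2)
  }
  c(s, unlist(rev(details)))
}

#' Wavelet coefficients of a spike set
#'
#' Computes the four-level Haar decomposition of every spike, yielding
#' an `n x k` coefficient matrix (one coefficient per original sampling
#' point).
#'
#' @param spikes a [spike_set()] or a waveform matrix with at least 16
#'   samples per row.
#' @param levels decomposition depth.
#' @return numeric coefficient matrix, one row per spike.
#' @export
wavelet_features <- function(spikes, levels = 4) {
  wf <- if (inherits(spikes, "bs_spikes")) spikes$waveforms else
    as.matrix(spikes)
  if (ncol(wf) < 16)
    stop("waveforms must have at least 16 samples for a 4-level ",
         "decomposition")
  t(apply(wf, 1, haar_decompose, levels = levels))
}

#' Deviation from normality of one coefficient
#'
#' Kolmogorov-Smirnov statistic of a sample against a normal
#' distribution with the sample's own mean and standard deviation
#' (Lilliefors-style). A zero-variance sample has statistic 0 so it is
#' never selected over varying coefficients.
#'
#' @param x numeric vector.
#' @return the KS statistic `D` in `[0, 1]`.
#' @export
ks_normal_stat <- function(x) {
  n <- length(x)
  if (n < 2L) return(0)
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(0)
  z <- sort((x - mean(x)) / s)
  cdf <- pnorm(z)
  i <- seq_len(n)
  max(i / n - cdf, cdf - (i - 1) / n)
}

#' Select wavelet features by deviation from normality
#'
#' A coefficient in which spikes of several neurons are mixed is
#' multimodal, hence far from normal; a coefficient carrying only noise
#' is approximately normal. For each coefficient the KS statistic
#' against a fitted normal is computed and the `d` coefficients with
#' the largest statistics are selected (ties broken by lower
#' coefficient index).
#'
#' @param coeffs `n x k` wavelet coefficient matrix.
#' @param d number of dimensions to keep.
#' @return an object of class `bs_features`: list with `values` (the
#'   `n x d` selected sub-matrix), `selected` (chosen coefficient
#'   indices) and `ks` (all `k` statistics).
#' @export
select_features_ks <- function(coeffs, d = 10) {
  coeffs <- as.matrix(coeffs)
  k <- ncol(coeffs)
  d <- min(d, k)
  ks <- apply(coeffs, 2, ks_normal_stat)
  sel <- order(-ks, seq_len(k))[seq_len(d)]
  structure(list(values = coeffs[, sel, drop = FALSE], selected = sel,
                 ks = ks),
            class = "bs_features")
}
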