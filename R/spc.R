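#' Superparamagnetic clustering over a temperature sweep
#'
#' Runs the Potts-model Swendsen-Wang simulation on the mutual
#' nearest-neighbour interaction graph of the feature vectors, once per
#' temperature, and reads out clusters as connected components of point
#' pairs whose spin-spin correlation exceeds `corr_thresh`. Low
#' temperatures give a single cluster (the ferromagnetic phase), high
#' temperatures fragment the data; informative cluster structure lives
#' at intermediate temperatures.
#'
#' The interaction strength between neighbours `i` and `j` is
#' `J_ij = (1/K) exp(-d_ij^2 / (2 a^2))` with `a` the mean
#' nearest-neighbour distance and `K` the mean degree of the graph; a
#' minimum spanning tree is unioned into the graph so it is always
#' connected. The simulation uses a self-contained RNG, so the result
#' is fully determined by `(features, params, hyper)`.
#'
#' @param features a `bs_features` object from [select_features_ks()],
#'   or a numeric matrix (one row per spike).
#' @param params a [sort_params()] object (supplies `n_T` and
#'   `T_range`).
#' @param hyper a [spc_hyper()] object.
#' @return an object of class `bs_spc`: list with `temperatures`
#'   (length `n_T`), `labels` (`n_T x n` integer matrix; each row is a
#'   partition with cluster 1 the largest) and `sizes` (per-temperature
#'   integer vectors of cluster sizes, descending).
#' @export
spc_run <- function(features, params = sort_params(),
                    hyper = spc_hyper()) {
  x <- if (inherits(features, "bs_features")) features$values else
    as.matrix(features)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 points to cluster")
  complete <- FALSE
  if (n < hyper$k_nn + 1) {
    warning("fewer points than k_nn + 1; using the complete graph")
    complete <- TRUE
  }
  temps <- seq(params$T_range[1], params$T_range[2],
               length.out = params$n_T)
  labels <- .spc_sw_cpp(x, temps, hyper$q, hyper$k_nn, hyper$sweeps,
                        hyper$burnin, hyper$corr_thresh,
                        as.numeric(hyper$seed), complete)
  sizes <- apply(labels, 1, function(l)
    sort(tabulate(l), decreasing = TRUE), simplify = FALSE)
  structure(list(temperatures = temps, labels = labels,
                 sizes = sizes),
            class = "bs_spc")
}

#' @export
print.bs_spc <- function(x, ...) {
  cat(sprintf("<bs_spc> %d points, %d temperatures in [%g, %g]\n",
              ncol(x$labels), length(x$temperatures),
              min(x$temperatures), max(x$temperatures)))
  invisible(x)
}
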