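#' Construct a continuous recording
#'
#' A recording holds one voltage trace per channel, all in microvolts
#' and all of equal length, together with the sampling rate.
#'
#' @param samples a numeric vector (single channel) or list of numeric
#'   vectors (one per channel), in microvolts.
#' @param rate sampling frequency in Hz.
#' @param channel_ids optional channel labels; defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @param start_time offset of the first sample from the session start,
#'   in seconds.
#'
#' @return An object of class `bs_recording`.
#' @export
recording <- function(samples, rate, channel_ids = NULL,
                      start_time = 0) {
  if (is.numeric(samples)) samples <- list(samples)
  if (!is.list(samples) || !length(samples))
    stop("samples must be a numeric vector or a non-empty list of them")
  if (is.null(channel_ids))
    channel_ids <- paste0("ch", seq_along(samples))
  if (length(channel_ids) != length(samples))
    stop("channel_ids length does not match number of channels")
  samples <- lapply(samples, as.numeric)
  names(samples) <- channel_ids
  rec <- structure(list(samples = samples, rate = as.numeric(rate),
                        channel_ids = as.character(channel_ids),
                        start_time = as.numeric(start_time)),
                   class = "bs_recording")
  validate_recording(rec)
}

validate_recording <- function(rec) {
  if (rec$rate <= 0) stop("sampling rate must be positive")
  lens <- vapply(rec$samples, length, integer(1))
  if (length(unique(lens)) > 1L)
    stop("channel length mismatch: ",
         paste(sprintf("%s=%d", rec$channel_ids, lens), collapse = ", "))
  for (i in seq_along(rec$samples))
    if (anyNA(rec$samples[[i]]) || !all(is.finite(rec$samples[[i]])))
      stop("non-finite samples in channel ", rec$channel_ids[i])
  rec
}

#' @export
print.bs_recording <- function(x, ...) {
  n <- length(x$samples[[1]])
  cat(sprintf(
    "<bs_recording> %d channel(s), %d samples @ %g Hz (%.1f s)\n",
    length(x$samples), n, x$rate, n / x$rate))
  invisible(x)
}

#' Number of samples per channel
#' @param rec a `bs_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(rec) length(rec$samples[[1]])

#' Write a recording to a flat-binary container
#'
#' The container is a directory holding `samples.bin` (channels stored
#' sequentially, little-endian) plus a `meta.json` sidecar with the
#' sampling rate, channel labels, sample count, on-disk data type and
#' per-channel gain. `float64` storage is lossless; `int16` stores
#' quantized samples with a per-channel gain in uV per bit (the format
#' used by many acquisition systems).
#'
#' @param rec a `bs_recording`.
#' @param path directory to create.
#' @param dtype on-disk sample type, `"float64"` or `"int16"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, dtype = c("float64", "int16")) {
  dtype <- match.arg(dtype)
  validate_recording(rec)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n <- n_samples(rec)
  gains <- rep(1, length(rec$samples))
  con <- file(file.path(path, "samples.bin"), "wb")
  on.exit(close(con))
  for (i in seq_along(rec$samples)) {
    x <- rec$samples[[i]]
    if (dtype == "int16") {
      m <- max(abs(x), 1e-12)
      gains[i] <- m / 32000
      writeBin(as.integer(round(x / gains[i])), con, size = 2L,
               endian = "little")
    } else {
      writeBin(as.numeric(x), con, size = 8L, endian = "little")
    }
  }
  meta <- list(container = "bs_recording", version = 1L,
               rate = rec$rate, channel_ids = rec$channel_ids,
               n_samples = n, dtype = dtype, gain_uv = gains,
               start_time = rec$start_time, byte_order = "little",
               unit = "uV")
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording container
#'
#' Reads the flat-binary + JSON-sidecar container written by
#' [write_recording()] (or by external tools following the same
#' schema). Samples are scaled to microvolts using the sidecar gain, so
#' the in-memory unit is always uV.
#'
#' @param path container directory.
#' @param format container format; only `"flat"` is supported in the
#'   core (`"auto"` infers it from the sidecar).
#' @return A validated `bs_recording`.
#' @export
read_recording <- function(path, format = c("auto", "flat")) {
  format <- match.arg(format)
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path))
    stop("not a recording container (missing meta.json): ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$container, "bs_recording"))
    stop("unknown container format: ",
         if (is.null(meta$container)) "<missing>" else meta$container)
  dtype <- meta$dtype
  if (!dtype %in% c("float64", "int16"))
    stop("unknown sample dtype: ", dtype)
  n <- as.integer(meta$n_samples)
  nch <- length(meta$channel_ids)
  con <- file(file.path(path, "samples.bin"), "rb")
  on.exit(close(con))
  samples <- vector("list", nch)
  for (i in seq_len(nch)) {
    if (dtype == "int16") {
      raw <- readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                     endian = "little")
      if (length(raw) < n) stop("truncated samples.bin in ", path)
      samples[[i]] <- raw * meta$gain_uv[i]
    } else {
      raw <- readBin(con, "numeric", n = n, size = 8L,
                     endian = "little")
      if (length(raw) < n) stop("truncated samples.bin in ", path)
      samples[[i]] <- raw
    }
  }
  recording(samples, rate = meta$rate, channel_ids = meta$channel_ids,
            start_time = meta$start_time %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
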