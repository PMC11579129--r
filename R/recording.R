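#' Multichannel epicortical recording
#'
#' Container for a channels x samples matrix in microvolts with its
#' sampling rate, channel labels and good-channel mask.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param fs_hz sampling rate in Hz (> 0).
#' @param channel_id character labels, one per row of `data`.
#' @param good_mask logical, one per channel; `NULL` means all good.
#' @param units signal units; only `"uV"` is used by the pipeline.
#' @return An object of class `ecog_recording`.
#' @export
recording <- function(data, fs_hz, channel_id = NULL, good_mask = NULL,
                      units = "uV") {
  data <- as.matrix(data)
  if (!is.numeric(fs_hz) || fs_hz <= 0) stop("fs_hz must be positive")
  n_ch <- nrow(data)
  if (is.null(channel_id)) channel_id <- sprintf("E%03d", seq_len(n_ch))
  if (length(channel_id) != n_ch)
    stop("channel_id length must equal channel count")
  if (is.null(good_mask)) good_mask <- rep(TRUE, n_ch)
  if (length(good_mask) != n_ch)
    stop("good_mask length must equal channel count")
  if (any(!is.finite(data[good_mask, , drop = FALSE])))
    stop("good channels must contain finite values")
  structure(list(data = data, fs_hz = fs_hz,
                 channel_id = as.character(channel_id),
                 good_mask = as.logical(good_mask), units = units),
            class = "ecog_recording")
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf("<ecog_recording> %d channels x %d samples @ %g Hz (%s), %d good\n",
              nrow(x$data), ncol(x$data), x$fs_hz, x$units, sum(x$good_mask)))
  invisible(x)
}

#' @export
plot.ecog_recording <- function(x, channels = 1:min(6, nrow(x$data)),
                                t_max_s = 2, ...) {
  n <- min(ncol(x$data), round(t_max_s * x$fs_hz))
  t <- (seq_len(n) - 1) / x$fs_hz
  sub <- x$data[channels, seq_len(n), drop = FALSE]
  off <- 3 * stats::median(apply(sub, 1, stats::sd))
  graphics::matplot(t, t(sub + off * (seq_along(channels) - 1)), type = "l",
                    lty = 1, xlab = "time (s)", ylab = "signal + offset", ...)
  invisible(x)
}

#' Write/read a recording as raw binary + JSON sidecar
#'
#' The container is a little-endian float64 matrix written sample-major
#' (channel 1 sample 1, channel 2 sample 1, ...) in `<path>.bin`, with a
#' JSON sidecar `<path>.json` holding `fs_hz`, `channel_id`, `good_mask`,
#' `units` and `n_samples`. The round trip is bit-identical.
#'
#' @param rec an `ecog_recording`.
#' @param path base path (extensions are appended).
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an `ecog_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ecog_recording"))
  meta <- list(fs_hz = rec$fs_hz, channel_id = rec$channel_id,
               good_mask = rec$good_mask, units = rec$units,
               n_channels = nrow(rec$data), n_samples = ncol(rec$data),
               byte_order = "little", dtype = "float64")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta_path <- paste0(path, ".json")
  bin_path <- paste0(path, ".bin")
  if (!file.exists(meta_path) || !file.exists(bin_path))
    stop("recording container not found at ", path, " (.json/.bin)")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$fs_hz)) stop("sidecar is missing fs_hz")
  n <- meta$n_channels * meta$n_samples
  con <- file(bin_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n, size = 8, endian = "little")
  if (length(vals) != n)
    stop(sprintf("binary payload has %d values, sidecar promises %d",
                 length(vals), n))
  recording(matrix(vals, nrow = meta$n_channels),
            fs_hz = as.numeric(meta$fs_hz), channel_id = meta$channel_id,
            good_mask = meta$good_mask, units = meta$units)
}

#' Read/write trial event tables
#'
#' BIDS-style `_events.tsv` with columns `onset` (s), `duration` (s) and
#' `trial_type`.
#'
#' @param events data frame with `onset`, `duration`, `trial_type`.
#' @param path file path.
#' @export
write_events <- function(events, path) {
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(events)))
    stop("events must have columns onset, duration, trial_type")
  utils::write.table(events[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("onset", "duration", "trial_type") %in% names(df)))
    stop("events table must have columns onset, duration, trial_type")
  df[order(df$onset), , drop = FALSE]
}
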