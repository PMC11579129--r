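#' Mean band power per trial and channel
#'
#' Morlet band power (default 64-128 Hz, the marker of local neural
#' activity) averaged over the samples of each epoch, one value per
#' (trial, channel).
#'
#' @param trials a `trial_set` of voltage epochs (fixed 1.5 s scheme for
#'   the task analysis).
#' @param band numeric `c(low_hz, high_hz)`.
#' @param n_cycles,n_freqs Morlet parameters, see [morlet_band_power()].
#' @param log take `log` of the power values (off by default; raw power is
#'   what enters the standard analysis).
#' @return Numeric matrix, trials x channels, with trial labels in
#'   attribute `label`.
#' @export
trial_band_power <- function(trials, band = c(64, 128), n_cycles = 7,
                             n_freqs = 5, log = FALSE) {
  stopifnot(inherits(trials, "trial_set"))
  n_tr <- dim(trials$epochs)[1]
  if (n_tr == 0 || dim(trials$epochs)[3] == 0) stop("empty trial set")
  out <- matrix(0, n_tr, dim(trials$epochs)[2],
                dimnames = list(NULL, trials$channel_id))
  for (k in seq_len(n_tr)) {
    rec <- recording(trials$epochs[k, , , drop = TRUE], fs_hz = trials$fs_hz,
                     channel_id = trials$channel_id,
                     good_mask = trials$good_mask)
    pw <- morlet_band_power(rec, band, n_cycles = n_cycles, n_freqs = n_freqs)
    out[k, ] <- rowMeans(pw$data)
  }
  if (log) out <- base::log(out)
  attr(out, "label") <- trials$label
  attr(out, "band") <- band
  out
}

#' Signed R-squared task-response map
#'
#' Correlates each channel's per-trial band power with a binary task
#' regressor (0 rest, 1 active) using Pearson's r; the signed coefficient
#' of determination is `sign(r) * r^2`. Two-sided p-values come from the
#' t-distribution, `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of
#' freedom (`|r| = 1` gives p = 0). Significance is Bonferroni-corrected
#' by the number of channels entering the analysis; zero-variance channels
#' are reported untested and do not reduce the denominator.
#'
#' @param powers trials x channels matrix from [trial_band_power()].
#' @param labels binary (0/1 or rest/active) regressor per trial; defaults
#'   to the labels attached to `powers`.
#' @param alpha significance level before correction.
#' @param n_channels Bonferroni denominator (defaults to the number of
#'   channels in `powers`).
#' @return An object of class `task_response_map`: data frame with columns
#'   `channel`, `r`, `signed_r2`, `p_value`, `significant`, and metadata
#'   attributes `band`, `n_trials`, `alpha`, `n_channels_tested`.
#' @export
signed_r2_map <- function(powers, labels = attr(powers, "label"),
                          alpha = 0.05, n_channels = ncol(powers)) {
  if (is.factor(labels) || is.character(labels))
    labels <- as.integer(as.character(labels) == "active")
  labels <- as.numeric(labels)
  n <- nrow(powers)
  if (n < 3) stop("need at least 3 trials")
  if (length(labels) != n) stop("labels length must match trial count")
  if (length(unique(labels)) < 2) stop("both rest and active labels required")
  r <- rep(NA_real_, ncol(powers))
  testable <- apply(powers, 2, stats::sd) > 0
  r[testable] <- suppressWarnings(as.vector(stats::cor(powers[, testable,
                                                              drop = FALSE],
                                                       labels)))
  p <- rep(NA_real_, length(r))
  sat <- !is.na(r) & abs(r) >= 1 - 1e-15
  p[sat] <- 0
  reg <- !is.na(r) & !sat
  tval <- r[reg] * sqrt((n - 2) / (1 - r[reg]^2))
  p[reg] <- 2 * stats::pt(-abs(tval), df = n - 2)
  thresh <- alpha / n_channels
  out <- data.frame(channel = colnames(powers), r = r,
                    signed_r2 = sign(r) * r^2, p_value = p,
                    significant = !is.na(p) & p < thresh,
                    stringsAsFactors = FALSE)
  attr(out, "band") <- attr(powers, "band")
  attr(out, "n_trials") <- n
  attr(out, "alpha") <- alpha
  attr(out, "n_channels_tested") <- n_channels
  class(out) <- c("task_response_map", "data.frame")
  out
}

#' @export
print.task_response_map <- function(x, ...) {
  cat(sprintf("<task_response_map> %d channels, %d trials, alpha = %g / %d channels\n",
              nrow(x), attr(x, "n_trials"), attr(x, "alpha"),
              attr(x, "n_channels_tested")))
  cat(sprintf("  significant: %d; untested (zero variance): %d\n",
              sum(x$significant, na.rm = TRUE), sum(is.na(x$r))))
  invisible(x)
}

#' Flat-map plot of a task-response map on its grid
#'
#' Draws the electrodes at their planar coordinates, coloured by signed
#' R-squared and circled when significant. No brain-surface rendering.
#'
#' @param x a `task_response_map`.
#' @param layout the [electrode_layout] the channels belong to.
#' @param ... passed to [graphics::plot()].
#' @export
plot.task_response_map <- function(x, layout, ...) {
  idx <- match(x$channel, layout$name)
  v <- x$signed_r2
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(101)
  col <- pal[round(50 * pmax(-1, pmin(1, v)) + 51)]
  col[is.na(v)] <- "grey60"
  graphics::plot(layout$x[idx], layout$y[idx], pch = 21, bg = col,
                 cex = 1 + 1.5 * abs(v), asp = 1, xlab = "x (mm)",
                 ylab = "y (mm)", ...)
  sig <- which(x$significant)
  if (length(sig))
    graphics::points(layout$x[idx[sig]], layout$y[idx[sig]], pch = 1,
                     cex = 2.2, lwd = 2)
  invisible(x)
}

#' Write a task-response map as TSV
#' @param x a `task_response_map`.
#' @param path output path.
#' @export
write_task_map <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
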