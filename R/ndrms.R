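#' Z-normalize a trial signal
#'
#' Centres by the trial mean and scales by the population (divide-by-N)
#' standard deviation, so the output has mean 0 and sd 1 exactly at finite
#' length. The population denominator makes the identity
#' `ndRMS = sqrt(2(1 - r))` and the theoretical bounds 0 / sqrt(2) / 2
#' exact rather than asymptotic.
#'
#' @param series numeric vector, length >= 2, non-constant.
#' @return Normalized numeric vector with attributes `mu` and `sigma`.
#' @export
znormalize <- function(series) {
  n <- length(series)
  if (n < 2) stop("series must have length >= 2")
  mu <- mean(series)
  centred <- series - mu
  sigma <- sqrt(mean(centred^2))
  if (is_degenerate_series(centred, sigma))
    stop("degenerate (constant) series cannot be z-normalized")
  out <- centred / sigma
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  out
}

# constant within 1e-12 of the series scale
is_degenerate_series <- function(centred, sigma) {
  scale <- max(abs(centred))
  scale == 0 || sigma < 1e-12 * scale
}

#' ndRMS between two signals
#'
#' The normalized differential root mean square: the RMS of the difference
#' between the two z-normalized signals. Bounded by 0 (identical up to a
#' positive affine transform), sqrt(2) (uncorrelated signals, e.g.
#' independent white noise) and 2 (exact antiphase). Symmetric in its
#' arguments.
#'
#' @param x,y numeric vectors of equal length, both non-constant.
#' @return ndRMS value in \[0, 2\].
#' @seealso [ndrms_oracle()] for the closed-form correlation identity.
#' @export
ndrms_pair <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  zx <- znormalize(x)
  zy <- znormalize(y)
  sqrt(mean((zx - zy)^2))
}

#' Correlation-identity oracle for the ndRMS
#'
#' Computes `sqrt(2 * (1 - r))` with `r` the Pearson correlation of the two
#' signals. With population z-normalization this equals [ndrms_pair()] to
#' numerical precision; it is kept as an independent verification route,
#' not as the implementation.
#'
#' @inheritParams ndrms_pair
#' @return ndRMS value in \[0, 2\].
#' @export
ndrms_oracle <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate (constant) series")
  r <- stats::cor(x, y)
  sqrt(max(0, 2 * (1 - r)))
}

#' Per-pair ndRMS over trials or a continuous stream
#'
#' In `awake` mode the ndRMS is computed per rest trial and summarized per
#' pair as the median over trials (midpoint of the two central values for
#' even counts). In `stream` mode (recordings under general anesthesia)
#' the ndRMS is computed once across the entire recording, one value per
#' pair. Pair-trials with a degenerate (constant) channel are excluded
#' from the median; a pair is dropped entirely when more than half of its
#' trials are degenerate or no valid trial remains.
#'
#' @param data a `trial_set` (awake) or an `ecog_recording` (stream); band
#'   filtering is applied upstream.
#' @param pairs a `pair_table` from [pair_distance_table()].
#' @param band band label carried into the output (e.g. `"unfiltered"`).
#' @param mode `"awake"` or `"stream"`; defaults to the type of `data`.
#' @param labels trial labels used in awake mode (default `"rest"`).
#' @return An object of class `pair_ndrms`: data frame with columns `a`,
#'   `b`, `distance_mm`, `band`, `n_trials`, `ndrms`, plus attribute
#'   `per_trial` (pairs x trials matrix, awake mode). Dropped pairs are
#'   absent; their names are in attribute `dropped`.
#' @export
ndrms_per_pair <- function(data, pairs, band = "unfiltered",
                           mode = c("awake", "stream"), labels = "rest") {
  if (inherits(data, "ecog_recording")) mode <- "stream"
  else mode <- match.arg(mode)
  if (mode == "stream") {
    chans <- list(data$data)
    ch_id <- data$channel_id
  } else {
    stopifnot(inherits(data, "trial_set"))
    keep <- which(data$label %in% labels)
    if (length(keep) == 0) stop("no trials with the requested label")
    chans <- lapply(keep, function(k) data$epochs[k, , ])
    ch_id <- data$channel_id
  }
  n_tr <- length(chans)
  ia <- match(pairs$a, ch_id)
  ib <- match(pairs$b, ch_id)
  if (anyNA(ia) || anyNA(ib))
    stop("pair table refers to channels absent from the data")
  # z-normalize each trial once per channel; NA rows mark degenerate trials
  znorm_mat <- function(m) {
    mu <- rowMeans(m)
    c_ <- m - mu
    sg <- sqrt(rowMeans(c_^2))
    bad <- sg == 0 | sg < 1e-12 * apply(abs(c_), 1, max)
    out <- c_ / sg
    out[bad, ] <- NA_real_
    out
  }
  per_trial <- matrix(NA_real_, nrow(pairs), n_tr)
  for (tr in seq_len(n_tr)) {
    z <- znorm_mat(chans[[tr]])
    # direct RMS of the normalized difference, chunked over pairs
    idx <- seq_len(nrow(pairs))
    for (chunk in split(idx, ceiling(idx / 512))) {
      d <- z[ia[chunk], , drop = FALSE] - z[ib[chunk], , drop = FALSE]
      per_trial[chunk, tr] <- sqrt(rowMeans(d^2))
    }
  }
  n_valid <- rowSums(!is.na(per_trial))
  drop <- n_valid == 0 | (n_tr - n_valid) / n_tr > 0.5
  summ <- apply(per_trial, 1, stats::median, na.rm = TRUE)
  out <- data.frame(a = pairs$a, b = pairs$b,
                    distance_mm = pairs$distance_mm,
                    band = band, n_trials = n_valid,
                    ndrms = summ, stringsAsFactors = FALSE)[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "per_trial") <- per_trial[!drop, , drop = FALSE]
  attr(out, "mode") <- mode
  attr(out, "dropped") <- paste(pairs$a[drop], pairs$b[drop], sep = "-")
  class(out) <- c("pair_ndrms", "data.frame")
  out
}

#' Write per-pair ndRMS values as TSV
#' @param x a `pair_ndrms` object.
#' @param path output path.
#' @export
write_pair_ndrms <- function(x, path) {
  utils::write.table(as.data.frame(x)[, c("a", "b", "distance_mm", "band",
                                          "n_trials", "ndrms")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
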