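#' Dyadic frequency band table
#'
#' The eight octave bands used throughout the analysis (1-4, 4-8, 8-16,
#' 16-32, 32-64, 64-128, 128-256, 256-499 Hz) plus an `unfiltered`
#' sentinel row, which downstream band operations treat as the identity.
#'
#' @param include_unfiltered include the sentinel row (default TRUE).
#' @return Data frame with columns `band` (label), `low_hz`, `high_hz`
#'   (NA for the sentinel).
#' @export
dyadic_bands <- function(include_unfiltered = TRUE) {
  lows <- c(1, 4, 8, 16, 32, 64, 128, 256)
  highs <- c(4, 8, 16, 32, 64, 128, 256, 499)
  out <- data.frame(band = sprintf("%d-%d", lows, highs),
                    low_hz = lows, high_hz = highs,
                    stringsAsFactors = FALSE)
  if (include_unfiltered)
    out <- rbind(out, data.frame(band = "unfiltered", low_hz = NA_real_,
                                 high_hz = NA_real_))
  out
}

#' Flag bad channels
#'
#' A channel is flagged with one or more reasons:
#' \describe{
#'   \item{flat}{standard deviation below `flat_sd` uV.}
#'   \item{amplitude}{robust amplitude (scaled MAD) more than `amp_mads`
#'     scaled MADs away from the cross-channel median amplitude.}
#'   \item{line_noise}{power at `line_freq` +/- 1 Hz exceeding
#'     `line_ratio` of the total 1-499 Hz power.}
#'   \item{outliers}{more than `outlier_frac` of samples beyond
#'     `outlier_sds` channel standard deviations.}
#' }
#' Thresholds are package defaults, all configurable; the report supports
#' the usual visual confirmation step.
#'
#' @param rec an `ecog_recording` (>= 2 channels).
#' @param flat_sd,amp_mads,line_ratio,line_freq,outlier_frac,outlier_sds
#'   thresholds as described above.
#' @return List with `good_mask` (logical; combines the input mask with new
#'   flags) and `report` (data frame: channel, flagged, reasons).
#' @export
detect_bad_channels <- function(rec, flat_sd = 1e-8, amp_mads = 5,
                                line_ratio = 0.5, line_freq = 50,
                                outlier_frac = 0.01, outlier_sds = 5) {
  stopifnot(inherits(rec, "ecog_recording"))
  n_ch <- nrow(rec$data)
  if (n_ch < 2) stop("need at least 2 channels")
  sds <- apply(rec$data, 1, stats::sd)
  mads <- apply(rec$data, 1, stats::mad)
  flat <- sds < flat_sd
  # amplitude criterion over non-flat channels (flat ones are already out)
  ref <- mads[!flat]
  amp <- !flat & abs(mads - stats::median(ref)) > amp_mads * stats::mad(ref)
  n <- ncol(rec$data)
  f <- seq(0, n - 1) * rec$fs_hz / n
  pos <- f > 0 & f <= rec$fs_hz / 2
  line <- logical(n_ch); outl <- logical(n_ch)
  for (i in seq_len(n_ch)) {
    x <- rec$data[i, ]
    p <- Mod(stats::fft(x))^2
    tot <- sum(p[pos & f >= 1 & f <= 499])
    inline <- sum(p[pos & abs(f - line_freq) <= 1])
    line[i] <- tot > 0 && inline > line_ratio * tot
    if (sds[i] > 0)
      outl[i] <- mean(abs(x - mean(x)) > outlier_sds * sds[i]) > outlier_frac
  }
  reasons <- vapply(seq_len(n_ch), function(i) {
    r <- c("flat"[flat[i]], "amplitude"[amp[i]], "line_noise"[line[i]],
           "outliers"[outl[i]])
    paste(r, collapse = ",")
  }, character(1))
  flagged <- flat | amp | line | outl
  list(good_mask = rec$good_mask & !flagged,
       report = data.frame(channel = rec$channel_id, flagged = flagged,
                           reasons = reasons, stringsAsFactors = FALSE))
}

#' Write the channel-quality report as TSV
#' @param report the `report` element of [detect_bad_channels()].
#' @param path output path.
#' @export
write_channel_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Butterworth band filter designed analytically as second-order sections:
# prototype poles exp(i*pi*(2k+n-1)/2n), analog band transform, bilinear
# map per pole. Narrow stop bands make the order-2n polynomial coefficients
# too ill-conditioned to factor (or run) in direct form, so poles are never
# taken through a polynomial; each conjugate pair becomes one biquad.
butter_sos <- function(order, band_hz, fs, type = c("pass", "stop")) {
  type <- match.arg(type)
  n <- order
  proto <- exp(1i * pi * (2 * seq_len(n) + n - 1) / (2 * n))
  wl <- 2 * fs * tan(pi * band_hz[1] / fs)   # prewarped edges
  wh <- 2 * fs * tan(pi * band_hz[2] / fs)
  w0 <- sqrt(wl * wh); bw <- wh - wl
  s_poles <- if (type == "pass") {
    unlist(lapply(proto, function(p) {
      disc <- sqrt((p * bw)^2 - 4 * w0^2)
      c((p * bw + disc) / 2, (p * bw - disc) / 2)
    }))
  } else {
    unlist(lapply(proto, function(p) {
      disc <- sqrt(as.complex(bw^2 - 4 * p^2 * w0^2))
      c((bw + disc) / (2 * p), (bw - disc) / (2 * p))
    }))
  }
  z_poles <- (2 * fs + s_poles) / (2 * fs - s_poles)
  pp <- z_poles[Im(z_poles) >= 0]            # one per conjugate pair
  a_secs <- lapply(pp, function(p) c(1, -2 * Re(p), Mod(p)^2))
  if (type == "pass") {
    b_secs <- replicate(n, c(1, 0, -1), simplify = FALSE)
    wr <- 2 * atan(w0 / (2 * fs))            # unity gain at band centre
  } else {
    wz <- 2 * atan(w0 / (2 * fs))
    b_secs <- replicate(n, c(1, -2 * cos(wz), 1), simplify = FALSE)
    wr <- 0                                  # unity gain at DC
  }
  zr <- exp(1i * wr)
  # normalize each biquad to unit gain at the reference frequency so
  # intermediate cascade signals stay O(1)
  b_secs <- lapply(seq_len(n), function(i) {
    hi <- sum(b_secs[[i]] * zr^-(0:2)) / sum(a_secs[[i]] * zr^-(0:2))
    b_secs[[i]] / Mod(hi)
  })
  # edge transients last ~1/bandwidth (and ~1/low-edge for low bands)
  pad_s <- 3 / min(band_hz[2] - band_hz[1], band_hz[1])
  list(b = b_secs, a = a_secs, gain = 1, pad_s = pad_s)
}

# zero-phase application: odd-reflection padding scaled to the filter's
# transient length, then each section forward-backward via signal::filtfilt
sos_filtfilt <- function(sos, x, fs) {
  n <- length(x)
  pad <- min(n - 1, round(fs * sos$pad_s))
  xx <- c(2 * x[1] - x[seq(pad + 1, 2)], x,
          2 * x[n] - x[seq(n - 1, n - pad)])
  for (i in seq_along(sos$b))
    xx <- signal::filtfilt(sos$b[[i]], sos$a[[i]], xx)
  xx[(pad + 1):(pad + n)] * sos$gain^2
}

apply_sos <- function(rec, sos) {
  out <- rec
  for (i in seq_len(nrow(out$data)))
    out$data[i, ] <- sos_filtfilt(sos, out$data[i, ], out$fs_hz)
  out
}

#' Notch out line noise and its harmonics
#'
#' Cascaded Butterworth band-stop filters (default order 4, designed before
#' the zero-phase forward-backward pass) at each base frequency and every
#' integer harmonic up to `max_freq_hz`, with stop bands of
#' `+/- half_width_hz`. The defaults remove 50 Hz mains and a 24 Hz
#' operating-room artifact with all harmonics up to 499 Hz. Filters run as
#' analytically designed second-order sections with odd-reflection edge
#' padding: narrow stop bands are numerically unusable in direct form.
#'
#' @param rec an `ecog_recording`.
#' @param base_freqs_hz base frequencies to notch.
#' @param half_width_hz half-width of each stop band.
#' @param order Butterworth order.
#' @param max_freq_hz highest harmonic to remove (499 Hz, the top analysis
#'   band edge).
#' @return Filtered `ecog_recording`.
#' @export
notch_filter <- function(rec, base_freqs_hz = c(50, 24), half_width_hz = 1,
                         order = 4, max_freq_hz = 499) {
  stopifnot(inherits(rec, "ecog_recording"))
  nyq <- rec$fs_hz / 2
  for (b in base_freqs_hz) {
    for (k in seq_len(floor(max_freq_hz / b))) {
      f <- k * b
      if (f + half_width_hz >= nyq)
        stop(sprintf("stop band %g +/- %g Hz reaches the Nyquist frequency",
                     f, half_width_hz))
      sos <- butter_sos(order, c(f - half_width_hz, f + half_width_hz),
                        rec$fs_hz, "stop")
      rec <- apply_sos(rec, sos)
    }
  }
  rec
}

#' Common median reference
#'
#' Subtracts, at each time sample, the median across good channels from
#' every good channel. Bad channels are left untouched. Removes signal
#' common to all electrodes (line noise, reference activity) while being
#' robust to outlier channels.
#'
#' @param rec an `ecog_recording` with >= 2 good channels.
#' @return Re-referenced `ecog_recording`.
#' @export
common_median_reference <- function(rec) {
  stopifnot(inherits(rec, "ecog_recording"))
  good <- which(rec$good_mask)
  if (length(good) < 2) stop("need at least 2 good channels")
  med <- apply(rec$data[good, , drop = FALSE], 2, stats::median)
  rec$data[good, ] <- sweep(rec$data[good, , drop = FALSE], 2, med)
  rec
}

#' Butterworth band-pass for an analysis band
#'
#' Order 3 for the two lowest bands (high edge at or below 8 Hz), order 4
#' otherwise, applied zero-phase (forward-backward) as second-order
#' sections. The `unfiltered` sentinel (NA band edges or the string
#' `"unfiltered"`) returns the input unchanged.
#'
#' @param rec an `ecog_recording`.
#' @param band numeric `c(low_hz, high_hz)`, a row of [dyadic_bands()], or
#'   `"unfiltered"`.
#' @param order filter order; `NULL` picks the band-dependent default.
#' @return Filtered `ecog_recording`.
#' @export
bandpass_filter <- function(rec, band, order = NULL) {
  stopifnot(inherits(rec, "ecog_recording"))
  band <- as_band(band)
  if (is_unfiltered(band)) return(rec)
  nyq <- rec$fs_hz / 2
  if (band[1] <= 0 || band[2] <= band[1] || band[2] >= nyq)
    stop("band must satisfy 0 < low < high < fs/2")
  if (is.null(order)) order <- if (band[2] <= 8) 3 else 4
  apply_sos(rec, butter_sos(order, band, rec$fs_hz, "pass"))
}

as_band <- function(band) {
  if (is.character(band) && identical(band, "unfiltered"))
    return(c(NA_real_, NA_real_))
  if (is.data.frame(band)) return(c(band$low_hz[1], band$high_hz[1]))
  if (is.list(band)) return(c(band$low_hz, band$high_hz))
  as.numeric(band)
}

is_unfiltered <- function(band) any(is.na(band))

#' Morlet wavelet band power
#'
#' Complex Morlet decomposition (default 7 cycles) at `n_freqs`
#' log-spaced centre frequencies within the band; the squared coefficient
#' magnitudes are averaged over frequencies, yielding one power time
#' series per channel. Scaled so a unit-amplitude sinusoid at a centre
#' frequency has power 1.
#'
#' @param rec an `ecog_recording` (voltage).
#' @param band numeric `c(low_hz, high_hz)`.
#' @param n_cycles wavelet width in cycles.
#' @param n_freqs number of centre frequencies.
#' @return An `ecog_recording` whose `data` holds band power (uV^2) and
#'   whose `units` is `"uV^2"`.
#' @export
morlet_band_power <- function(rec, band, n_cycles = 7, n_freqs = 5) {
  stopifnot(inherits(rec, "ecog_recording"))
  band <- as_band(band)
  if (is_unfiltered(band)) stop("Morlet band power needs a finite band")
  if (band[1] <= 0 || band[2] <= band[1] || band[2] >= rec$fs_hz / 2)
    stop("band must satisfy 0 < low < high < fs/2")
  freqs <- exp(seq(log(band[1]), log(band[2]), length.out = n_freqs))
  if (n_freqs > 1 && min(diff(freqs)) <= 0)
    stop("band too narrow for the requested number of frequencies")
  n <- ncol(rec$data)
  fbin <- seq(0, n - 1) * rec$fs_hz / n
  xf <- stats::mvfft(t(rec$data))           # samples x channels
  pow <- matrix(0, nrow(rec$data), n)
  for (f0 in freqs) {
    sigma_t <- n_cycles / (2 * pi * f0)
    h <- 2 * exp(-0.5 * (2 * pi * (fbin - f0) * sigma_t)^2)
    h[fbin > rec$fs_hz / 2] <- 0            # analytic: kill negative freqs
    coef <- stats::mvfft(xf * h, inverse = TRUE) / n
    pow <- pow + t(Mod(coef)^2)
  }
  out <- rec
  out$data <- pow / length(freqs)
  out$units <- "uV^2"
  out
}

#' Segment a recording into rest and active trials
#'
#' Two schemes: `half_isi` takes rest as the half inter-stimulus interval
#' before each stimulus and active as the half interval after it;
#' `fixed_1p5s` uses 1.5 s windows on each side. Intervals are half-open
#' in samples, so each trial has exactly `round(duration * fs)` samples.
#' Trials that would exceed the recording bounds are dropped.
#'
#' @param rec an `ecog_recording`.
#' @param events data frame with `onset` (s), sorted ascending.
#' @param scheme `"half_isi"` or `"fixed_1p5s"`.
#' @return An object of class `trial_set`: list with `epochs` (trial x
#'   channel x sample array), `label` (factor rest/active), `onset_s`,
#'   `duration_s`, `fs_hz`, `channel_id`, `good_mask`.
#' @export
segment_trials <- function(rec, events, scheme = c("half_isi", "fixed_1p5s")) {
  stopifnot(inherits(rec, "ecog_recording"))
  scheme <- match.arg(scheme)
  if (nrow(events) < 1) stop("need at least one stimulus event")
  onsets <- events$onset
  if (is.unsorted(onsets)) stop("events must be sorted by onset")
  if (scheme == "half_isi") {
    if (length(onsets) < 2)
      stop("half_isi scheme needs at least two events to define the ISI")
    half <- stats::median(diff(onsets)) / 2
  } else half <- 1.5
  fs <- rec$fs_hz
  n <- ncol(rec$data)
  win <- round(half * fs)
  starts <- c(); labels <- c(); t0 <- c()
  for (on in onsets) {
    i_on <- round(on * fs)                  # 0-based sample of the onset
    for (side in c("rest", "active")) {
      i0 <- if (side == "rest") i_on - win else i_on
      if (i0 >= 0 && i0 + win <= n) {
        starts <- c(starts, i0); labels <- c(labels, side)
        t0 <- c(t0, i0 / fs)
      }
    }
  }
  if (length(starts) == 0) stop("no valid trials within the recording bounds")
  n_tr <- length(starts)
  epochs <- array(0, dim = c(n_tr, nrow(rec$data), win))
  for (k in seq_len(n_tr))
    epochs[k, , ] <- rec$data[, (starts[k] + 1):(starts[k] + win)]
  structure(list(epochs = epochs,
                 label = factor(labels, levels = c("rest", "active")),
                 onset_s = t0, duration_s = rep(win / fs, n_tr),
                 fs_hz = fs, channel_id = rec$channel_id,
                 good_mask = rec$good_mask),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials (%d rest, %d active) x %d channels x %d samples @ %g Hz\n",
              dim(x$epochs)[1], sum(x$label == "rest"),
              sum(x$label == "active"), dim(x$epochs)[2], dim(x$epochs)[3],
              x$fs_hz))
  invisible(x)
}
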