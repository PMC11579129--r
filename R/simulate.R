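#' Simulation configuration for the epicortical forward model
#'
#' The simulator generates epicortical potentials from three components:
#' planar traveling oscillations (shared sources whose phase advances across
#' the grid at a cortical conduction speed), power-law broadband activity on
#' a dense source lattice mixed into the electrodes through an exponential
#' volume-conduction kernel, and independent per-electrode sensor noise.
#' Electrode contacts spatially average the field over their exposed disc.
#'
#' Broadband sources have a power spectrum proportional to
#' `1/f^power_law_exponent` (amplitude `f^(-exponent/2)`), flattened below
#' 1 Hz, each scaled to unit standard deviation times `amplitude` before
#' conduction mixing. Conduction mixing is a normalized weighted average
#' (`exp(-d/lambda)` weights), so oscillation amplitudes at the electrodes
#' stay close to the source amplitudes while dense independent broadband is
#' attenuated by spatial averaging, as physical spatial integration would.
#'
#' All randomness flows from `seed` with a fixed split: sources use `seed`,
#' sensor noise `seed + 1`, task modulation `seed + 2`.
#'
#' @param fs_hz sampling rate, Hz.
#' @param duration_s simulated duration, s.
#' @param oscillations list of [oscillation()] entries.
#' @param broadband list with `power_law_exponent`, `amplitude` (per-source
#'   sd, arbitrary units mapped to uV), `spatial_correlation_length_mm`
#'   (Gaussian correlation length of the source field; lengths at or below
#'   the source spacing leave sources independent).
#' @param conduction_lambda_mm decay length of the volume-conduction kernel.
#' @param source_spacing_mm spacing of the broadband source lattice.
#' @param sensor_noise_sd per-electrode white-noise sd (uV).
#' @param n_subpoints points of the deterministic sunflower pattern used to
#'   average over the exposed disc (1 = centre sample only).
#' @param task optional list `(channels, freq_hz, amplitude)` adding a
#'   narrow-band response on the given channels during active trial windows
#'   of [generate_dataset()].
#' @param seed integer master seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(fs_hz = 2000, duration_s = 8,
                       oscillations = list(
                         oscillation(10, 1.0, 2.5, direction_deg = 0),
                         oscillation(22, 0.6, 2.5, direction_deg = 90)),
                       broadband = list(power_law_exponent = 2,
                                        amplitude = 6,
                                        spatial_correlation_length_mm = 0.5),
                       conduction_lambda_mm = 2,
                       source_spacing_mm = 1,
                       sensor_noise_sd = 0.4,
                       n_subpoints = 12,
                       task = NULL,
                       seed = 1L) {
  cfg <- structure(list(fs_hz = fs_hz, duration_s = duration_s,
                        oscillations = oscillations, broadband = broadband,
                        conduction_lambda_mm = conduction_lambda_mm,
                        source_spacing_mm = source_spacing_mm,
                        sensor_noise_sd = sensor_noise_sd,
                        n_subpoints = n_subpoints, task = task,
                        seed = as.integer(seed)),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Traveling-oscillation component
#'
#' A planar wave of frequency `freq_hz` whose phase at position `p` (mm) is
#' `2*pi*freq_hz * ((p - origin) . u) / (1000 * speed_m_s)`, `u` the unit
#' vector at `direction_deg`. Speeds of 2-3 m/s are typical of short-range
#' cortico-cortical transmission in sensorimotor cortex.
#'
#' @param freq_hz oscillation frequency, Hz.
#' @param amplitude source amplitude (uV).
#' @param speed_m_s propagation speed, m/s.
#' @param direction_deg propagation direction, degrees from the x axis.
#' @param origin 2-D origin, mm (phase reference).
#' @export
oscillation <- function(freq_hz, amplitude, speed_m_s, direction_deg = 0,
                        origin = c(0, 0)) {
  list(freq_hz = freq_hz, amplitude = amplitude, speed_m_s = speed_m_s,
       direction_deg = direction_deg, origin = origin)
}

validate_sim_config <- function(cfg) {
  if (cfg$fs_hz <= 0 || cfg$duration_s <= 0)
    stop("fs_hz and duration_s must be positive")
  for (o in cfg$oscillations) {
    if (o$amplitude < 0) stop("oscillation amplitudes must be >= 0")
    if (o$speed_m_s <= 0) stop("propagation speed must be positive")
    if (cfg$fs_hz <= 2 * o$freq_hz)
      stop("fs_hz must exceed twice every oscillation frequency")
  }
  if (cfg$broadband$amplitude < 0) stop("broadband amplitude must be >= 0")
  if (cfg$broadband$power_law_exponent < 0)
    stop("power_law_exponent must be >= 0")
  if (cfg$conduction_lambda_mm <= 0) stop("conduction_lambda_mm must be positive")
  if (cfg$source_spacing_mm <= 0) stop("source_spacing_mm must be positive")
  if (cfg$sensor_noise_sd < 0) stop("sensor_noise_sd must be >= 0")
  if (cfg$n_subpoints < 1) stop("n_subpoints must be >= 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> fs %g Hz, %g s, %d oscillation(s), bb amp %g (1/f^%g), lambda %g mm, noise sd %g, seed %d\n",
              x$fs_hz, x$duration_s, length(x$oscillations),
              x$broadband$amplitude, x$broadband$power_law_exponent,
              x$conduction_lambda_mm, x$sensor_noise_sd, x$seed))
  invisible(x)
}

#' Volume-conduction weight
#'
#' Exponential distance decay `exp(-distance/lambda)`: 1 at the source,
#' strictly decreasing with distance.
#'
#' @param distance_mm distance from the source, mm (>= 0).
#' @param lambda_mm decay length, mm (> 0).
#' @return Weight in (0, 1].
#' @export
conduction_weight <- function(distance_mm, lambda_mm) {
  if (any(distance_mm < 0)) stop("distance_mm must be >= 0")
  if (any(lambda_mm <= 0)) stop("lambda_mm must be positive")
  exp(-distance_mm / lambda_mm)
}

power_law_noise <- function(n_samples, n_series, fs, exponent, f_floor = 1) {
  # spectral shaping of white noise: power ~ 1/f^exponent, flat below f_floor
  w <- matrix(stats::rnorm(n_samples * n_series), n_samples, n_series)
  if (exponent == 0) return(w)
  f <- seq(0, n_samples - 1) * fs / n_samples
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  a <- pmax(f, f_floor)^(-exponent / 2)
  a[1] <- 0                                 # no DC
  x <- Re(stats::mvfft(stats::mvfft(w) * a, inverse = TRUE)) / n_samples
  # unit sd per series
  sweep(x, 2, apply(x, 2, stats::sd), "/")
}

#' Simulate the epicortical source field
#'
#' Places broadband sources on a regular lattice covering the layout plus a
#' margin of four conduction lengths, and attaches each oscillation as a
#' traveling wave with a deterministic phase per source position.
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param layout an [electrode_layout] (defines the covered area).
#' @param source_positions optional n x 2 matrix of source positions (mm)
#'   overriding the lattice; spatial smoothing of broadband is then skipped.
#' @return An object of class `source_field` with elements `positions`,
#'   `fs_hz`, `n_samples`, `broadband` (samples x sources matrix, or NULL),
#'   and `oscillations` (each with a per-source `phase` vector). Use
#'   [source_series()] to materialize the full source x sample matrix.
#' @export
simulate_source_field <- function(config, layout, source_positions = NULL) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_samples <- round(config$duration_s * config$fs_hz)
  grid_dims <- NULL
  if (is.null(source_positions)) {
    s <- config$source_spacing_mm
    margin <- 4 * config$conduction_lambda_mm
    xs <- seq(min(layout$x) - margin, max(layout$x) + margin, by = s)
    ys <- seq(min(layout$y) - margin, max(layout$y) + margin, by = s)
    source_positions <- as.matrix(expand.grid(x = xs, y = ys))
    grid_dims <- c(length(xs), length(ys))
  } else {
    source_positions <- as.matrix(source_positions)
  }
  n_src <- nrow(source_positions)

  bb <- NULL
  if (config$broadband$amplitude > 0) {
    bb <- power_law_noise(n_samples, n_src, config$fs_hz,
                          config$broadband$power_law_exponent)
    L <- config$broadband$spatial_correlation_length_mm
    if (!is.null(grid_dims) && L > config$source_spacing_mm)
      bb <- smooth_sources_grid(bb, grid_dims, L / config$source_spacing_mm)
    bb <- bb * config$broadband$amplitude
  }

  oscs <- lapply(config$oscillations, function(o) {
    u <- c(cos(o$direction_deg * pi / 180), sin(o$direction_deg * pi / 180))
    proj_mm <- (source_positions[, 1] - o$origin[1]) * u[1] +
      (source_positions[, 2] - o$origin[2]) * u[2]
    o$phase <- 2 * pi * o$freq_hz * proj_mm / (1000 * o$speed_m_s)
    o
  })

  structure(list(positions = source_positions, fs_hz = config$fs_hz,
                 n_samples = n_samples, broadband = bb,
                 oscillations = oscs, grid_dims = grid_dims),
            class = "source_field")
}

# separable Gaussian smoothing of sources laid out on an (nx, ny) grid;
# sigma_units is the correlation length in lattice units (corr exp(-d^2/2L^2))
smooth_sources_grid <- function(bb, grid_dims, sigma_units) {
  sk <- sigma_units / sqrt(2)               # kernel sd giving field corr length L
  half <- max(1L, ceiling(3 * sk))
  k <- exp(-0.5 * ((-half):half / sk)^2)
  nx <- grid_dims[1]; ny <- grid_dims[2]
  n_samples <- nrow(bb)
  arr <- array(t(bb), dim = c(nx, ny, n_samples))
  conv_axis <- function(a, along) {
    out <- array(0, dim = dim(a))
    n <- dim(a)[along]
    for (j in seq_along(k)) {
      off <- j - half - 1L
      src <- pmin(pmax(seq_len(n) + off, 1L), n)  # replicate edges
      if (along == 1) out <- out + k[j] * a[src, , , drop = FALSE]
      else out <- out + k[j] * a[, src, , drop = FALSE]
    }
    out
  }
  arr <- conv_axis(conv_axis(arr, 1), 2)
  out <- t(matrix(arr, nx * ny, n_samples))
  # restore unit variance (iid input smoothed by normalized 2-D kernel)
  sweep(out, 2, apply(out, 2, stats::sd), "/")
}

#' @export
print.source_field <- function(x, ...) {
  cat(sprintf("<source_field> %d sources, %d samples @ %g Hz, %d oscillation(s), broadband: %s\n",
              nrow(x$positions), x$n_samples, x$fs_hz,
              length(x$oscillations),
              if (is.null(x$broadband)) "none" else "yes"))
  invisible(x)
}

#' Materialize the source x sample series matrix of a field
#'
#' @param field a `source_field`.
#' @return Numeric matrix, sources in rows.
#' @export
source_series <- function(field) {
  stopifnot(inherits(field, "source_field"))
  t_s <- (seq_len(field$n_samples) - 1) / field$fs_hz
  out <- if (is.null(field$broadband))
    matrix(0, nrow(field$positions), field$n_samples)
  else t(field$broadband)
  for (o in field$oscillations) {
    if (o$amplitude == 0) next
    wt <- 2 * pi * o$freq_hz * t_s
    out <- out + o$amplitude *
      (outer(cos(o$phase), sin(wt)) - outer(sin(o$phase), cos(wt)))
  }
  out
}

sunflower_disc <- function(n, radius) {
  if (n == 1) return(matrix(0, 1, 2))
  i <- seq_len(n)
  r <- radius * sqrt((i - 0.5) / n)
  th <- i * pi * (3 - sqrt(5))              # golden angle
  cbind(r * cos(th), r * sin(th))
}

#' Sample a source field at disc-averaging electrodes
#'
#' Each electrode signal is the mean, over `n_subpoints` sunflower-pattern
#' points on its exposed disc, of the conduction-weighted average of the
#' source series, plus independent sensor noise (seeded at
#' `config$seed + 1`). Larger discs average more independent fine-scale
#' activity, which is the mechanism behind the electrode-size effect on
#' pairwise similarity.
#'
#' @param field a `source_field`.
#' @param layout an [electrode_layout]; its exposed diameter sets the disc.
#' @param config the [sim_config()] used for the field.
#' @param n_subpoints number of disc sample points (default from config).
#' @return An `ecog_recording`.
#' @export
sample_electrodes <- function(field, layout, config,
                              n_subpoints = config$n_subpoints) {
  stopifnot(inherits(field, "source_field"), inherits(layout, "electrode_layout"))
  if (n_subpoints < 1) stop("n_subpoints must be >= 1")
  dia <- attr(layout, "exposed_diameter_mm")
  if (dia > attr(layout, "pitch_mm"))
    stop("exposed disc larger than pitch")
  n_el <- nrow(layout)
  sub <- sunflower_disc(n_subpoints, dia / 2)
  pts <- cbind(rep(layout$x, each = n_subpoints) + sub[, 1],
               rep(layout$y, each = n_subpoints) + sub[, 2])
  # conduction weights, normalized per point (weighted average of sources)
  dx <- outer(pts[, 1], field$positions[, 1], "-")
  dy <- outer(pts[, 2], field$positions[, 2], "-")
  w <- conduction_weight(sqrt(dx * dx + dy * dy), config$conduction_lambda_mm)
  w <- w / rowSums(w)
  # disc averaging commutes with the linear mixing: average weight rows
  grp <- rep(seq_len(n_el), each = n_subpoints)
  m_e <- rowsum(w, grp) / n_subpoints       # n_el x n_src
  t_s <- (seq_len(field$n_samples) - 1) / field$fs_hz
  sig <- matrix(0, n_el, field$n_samples)
  for (o in field$oscillations) {
    if (o$amplitude == 0) next
    wt <- 2 * pi * o$freq_hz * t_s
    cvec <- as.vector(m_e %*% cos(o$phase))
    svec <- as.vector(m_e %*% sin(o$phase))
    sig <- sig + o$amplitude * (outer(cvec, sin(wt)) - outer(svec, cos(wt)))
  }
  if (!is.null(field$broadband))
    sig <- sig + t(field$broadband %*% t(m_e))
  if (config$sensor_noise_sd > 0) {
    set.seed(config$seed + 1L)
    sig <- sig + matrix(stats::rnorm(length(sig), 0, config$sensor_noise_sd),
                        n_el, field$n_samples)
  }
  recording(sig, fs_hz = field$fs_hz, channel_id = layout$name)
}

#' Generate a complete synthetic dataset (recording + events)
#'
#' Simulates the source field, samples the electrodes, and lays regular
#' stimulus events on top (onsets at `isi_s, 2*isi_s, ...`), so that
#' [segment_trials()] can derive rest and active epochs. If `config$task`
#' is set, a narrow-band response (amplitude jittered per trial) is added
#' on the given channels during active windows. Fully reproducible from
#' `seed`.
#'
#' @param config a [sim_config()]; `duration_s` must cover
#'   `n_trials * isi_s + isi_s/2`.
#' @param layout an [electrode_layout].
#' @param n_trials number of stimulus events.
#' @param isi_s inter-stimulus interval, s.
#' @param seed master seed (defaults to `config$seed`).
#' @return List with elements `recording` (`ecog_recording`) and `events`
#'   (data frame: onset, duration, trial_type).
#' @export
generate_dataset <- function(config, layout, n_trials = 10, isi_s = 3,
                             seed = config$seed) {
  need <- n_trials * isi_s + isi_s / 2
  if (config$duration_s < need)
    stop(sprintf("duration_s = %g too short for %d trials at isi %g s (need >= %g s)",
                 config$duration_s, n_trials, isi_s, need))
  cfg <- config
  cfg$seed <- as.integer(seed)
  field <- simulate_source_field(cfg, layout)
  rec <- sample_electrodes(field, layout, cfg)
  events <- data.frame(onset = isi_s * seq_len(n_trials),
                       duration = isi_s / 2,
                       trial_type = "stimulus", stringsAsFactors = FALSE)
  if (!is.null(cfg$task)) {
    tk <- cfg$task
    ch <- tk$channels
    if (is.character(ch)) ch <- match(ch, rec$channel_id)
    set.seed(cfg$seed + 2L)
    t_s <- (seq_len(ncol(rec$data)) - 1) / rec$fs_hz
    carrier <- sin(2 * pi * tk$freq_hz * t_s)
    for (k in seq_len(n_trials)) {
      on_i <- round(events$onset[k] * rec$fs_hz) + 1L
      off_i <- min(round((events$onset[k] + isi_s / 2) * rec$fs_hz), ncol(rec$data))
      amp <- tk$amplitude * stats::runif(1, 0.8, 1.2)
      rec$data[ch, on_i:off_i] <- rec$data[ch, on_i:off_i] +
        amp * rep(carrier[on_i:off_i], each = length(ch))
    }
  }
  list(recording = rec, events = events)
}

#' Read or write a simulation configuration as JSON or YAML
#'
#' File fields mirror the [sim_config()] argument names exactly.
#'
#' @param path file path; extension `.json`, `.yaml` or `.yml`.
#' @export
read_sim_config <- function(path) {
  lst <- if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.data.frame(lst$oscillations))
    lst$oscillations <- lapply(seq_len(nrow(lst$oscillations)),
                               function(i) as.list(lst$oscillations[i, ]))
  oscs <- lapply(lst$oscillations, function(o)
    oscillation(o$freq_hz, o$amplitude, o$speed_m_s,
                direction_deg = if (is.null(o$direction_deg)) 0 else o$direction_deg,
                origin = if (is.null(o$origin)) c(0, 0) else unlist(o$origin)))
  args <- lst
  args$oscillations <- oscs
  do.call(sim_config, args)
}

#' @rdname read_sim_config
#' @param config a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  lst <- unclass(config)
  if (grepl("\\.json$", path))
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(lst, path)
  invisible(path)
}
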