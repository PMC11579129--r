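#' Mean ndRMS per equidistant IED bin
#'
#' Averages the per-pair ndRMS summaries within each retained IED bin,
#' producing recording-level rows of the tidy results table.
#'
#' @param pair_values a `pair_ndrms` from [ndrms_per_pair()].
#' @param bins an `ied_bins` from [bin_equidistant()] built on the same
#'   pair table.
#' @param pairs the `pair_table` the bins index into.
#' @param participant,repetition identifiers carried into the rows.
#' @return Tidy data frame with columns `level`, `participant`,
#'   `repetition`, `ied_mm`, `band`, `statistic`, `value`, `n` (pair count
#'   after exclusions). Bins emptied by pair exclusions are dropped with a
#'   warning.
#' @export
ndrms_by_ied <- function(pair_values, bins, pairs,
                         participant = NA, repetition = NA) {
  stopifnot(inherits(bins, "ied_bins"))
  key <- function(a, b) paste(a, b, sep = "\r")
  val <- stats::setNames(pair_values$ndrms, key(pair_values$a, pair_values$b))
  members <- attr(bins, "members")
  rows <- lapply(seq_len(nrow(bins)), function(i) {
    k <- key(pairs$a[members[[i]]], pairs$b[members[[i]]])
    v <- val[k]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NULL)
    data.frame(level = "recording", participant = participant,
               repetition = repetition, ied_mm = bins$distance_mm[i],
               band = pair_values$band[1], statistic = "ndrms",
               value = mean(v), n = length(v), stringsAsFactors = FALSE)
  })
  empty <- vapply(rows, is.null, logical(1))
  if (any(empty))
    warning(sprintf("%d bin(s) dropped: all member pairs excluded", sum(empty)))
  out <- do.call(rbind, rows[!empty])
  rownames(out) <- NULL
  out
}

#' Aggregate tidy result rows to the participant or group level
#'
#' `recording -> participant`: mean over task repetitions per
#' (participant, IED, band). `participant -> group`: mean over
#' participants per (IED, band), keeping only bins present in two or more
#' participants. Requires the input rows to be at the immediately lower
#' level.
#'
#' @param rows tidy rows as produced by [ndrms_by_ied()] or
#'   [correlation_by_ied()].
#' @param level target level, `"participant"` or `"group"`.
#' @return Tidy rows at the target level; `n` counts the contributing
#'   repetitions or participants.
#' @export
average_levels <- function(rows, level = c("participant", "group")) {
  level <- match.arg(level)
  from <- if (level == "participant") "recording" else "participant"
  if (!all(rows$level == from))
    stop(sprintf("input rows must all be at level '%s'", from))
  if (level == "participant") {
    keyv <- interaction(rows$participant, rows$ied_mm, rows$band,
                        rows$statistic, drop = TRUE)
    agg <- lapply(split(rows, keyv), function(g)
      data.frame(level = "participant", participant = g$participant[1],
                 repetition = NA, ied_mm = g$ied_mm[1], band = g$band[1],
                 statistic = g$statistic[1], value = mean(g$value),
                 n = nrow(g), stringsAsFactors = FALSE))
  } else {
    keyv <- interaction(rows$ied_mm, rows$band, rows$statistic, drop = TRUE)
    agg <- lapply(split(rows, keyv), function(g) {
      if (length(unique(g$participant)) < 2) return(NULL)
      data.frame(level = "group", participant = NA, repetition = NA,
                 ied_mm = g$ied_mm[1], band = g$band[1],
                 statistic = g$statistic[1], value = mean(g$value),
                 n = nrow(g), stringsAsFactors = FALSE)
    })
    agg <- agg[!vapply(agg, is.null, logical(1))]
  }
  if (length(agg) == 0)
    return(data.frame(level = character(0), participant = character(0),
                      repetition = character(0), ied_mm = numeric(0),
                      band = character(0), statistic = character(0),
                      value = numeric(0), n = integer(0)))
  out <- do.call(rbind, agg)
  out <- out[order(out$band, out$ied_mm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distance-averaged pairwise correlation
#'
#' Pearson correlation between the two channels of every pair, per trial,
#' averaged over trials and then per IED bin (with the same >= 10 pairs
#' rule as the ndRMS). The epochs are expected to hold the band signal of
#' interest — Morlet band power from [morlet_band_power()] in the standard
#' analysis, or band-passed voltage if that option is chosen upstream.
#'
#' @param trials a `trial_set` whose epochs carry the band series.
#' @param pairs a `pair_table`.
#' @param bins an `ied_bins` built on `pairs`.
#' @param band band label for the output rows.
#' @param labels trial labels to use (default rest trials).
#' @inheritParams ndrms_by_ied
#' @return Tidy rows with `statistic = "correlation"`.
#' @export
correlation_by_ied <- function(trials, pairs, bins, band = "unfiltered",
                               labels = "rest",
                               participant = NA, repetition = NA) {
  stopifnot(inherits(trials, "trial_set"), inherits(bins, "ied_bins"))
  keep <- which(trials$label %in% labels)
  if (length(keep) == 0) stop("no trials with the requested label")
  ia <- match(pairs$a, trials$channel_id)
  ib <- match(pairs$b, trials$channel_id)
  rsum <- numeric(nrow(pairs)); rcount <- integer(nrow(pairs))
  for (k in keep) {
    ep <- trials$epochs[k, , ]
    cm <- suppressWarnings(stats::cor(t(ep)))  # NA for degenerate channels
    rtr <- cm[cbind(ia, ib)]
    ok <- !is.na(rtr)
    rsum[ok] <- rsum[ok] + rtr[ok]
    rcount[ok] <- rcount[ok] + 1L
  }
  rbar <- ifelse(rcount > 0, rsum / pmax(rcount, 1L), NA_real_)
  members <- attr(bins, "members")
  rows <- lapply(seq_len(nrow(bins)), function(i) {
    v <- rbar[members[[i]]]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NULL)
    data.frame(level = "recording", participant = participant,
               repetition = repetition, ied_mm = bins$distance_mm[i],
               band = band, statistic = "correlation", value = mean(v),
               n = length(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Two-sample Wilcoxon rank-sum test, lower-rank-sum convention
#'
#' Reports the statistic as the sum of (mid)ranks of the lower-ranked
#' sample — the convention under which complete separation of two
#' nine-value samples gives W = 45. P-values are exact for sample sizes up
#' to 12 without ties, and use the normal approximation (with continuity
#' correction) otherwise.
#'
#' @param x,y numeric samples (each length >= 2).
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @return List with `statistic` (lower rank sum), `rank_sum_x`,
#'   `rank_sum_y`, `p_value`, `exact` (logical).
#' @export
rank_sum_test <- function(x, y, alternative = "two.sided") {
  n <- length(x); m <- length(y)
  if (n < 2 || m < 2) stop("each sample needs at least 2 values")
  rk <- rank(c(x, y))
  wx <- sum(rk[seq_len(n)])
  wy <- sum(rk) - wx
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && n <= 12 && m <= 12
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = exact, correct = TRUE))
  list(statistic = min(wx, wy), rank_sum_x = wx, rank_sum_y = wy,
       p_value = ht$p.value, exact = exact)
}

#' Compare two grids at matched inter-electrode distances
#'
#' At each matched IED, the per-band values (the eight dyadic bands plus
#' unfiltered, so nine values per grid at group level) of the two grids
#' are compared with a two-sided Wilcoxon rank-sum test; p-values are
#' Bonferroni-corrected by the number of matched IEDs.
#'
#' @param table_a,table_b tidy rows (same level) containing per-band values
#'   at the matched IEDs; grid A supplies `distance_a_mm`, grid B
#'   `distance_b_mm`.
#' @param matched matched bin pairs from [matched_ied_bins()].
#' @param alpha significance level before correction.
#' @return An object of class `grid_comparison`: data frame with one row
#'   per matched IED (`ied_a_mm`, `ied_b_mm`, `n_a`, `n_b`, `statistic`,
#'   `p_value`, `p_bonferroni`, `significant`).
#' @export
compare_grids <- function(table_a, table_b, matched, alpha = 0.05) {
  if (nrow(matched) == 0) stop("no matched IED bins to compare")
  n_tests <- nrow(matched)
  rows <- lapply(seq_len(n_tests), function(i) {
    va <- table_a$value[abs(table_a$ied_mm - matched$distance_a_mm[i]) < 1e-9]
    vb <- table_b$value[abs(table_b$ied_mm - matched$distance_b_mm[i]) < 1e-9]
    if (length(va) < 2 || length(vb) < 2)
      stop(sprintf("fewer than 2 per-band values at matched IED %.1f/%.1f mm",
                   matched$distance_a_mm[i], matched$distance_b_mm[i]))
    ht <- rank_sum_test(va, vb)
    data.frame(ied_a_mm = matched$distance_a_mm[i],
               ied_b_mm = matched$distance_b_mm[i],
               n_a = length(va), n_b = length(vb),
               statistic = ht$statistic, p_value = ht$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * n_tests)
  out$significant <- out$p_bonferroni < alpha
  attr(out, "alpha") <- alpha
  class(out) <- c("grid_comparison", "data.frame")
  out
}

#' @export
print.grid_comparison <- function(x, ...) {
  cat(sprintf("<grid_comparison> %d matched IED(s), alpha = %g (Bonferroni-corrected)\n",
              nrow(x), attr(x, "alpha")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write tidy result rows with a provenance header
#'
#' Tab-separated results preceded by comment lines (`# key=value`) carrying
#' the package version, seed and configuration hash, so output files are
#' traceable and reruns are byte-comparable.
#'
#' @param rows data frame of result rows.
#' @param path output path.
#' @param provenance named list written as header comments.
#' @export
write_result_table <- function(rows, path, provenance = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(provenance))
    writeLines(sprintf("# %s=%s", nm, provenance[[nm]]), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Plot distance-resolved curves
#'
#' Base-graphics line plot of `value` against IED, one line per band, with
#' a dashed reference at sqrt(2) for ndRMS tables.
#'
#' @param rows tidy rows from [ndrms_by_ied()] / [correlation_by_ied()]
#'   (any level).
#' @param ... passed to [graphics::matplot()].
#' @export
plot_by_ied <- function(rows, ...) {
  bands <- unique(rows$band)
  ieds <- sort(unique(rows$ied_mm))
  mat <- sapply(bands, function(b) {
    g <- rows[rows$band == b, ]
    g$value[match(ieds, g$ied_mm)]
  })
  graphics::matplot(ieds, mat, type = "b", pch = 16, lty = 1,
                    xlab = "IED (mm)", ylab = rows$statistic[1], ...)
  if (rows$statistic[1] == "ndrms")
    graphics::abline(h = sqrt(2), lty = 2, col = "grey40")
  graphics::legend("bottomright", legend = bands, col = seq_along(bands),
                   lty = 1, pch = 16, cex = 0.7, bty = "n")
  invisible(NULL)
}
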