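make_bins <- function(lay, pt, min_pairs = 1)
  bin_equidistant(pt, min_pairs = min_pairs)

test_that("bin means average the per-pair summaries", {
  lay <- make_square_layout(2, 3, 1, 0.4)
  pt <- pair_distance_table(lay)
  b <- make_bins(lay, pt)
  pv <- data.frame(a = pt$a, b = pt$b, distance_mm = pt$distance_mm,
                   band = "unfiltered", n_trials = 1,
                   ndrms = seq(0.1, by = 0.1, length.out = nrow(pt)))
  rows <- ndrms_by_ied(pv, b, pt)
  members <- attr(b, "members")
  for (i in seq_len(nrow(b)))
    expect_equal(rows$value[rows$ied_mm == b$distance_mm[i]],
                 mean(pv$ndrms[members[[i]]]))
  expect_equal(rows$n, b$n_pairs)

  pv0 <- pv; pv0$ndrms <- 0
  expect_true(all(ndrms_by_ied(pv0, b, pt)$value == 0))
})

test_that("level averaging follows the repetition and participant rules", {
  rec_rows <- rbind(
    data.frame(level = "recording", participant = "S1", repetition = 1:2,
               ied_mm = 3, band = "unfiltered", statistic = "ndrms",
               value = c(1.2, 1.4), n = 20),
    data.frame(level = "recording", participant = "S2", repetition = 1,
               ied_mm = 3, band = "unfiltered", statistic = "ndrms",
               value = 1.0, n = 15),
    data.frame(level = "recording", participant = "S2", repetition = 1,
               ied_mm = 5, band = "unfiltered", statistic = "ndrms",
               value = 1.6, n = 12))
  part <- average_levels(rec_rows, "participant")
  expect_equal(part$value[part$participant == "S1"], 1.3)
  grp <- average_levels(part, "group")
  # the 5 mm bin exists in one participant only and is excluded
  expect_equal(grp$ied_mm, 3)
  expect_equal(grp$value, mean(c(1.3, 1.0)))
  expect_equal(grp$n, 2)

  solo <- average_levels(part[part$participant == "S1", , drop = FALSE],
                         "group")
  expect_equal(nrow(solo), 0)
  expect_error(average_levels(grp, "participant"), "level 'recording'")
})

test_that("group means are convex combinations of participant means", {
  set.seed(14)
  rows <- expand.grid(participant = c("S1", "S2", "S3"), ied_mm = c(3, 4, 5),
                      band = c("1-4", "unfiltered"),
                      stringsAsFactors = FALSE)
  rows$level <- "participant"; rows$repetition <- NA
  rows$statistic <- "ndrms"; rows$value <- runif(nrow(rows), 0.5, 2)
  rows$n <- 1
  grp <- average_levels(rows, "group")
  for (i in seq_len(nrow(grp))) {
    contrib <- rows$value[rows$ied_mm == grp$ied_mm[i] &
                            rows$band == grp$band[i]]
    expect_gte(grp$value[i], min(contrib))
    expect_lte(grp$value[i], max(contrib))
  }
})

test_that("correlation by IED matches its definition on controlled trials", {
  lay <- make_square_layout(2, 3, 1, 0.4)
  pt <- pair_distance_table(lay)
  b <- make_bins(lay, pt)
  # identical channels: r = 1 everywhere
  ep <- array(rnorm(3 * 6 * 80), dim = c(3, 6, 80))
  for (ch in 2:6) ep[, ch, ] <- ep[, 1, ]
  ts <- manual_trial_set(ep, rep("rest", 3))
  lay$name <- ts$channel_id
  pt <- pair_distance_table(lay); b <- make_bins(lay, pt)
  rows <- correlation_by_ied(ts, pt, b)
  expect_equal(rows$value, rep(1, nrow(rows)), tolerance = 1e-12)

  # independent channels: bin means near zero
  set.seed(15)
  ep2 <- array(rnorm(200 * 6 * 60), dim = c(200, 6, 60))
  ts2 <- manual_trial_set(ep2, rep("rest", 200))
  rows2 <- correlation_by_ied(ts2, pt, b)
  expect_true(all(abs(rows2$value) < 0.05))
})

test_that("ndRMS and correlation agree exactly at single-trial granularity", {
  set.seed(16)
  x <- rnorm(400); y <- 0.6 * x + rnorm(400)
  expect_equal(ndrms_pair(x, y), sqrt(2 * (1 - cor(x, y))), tolerance = 1e-12)
})

test_that("rank-sum statistic and exact p match the closed-form anchor", {
  ht <- rank_sum_test(1:9, 11:19)
  expect_equal(ht$statistic, 45)
  expect_equal(ht$p_value, 2 / choose(18, 9))
  expect_true(ht$exact)
  expect_lt(ht$p_value, 1e-4)

  same <- rank_sum_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p_value, 0.9)
})

test_that("exact rank-sum p-values match exhaustive enumeration", {
  set.seed(17)
  for (n in c(4, 5, 7)) {
    for (rep in 1:3) {
      x <- rnorm(n); y <- rnorm(n, mean = runif(1, 0, 2))
      ht <- rank_sum_test(x, y)
      expect_equal(ht$p_value, enumerate_rank_sum_p(x, y), tolerance = 1e-12)
    }
  }
})

test_that("grid comparison applies Bonferroni over matched IEDs", {
  mkrows <- function(vals, ied) data.frame(
    level = "group", participant = NA, repetition = NA, ied_mm = ied,
    band = c(dyadic_bands()$band), statistic = "ndrms", value = vals, n = 2)
  ta <- rbind(mkrows(seq(1.0, 1.08, length.out = 9), 3.0),
              mkrows(seq(1.1, 1.18, length.out = 9), 4.2))
  tb <- rbind(mkrows(seq(1.2, 1.28, length.out = 9), 3.1),
              mkrows(seq(1.3, 1.38, length.out = 9), 4.1))
  matched <- data.frame(distance_a_mm = c(3.0, 4.2),
                        distance_b_mm = c(3.1, 4.1),
                        difference_mm = 0.1)
  cmp <- compare_grids(ta, tb, matched)
  expect_equal(cmp$statistic, c(45, 45))
  expect_equal(cmp$p_bonferroni, 2 * cmp$p_value)
  expect_true(all(cmp$significant))

  expect_error(compare_grids(ta[1, , drop = FALSE], tb, matched),
               "fewer than 2")
})

test_that("result tables round-trip through the provenance TSV", {
  rows <- data.frame(level = "recording", participant = "S1", repetition = 1,
                     ied_mm = c(3, 4.2), band = "unfiltered",
                     statistic = "ndrms", value = c(1.21, 1.34), n = c(10, 12))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_result_table(rows, path, provenance = list(seed = 1, version = "x"))
  expect_match(readLines(path, n = 1), "^# seed=1")
  back <- read_result_table(path)
  expect_equal(back$value, rows$value)
  expect_equal(back$ied_mm, rows$ied_mm)
})
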