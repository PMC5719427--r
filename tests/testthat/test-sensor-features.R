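mk_stream <- function(subject, channel, t_min, values,
                      origin = as.POSIXct("2016-03-07 00:00:00", tz = "UTC")) {
  tibble::tibble(subject = subject, channel = channel,
                 timestamp = origin + t_min * 60, value = values)
}

test_that("binning aggregates with half-open bins and conserves sums", {
  # 60 one-minute records of value 5 -> single hourly bin of mean 5
  st <- mk_stream("S1", "hr", 0:59, rep(5, 60))
  b <- bin_stream(st, 60)
  expect_equal(nrow(b), 1)
  expect_equal(b$value, 5)
  expect_equal(b$n_obs, 60L)

  # t = 0 and t = 59.9 min share a bin; t = 60 starts the next
  st2 <- mk_stream("S1", "hr", c(0, 59.9, 60), c(1, 2, 3))
  b2 <- bin_stream(st2, 60)
  expect_equal(nrow(b2), 2)
  expect_equal(b2$n_obs, c(2L, 1L))

  # event channels sum and conserve totals
  ev <- mk_stream("S1", "communication", seq(0, 239, by = 10),
                  rpois(24, 3))
  b3 <- bin_stream(ev, 60)
  expect_equal(sum(b3$value), sum(ev$value))

  # empty input is an empty series, not an error
  expect_equal(nrow(bin_stream(ev[0, ], 60)), 0)
  expect_error(bin_stream(ev, 7), "divide 24 h")
})

test_that("binned means equal brute-force per-bin means and ignore record order", {
  set.seed(31)
  st <- mk_stream("S1", "map", sort(sample(0:719, 300)), rnorm(300, 90, 6))
  b <- bin_stream(st, 60)
  brute <- tapply(st$value, floor((as.numeric(st$timestamp) / 60) / 60),
                  mean)
  expect_equal(unname(b$value), unname(as.numeric(brute)), tolerance = 1e-12)
  # permutation invariance to record order
  b_shuf <- bin_stream(st[sample(nrow(st)), ], 60)
  expect_equal(b_shuf, b)
})

test_that("wake/sleep summary splits by bin midpoint and dip is antisymmetric", {
  origin <- as.POSIXct("2016-03-07 00:00:00", tz = "UTC")
  diary <- tibble::tibble(subject = "S1",
                          sleep_start = origin,
                          sleep_end = origin + 8 * 3600)
  # constant series: dip = 0
  st <- mk_stream("S1", "hr", seq(0, 24 * 60 - 1, by = 30), 70)
  ws <- wake_sleep_summary(bin_stream(st, 60), diary)
  expect_equal(ws$dip, 0)

  # planted difference: sleep bins are hours 0..7, wake 8..23
  v <- ifelse(seq(0, 23) < 8, 50, 70)
  st2 <- mk_stream("S1", "hr", seq(0, 23) * 60, v)
  ws2 <- wake_sleep_summary(bin_stream(st2, 60), diary)
  expect_equal(ws2$dip, 20)
  expect_equal(ws2$n_sleep, 8L)

  # swapping the epoch labelling flips the sign of the dip
  diary_flipped <- tibble::tibble(subject = "S1",
                                  sleep_start = origin + 8 * 3600,
                                  sleep_end = origin + 24 * 3600)
  ws3 <- wake_sleep_summary(bin_stream(st2, 60), diary_flipped)
  expect_equal(ws3$dip, -ws2$dip)

  # all bins in one epoch: the other mean undefined, flagged
  diary_none <- tibble::tibble(subject = "S1",
                               sleep_start = origin + 48 * 3600,
                               sleep_end = origin + 56 * 3600)
  ws4 <- wake_sleep_summary(bin_stream(st2, 60), diary_none)
  expect_false(ws4$complete)
  expect_true(is.nan(ws4$sleep_mean) || is.na(ws4$sleep_mean))
})

test_that("epoch aggregation matches brute-force group means on the reference design", {
  cfg <- fast_config(seed = 13, n_features = 8)
  om <- generate_omics(cfg, "metabolome")
  ag <- epoch_aggregate(om, "epoch")
  # 6 subjects x 2 sessions: 36 morning and 24 evening samples
  expect_equal(unique(ag$n[ag$group == "morning"]), 36L)
  expect_equal(unique(ag$n[ag$group == "evening"]), 24L)

  lv <- transform_values(om$values, "log10_offset")
  morning <- om$sample_meta$epoch == "morning"
  expect_equal(ag$mean[ag$group == "morning"],
               unname(colMeans(lv[morning, ])), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(ag$sd[ag$group == "evening"],
               unname(apply(lv[!morning, ], 2, sd)), tolerance = 1e-12,
               ignore_attr = TRUE)

  tg <- epoch_aggregate(om, "timepoint")
  expect_equal(sort(unique(tg$group)),
               c("t00", "t12", "t24", "t36", "t48"))
  expect_equal(unique(tg$n), 12L)

  # noise-free planted beta appears exactly in the epoch log-mean gap
  cfg0 <- generator_config(
    seed = 14, omics = list(metabolome = list(
      n_features = 6, fraction_rhythmic = 1, beta = 1,
      sigma_s = 0, sigma_e = 0)))
  om0 <- generate_omics(cfg0, "metabolome")
  ag0 <- epoch_aggregate(om0, "epoch", transform = FALSE)
  gap <- log(ag0$mean[ag0$group == "morning"]) -
    log(ag0$mean[ag0$group == "evening"])
  expect_equal(gap, rep(1, 6), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("default-config dipping recovery lands within sampling error of truth", {
  cfg <- fast_config(seed = 17)
  s <- generate_sensor_streams(cfg)
  b <- bin_stream(dplyr::filter(s$streams, channel %in% c("map", "hr")), 60)
  panel <- wake_sleep_panel(b, s$diary)
  per <- dplyr::filter(panel, mode == "per_subject")
  sch <- sensor_defaults()
  for (ch in c("map", "hr")) {
    planted <- sch$dip[sch$channel == ch]
    got <- dplyr::filter(per, channel == ch)
    se <- got$dip_sd / sqrt(6)
    expect_lt(abs(got$dip - planted), 3 * se + 1)
  }
})
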