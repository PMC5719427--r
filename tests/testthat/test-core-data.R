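test_that("reference design maps timepoints to epochs as a function of hour", {
  d <- study_design()
  expect_equal(epoch_of(d, c(0, 24, 48)), rep("morning", 3))
  expect_equal(epoch_of(d, c(12, 36)), rep("evening", 2))
  # every timepoint maps to exactly one epoch
  ep <- epoch_of(d, d$timepoints)
  expect_true(all(ep %in% c("morning", "evening")))
  expect_error(epoch_of(d, 6), "not part of the design")
  expect_error(study_design(timepoints = c(0, 6)), "multiples of 12")
  expect_error(study_design(subjects = character(0)))
})

test_that("design_samples enumerates subject x session x timepoint", {
  d <- ref_design(2)
  s <- design_samples(d)
  expect_equal(nrow(s), 6 * 2 * 5)
  expect_equal(sum(s$epoch == "morning"), 6 * 2 * 3)
  expect_false(anyDuplicated(s$sample_id) > 0)
})

test_that("transforms are exact on known values and reject negatives", {
  expect_equal(transform_values(0, "sqrt"), 0)
  expect_equal(transform_values(c(1, 4, 9), "sqrt"), c(1, 2, 3))
  expect_equal(transform_values(99, "log10_offset", delta = 1), 2)
  expect_error(transform_values(-1, "sqrt"), "negative")
  expect_error(transform_values(1, "log10_offset", delta = -2), "delta > 0")
  # order preserving
  x <- c(0, 0.3, 2, 50)
  expect_true(all(diff(transform_values(x, "log10_offset")) > 0))
  # default offset is half the smallest positive value
  expect_equal(transform_values(c(0, 4), "log10_offset"),
               log10(c(0, 4) + 2))
})

test_that("sensor table parsing groups streams and round-trips losslessly", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,channel,timestamp,value",
               "S1,hr,2016-03-07T08:00:00,60",
               "S1,hr,2016-03-07T08:30:00,65",
               "S1,hr,2016-03-07T09:00:00,70"), tmp)
  st <- read_sensor_table(tmp)
  expect_equal(nrow(st), 3)
  expect_equal(unique(st$unit), "bpm")

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,channel,timestamp,value",
               "S1,sbp,2016-03-07T08:00:00,120",
               "S1,dbp,2016-03-07T08:00:00,80",
               "S2,sbp,2016-03-07T08:00:00,118",
               "S2,dbp,2016-03-07T08:00:00,76"), tmp2)
  st2 <- read_sensor_table(tmp2)
  expect_equal(nrow(dplyr::distinct(st2, subject, channel)), 4)

  # round trip of a generated stream
  gen <- generate_sensor_streams(flat_config(seed = 7))
  sub <- dplyr::filter(gen$streams, channel %in% c("hr", "map"))
  out <- withr::local_tempfile(fileext = ".csv")
  write_sensor_table(sub, out)
  back <- read_sensor_table(out)
  expect_equal(back$timestamp, sub$timestamp)
  expect_equal(back$value, sub$value, tolerance = 1e-12)
})

test_that("malformed sensor tables are rejected with a specific error", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,channel,timestamp,value",
               "S1,respiration,2016-03-07T08:00:00,12"), tmp)
  expect_error(read_sensor_table(tmp), "unknown sensor channel.*respiration")

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,channel,timestamp,value",
               "S1,hr,2016-03-07T08:00:00,60",
               "S1,hr,2016-03-07T08:00:00,61"), tmp2)
  expect_error(read_sensor_table(tmp2), "duplicate timestamp")

  tmp3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,channel,timestamp,value",
               "S1,light,2016-03-07T08:00:00,-4"), tmp3)
  expect_error(read_sensor_table(tmp3), "negative value")
})

test_that("sleep diary validation rejects inverted and overlapping intervals", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,sleep_start,sleep_end",
               "S1,2016-03-07T23:00:00,2016-03-07T22:00:00"), tmp)
  expect_error(read_sleep_diary(tmp), "sleep_end <= sleep_start")
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,sleep_start,sleep_end",
               "S1,2016-03-07T23:00:00,2016-03-08T07:00:00",
               "S1,2016-03-08T05:00:00,2016-03-08T09:00:00"), tmp2)
  expect_error(read_sleep_diary(tmp2), "overlapping")
})

test_that("omics matrices validate design metadata and composition", {
  d <- ref_design(1)
  m <- matrix(runif(30 * 10, 1, 5), 30, 10)
  om <- toy_omics(m, d)
  expect_s3_class(om, "omics_matrix")
  expect_equal(dim(om$values), c(30, 10))

  # sample missing from metadata
  meta <- design_samples(d)
  rownames(m) <- meta$sample_id
  expect_error(omics_matrix(m, meta[-1, ], kind = "metabolome", design = d),
               "missing from metadata")
  # contradicting epoch label
  bad <- meta
  bad$epoch[1] <- "evening"
  expect_error(omics_matrix(m, bad, kind = "metabolome", design = d),
               "contradicts timepoint")
  # microbiome row summing to 0.9 is rejected; near-1 is renormalized
  comp <- matrix(1 / 10, 30, 10, dimnames = list(meta$sample_id, NULL))
  comp[1, ] <- 0.09
  expect_error(omics_matrix(comp, meta, kind = "microbiome", design = d),
               "sums to 0.9")
  comp[1, ] <- (1 + 5e-7) / 10
  ok <- omics_matrix(comp, meta, kind = "microbiome", design = d)
  expect_equal(rowSums(ok$values), rep(1, 30), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("omics tables round-trip through the CSV pair losslessly", {
  cfg <- fast_config(seed = 3, n_features = 12)
  om <- generate_omics(cfg, "metabolome")
  vp <- withr::local_tempfile(fileext = ".csv")
  mp <- withr::local_tempfile(fileext = ".csv")
  write_omics_table(om, vp, mp)
  back <- read_omics_table(vp, mp, kind = "metabolome")
  expect_equal(back$values, om$values, tolerance = 1e-12)
  expect_equal(back$sample_meta, om$sample_meta)
})
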