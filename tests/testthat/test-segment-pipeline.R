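seg_recording <- function(duration_s, intervals, n_channels = 23,
                          seed = 23) {
  cfg <- synth_config(n_channels = n_channels, seed = seed)
  rec <- generate_recording(cfg, duration_s = duration_s, n_seizures = 0)
  rec$seizure_intervals <- ictalcae:::as_intervals(intervals)
  rec
}

test_that("segment extraction cuts left-aligned non-overlapping windows", {
  rec <- seg_recording(80, rbind(c(10, 70)))
  # a 60-s ictal interval yields floor(60/4) = 15 four-second segments
  ict <- extract_segments(rec, segment_seconds = 4, state = "ictal")
  expect_equal(dim(ict$x), c(15, 1024, 23))
  expect_true(all(ict$labels == 1))
  # 2-s segments at 256 Hz are 512 x 23 matrices
  ict2 <- extract_segments(rec, segment_seconds = 2, state = "ictal")
  expect_equal(dim(ict2$x)[2:3], c(512, 23))
  # a region shorter than the window yields zero segments, not an error
  rec3 <- seg_recording(20, rbind(c(5, 8)))
  expect_equal(dim(extract_segments(rec3, segment_seconds = 4,
                                    state = "ictal")$x)[1], 0)
  # segments tile the region contiguously from its start
  first <- t(rec$values[, (10 * 256 + 1):(10 * 256 + 1024)])
  expect_equal(ict$x[1, , ], first)
})

test_that("interictal segments avoid the buffered seizure neighbourhood", {
  rec <- seg_recording(120, rbind(c(50, 70)), n_channels = 4)
  inter <- extract_segments(rec, segment_seconds = 4, state = "interictal",
                            buffer_s = 10)
  # usable regions are [0, 40) and [80, 120): 10 + 10 segments
  expect_equal(dim(inter$x)[1], 20)
  expect_true(all(inter$labels == 0))
  # ictal and interictal sets are disjoint in recording time: with the
  # default 30-min buffer this short recording has no interictal data at all
  none <- extract_segments(rec, segment_seconds = 4, state = "interictal")
  expect_equal(dim(none$x)[1], 0)
})

test_that("class balancing down-samples the interictal majority", {
  set.seed(29)
  ict <- array(rnorm(10 * 8 * 3), c(10, 8, 3))
  inter <- array(rnorm(100 * 8 * 3), c(100, 8, 3))
  bal <- balance_classes(ict, inter, seed = 4)
  expect_equal(dim(bal$x)[1], 20)
  expect_equal(sum(bal$labels == 1), sum(bal$labels == 0))
  # equal counts pass through unchanged
  same <- balance_classes(ict, ict + 1, seed = 4)
  expect_equal(same$x[11:20, , ], ict + 1)
  # fixed seed reproduces the subsample
  expect_identical(balance_classes(ict, inter, seed = 4)$x, bal$x)
  # not enough interictal data is an instructive error
  expect_error(balance_classes(inter, ict, seed = 1),
               "extract more interictal")
})

test_that("z-scoring uses merged population statistics with a zero-sd guard", {
  # a channel holding {1, 2, 3} across the merged data
  x <- array(c(1, 2, 3), c(3, 1, 1))
  z <- zscore_channels(x)
  expect_equal(as.numeric(z), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-6)
  # an already standardized channel is unchanged (population sd of {-1,1} = 1)
  x2 <- array(c(-1, 1), c(2, 1, 1))
  expect_equal(zscore_channels(x2), x2, tolerance = 1e-9)
  # a constant channel becomes all zeros, never a division fault
  x3 <- array(5, c(4, 2, 2))
  expect_true(all(zscore_channels(x3) == 0))
  # post-condition on real data: per-channel mean 0, sd 1 within 1e-6
  set.seed(31)
  xr <- array(rnorm(20 * 64 * 5, mean = 2, sd = 3), c(20, 64, 5))
  zr <- zscore_channels(xr)
  st <- channel_stats(zr)
  expect_true(all(abs(st$mean) < 1e-6))
  expect_true(all(abs(st$sd - 1) < 1e-6))
})

test_that("min-max scaling is one global affine map to [0, 1]", {
  mm <- minmax_scale(array(c(-1, 0, 1), c(3, 1, 1)))
  expect_equal(as.numeric(mm$values), c(0, 0.5, 1))
  expect_equal(mm$bounds, c(-1, 1))
  set.seed(32)
  r <- minmax_scale(array(rnorm(200), c(10, 5, 4)))
  expect_true(all(r$values >= 0 & r$values <= 1))
  expect_equal(range(r$values), c(0, 1))
  # degenerate constant input maps to zero
  expect_true(all(minmax_scale(array(3, c(2, 2, 1)))$values == 0))
})

test_that("normalization round-trips through denormalize within 1e-6", {
  set.seed(33)
  x <- array(rnorm(12 * 32 * 6, mean = -4, sd = 7), c(12, 32, 6))
  st <- channel_stats(x)
  z <- zscore_channels(x, st)
  mm <- minmax_scale(z)
  back <- denormalize(mm$values, st, mm$bounds)
  expect_equal(back, x, tolerance = 1e-6)
})

test_that("stratified folds balance classes within one segment", {
  labels <- rep(c(1L, 0L), each = 50)
  f <- assign_folds(labels, k = 10, seed = 5)
  expect_equal(sort(unique(f)), 0:9)
  expect_true(all(table(f) == 10))
  expect_true(all(table(f[labels == 1]) == 5))
  # 94 balanced segments: fold sizes and class counts within +/- 1
  lab94 <- rep(c(1L, 0L), each = 47)
  f94 <- assign_folds(lab94, k = 10, seed = 6)
  expect_equal(length(f94), 94)
  expect_true(max(table(f94)) - min(table(f94)) <= 2)
  for (cl in 0:1) {
    per <- table(factor(f94[lab94 == cl], levels = 0:9))
    expect_true(max(per) - min(per) <= 1)
  }
  expect_error(assign_folds(rep(c(0, 1), c(5, 50)), k = 10, seed = 1),
               "fewer than")
})

test_that("prepare_dataset applies the full pipeline in order", {
  set.seed(34)
  cfg <- synth_config(n_channels = 6, segment_seconds = 1,
                      n_segments_per_class = 15, seed = 35)
  seg <- generate_segments(cfg)
  ds <- prepare_dataset(seg$x[seg$labels == 1, , ],
                        seg$x[seg$labels == 0, , ], seed = 1, k = 5)
  expect_s3_class(ds, "eeg_dataset")
  expect_equal(dim(ds$x), c(30, 256, 6, 1))       # depth axis added
  expect_true(all(ds$x >= 0 & ds$x <= 1))
  expect_equal(sum(ds$labels == 1), sum(ds$labels == 0))
  expect_equal(sort(unique(ds$fold_ids)), 0:4)
  # recorded stats and bounds invert the normalization
  back <- denormalize(ds$x[, , , 1], ds$stats, ds$bounds)
  merged <- balance_classes(seg$x[seg$labels == 1, , ],
                            seg$x[seg$labels == 0, , ], seed = 1)
  expect_equal(back, merged$x, tolerance = 1e-6)
  # container round-trip
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(path))
  save_dataset(ds, path)
  expect_identical(load_dataset(path), ds)
})

test_that("segment provenance records source region and offset", {
  rec <- seg_recording(80, rbind(c(10, 70)), n_channels = 4)
  ict <- extract_segments(rec, segment_seconds = 4, state = "ictal",
                          record_id = "rec80")
  expect_equal(nrow(ict$provenance), dim(ict$x)[1])
  expect_true(all(ict$provenance$record_id == "rec80"))
  expect_true(all(ict$provenance$state == "ictal"))
  expect_equal(ict$provenance$offset_s, 10 + 4 * (0:14))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_segment_manifest(ict$provenance, path)
  back <- read.csv(path)
  expect_equal(back$offset_s, ict$provenance$offset_s)
})
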