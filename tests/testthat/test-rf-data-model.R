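test_that("RF container round-trips samples and metadata bitwise", {
  set.seed(1)
  frame <- rf_frame(matrix(rnorm(64 * 1024), 64, 1024),
                    sampling_rate = 40e6, center_frequency = 6e6,
                    line_pitch = 0.3e-3, sound_speed = 1540,
                    depth_origin = 2e-3)
  path <- withr::local_tempfile()
  write_rf_container(frame, path)
  back <- read_rf_container(path)
  expect_identical(back$samples, frame$samples)
  expect_identical(back$sampling_rate, frame$sampling_rate)
  expect_identical(back$depth_origin, frame$depth_origin)
})

test_that("container validation names the missing metadata key", {
  frame <- rf_frame(matrix(rnorm(8 * 32), 8, 32), 40e6, 6e6, 3e-4, 1540)
  path <- withr::local_tempfile()
  write_rf_container(frame, path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  meta$sampling_rate_hz <- NULL
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_rf_container(path), "sampling_rate_hz")
  expect_error(read_rf_container(withr::local_tempfile()), "sidecar")
})

test_that("a synthetic frame written to disk keeps a consistent depth axis", {
  acq <- tiny_acq(n_lines = 8, n_samples = 256)
  frame <- synthesize_reference(acq, seed = 3)
  path <- withr::local_tempfile()
  write_rf_container(frame, path)
  back <- read_rf_container(path)
  expect_length(rf_depth_axis(back), ncol(back$samples))
  expect_equal(rf_depth_axis(back)[1], acq$depth_origin)
  # deepest depth is bounded by what the record length can hold
  expect_lt(max(rf_depth_axis(back)),
            acq$depth_origin + acq$n_samples * 1540 / (2 * 40e6))
})

test_that("frame constructor rejects invalid inputs", {
  expect_error(rf_frame(matrix(c(1, NA), 1, 2), 40e6, 6e6, 3e-4, 1540),
               "finite")
  expect_error(rf_frame(matrix(1, 2, 2), -1, 6e6, 3e-4, 1540), "range")
})

test_that("partitioning a block-sized ROI yields exactly one block", {
  acq <- tiny_acq(n_lines = 16, n_samples = 600)
  frame <- rf_frame(matrix(rnorm(16 * 600), 16, 600), 40e6, 6e6,
                    0.25e-3, 1540, 2e-3)
  mm_s <- rf_mm_per_sample(frame)
  nbs <- round(2 / mm_s)          # samples spanning 2 mm
  nbl <- round(2 / 0.25)          # lines spanning 2 mm
  mask <- matrix(FALSE, 16, 600)
  mask[3:(3 + nbl - 1), 100:(100 + nbs - 1)] <- TRUE
  blocks <- partition_roi(frame, roi_from_mask(frame, mask))
  expect_length(blocks, 1)
  expect_equal(dim(blocks[[1]]$data), c(nbl, nbs))
})

test_that("a 4 x 2 mm ROI at 80% overlap tiles into 6 axial blocks", {
  frame <- rf_frame(matrix(rnorm(16 * 600), 16, 600), 40e6, 6e6,
                    0.25e-3, 1540, 0)
  mm_s <- rf_mm_per_sample(frame)
  nbs4 <- round(4 / mm_s)
  mask <- matrix(FALSE, 16, 600)
  mask[3:10, 100:(100 + nbs4 - 1)] <- TRUE   # 2 mm lateral, 4 mm axial
  blocks <- partition_roi(frame, roi_from_mask(frame, mask))
  expect_length(blocks, 6)
  centers_mm <- sapply(blocks, `[[`, "center_depth_cm") * 10
  # stride 0.4 mm: centers 1.0 ... 3.0 mm past the ROI top
  expect_equal(diff(sort(centers_mm)), rep(0.4, 5), tolerance = 0.05)
  expect_equal(max(centers_mm) - min(centers_mm), 2.0, tolerance = 0.05)
})

test_that("degenerate ROIs partition to an empty list", {
  frame <- rf_frame(matrix(rnorm(16 * 300), 16, 300), 40e6, 6e6,
                    0.25e-3, 1540, 0)
  empty <- roi_from_mask(frame, matrix(FALSE, 16, 300))
  expect_length(partition_roi(frame, empty), 0)
  small <- matrix(FALSE, 16, 300)
  small[1:3, 1:10] <- TRUE
  expect_warning(out <- partition_roi(frame, roi_from_mask(frame, small)),
                 "smaller than one")
  expect_length(out, 0)
})

test_that("block counts match a brute-force grid enumeration on random ROIs", {
  set.seed(7)
  frame <- rf_frame(matrix(rnorm(40 * 900), 40, 900), 40e6, 6e6,
                    0.3e-3, 1540, 1e-3)
  for (i in 1:50) {
    r0 <- sample(1:20, 1); r1 <- min(40, r0 + sample(5:25, 1))
    c0 <- sample(1:400, 1); c1 <- min(900, c0 + sample(80:450, 1))
    mask <- matrix(FALSE, 40, 900)
    mask[r0:r1, c0:c1] <- TRUE
    # randomly punch a hole to exercise the coverage rule
    if (i %% 3 == 0) {
      hr <- r0:min(r1, r0 + 3)
      hc <- c0:min(c1, c0 + 60)
      mask[hr, hc] <- FALSE
    }
    got <- suppressWarnings(
      length(partition_roi(frame, roi_from_mask(frame, mask))))
    want <- bf_block_count(frame, mask)
    expect_equal(got, want, info = paste("ROI case", i))
  }
})
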