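test_that("model invariants are enforced with named errors", {
  expect_error(grasp_model(onset_time = 5, offset_time = 3),
               "onset_time < offset_time")
  expect_error(grasp_model(duration = 2, offset_time = 6.5),
               "offset_time < duration")
  expect_error(grasp_model(n_active_sensors = 2000), "n_active_sensors")
  expect_error(grasp_model(peak_pressure = 600, baseline = 600), "bit_depth")
})

test_that("zero stimulus with zero noise and zero baseline is silence", {
  m <- test_model(peak_pressure = 0, noise_sd = 0, baseline = 0)
  rec <- generate_grasp(m)
  expect_true(all(rec$frames == 0))
})

test_that("generation is a pure function of the model", {
  m <- test_model()
  r1 <- generate_grasp(m)
  r2 <- generate_grasp(m)
  expect_identical(r1$frames, r2$frames)
  expect_identical(r1$sensor_mask, r2$sensor_mask)
  r3 <- generate_grasp(test_model(seed = 43L))
  expect_false(identical(r1$frames, r3$frames))
})

test_that("samples are integers inside the ADC range", {
  rec <- generate_grasp(test_model(noise_sd = 30))
  expect_true(all(rec$frames == round(rec$frames)))
  expect_gte(min(rec$frames), 0)
  expect_lte(max(rec$frames), 2^10 - 1)
})

test_that("a single narrow blob touches a small spatial footprint", {
  m <- grasp_model(noise_sd = 0, n_blobs = 1L, blob_width = 1.5, baseline = 0)
  rec <- generate_grasp(m)
  # oracle: count grid cells whose spatial Gaussian exceeds 1% of the peak,
  # computed from the blob geometry alone before looking at the recording
  fields <- tactwave:::.grasp_fields(m)
  s <- tactwave:::.spatial_field(m, fields)
  expected_cells <- sum(s > 0.01)
  touched <- apply(rec$frames, c(2, 3), max) > 0.01 * m$peak_pressure
  expect_lte(sum(touched), expected_cells)
  expect_lt(sum(touched) / (m$grid_rows * m$grid_cols), 0.10)
})

test_that("default recordings are spatiotemporally sparse above the resting level", {
  m <- grasp_model()
  rec <- generate_grasp(m)
  rest <- m$baseline * rep(as.logical(rec$sensor_mask), each = dim(rec$frames)[1])
  frac <- mean(abs(rec$frames - rest) > 0.01 * m$peak_pressure)
  expect_lt(frac, 0.20)
})

test_that("the envelope is zero outside the grasp and smooth inside", {
  m <- test_model(noise_sd = 0)
  rec <- generate_grasp(m)
  t <- (seq_len(dim(rec$frames)[1]) - 1) / m$sampling_rate
  active_energy <- apply(rec$frames, 1, function(f) sum(abs(f - m$baseline * rec$sensor_mask)))
  expect_true(all(active_energy[t < m$onset_time] == 0))
  expect_true(all(active_energy[t > m$offset_time] == 0))
  expect_gt(max(active_energy), 0)
})

test_that("zero-jitter trials replicate exactly apart from metadata", {
  m <- test_model()
  ds <- generate_dataset(m, 3, jitter = list(onset_sd = 0, amplitude_sd = 0,
                                             center_sd = 0))
  expect_length(ds, 3L)
  expect_identical(ds[[1]]$frames, ds[[2]]$frames)
  expect_identical(ds[[2]]$frames, ds[[3]]$frames)
  expect_equal(purrr::map_chr(ds, ~ .x$metadata$trial), c("1", "2", "3"))
})

test_that("a full multi-trial dataset carries distinct labels", {
  ds <- generate_dataset(test_model(), 26)
  expect_length(ds, 26L)
  expect_equal(anyDuplicated(purrr::map_chr(ds, ~ .x$metadata$trial)), 0L)
  # the sensor mask is a fixed property of the array
  expect_identical(ds[[1]]$sensor_mask, ds[[26]]$sensor_mask)
})

test_that("jittered peak times average to the configured peak time", {
  m <- test_model(noise_sd = 0)
  n <- 40
  ds <- generate_dataset(m, n, jitter = list(onset_sd = 0.2, amplitude_sd = 0,
                                             center_sd = 0))
  peak_t <- purrr::map_dbl(ds, function(r) {
    act <- apply(r$frames, 1, sum)
    ((which(act == max(act))[1] + rev(which(act == max(act)))[1]) / 2 - 1) /
      r$sampling_rate
  })
  configured <- (m$onset_time + m$offset_time) / 2
  se <- stats::sd(peak_t) / sqrt(n)
  expect_lt(abs(mean(peak_t) - configured), 3 * se + 1 / m$sampling_rate)
})
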