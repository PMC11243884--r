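small_survey <- function() {
  m <- test_model()
  ds <- generate_dataset(m, 2)
  # tolerance matched to the fixture's size (see test-search.R)
  run_survey(ds, wavelets = c("haar", "db2", "sym4"), dimensionalities = c(1, 3),
             targets = c(0.01, 0.0043), include_dct = TRUE,
             tolerance_factor = 1e-3)
}

test_that("the sweep produces one row per candidate cell", {
  tb <- small_survey()
  expect_s3_class(tb, "survey_table")
  expect_equal(nrow(tb), (3 + 1) * 2 * 2)  # (wavelets + dct) x dims x targets
  expect_equal(anyDuplicated(tb[, c("wavelet", "dimensionality", "target_nmse")]), 0L)
  expect_true(all(tb$status == "converged"))
  expect_true(all(abs(tb$achieved_nmse - tb$target_nmse) <=
                    1e-3 * tb$target_nmse + 1e-15))
  g <- glance(tb)
  expect_equal(g$n_cells, nrow(tb))
  expect_equal(g$n_converged, nrow(tb))
})

test_that("the survey is deterministic given dataset and settings", {
  t1 <- small_survey()
  t2 <- small_survey()
  expect_equal(tibble::as_tibble(t1), tibble::as_tibble(t2), tolerance = 0)
  expect_equal(attr(t1, "dataset_id"), attr(t2, "dataset_id"))
})

test_that("rankings sort correctly and exclude what they must", {
  tb <- small_survey()
  r <- rank_by(tb, 1, "sparsity", top_k = 2)
  expect_equal(nrow(r), 2L)
  expect_true(all(diff(r$sparsity) >= 0))
  expect_false("dct" %in% r$wavelet)
  r_all <- rank_by(tb, 1, "sparsity", top_k = 99)
  expect_equal(nrow(r_all), 3L)  # no padding beyond the converged entries
  re <- rank_by(tb, 1, "energy_ratio", top_k = 3)
  expect_true(all(diff(re$energy_ratio) <= 0))
  single <- rank_by(tb[tb$wavelet == "haar", ], 1, "sparsity", top_k = 5)
  expect_equal(single$rank, 1L)
  expect_equal(rank_by(tb, 1, "nbp", 3), rank_by(tb, 1, "nbp", 3))
})

test_that("the DCT-to-best-wavelet sparsity ratio behaves", {
  tb <- small_survey()
  ratio <- dct_sparsity_ratio(tb, 1, 0.01)
  dct_sp <- tb$sparsity[tb$transform == "dct" & tb$dimensionality == 1 &
                          tb$target_nmse == 0.01]
  best <- min(tb$sparsity[tb$transform == "dwt" & tb$dimensionality == 1 &
                            tb$target_nmse == 0.01])
  expect_equal(ratio, dct_sp / best)
  expect_error(dct_sparsity_ratio(tb, 2, 0.01), "lacks")
})

test_that("identical sparsities give a unit ratio", {
  tb <- tibble::tibble(
    wavelet = c("dct", "w1"), family = c("DCT", "F"),
    transform = c("dct", "dwt"), dimensionality = 1L, target_nmse = 0.01,
    sparsity = c(0.05, 0.05), status = "converged"
  )
  expect_equal(dct_sparsity_ratio(tb, 1, 0.01), 1)
})

test_that("the ratio is invariant to consistent rescaling of the data", {
  m <- test_model(noise_sd = 1)
  rec <- lowpass_denoise(generate_grasp(m))
  run_ratio <- function(scale, target) {
    d <- rec$frames * scale
    s_dct <- search_q(d, "dct", 1, target_nmse = target)
    s_dwt <- search_q(d, "sym4", 1, target_nmse = target)
    s_dct$sparsity / s_dwt$sparsity
  }
  # NMSE scales linearly under y -> c*y (squared error over mean), so the
  # target must be rescaled by the same factor
  r1 <- run_ratio(1, 0.01)
  r2 <- run_ratio(2, 0.02)
  expect_equal(r1, r2, tolerance = 1e-6)
})

test_that("an empty dataset is rejected and per-cell failures are recorded", {
  expect_error(run_survey(list()), "empty")
  m <- test_model()
  ds <- list(generate_grasp(m))
  tb <- run_survey(ds, wavelets = "fk4", dimensionalities = 1, targets = 0.01,
                   include_dct = FALSE)
  expect_match(tb$status, "error")
  expect_equal(tb$n_recordings, 0L)
})
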