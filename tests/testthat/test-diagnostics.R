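test_that("top-k curve endpoints satisfy the algebraic identities", {
  set.seed(51)
  x <- 50 + 10 * sin(seq(0, 6 * pi, length.out = 64)) + rnorm(64)
  res <- topk_reconstruction_curve(x, "sym4", 1, k_values = c(0, 8, 64))
  expect_equal(res$curve$nmse[res$curve$k == 64], 0, tolerance = 1e-12)
  expect_equal(res$curve$nmse[res$curve$k == 0], mean(x^2) / mean(x),
               tolerance = 1e-10)
  # float-exact reconstruction: PSNR at the Inf sentinel or numerically huge
  expect_gt(res$curve$psnr[res$curve$k == 64], 200)
  expect_equal(length(res$magnitudes), 64L)
  expect_true(all(diff(res$magnitudes) <= 0))
  expect_error(topk_reconstruction_curve(x, "sym4", 1, k_values = c(-1, 5)),
               "k_values")
  expect_error(topk_reconstruction_curve(x, "sym4", 1, k_values = integer(0)),
               "empty")
})

test_that("NMSE is non-increasing in k for orthogonal wavelets", {
  set.seed(52)
  x <- 100 + cumsum(rnorm(128))
  for (w in c("haar", "sym4")) {
    res <- topk_reconstruction_curve(x, w, 1, k_values = seq(0, 128, by = 8))
    expect_true(all(diff(res$curve$nmse) <= 1e-12))
  }
})

test_that("the top-k curve is reproducible bit for bit", {
  set.seed(53)
  x <- 10 + rnorm(64)
  r1 <- topk_reconstruction_curve(x, "db2", 1, k_values = c(4, 16))
  r2 <- topk_reconstruction_curve(x, "db2", 1, k_values = c(4, 16))
  expect_identical(r1$curve, r2$curve)
})

test_that("error profiles are exact on trivial cases and localized", {
  m <- test_model()
  rec <- generate_grasp(m)
  prof0 <- spatiotemporal_error_profile(rec, rec)
  expect_true(all(prof0$temporal$nmse == 0, na.rm = TRUE))
  expect_true(all(prof0$spatial$nmse == 0, na.rm = TRUE))
  # corrupt exactly one frame: the spatial profile flags only that time index
  bad <- rec$frames
  bad[17, , ] <- bad[17, , ] + 5
  prof <- spatiotemporal_error_profile(rec$frames, bad, rec$sensor_mask)
  nz <- which(prof$spatial$nmse != 0)
  expect_equal(nz, 17L)
  expect_error(spatiotemporal_error_profile(rec$frames, bad[1:10, , ]),
               "same shape")
})

test_that("per-slice profiles aggregate to the pooled NMSE when means agree", {
  set.seed(54)
  n_t <- 32; n_s <- 6
  y <- array(0, c(n_t, n_s, 1))
  for (j in seq_len(n_s)) {
    e <- rnorm(n_t)
    y[, j, 1] <- 100 + e - mean(e)  # every sensor has the same mean
  }
  yh <- y + array(rnorm(n_t * n_s, sd = 0.5), c(n_t, n_s, 1))
  prof <- spatiotemporal_error_profile(y, yh)
  pooled <- nmse(y, yh)
  expect_equal(mean(prof$temporal$nmse), pooled, tolerance = 1e-10)
})

test_that("the grand average recovers a shared envelope under onset jitter", {
  m <- test_model(noise_sd = 0)
  ds <- generate_dataset(m, 8, jitter = list(onset_sd = 0.25, amplitude_sd = 0,
                                             center_sd = 0))
  ga <- grand_average_interaction(ds)
  expect_equal(ga$n_trials, 8L)
  # true envelope: the activity series of an unjittered trial, from its onset
  ref <- generate_grasp(m)
  act <- tactwave:::.activity_series(ref)
  onset <- which(act > 0.1 * max(act))[1]
  truth <- act[onset:length(act)]
  truth_rs <- stats::approx(seq_along(truth), truth,
                            xout = seq(1, length(truth),
                                       length.out = nrow(ga$template)))$y
  expect_gt(stats::cor(ga$template$mean, truth_rs), 0.99)
})

test_that("identical trials average to themselves with zero deviation", {
  m <- test_model()
  ds <- generate_dataset(m, 3, jitter = list(onset_sd = 0, amplitude_sd = 0,
                                             center_sd = 0))
  ga <- grand_average_interaction(ds)
  expect_equal(max(ga$template$sd), 0, tolerance = 1e-10)
  expect_error(grand_average_interaction(ds[1]), "at least 2")
})

test_that("the filter-length trend fit recovers exact collinear points", {
  lengths <- c(2, 4, 6, 8, 10)
  tb <- tibble::tibble(
    wavelet = c("haar", "db2", "db3", "db4", "db5"),
    family = "Daubechies", transform = "dwt", dimensionality = 1L,
    target_nmse = 0.01, sparsity = 0.001 + 0.002 * lengths,
    status = "converged"
  )
  fit <- filter_length_vs_sparsity(tb, 1, 0.01)
  expect_equal(fit$slope, 0.002, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.001, tolerance = 1e-10)
  expect_equal(fit$conf_high - fit$conf_low, 0, tolerance = 1e-8)
  expect_error(filter_length_vs_sparsity(tb[1:2, ], 1, 0.01), "at least 3")
})

test_that("the slope CI covers zero at the nominal rate under the null", {
  set.seed(55)
  names12 <- c("haar", "db2", "db3", "db4", "db5", "db6", "db7", "db8",
               "sym4", "sym6", "coif1", "coif2")
  hits <- 0
  n_rep <- 400
  for (i in seq_len(n_rep)) {
    tb <- tibble::tibble(
      wavelet = names12, family = "x", transform = "dwt", dimensionality = 1L,
      target_nmse = 0.01, sparsity = rnorm(length(names12)),
      status = "converged"
    )
    fit <- filter_length_vs_sparsity(tb, 1, 0.01)
    if (fit$conf_low <= 0 && 0 <= fit$conf_high) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.93)
})

test_that("scaling-function similarity is signed and discriminates smoothness", {
  phi <- scaling_function("sym4")$phi
  expect_equal(scaling_similarity("sym4", phi), 1, tolerance = 1e-6)
  expect_equal(scaling_similarity("sym4", -phi), -1, tolerance = 1e-6)
  bump <- tactwave:::.grasp_envelope(seq(0, 8, by = 1 / 16), 1.5, 6.5, 0.4)
  expect_gt(scaling_similarity("sym4", bump), scaling_similarity("haar", bump))
  expect_error(scaling_similarity("sym4", rep(1, 50)), "non-constant")
})
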