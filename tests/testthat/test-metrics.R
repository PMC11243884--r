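make_cs <- function(values) {
  # a 1D DCT coefficient set is a convenient carrier for metric tests
  cs <- dct_forward(numeric(length(values)), 1)
  cs$bands$c[] <- values
  cs
}

test_that("quantization truncates toward zero", {
  cs <- make_cs(c(3.7, -3.7, 1.9, -1.9, 4.0, 0))
  q <- quantize(cs, 2)
  expect_equal(coef_values(q), c(2, -2, 0, 0, 4, 0))
  expect_error(quantize(cs, 0), "positive")
  expect_error(quantize(cs, -1), "positive")
})

test_that("NMSE is evaluated exactly as defined", {
  expect_equal(nmse(c(2, 2, 2), c(2, 2, 2)), 0)
  expect_equal(nmse(c(2, 2, 2), c(1, 2, 3)), 1 / 3)
  # constant offset: mean((c)^2)/mean(y) = c^2 / ybar
  y <- c(4, 6, 10)
  expect_equal(nmse(y, y + 0.5), 0.25 / mean(y), tolerance = 1e-12)
  expect_error(nmse(c(1, -1), c(0, 0)), "zero mean")
  expect_error(nmse(1:4, 1:3), "same shape")
  # the documented variance-normalized variant divides by the mean square
  expect_equal(nmse(y, y + 0.5, variance_normalized = TRUE),
               0.25 / mean(y^2), tolerance = 1e-12)
})

test_that("PSNR follows the closed form with an infinity sentinel", {
  y <- rep(0, 4)
  expect_equal(psnr(y, y), Inf)
  expect_equal(psnr(y, y + 1, peak = 1023), 10 * log10(1023^2),
               tolerance = 1e-12)
  expect_equal(psnr(y, y + 1, peak = 1023), 60.2, tolerance = 1e-3)
  # doubling the MSE lowers PSNR by ~3.01 dB
  expect_equal(psnr(y, y + 1, 1023) - psnr(y, y + sqrt(2), 1023),
               10 * log10(2), tolerance = 1e-10)
})

test_that("sparsity counts nonzeros against the input length", {
  expect_equal(sparsity_of(make_cs(c(0, 0, 5, 0))), 0.25)
  expect_equal(sparsity_of(make_cs(rep(0, 8))), 0)
  set.seed(20)
  cs <- dwt_forward(rnorm(64) + 10, "sym4", 1)
  expect_gt(sparsity_of(cs), 0.95)
})

test_that("bits per pixel implements the sign+magnitude accounting", {
  v <- rep(0, 100)
  v[7] <- 30  # k = 15 at Q = 2 -> b = 1 + ceil(log2(16)) = 5 bits
  cs <- make_cs(v)
  expect_equal(bits_per_pixel(cs, 2), 5 / 100)
  expect_equal(bits_per_pixel(make_cs(rep(0, 100)), 2), 0)
  expect_error(bits_per_pixel(make_cs(c(1.5, 0)), 2), "integer multiples")
})

test_that("bits per pixel is non-increasing in Q on a fixed coefficient set", {
  set.seed(21)
  cs <- dwt_forward(rnorm(128) * 50 + 200, "db2", 1)
  qs <- exp(seq(log(0.01), log(500), length.out = 40))
  nbp <- vapply(qs, function(q) bits_per_pixel(quantize(cs, q), q), numeric(1))
  expect_true(all(diff(nbp) <= 1e-12))
})

test_that("energy ratio is bounded and monotone in Q", {
  set.seed(22)
  cs <- dwt_forward(rnorm(128) * 10 + 100, "sym4", 1)
  expect_equal(energy_ratio(cs, cs), 1)
  zero <- quantize(cs, 2 * max(abs(coef_values(cs))))
  expect_equal(energy_ratio(zero, cs), 0)
  qs <- exp(seq(log(1e-6), log(1e4), length.out = 50))
  ers <- vapply(qs, function(q) energy_ratio(quantize(cs, q), cs), numeric(1))
  # truncation never grows a magnitude, so ER <= 1 always, -> 1 as Q -> 0 and
  # -> 0 once Q clears the largest coefficient; between those limits ER is a
  # sawtooth in Q (re-alignment on coarse grids), so no pointwise monotonicity
  expect_true(all(ers >= 0 & ers <= 1 + 1e-12))
  expect_equal(ers[1], 1, tolerance = 1e-6)
  expect_equal(ers[50], 0)
  expect_lt(stats::cor(log(qs), ers, method = "spearman"), -0.9)
  sps <- vapply(qs, function(q) sparsity_of(quantize(cs, q)), numeric(1))
  expect_true(all(diff(sps) <= 1e-12))
  expect_error(energy_ratio(make_cs(c(0, 0)), make_cs(c(0, 0))), "zero energy")
})
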