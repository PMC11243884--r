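test_that("maximum decomposition level follows the floor-log2 rule", {
  expect_equal(max_decomposition_level(8, 1), 3L)
  expect_equal(max_decomposition_level(100, 1), 6L)
  expect_equal(max_decomposition_level(c(500, 32, 32), 3), 5L)
  expect_equal(max_decomposition_level(c(500, 32, 32), 2), 5L)
  expect_equal(max_decomposition_level(c(500, 32, 32), 1), 8L)
  expect_error(max_decomposition_level(c(1, 32), 2), "at least 2")
})

test_that("constant input sends all detail coefficients to zero (Haar)", {
  cs <- dwt_forward(rep(7, 16), "haar", 1, level = 2)
  expect_equal(max(abs(cs$bands$d1)), 0)
  expect_equal(max(abs(cs$bands$d2)), 0)
  expect_equal(sum(cs$bands$a^2), sum(rep(7, 16)^2), tolerance = 1e-12)
})

test_that("multilevel output matches the naive convolve-then-decimate oracle", {
  set.seed(7)
  for (name in c("db2", "sym4", "bior2.2", "vaid")) {
    w <- wavelet_filter(name)
    x <- rnorm(64)
    want <- naive_pdwt_multilevel(x, w$dec_lo, w$dec_hi, level = 3)
    cs <- dwt_forward(x, name, 1, level = 3)
    expect_equal(as.numeric(cs$bands$a), want$a, tolerance = 1e-12)
    expect_equal(as.numeric(cs$bands$d1), want$d1, tolerance = 1e-12)
    expect_equal(as.numeric(cs$bands$d2), want$d2, tolerance = 1e-12)
    expect_equal(as.numeric(cs$bands$d3), want$d3, tolerance = 1e-12)
  }
})

test_that("transform agrees with the frozen external reference coefficients", {
  ref <- jsonlite::fromJSON(test_path("fixtures", "pywt_reference.json"),
                            simplifyVector = FALSE)
  x16 <- unlist(ref$x16)
  for (cse in ref$cases) {
    cs1 <- dwt_forward(x16, cse$wavelet, 1, level = 1)
    expect_equal(as.numeric(cs1$bands$a), unlist(cse$dwt_a), tolerance = 1e-10)
    expect_equal(as.numeric(cs1$bands$d1), unlist(cse$dwt_d), tolerance = 1e-10)
    cs2 <- dwt_forward(x16, cse$wavelet, 1, level = 2)
    expect_equal(as.numeric(cs2$bands$a), unlist(cse$wavedec2_a2), tolerance = 1e-10)
    expect_equal(as.numeric(cs2$bands$d2), unlist(cse$wavedec2_d2), tolerance = 1e-10)
    expect_equal(as.numeric(cs2$bands$d1), unlist(cse$wavedec2_d1), tolerance = 1e-10)
  }
})

test_that("perfect reconstruction holds across dimensionalities and batching", {
  set.seed(11)
  x1 <- rnorm(64)
  x2 <- array(rnorm(16 * 16), c(16, 16))
  x3 <- array(rnorm(32 * 16 * 16), c(32, 16, 16))
  for (name in c("db3", "sym8", "coif3", "bior4.4", "rbio2.8", "beyl")) {
    expect_equal(dwt_inverse(dwt_forward(x1, name, 1)), x1, tolerance = 1e-9)
    expect_equal(dwt_inverse(dwt_forward(x2, name, 2)), x2, tolerance = 1e-9)
    expect_equal(dwt_inverse(dwt_forward(x3, name, 3)), x3, tolerance = 1e-9)
    # batched semantics: 1D and 2D transforms of a volume
    expect_equal(dwt_inverse(dwt_forward(x3, name, 1)), x3, tolerance = 1e-9)
    expect_equal(dwt_inverse(dwt_forward(x3, name, 2)), x3, tolerance = 1e-9)
  }
})

test_that("batched 1D transform equals the per-taxel transform", {
  set.seed(12)
  x3 <- array(rnorm(32 * 4 * 3), c(32, 4, 3))
  cs <- dwt_forward(x3, "db2", 1)
  one <- dwt_forward(x3[, 2, 3], "db2", 1)
  expect_equal(as.numeric(cs$bands$a[, 2, 3]), as.numeric(one$bands$a),
               tolerance = 1e-12)
  expect_equal(as.numeric(cs$bands$d1[, 2, 3]), as.numeric(one$bands$d1),
               tolerance = 1e-12)
})

test_that("coefficient count equals the sample count (periodized extension)", {
  set.seed(13)
  x3 <- array(rnorm(64 * 8 * 8), c(64, 8, 8))
  for (d in 1:3) {
    cs <- dwt_forward(x3, "sym4", d)
    expect_equal(length(coef_values(cs)), length(x3))
  }
})

test_that("odd lengths are handled by replication and still reconstruct", {
  set.seed(14)
  x <- rnorm(100)  # 100 -> 50 -> 25 (odd) -> 13 ...
  cs <- dwt_forward(x, "db2", 1)  # max level 6
  expect_equal(cs$level, 6L)
  expect_equal(dwt_inverse(cs), x, tolerance = 1e-9)
})

test_that("Parseval equality holds for orthogonal wavelets", {
  set.seed(15)
  x <- rnorm(64)
  for (name in c("haar", "db6", "sym7", "coif4", "beyl", "vaid")) {
    cs <- dwt_forward(x, name, 1)
    expect_equal(sum(coef_values(cs)^2), sum(x^2), tolerance = 1e-10)
  }
  # biorthogonal transforms are not energy preserving; deviation is real
  csb <- dwt_forward(x, "bior3.1", 1)
  expect_gt(abs(sum(coef_values(csb)^2) - sum(x^2)) / sum(x^2), 0.01)
})

test_that("zeroing Haar details leaves blockwise means", {
  cs <- dwt_forward(c(1, 3, 5, 7), "haar", 1, level = 1)
  cs$bands$d1[] <- 0
  expect_equal(dwt_inverse(cs), c(2, 2, 6, 6), tolerance = 1e-12)
})

test_that("all-zero coefficients invert to an all-zero signal", {
  cs <- dwt_forward(rnorm(32), "sym4", 1)
  for (nm in names(cs$bands)) cs$bands[[nm]][] <- 0
  expect_equal(dwt_inverse(cs), rep(0, 32))
})

test_that("level and wavelet mismatches are rejected", {
  expect_error(dwt_forward(rnorm(16), "db2", 1, level = 10), "level")
  cs <- dwt_forward(rnorm(16), "db2", 1)
  expect_error(dwt_inverse(cs, "sym4"), "computed with")
  expect_error(dwt_forward(c(1, NA, 3, 4), "db2", 1), "finite")
})

test_that("DCT is orthonormal, invertible and concentrates constants", {
  set.seed(16)
  x1 <- rnorm(64)
  x3 <- array(rnorm(32 * 8 * 8), c(32, 8, 8))
  for (d in c(1, 3)) {
    x <- if (d == 1) x1 else x3
    cs <- dct_forward(x, d)
    expect_equal(dct_inverse(cs), x, tolerance = 1e-10)
    expect_equal(sum(coef_values(cs)^2), sum(x^2), tolerance = 1e-10)
  }
  x2 <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  cs2 <- dct_forward(x2, 2)
  expect_equal(dct_inverse(cs2), x2, tolerance = 1e-10)
  expect_equal(sum(coef_values(cs2)^2), sum(x2^2), tolerance = 1e-10)
  cc <- dct_forward(rep(5, 32), 1)
  v <- coef_values(cc)
  expect_equal(sum(abs(v) > 1e-10), 1L)
  expect_equal(v[1], 5 * sqrt(32), tolerance = 1e-12)
})

test_that("DCT agrees with the explicit cosine-matrix oracle", {
  set.seed(17)
  n <- 12
  x <- rnorm(n)
  k <- 0:(n - 1)
  basis <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
  basis[1, ] <- basis[1, ] / sqrt(2)
  expect_equal(coef_values(dct_forward(x, 1)), as.numeric(basis %*% x),
               tolerance = 1e-12)
})
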