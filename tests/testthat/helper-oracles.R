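# Independent oracles and shared fixtures for the test suite.

# Brute-force periodized filter-bank oracle: explicit full circular
# convolution followed by decimation, written independently of the package's
# transform code path. One level; iterate on `a` for multilevel.
naive_pdwt_level <- function(x, lo, hi) {
  n <- length(x)
  stopifnot(n %% 2 == 0)
  m <- length(lo)
  conv_circ <- function(f) {
    y <- numeric(n)
    for (i in seq_len(n)) {
      s <- 0
      for (j in seq_len(m)) {
        s <- s + f[j] * x[((i - 1) - (j - 1)) %% n + 1]
      }
      y[i] <- s
    }
    y
  }
  ylo <- conv_circ(lo)
  yhi <- conv_circ(hi)
  keep <- (2 * (seq_len(n / 2) - 1) + m %/% 2) %% n + 1
  list(a = ylo[keep], d = yhi[keep])
}

naive_pdwt_multilevel <- function(x, lo, hi, level) {
  details <- list()
  cur <- x
  for (l in seq_len(level)) {
    s <- naive_pdwt_level(cur, lo, hi)
    details[[sprintf("d%d", l)]] <- s$d
    cur <- s$a
  }
  c(list(a = cur), details)
}

# Exhaustive grid-search oracle for the quantization step
grid_search_q <- function(data, wavelet, dimensionality, target,
                          n_grid = 4000) {
  cs <- dwt_forward(data, wavelet, dimensionality)
  maxc <- max(abs(coef_values(cs)))
  lq <- seq(log(.Machine$double.eps * maxc), log(2 * maxc),
            length.out = n_grid)
  errs <- vapply(lq, function(l) {
    nmse(data, dwt_inverse(quantize(cs, exp(l))))
  }, numeric(1))
  best <- which.min(abs(errs - target))
  list(q = exp(lq[best]), nmse = errs[best], log_step = diff(lq[1:2]),
       log_q = lq, errs = errs)
}

# small deterministic model for desk-scale tests (16 x 16 grid keeps the
# spatial transforms cheap; proportions follow the full-size defaults)
test_model <- function(...) {
  args <- utils::modifyList(
    list(grid_rows = 16L, grid_cols = 16L, n_active_sensors = 137L,
         sampling_rate = 16, duration = 4, onset_time = 0.8,
         offset_time = 3.2, n_blobs = 2L, seed = 42L),
    list(...))
  do.call(grasp_model, args)
}
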