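# Binning, SNR, CV and mutual-information estimators.

test_that("equal-count binning splits evenly and degenerates are errors", {
  f <- field_from_xy(1:10, rep(0, 10), response = stats::runif(10),
                     covariate = 1:10)
  bs <- bin_cells(f, equal_count(5))
  expect_equal(bs$n, rep(2L, 5))
  # identical covariates cannot be binned
  f2 <- field_from_xy(1:10, rep(0, 10), response = 1:10, covariate = 1)
  expect_error(bin_cells(f2, equal_count(3)), "identical")
  # by-group bookkeeping over a dose series
  doses <- c(0.1, 1, 10)
  w <- make_dose_replicate(1, doses = doses, width = 250)
  bs3 <- bin_cells(w, by_group())
  expect_equal(nrow(bs3), 3L)
  expect_equal(sum(bs3$n), nrow(w))
  expect_equal(as.vector(table(w$group)[order(unique(w$group))]),
               bs3$n[order(unique(w$group))])
})

test_that("SNR matches the hand-computed two-bin example", {
  f <- field_from_xy(1:4, rep(0, 4), response = c(0, 2, 4, 6),
                     covariate = c(1, 1, 2, 2))
  r <- snr(f, equal_count(2))
  expect_equal(r$signal, 8)
  expect_equal(r$noise, 2)
  expect_equal(r$snr, 4)
  # zero-noise error path
  fz <- field_from_xy(1:4, rep(0, 4), response = c(0, 0, 1, 1),
                      covariate = c(1, 1, 2, 2))
  expect_error(snr(fz, equal_count(2)), "zero noise")
})

test_that("SNR is invariant under affine response rescaling", {
  w <- make_wound_replicate(2, side = 800)
  r1 <- snr(w, equal_count(10))
  w2 <- w
  w2$response <- 7 * w$response + 3
  r2 <- snr(w2, equal_count(10))
  expect_equal(r2$snr, r1$snr, tolerance = 1e-12)
})

test_that("shuffling responses destroys the gradient SNR", {
  hits <- 0L
  for (s in 1:50) {
    w <- make_wound_replicate(s, side = 800)
    r <- snr(w, equal_count(10))$snr
    set.seed(s + 4000L)
    ws <- w
    ws$response <- sample(w$response)
    if (snr(ws, equal_count(10))$snr < r) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.95)
})

test_that("paracrine averaging lowers the per-bin CV of noisy uniform responses", {
  hits <- 0L
  for (s in 1:50) {
    f <- dose_response_field(small_positions(s, width = 500, height = 500,
                                             density = 2e-3), 1,
                             noise = noise_model(0.8), seed = s + 900L)
    f$covariate <- f$x  # bin spatially: dose is uniform
    p <- paracrine_average(f, kernel_spec(100))
    cmp <- cv_compare(cv_by_bin(f, equal_count(8)),
                      cv_by_bin(p, equal_count(8)))
    if (cmp$mean_cv_a > cmp$mean_cv_b) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.95)
})

test_that("identical and constant inputs give the trivial CV comparisons", {
  w <- make_wound_replicate(3, side = 800)
  a <- cv_by_bin(w, equal_count(10))
  cmp <- cv_compare(a, a)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$mean_cv_a, cmp$mean_cv_b)
  wc <- w
  wc$response <- rep(2, nrow(w))
  expect_true(all(cv_by_bin(wc, equal_count(10))$cv == 0))
})

test_that("kNN density matches brute force and the uniform-grid closed form", {
  v <- seq(0, 1, length.out = 101)
  d <- knn_density(v, k = 10)
  # brute-force oracle per the definition
  brute <- vapply(seq_along(v), function(i) {
    w <- 2 * sort(abs(v[-i] - v[i]))[10]
    10 / (101 * w)
  }, numeric(1))
  expect_equal(d, brute, tolerance = 1e-12)
  # interior closed form: 10th NN at 5 grid steps -> width 0.1
  expect_equal(d[51], 10 / (101 * 0.1), tolerance = 1e-12)
  # scaling: values x c => density / c
  expect_equal(knn_density(3 * v, k = 10), d / 3, tolerance = 1e-12)
})

test_that("kNN density recovers the standard normal pdf at the median", {
  # a single k = 10 estimate has ~1/sqrt(k) relative noise, so the
  # Monte-Carlo check targets the seed-averaged estimate (the bias)
  ratios <- vapply(1:20, function(s) {
    set.seed(s)
    v <- stats::rnorm(1e4)
    med <- which.min(abs(v - stats::median(v)))
    knn_density(v)[med] / stats::dnorm(v[med])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.10)
})

test_that("duplicate-heavy samples trigger the zero-width fallback", {
  v <- c(rep(1, 15), seq(2, 3, length.out = 10))
  expect_warning(d <- knn_density(v, k = 10), "zero kNN width")
  expect_true(all(is.finite(d) & d > 0))
})

test_that("mutual information vanishes for independent responses", {
  mis <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 600
    f <- field_from_xy(stats::runif(n, 0, 1000), stats::runif(n, 0, 1000),
                       response = stats::rlnorm(n),
                       covariate = stats::runif(n))
    # the raw intercept (the clamp warning is expected under the null)
    suppressWarnings(
      mutual_information(f, bin_counts = c(4, 6, 8, 10))$fit_intercept)
  }, numeric(1))
  se <- stats::sd(mis) / sqrt(length(mis))
  expect_lt(abs(mean(mis)), 3 * se)
})

test_that("a noiseless channel carries log2(B) bits per binning", {
  set.seed(9)
  n <- 4000
  v <- stats::runif(n)
  f <- field_from_xy(stats::runif(n), stats::runif(n),
                     response = v, covariate = v)
  mi <- mutual_information(f, bin_counts = c(4, 8, 16))
  expect_equal(mi$mi_by_bins, log2(c(4, 8, 16)), tolerance = 0.15)
})

test_that("mutual information is invariant to monotone response transforms", {
  set.seed(10)
  n <- 5000
  w <- make_wound_replicate(10, side = 1200)
  mi1 <- mutual_information(w)$mi_bits
  wt <- w
  wt$response <- log1p(w$response)^3
  mi2 <- mutual_information(wt)$mi_bits
  expect_equal(mi2, mi1, tolerance = 0.1)
})

test_that("undersized bins are reported by name", {
  f <- field_from_xy(1:40, rep(0, 40), response = stats::runif(40),
                     covariate = 1:40)
  expect_error(mutual_information(f, bin_counts = c(4, 8)), "need > k_nn")
})
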