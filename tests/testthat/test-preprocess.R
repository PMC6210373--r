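test_that("sg_config enforces window constraints", {
  expect_error(sg_config(window = 120), "odd")
  expect_error(sg_config(window = 3, poly_order = 3), "exceed")
  ds <- toy_spectra(p = 40)
  expect_error(sg_smooth(ds, sg_config(window = 41, poly_order = 2)),
               "exceeds")
})

test_that("SG smoothing reproduces polynomials up to its order exactly", {
  p <- 200
  idx <- seq_len(p)
  set.seed(3)
  for (rep in 1:5) {
    coefs <- rnorm(3)
    spec <- coefs[1] + coefs[2] * idx + coefs[3] * idx^2
    ds <- spectra_set(seq(9000, 4000, length.out = p), rbind(spec, spec),
                      c("A", "B"))
    sm <- sg_smooth(ds, sg_config(window = 21, poly_order = 2))
    expect_equal(sm$absorbance[1, ], spec, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  # constant spectrum unchanged <=> coefficients sum to 1
  const <- spectra_set(seq_len(p), matrix(2.5, 1, p), "A")
  expect_equal(sg_smooth(const, sg_config(window = 31))$absorbance[1, ],
               rep(2.5, p), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum(sg_coeffs_oracle(31L, 2L)), 1, tolerance = 1e-12)
})

test_that("SG smoothing is linear in its input", {
  p <- 150
  set.seed(8)
  x1 <- rnorm(p); x2 <- rnorm(p)
  wn <- seq_len(p)
  sm <- function(v) {
    sg_smooth(spectra_set(wn, rbind(v), "A"),
              sg_config(window = 25))$absorbance[1, ]
  }
  expect_equal(sm(2 * x1 - 3 * x2), 2 * sm(x1) - 3 * sm(x2),
               tolerance = 1e-10)
})

test_that("SG noise-variance reduction matches the filter's sum of squared
           coefficients", {
  window <- 121L
  cc <- sg_coeffs_oracle(window, 2L)
  expect_lt(sum(cc^2), 1)
  p <- 100000L
  set.seed(21)
  noise <- rnorm(p)
  sm <- sg_smooth(spectra_set(seq_len(p), rbind(noise), "A"),
                  sg_config(window = window))$absorbance[1, ]
  interior <- (window + 1):(p - window)
  expect_equal(var(sm[interior]), sum(cc^2), tolerance = 0.02)
})

test_that("Mahalanobis distances match the definition on whitened data", {
  # identity covariance: distance equals Euclidean distance to the mean
  set.seed(14)
  x <- matrix(rnorm(200 * 5), 200, 5)
  x <- scale(x, center = TRUE, scale = FALSE)
  x <- x %*% solve(chol(cov(x)))        # exactly whitened
  ds <- spectra_set(1:5, x, rep(c("A", "B"), 100))
  rep_raw <- mahalanobis_distances(ds, space = "raw")
  eucl <- sqrt(rowSums(sweep(x, 2, colMeans(x))^2))
  expect_equal(rep_raw$distances, eucl, tolerance = 1e-3)

  # a sample equal to the mean has distance ~0
  x2 <- rbind(x, colMeans(x))
  ds2 <- spectra_set(1:5, x2, rep("A", 201))
  d2 <- mahalanobis_distances(ds2, space = "raw")$distances
  expect_lt(d2[201], 1e-6)

  expect_error(mahalanobis_distances(
    spectra_set(1:5, x[1:2, ], c("A", "B")), space = "raw"), "3 samples")
})

test_that("a displaced sample gets the largest distance and is removed", {
  set.seed(31)
  x <- matrix(rnorm(50 * 5), 50, 5)
  x[17, 1] <- x[17, 1] + 10            # 10-sd displacement on axis 1
  ds <- spectra_set(1:5, x, rep(letters[1:2], 25))
  rep_raw <- mahalanobis_distances(ds, space = "raw")
  expect_equal(which.max(rep_raw$distances), 17L)
  # dense linear-algebra oracle
  s <- cov(x) + diag(1e-6 * sum(diag(cov(x))) / 5, 5)
  d_oracle <- sqrt(mahalanobis(x, colMeans(x), s))
  expect_equal(rep_raw$distances, d_oracle, tolerance = 1e-8)

  out <- remove_outliers(ds, space = "raw", quantile = 0.999)
  expect_equal(out$report$flagged, 17L)
  expect_equal(nrow(out$spectra$absorbance), 49L)
  # surviving samples keep their order
  expect_equal(out$spectra$sample_ids, ds$sample_ids[-17])
})

test_that("outlier removal honours thresholds and refuses to empty the set", {
  set.seed(5)
  x <- matrix(rnorm(30 * 4), 30, 4)
  ds <- spectra_set(1:4, x, rep("A", 30))
  keep_all <- remove_outliers(ds, space = "raw", threshold = Inf)
  expect_length(keep_all$report$flagged, 0)
  expect_equal(keep_all$spectra$absorbance, ds$absorbance)
  expect_error(remove_outliers(ds, space = "raw", threshold = -1), "flags all")
})
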