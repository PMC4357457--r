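test_that("moment equations invert in closed form and round-trip", {
  p <- exgauss_from_moments(1.2, 0.24, tau_fraction = 0.5)
  expect_equal(p$tau, 0.288 / sqrt(2), tolerance = 1e-12)
  expect_equal(p$sigma_g, 0.288 / sqrt(2), tolerance = 1e-12)
  expect_equal(p$mu_g, 1.2 - 0.288 / sqrt(2), tolerance = 1e-12)
  # recomputed moments equal the targets to machine precision
  expect_equal(p$mu_g + p$tau, 1.2)
  expect_equal(sqrt(p$sigma_g^2 + p$tau^2) / 1.2, 0.24)

  # degenerate zero-variance case
  d <- exgauss_from_moments(0.857, 0)
  expect_equal(d$mu_g, 0.857)
  expect_identical(c(d$sigma_g, d$tau), c(0, 0))

  # the variance split moves mass between components but not the moments
  for (tf in c(0.2, 0.5, 0.8)) {
    q <- exgauss_from_moments(0.7, 0.24, tf)
    expect_equal(q$mu_g + q$tau, 0.7)
    expect_equal(sqrt(q$sigma_g^2 + q$tau^2) / 0.7, 0.24)
    expect_equal(q$tau^2 / (q$sigma_g^2 + q$tau^2), tf)
  }

  expect_error(exgauss_from_moments(-1, 0.24), "positive")
  expect_error(exgauss_from_moments(1.2, 1.0), "cv")
  expect_error(exgauss_from_moments(1.2, 0.24, 0), "tau_fraction")
})

test_that("sampled sequences recover the prescribed mean and cv", {
  rr <- sample_rr(5000, hr = 50, cv = 0.24, seed = 1)
  m <- mean(rr$intervals)
  expect_lt(abs(m - 1.2) / 1.2, 0.02)
  expect_lt(abs(sd(rr$intervals) / m - 0.24), 0.02)
  expect_true(all(rr$intervals > 0))
  expect_length(rr$intervals, 5000)
})

test_that("cv = 0 yields a strictly regular rhythm", {
  rr <- sample_rr(10, hr = 60, cv = 0)
  expect_identical(rr$intervals, rep(1.0, 10))
})

test_that("the exponential tail produces right-skewed sequences", {
  rr <- sample_rr(5000, hr = 130, cv = 0.24, seed = 7)
  # exGaussian skewness 2 tau^3 / (sigma^2 + tau^2)^(3/2) = 0.707 at the
  # default equal variance split; well above zero
  expect_gt(sample_skewness(rr$intervals), 0.3)
})

test_that("sampling is reproducible and respects the physiological floor", {
  a <- sample_rr(500, hr = 110, cv = 0.24, seed = 42)
  b <- sample_rr(500, hr = 110, cv = 0.24, seed = 42)
  expect_identical(a$intervals, b$intervals)
  c <- sample_rr(500, hr = 110, cv = 0.24, seed = 43)
  expect_false(identical(a$intervals, c$intervals))
  expect_true(all(a$intervals >= 0.25))
  # incompatible floor: nearly everything would be rejected
  expect_error(sample_rr(1000, hr = 130, cv = 0.24, rr_min = 0.6, seed = 1),
               "rejection")
  expect_warning(sample_rr(10, hr = 40, cv = 0.24, seed = 1), "50-130")
})

test_that("cv is recovered across the whole heart-rate range", {
  for (hr in c(50, 70, 90, 110, 130)) {
    rr <- sample_rr(20000, hr = hr, cv = 0.24, seed = 100 + hr)
    expect_lt(abs(sd(rr$intervals) / mean(rr$intervals) - 0.24), 0.02,
              label = paste("cv at", hr, "bpm"))
    expect_lt(abs(mean(rr$intervals) - 60 / hr) / (60 / hr), 0.02,
              label = paste("mean at", hr, "bpm"))
  }
})

test_that("the exGaussian density is normalized with the right moments", {
  p <- exgauss_from_moments(1.2, 0.24)
  total <- integrate(function(t) exgauss_pdf(t, p), -Inf, Inf,
                     rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-6)
  m1 <- integrate(function(t) t * exgauss_pdf(t, p), -Inf, Inf,
                  rel.tol = 1e-9)$value
  expect_equal(m1, p$mu_g + p$tau, tolerance = 1e-6)

  # faster rates shift the mode to shorter intervals
  grid <- seq(0.05, 2.5, by = 1e-3)
  mode_at <- function(hr) {
    q <- exgauss_from_moments(60 / hr, 0.24)
    grid[which.max(exgauss_pdf(grid, q))]
  }
  expect_lt(mode_at(130), mode_at(50))

  expect_error(exgauss_pdf(1, exgauss_from_moments(1.2, 0)), "degenerate")
})

test_that("RR sequences round-trip through the CSV writer", {
  rr <- sample_rr(50, hr = 70, cv = 0.24, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_rr_csv(rr, path)
  back <- read_rr_csv(path)
  expect_equal(back$intervals, round(rr$intervals, 6))
  expect_equal(back$hr_nominal, 70)
  expect_equal(back$cv_target, 0.24)
  expect_equal(back$seed, 3L)
})
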