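test_that("k = 1 fits return the exact ML mean and standard deviation", {
  set.seed(1)
  x <- rnorm(100, 39, 5)
  f <- fit_mixture(x, k = 1)
  expect_equal(f$means, mean(x), tolerance = 1e-6)
  expect_equal(f$sds, sqrt(mean((x - mean(x))^2)), tolerance = 1e-4)
  # order invariance
  f2 <- fit_mixture(sample(x), k = 1)
  expect_equal(f2$means, f$means, tolerance = 1e-9)
})

test_that("BIC selects one component for unimodal samples", {
  set.seed(2)
  f <- fit_mixture(rnorm(500, 39, 5), k = "auto")
  expect_equal(f$k, 1L)
  expect_lt(abs(f$means[1] - 39), 0.7)    # ~3 SE of the sample mean
})

test_that("a two-component sample at the reported mono mixture is recovered", {
  set.seed(3)
  n <- 1000
  comp <- rbinom(n, 1, 0.46)
  x <- ifelse(comp == 0, rnorm(n, 39, 5), rnorm(n, 14, 16))
  f <- fit_mixture(x, k = "auto")
  expect_equal(f$k, 2L)
  ord <- order(f$means, decreasing = TRUE)
  expect_lt(abs(f$means[ord][1] - 39), 2)
  expect_lt(abs(f$means[ord][2] - 14), 2)
  expect_lt(abs(f$weights[ord][1] - 0.54), 0.05)
  expect_equal(sum(f$weights), 1, tolerance = 1e-9)
  expect_true(all(diff(f$weights) <= 0))  # ordered by descending weight
})

test_that("small samples are refused", {
  expect_error(fit_mixture(rnorm(5)), "sample-too-small")
  expect_error(fit_mixture(rnorm(15), k = 2), "sample-too-small")
})

test_that("kde curves integrate to one and honour a fixed bandwidth", {
  set.seed(4)
  x <- rnorm(200, 10, 3)
  kd <- kde_curve(x)
  integral <- sum(diff(kd$grid) * (head(kd$density, -1) +
                                     tail(kd$density, -1)) / 2)
  expect_lt(abs(integral - 1), 0.02)

  # constant sample with bandwidth h -> a single Gaussian of sd h
  kc <- kde_curve(rep(5, 50), bandwidth = 2)
  expect_equal(kc$grid[which.max(kc$density)], 5, tolerance = 0.05)
  expect_equal(max(kc$density), stats::dnorm(0, sd = 2), tolerance = 1e-3)

  # two separated clusters -> bimodal curve
  kb <- kde_curve(c(rnorm(300, 0, 1), rnorm(300, 20, 1)))
  dens <- kb$density
  peaks <- which(diff(sign(diff(dens))) == -2) + 1
  expect_gte(length(peaks), 2)
  expect_error(kde_curve(rnorm(3)), "sample-too-small")
})

test_that("KDE curves export to CSV and read back", {
  kd <- kde_curve(rnorm(100), bandwidth = 1.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_kde_csv(kd, path)
  tab <- read.csv(path)
  expect_equal(tab$density, kd$density)
})

test_that("Boltzmann gaps match direct evaluation of -ln(p_i/p_j)", {
  expect_equal(boltzmann_gap(0.5, 0.5)$delta_u_kbt, 0)
  expect_equal(boltzmann_gap(0.38, 0.62)$delta_u_kbt, log(62 / 38),
               tolerance = 1e-12)
  expect_equal(boltzmann_gap(0.33, 0.67)$delta_u_kbt, log(67 / 33),
               tolerance = 1e-12)
  # antisymmetry, exactly
  expect_identical(boltzmann_gap(0.3, 0.6)$delta_u_kbt,
                   -boltzmann_gap(0.6, 0.3)$delta_u_kbt)
  expect_error(boltzmann_gap(0, 0.5), "strictly")
  expect_error(boltzmann_gap(0.5, 1), "strictly")
})

test_that("the sine-null KS statistic matches its closed forms", {
  # all mass at 45 degrees: sup gap is 1 - (1 - cos 45)
  res <- sin_null_test(rep(45, 50))
  expect_equal(res$statistic, cos(pi / 4), tolerance = 1e-9)

  # inverse-CDF draws from the null have small D
  set.seed(6)
  u <- runif(2000)
  phi <- acos(1 - u) * 180 / pi
  expect_lt(sin_null_test(phi)$statistic, 0.04)

  expect_error(sin_null_test(c(10, 95, rep(20, 10))), "\\[0, 90\\]")
  expect_error(sin_null_test(numeric(0)), "at least 10")
})

test_that("sine-null D shrinks with sample size under the null", {
  set.seed(7)
  med_d <- vapply(c(100, 1000, 10000), function(n) {
    median(vapply(1:5, function(i) {
      phi <- acos(1 - runif(n)) * 180 / pi
      sin_null_test(phi)$statistic
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_d) < 0))
})

test_that("Pearson correlation handles exact and null cases", {
  x <- 1:20
  expect_equal(pearson_r(x, 2 * x)$r, 1)
  set.seed(8)
  expect_lt(pearson_r(x, -x + rnorm(20, 0, 1e-8))$r, -0.999)
  r_null <- pearson_r(rnorm(1000), rnorm(1000))$r
  expect_lt(abs(r_null), 0.1)
  expect_error(pearson_r(1:5, rep(2, 5)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})
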