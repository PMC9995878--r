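test_that("coefficient of variation is SD over mean and scale-invariant", {
  expect_equal(coefficient_of_variation(c(1, 1, 1, 1)), 0)
  expect_equal(coefficient_of_variation(c(8, 12)), sqrt(8) / 10)
  x <- c(2, 3, 5, 7)
  expect_equal(coefficient_of_variation(13 * x),
               coefficient_of_variation(x))
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("within/between fascicle CoV separates the variance axes", {
  const <- matrix(0.4, 3, 4)
  cv <- cov_within_between(const)
  expect_equal(unname(cv$within), rep(0, 3))
  expect_equal(unname(cv$between), rep(0, 4))
  # variation only across slices: between-fascicle CoV stays 0
  tab <- matrix(rep(c(0.3, 0.4, 0.5, 0.6), each = 3), 3, 4)
  cv2 <- cov_within_between(tab)
  expect_equal(unname(cv2$between), rep(0, 4))
  expect_true(all(cv2$within > 0))
  # missing cells are skipped and counted
  tab[1, 2] <- NA
  cv3 <- cov_within_between(tab)
  expect_equal(cv3$n_missing, 1L)
  expect_error(cov_within_between(matrix(1, 1, 3)), "at least 2")
})

test_that("one-way ICC matches the ANOVA mean-squares oracle", {
  # perfect agreement
  tab <- cbind(c(0.2, 0.4, 0.6, 0.8), c(0.2, 0.4, 0.6, 0.8))
  expect_equal(icc_oneway(tab), 1)
  # oracle: mean squares from stats::aov on the long-format table
  icc_aov <- function(m) {
    d <- data.frame(y = as.vector(m),
                    subj = factor(rep(seq_len(nrow(m)), ncol(m))))
    ms <- summary(stats::aov(y ~ subj, data = d))[[1]]$`Mean Sq`
    k <- ncol(m)
    (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
  }
  set.seed(31)
  for (i in 1:20) {
    m <- matrix(stats::rnorm(10, mean = 0.5, sd = 0.1), 5, 2)
    expect_equal(icc_oneway(m), icc_aov(m), tolerance = 1e-10)
  }
  # identical subject means with pure within-subject noise: MSB = 0, so
  # ICC(1) collapses to -1/(k-1) exactly
  set.seed(32)
  for (k in 2:4) {
    m <- matrix(stats::rnorm(6 * k), 6, k)
    m <- m - rowMeans(m) + 0.5
    expect_equal(icc_oneway(m), -1 / (k - 1), tolerance = 1e-12)
  }
  # averaged-ratings form is larger for positive agreement
  m <- matrix(c(1, 2, 3, 1.1, 2.1, 3.2), 3, 2)
  expect_gt(icc_oneway(m, type = "ICC1k"), icc_oneway(m))
  expect_error(icc_oneway(matrix(0.5, 4, 2)), "zero total variance")
})

test_that("slice trend regression handles exact and degenerate series", {
  tr <- slice_trend(1:10, 0.3 + 0.02 * (1:10))
  expect_equal(tr$slope, 0.02, tolerance = 1e-12)
  expect_equal(tr$r, 1)
  expect_lt(tr$p, 1e-10)
  # constant index: no trend, by convention r = 0
  tr0 <- slice_trend(1:8, rep(0.4, 8))
  expect_equal(tr0$slope, 0)
  expect_equal(tr0$r, 0)
  expect_equal(tr0$p, 1)
  expect_error(slice_trend(rep(2, 5), stats::rnorm(5)), "constant")
  expect_error(slice_trend(1:2, c(1, 2)), "at least 3")
})

test_that("per-sample slope testing behaves on constructed cases", {
  # exact common slope: p below machine tolerance
  pairs <- lapply(1:3, function(i) list(x = 1:5, y = 2 * (1:5) + i))
  fc <- fascicle_correlation_test(pairs)
  expect_equal(unname(fc$slopes), rep(2, 3), tolerance = 1e-12)
  expect_equal(fc$p, 0)
  # antisymmetric slopes cancel: t = 0, p = 1
  pairs2 <- list(a = list(x = 1:5, y = (1:5)),
                 b = list(x = 1:5, y = -(1:5)))
  fc2 <- fascicle_correlation_test(pairs2)
  expect_equal(fc2$t, 0)
  expect_equal(fc2$p, 1)
  # degenerate sample dropped with warning
  pairs3 <- list(a = list(x = 1:5, y = stats::rnorm(5)),
                 b = list(x = 1:5, y = stats::rnorm(5)),
                 c = list(x = rep(1, 5), y = stats::rnorm(5)))
  expect_warning(fc3 <- fascicle_correlation_test(pairs3), "constant x")
  expect_equal(fc3$n_dropped, 1L)
  expect_length(fc3$slopes, 2)
})

test_that("type-I error of the slope test is near nominal under the null", {
  set.seed(77)
  n_rep <- 1000
  pvals <- replicate(n_rep, {
    pairs <- lapply(1:5, function(i)
      list(x = stats::rnorm(10), y = stats::rnorm(10)))
    fascicle_correlation_test(pairs)$p
  })
  rejection <- mean(pvals < 0.05)
  expect_equal(rejection, 0.05, tolerance = 0.02 / 0.05)
})

test_that("compartment contrast reports paired percent differences", {
  b <- c(0.5, 0.52, 0.48, 0.51)
  cc <- compartment_contrast(1.5 * b, b)
  expect_equal(cc$mean_pct, 50)
  expect_equal(cc$sd_pct, 0)
  cc0 <- compartment_contrast(b, b)
  expect_equal(cc0$mean_pct, 0)
  # closed form from the default compartment triples:
  # perineurium MD 0.7833, fascicle MD 0.53 -> +47.8%
  peri <- rep(compute_md(c(1.07, 0.75, 0.53)), 5)
  fasc <- rep(compute_md(c(0.81, 0.41, 0.37)), 5)
  cc2 <- compartment_contrast(peri, fasc)
  expect_equal(cc2$mean_pct, 47.8, tolerance = 0.01)
  expect_equal(cc2$sd_pct, 0)
  # scale invariance of the contrast
  cc3 <- compartment_contrast(3 * peri, 3 * fasc)
  expect_equal(cc3$mean_pct, cc2$mean_pct)
  expect_error(compartment_contrast(c(1, 2), c(1, 0)), "zero")
})
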