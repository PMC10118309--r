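test_that("detection model validates its parameters", {
  expect_s3_class(detection_model(1, 1), "detection_model")
  expect_error(detection_model(-0.1, 1), "mu")
  expect_error(detection_model(1, 0), "sigma")
  expect_error(detection_model(1, 1, prior_present = 1), "prior_present")
  expect_error(detection_model(1, 1, prior_present = 0), "prior_present")
})

test_that("log posterior ratio is affine in the measurement", {
  m <- detection_model(1, 1)
  expect_equal(log_posterior_ratio(0.5, m), 0)           # midpoint, equal priors
  expect_equal(log_posterior_ratio(1.5, m), 1.0)
  expect_equal(log_posterior_ratio(0, detection_model(2, 1)), -2.0)
  # unequal priors shift by the log prior odds
  m2 <- detection_model(1, 1, prior_present = 0.73)
  expect_equal(log_posterior_ratio(0.5, m2), log(0.73 / 0.27))
  # strictly increasing in x
  xs <- seq(-3, 3, length.out = 50)
  expect_true(all(diff(log_posterior_ratio(xs, m)) > 0))
  expect_error(log_posterior_ratio(0, detection_model(0, 1)), "degenerate")
})

test_that("criterion conversions match their closed forms and invert", {
  expect_equal(relative_from_absolute(k = 0.7, mu = 1.4, sigma = 3), 0)
  expect_equal(relative_from_absolute(1, 1, 1), 0.5)
  expect_equal(relative_from_absolute(1, 1, 2), 0.25)
  expect_equal(absolute_from_relative(0, 1, 1), 0.5)
  expect_equal(absolute_from_relative(0.5, 1, 1), 1.0)
  expect_equal(absolute_from_relative(0, 0, 5), 0)
  expect_error(relative_from_absolute(1, 1, 0), "sigma")
  expect_error(absolute_from_relative(1, 1, -1), "sigma")
  # inverse maps when mu = d' * sigma
  for (i in 1:25) {
    sigma <- runif(1, 0.1, 4); d <- runif(1, 0.1, 4); k <- rnorm(1, 0, 2)
    c_rel <- relative_from_absolute(k, d * sigma, sigma)
    expect_equal(absolute_from_relative(c_rel, d, sigma), k,
                 tolerance = 1e-12)
  }
})

test_that("threshold observer rates follow the normal CDF", {
  r <- rates_from_params(detection_model(1, 1), 0.5)
  expect_equal(r$H, 0.6914624613, tolerance = 1e-9)
  expect_equal(r$F, 0.3085375387, tolerance = 1e-9)
  r0 <- rates_from_params(detection_model(0, 2), 0)
  expect_equal(c(r0$H, r0$F), c(0.5, 0.5))
  r_far <- rates_from_params(detection_model(1, 1), 50)
  expect_true(all(c(r_far$H, r_far$F) < 1e-100))
  # H >= F whenever mu >= 0
  for (i in 1:20) {
    rr <- rates_from_params(detection_model(runif(1, 0, 3), runif(1, 0.2, 3)),
                            rnorm(1))
    expect_gte(rr$H, rr$F)
  }
})

test_that("z-transform summaries recover d' and c", {
  s <- summary_from_rates(0.5, 0.5)
  expect_equal(c(s$d_prime, s$c), c(0, 0))
  s1 <- summary_from_rates(0.6914624613, 0.3085375387)
  expect_equal(s1$d_prime, 1.0, tolerance = 1e-8)
  expect_equal(s1$c, 0.0, tolerance = 1e-8)
  s2 <- summary_from_rates(0.6914624613, 0.0668072013)
  expect_equal(s2$d_prime, 2.0, tolerance = 1e-8)
  expect_equal(s2$c, 0.5, tolerance = 1e-8)
  expect_error(summary_from_rates(1, 0.5), "boundary")
  expect_error(summary_from_rates(0.5, 0), "boundary")
})

test_that("round-trip from parameters to rates to summary is exact", {
  set.seed(42)
  for (i in 1:200) {
    # rates within the z-range double precision supports at 1e-9
    sigma <- runif(1, 0.05, 5)
    d <- runif(1, 0.05, 4)
    c_rel <- runif(1, -2.5, 2.5)
    mu <- d * sigma
    k <- sigma * (c_rel + d / 2)
    r <- rates_from_params(detection_model(mu, sigma), k)
    s <- summary_from_rates(r$H, r$F)
    expect_equal(s$d_prime, mu / sigma, tolerance = 1e-9)
    expect_equal(s$c, (k - mu / 2) / sigma, tolerance = 1e-9)
  }
})

test_that("Bayes criterion sits at the posterior crossover and maximizes accuracy", {
  b <- bayes_criterion(detection_model(1, 1))
  expect_equal(b$k, 0.5)
  expect_equal(b$c, 0)
  # equal priors: c is 0 whatever the absolute scale
  for (i in 1:10) {
    m <- detection_model(runif(1, 0.1, 4), runif(1, 0.1, 4))
    expect_identical(bayes_criterion(m)$c, 0)
  }
  # unequal priors: log prior odds near 1 pulls k to about -0.5
  m_biased <- detection_model(1, 1, prior_present = 0.73)
  b_biased <- bayes_criterion(m_biased)
  expect_equal(b_biased$k, 0.5 - log(0.73 / 0.27), tolerance = 1e-12)
  expect_equal(b_biased$k, -0.4946, tolerance = 1e-3)
  # grid-search oracle: expected accuracy is maximized at k_Bayes
  for (p in c(0.3, 0.5, 0.73)) {
    m <- detection_model(1.2, 0.8, prior_present = p)
    k_grid <- grid_optimal_detection_k(1.2, 0.8, p)
    expect_lt(abs(bayes_criterion(m)$k - k_grid), 1.001e-3)
  }
  # LPR at k_Bayes equals the decision threshold 0 at equal priors
  m <- detection_model(2, 1.5)
  expect_equal(log_posterior_ratio(bayes_criterion(m)$k, m), 0,
               tolerance = 1e-12)
  expect_error(bayes_criterion(detection_model(0, 1)), "degenerate")
})

test_that("LPR thresholding and measurement thresholding make identical decisions", {
  set.seed(7)
  for (i in 1:10) {
    m <- detection_model(runif(1, 0.2, 3), runif(1, 0.2, 3))
    x <- rnorm(200, mean = m$mu / 2, sd = 2 * m$sigma)
    k_b <- bayes_criterion(m)$k
    expect_identical(log_posterior_ratio(x, m) > 0, x > k_b)
  }
})

test_that("every noise-SD choice reproduces the same measured rates", {
  fam <- params_family_from_summary(1, 0.5, c(1, 2))
  expect_equal(fam$mu, c(1, 2))
  expect_equal(fam$k, c(1, 2))
  fam0 <- params_family_from_summary(0, 0, c(0.5, 1, 7))
  expect_true(all(fam0$mu == 0) && all(fam0$k == 0))
  # the degeneracy: identical (H, F) across arbitrary sigma choices
  set.seed(11)
  for (i in 1:30) {
    d <- runif(1, 0.1, 3); c_rel <- runif(1, -1, 1)
    sigmas <- runif(2, 0.1, 5)
    fam <- params_family_from_summary(d, c_rel, sigmas)
    r1 <- rates_from_params(detection_model(fam$mu[1], fam$sigma[1]), fam$k[1])
    r2 <- rates_from_params(detection_model(fam$mu[2], fam$sigma[2]), fam$k[2])
    expect_equal(r1$H, r2$H, tolerance = 1e-12)
    expect_equal(r1$F, r2$F, tolerance = 1e-12)
  }
})
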