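test_that("policy constructor enforces its parameter structure", {
  expect_s3_class(criterion_policy("fixed", k_ref = 1), "criterion_policy")
  expect_error(criterion_policy("power", k_ref = 1), "gamma")
  expect_error(criterion_policy("fixed", k_ref = 1, gamma = 0.5), "gamma")
  expect_error(criterion_policy("misbelief_bayes", k_ref = 1), "believed")
  expect_error(criterion_policy("fixed", k_ref = 1, sigma_ref = 0), "sigma_ref")
})

test_that("policies map noise to criteria by their stated rules", {
  fixed <- criterion_policy("fixed", k_ref = 1, sigma_ref = 1)
  expect_equal(policy_criterion(fixed, 2), 1)
  sqrt_pol <- criterion_policy("power", k_ref = 1, sigma_ref = 1, gamma = 0.5)
  expect_equal(policy_criterion(sqrt_pol, 2), sqrt(2))
  opt <- criterion_policy("bayes_optimal", k_ref = 1, sigma_ref = 1)
  expect_equal(policy_criterion(opt, 2), 2)
  expect_error(policy_criterion(fixed, -1), "sigma")
  # fixed is the gamma = 0 power law; optimal is the gamma = 1 power law
  sig <- c(0.5, 1, 1.7, 3)
  g0 <- criterion_policy("power", k_ref = 1.3, sigma_ref = 1, gamma = 0)
  g1 <- criterion_policy("power", k_ref = 1.3, sigma_ref = 1, gamma = 1)
  expect_equal(policy_criterion(g0, sig),
               policy_criterion(criterion_policy("fixed", 1.3), sig))
  expect_equal(policy_criterion(g1, sig),
               policy_criterion(criterion_policy("bayes_optimal", 1.3), sig))
})

test_that("linear scaling is the Bayes criterion under d'-matching", {
  # mu = d' * sigma with equal priors gives k_Bayes = mu/2 = (d'/2) * sigma
  d <- 1.4
  opt <- criterion_policy("bayes_optimal", k_ref = d / 2, sigma_ref = 1)
  for (sigma in c(1, 1.5, 2.5)) {
    kb <- bayes_criterion(detection_model(d * sigma, sigma))$k
    expect_equal(policy_criterion(opt, sigma), kb, tolerance = 1e-12)
  }
  # unequal priors defer to the full closed form
  k_unequal <- policy_criterion(opt, 2, prior_present = 0.7, d_prime = d)
  expect_equal(k_unequal,
               bayes_criterion(detection_model(d * 2, 2, 0.7))$k)
  expect_error(policy_criterion(opt, 2, prior_present = 0.7), "d_prime")
})

test_that("wrong-belief Bayesian observer spans fixed to optimal", {
  sig <- c(1, 1.6, 2, 3)
  believe_nothing <- criterion_policy("misbelief_bayes", k_ref = 0.8,
                                      sigma_ref = 1, believed_sigma_ratio = 1)
  expect_equal(policy_criterion(believe_nothing, sig),
               policy_criterion(criterion_policy("fixed", 0.8), sig))
  # believing the true ratio recovers the optimal criterion at that ratio
  true_ratio <- 2
  believer <- criterion_policy("misbelief_bayes", k_ref = 0.8, sigma_ref = 1,
                               believed_sigma_ratio = true_ratio)
  opt <- criterion_policy("bayes_optimal", k_ref = 0.8, sigma_ref = 1)
  expect_equal(policy_criterion(believer, true_ratio),
               policy_criterion(opt, true_ratio))
  # an intermediate wrong belief lands strictly inside the admissible region
  partial <- criterion_policy("misbelief_bayes", k_ref = 0.8, sigma_ref = 1,
                              believed_sigma_ratio = 1.5)
  k_inv <- policy_criterion(partial, 2)
  expect_identical(iarf_satisfied(1, 2, k_val = 0.8, k_inv = k_inv),
                   "strictly_inside")
})

test_that("criterion pairs classify against the signature inequality", {
  expect_identical(iarf_satisfied(1, 2, k_val = 1, k_inv = 1),
                   "strictly_inside")
  expect_identical(iarf_satisfied(1, 2, k_val = 1, k_inv = 2), "boundary")
  expect_identical(iarf_satisfied(1, 2, k_val = 1, k_inv = 2.5), "outside")
  expect_error(iarf_satisfied(2, 1, 1, 1), "sigma_inv > sigma_val")
  expect_error(iarf_satisfied(1, 2, k_val = 0, k_inv = 1), "k_val")
})

test_that("sub-linear policies stay strictly inside; linear rides the boundary", {
  set.seed(5)
  for (i in 1:40) {
    gamma <- runif(1, 0, 1 - 1e-6)
    k_val <- runif(1, 0.1, 3)
    ratio <- runif(1, 1 + 1e-4, 5)
    pol <- criterion_policy("power", k_ref = k_val, sigma_ref = 1,
                            gamma = gamma)
    expect_identical(
      iarf_satisfied(1, ratio, k_val, policy_criterion(pol, ratio)),
      "strictly_inside")
    lin <- criterion_policy("bayes_optimal", k_ref = k_val, sigma_ref = 1)
    expect_identical(
      iarf_satisfied(1, ratio, k_val, policy_criterion(lin, ratio)),
      "boundary")
  }
})

test_that("region map marks the admissible set, its boundary, and the invalid zone", {
  reg <- iarf_region(sigma_ratio_grid = c(0.5, 1, 2, 3),
                     k_ratio_grid = c(0, 1, 2, 2.5))
  at <- function(sr, kr) reg$status[reg$sigma_ratio == sr & reg$k_ratio == kr]
  expect_identical(at(2, 1), "strictly_inside")
  expect_identical(at(2, 2), "boundary")
  expect_identical(at(2, 2.5), "outside")
  expect_true(all(reg$status[reg$sigma_ratio < 1] == "invalid"))
  expect_error(iarf_region(numeric(0)), "empty")
  expect_error(iarf_region(c(-1, 2)), "positive")
  # default grid contains the three reference lines' span
  reg_d <- iarf_region()
  expect_equal(range(reg_d$sigma_ratio), c(1, 3))
  expect_equal(range(reg_d$k_ratio), c(0, 2.5))
  expect_equal(nrow(reg_d), 251L * 251L)
})

test_that("relative-criterion signature separates policies by exponent", {
  fixed <- criterion_policy("fixed", k_ref = 1, sigma_ref = 1)
  expect_equal(signature_under_policy(fixed, 1, 2, 1),
               c(c_val = 0.5, c_inv = 0))
  sqrt_pol <- criterion_policy("power", k_ref = 1, sigma_ref = 1, gamma = 0.5)
  expect_equal(signature_under_policy(sqrt_pol, 1, 2, 1),
               c(c_val = 0.5, c_inv = sqrt(2) / 2 - 0.5))
  opt <- criterion_policy("bayes_optimal", k_ref = 0.7, sigma_ref = 1)
  cc <- signature_under_policy(opt, 1, 2, 1)
  expect_equal(cc[["c_val"]], cc[["c_inv"]])
  # gamma < 1 shows the inflation signature, gamma > 1 reverses it:
  # measuring the signature cannot identify the exponent
  set.seed(9)
  for (i in 1:20) {
    g <- runif(1, 0, 2)
    pol <- criterion_policy("power", k_ref = runif(1, 0.2, 2),
                            sigma_ref = 1, gamma = g)
    cc <- signature_under_policy(pol, 1, runif(1, 1.2, 3), runif(1, 0.5, 2))
    if (g < 1) expect_lt(cc[["c_inv"]], cc[["c_val"]])
    if (g > 1) expect_gt(cc[["c_inv"]], cc[["c_val"]])
  }
  # cross-check against the analytic signature expression
  expect_equal(signature_under_policy(sqrt_pol, 1, 2, 1),
               c(c_val = analytic_signature(0.5, 1, 1, 2, 1)[1],
                 c_inv = analytic_signature(0.5, 1, 1, 2, 1)[2]))
})
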