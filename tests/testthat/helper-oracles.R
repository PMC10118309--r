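# Independent oracles used across the suite. These deliberately avoid the
# package's own closed forms: quadrature and grid search only.

# P(respond "category 2") under the embedded-category generative model,
# by numeric quadrature over the true stimulus s
quad_embedded_cat2_fraction <- function(sigma_narrow, sigma_broad, sigma_m,
                                        prior_cat1, k) {
  f <- function(s) {
    mix <- prior_cat1 * dnorm(s, 0, sigma_narrow) +
      (1 - prior_cat1) * dnorm(s, 0, sigma_broad)
    p_resp2 <- if (sigma_m > 0) {
      pnorm((s - k) / sigma_m) + pnorm((-k - s) / sigma_m)
    } else {
      as.numeric(abs(s) > k)
    }
    mix * p_resp2
  }
  integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
}

# expected accuracy of the two-sided rule |x| > k in the embedded task,
# using only the marginal measurement distributions
embedded_accuracy <- function(k, v1, v2, prior_cat1) {
  prior_cat1 * (2 * pnorm(k / sqrt(v1)) - 1) +
    (1 - prior_cat1) * 2 * pnorm(-k / sqrt(v2))
}

# brute-force maximiser of embedded-task accuracy on a fixed-resolution grid
grid_optimal_embedded_k <- function(sigma_narrow, sigma_broad, sigma_m,
                                    prior_cat1 = 0.5, k_max = NULL,
                                    resolution = 1e-3) {
  v1 <- sigma_narrow^2 + sigma_m^2
  v2 <- sigma_broad^2 + sigma_m^2
  if (is.null(k_max)) k_max <- 5 * sqrt(v2)
  ks <- seq(0, k_max, by = resolution)
  ks[which.max(embedded_accuracy(ks, v1, v2, prior_cat1))]
}

# brute-force maximiser of detection-task response accuracy over k
grid_optimal_detection_k <- function(mu, sigma, prior_present,
                                     resolution = 1e-3) {
  ks <- seq(-3 * sigma + min(0, mu), mu + 3 * sigma, by = resolution)
  acc <- (1 - prior_present) * pnorm(ks / sigma) +
    prior_present * pnorm((mu - ks) / sigma)
  ks[which.max(acc)]
}

# delta-method standard error of the empirical relative criterion
# c_hat = -(z(H) + z(F))/2
se_c_hat <- function(H, F, n_present, n_absent) {
  var_zH <- H * (1 - H) / (n_present * dnorm(qnorm(H))^2)
  var_zF <- F * (1 - F) / (n_absent * dnorm(qnorm(F))^2)
  0.5 * sqrt(var_zH + var_zF)
}

# analytic (c_val, c_inv) for a power-law criterion policy under d'-matching
analytic_signature <- function(gamma, k_ref, sigma_val, sigma_inv, d_prime) {
  k <- k_ref * (c(sigma_val, sigma_inv) / sigma_val)^gamma
  k / c(sigma_val, sigma_inv) - d_prime / 2
}
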