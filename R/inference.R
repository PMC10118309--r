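#' Per-condition SDT summaries from trial data
#'
#' Computes empirical hit and false-alarm rates per condition and converts
#' them to d' and c with [summary_from_rates()]. Rates of exactly 0 or 1 are
#' boundary-corrected by the 1/(2N) rule (0 becomes 1/(2N), 1 becomes
#' 1 - 1/(2N), with N the number of trials of that truth class in that
#' condition) before the z-transform.
#'
#' @param trials A trial table from [simulate_detection()] (or a compatible
#'   data frame with columns \code{condition}, \code{truth}, \code{response};
#'   truth coded "present"/"absent" and response 1 = "present").
#' @return An \code{sdt_summary} data frame with one row per condition:
#'   columns \code{condition}, \code{n_present}, \code{n_absent}, \code{H},
#'   \code{F}, \code{d_prime}, \code{c}.
#' @export
estimate_summary <- function(trials) {
  stopifnot(all(c("condition", "truth", "response") %in% names(trials)))
  conds <- unique(trials$condition)
  rows <- lapply(conds, function(cond) {
    tt <- trials[trials$condition == cond, ]
    n_p <- sum(tt$truth == "present")
    n_a <- sum(tt$truth == "absent")
    if (n_p == 0L || n_a == 0L)
      stop("insufficient data: condition '", cond,
           "' is missing present or absent trials")
    H <- correct_boundary_rate(sum(tt$response == 1L & tt$truth == "present") / n_p, n_p)
    F <- correct_boundary_rate(sum(tt$response == 1L & tt$truth == "absent") / n_a, n_a)
    cbind(data.frame(condition = cond, n_present = n_p, n_absent = n_a),
          as.data.frame(summary_from_rates(H, F)))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("sdt_summary", "data.frame"))
}

correct_boundary_rate <- function(p, n) {
  if (p <= 0) 1 / (2 * n) else if (p >= 1) 1 - 1 / (2 * n) else p
}

#' Ideal decision boundary for the embedded-category task
#'
#' Under the generative model, the measurement is marginally
#' Normal(0, sigma_C^2 + sigma_m^2) for category C, so the likelihood-ratio
#' rule is two-sided in |x| and the ideal boundary k* equates the
#' prior-weighted measurement densities of the two categories. With
#' v1 = sigma_narrow^2 + sigma_m^2, v2 = sigma_broad^2 + sigma_m^2 and prior
#' odds pi = prior_cat1 / (1 - prior_cat1),
#' \deqn{k^{*2} = \frac{\log(v_2/v_1) + 2 \log \pi}{1/v_1 - 1/v_2}.}
#' The boundary grows with measurement noise — the incentive to shift the
#' criterion that detection tasks lack. When the prior term makes the
#' numerator non-positive (an extreme category-2 prior), no interior boundary
#' exists and one response is always optimal; this is reported as an error
#' rather than clamped.
#'
#' @param model An [embedded_category_model()].
#' @return Ideal absolute boundary k*, degrees (a single non-negative number).
#' @examples
#' # unit-variance narrow and 4x broad category, no measurement noise:
#' m <- embedded_category_model(1, 2, sigma_m = 0)
#' optimal_embedded_criterion(m)  # sqrt(log(4) / 0.75)
#' @export
optimal_embedded_criterion <- function(model) {
  stopifnot(inherits(model, "embedded_category_model"))
  v1 <- model$sigma_narrow^2 + model$sigma_m^2
  v2 <- model$sigma_broad^2 + model$sigma_m^2
  log_odds <- log(model$prior_cat1 / (1 - model$prior_cat1))
  bracket <- log(v2 / v1) + 2 * log_odds
  if (bracket <= 0)
    stop("no interior boundary: the category-2 prior is extreme enough that responding \"category 2\" (or 1) is always optimal")
  sqrt(bracket / (1 / v1 - 1 / v2))
}

#' Probability of a "category 2" response given the true orientation
#'
#' The Bernoulli kernel of the embedded-category observer: with measurement
#' x ~ Normal(s, sigma_m) and the two-sided rule |x| > k,
#' \code{P(resp = 2 | s) = pnorm((s - k)/sigma_m) + pnorm((-k - s)/sigma_m)}.
#' Symmetric in s, increasing in |s|; this is the likelihood kernel
#' [fit_embedded_observer()] maximises.
#'
#' @param s True orientation(s), degrees.
#' @param k Decision boundary, degrees; >= 0.
#' @param sigma_m Measurement-noise SD, degrees; > 0.
#' @return Probabilities in (0, 1), vectorised over \code{s}.
#' @export
embedded_response_probability <- function(s, k, sigma_m) {
  stopifnot(is.numeric(s), is.numeric(k), is.numeric(sigma_m))
  if (any(sigma_m <= 0)) stop("'sigma_m' must be > 0")
  if (any(k < 0)) stop("'k' must be >= 0")
  stats::pnorm((s - k) / sigma_m) + stats::pnorm((-k - s) / sigma_m)
}

#' Enumerate the (mu, sigma, k) family behind one measured (d', c)
#'
#' For each noise-SD choice on \code{sigma_grid}, reports the generative
#' triple that reproduces the given summary statistics, together with the hit
#' and false-alarm rates it implies — identical for every row, which is the
#' unidentifiability at the heart of the detection task. A companion table
#' classifies candidate criterion ratios for a valid/invalid pair with noise
#' ratio \code{sigma_ratio} (fixed = 1, square-root, and linear scaling)
#' against the signature inequality, showing that both fixed and flexible
#' criteria sit inside the admissible region.
#'
#' @param d_prime Measured discriminability.
#' @param c_rel Measured relative criterion.
#' @param sigma_grid Noise-SD choices, > 0.
#' @param sigma_ratio Noise ratio sigma_inv/sigma_val for the pair analysis,
#'   > 1.
#' @param tol Boundary tolerance passed to the signature classification.
#' @return An object of class \code{"degeneracy_report"}: a list with
#'   \code{family} (data frame sigma, mu, k, H, F) and \code{pair} (data
#'   frame policy, k_ratio, status).
#' @export
degeneracy_report <- function(d_prime, c_rel, sigma_grid = c(0.5, 1, 2, 4),
                              sigma_ratio = 2, tol = 1e-9) {
  stopifnot(is.numeric(sigma_grid), all(sigma_grid > 0), sigma_ratio > 1)
  fam <- params_family_from_summary(d_prime, c_rel, sigma_grid)
  rates <- mapply(function(mu, sigma, k) {
    r <- rates_from_params(detection_model(mu, sigma), k)
    c(r$H, r$F)
  }, fam$mu, fam$sigma, fam$k)
  fam$H <- rates[1, ]
  fam$F <- rates[2, ]
  k_ratios <- c(fixed = 1, sqrt = sqrt(sigma_ratio), linear = sigma_ratio)
  pair <- data.frame(policy = names(k_ratios),
                     sigma_ratio = sigma_ratio,
                     k_ratio = unname(k_ratios),
                     status = classify_iarf(sigma_ratio, unname(k_ratios), tol),
                     row.names = NULL)
  structure(list(family = fam, pair = pair,
                 d_prime = d_prime, c_rel = c_rel),
            class = "degeneracy_report")
}

#' @export
print.degeneracy_report <- function(x, ...) {
  cat(sprintf("Solution family for measured d' = %g, c = %g\n",
              x$d_prime, x$c_rel))
  cat("Every (mu, sigma, k) row reproduces the same (H, F):\n")
  print(x$family, row.names = FALSE)
  cat(sprintf("\nCriterion-ratio candidates at noise ratio %g:\n",
              x$pair$sigma_ratio[1]))
  print(x$pair, row.names = FALSE)
  invisible(x)
}
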