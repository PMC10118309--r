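#' Criterion-setting policy: how the absolute criterion tracks noise
#'
#' A policy is a rule mapping the measurement-noise level sigma to an absolute
#' criterion k. The family is anchored at a reference condition
#' (\code{k_ref} at \code{sigma_ref}) and covers:
#' \describe{
#'   \item{\code{"fixed"}}{k is constant across noise levels — the unified
#'     criterion hypothesis. Equivalent to \code{"power"} with
#'     \code{gamma = 0}.}
#'   \item{\code{"power"}}{\code{k = k_ref * (sigma/sigma_ref)^gamma}. The
#'     square-root observer is \code{gamma = 0.5}; any \code{gamma} in [0, 1)
#'     shifts the criterion in the optimal direction but short of the optimal
#'     magnitude.}
#'   \item{\code{"bayes_optimal"}}{linear scaling \code{k = k_ref *
#'     (sigma/sigma_ref)}, the Bayes-optimal rule for a d'-matched detection
#'     task with equal priors (where \code{k_Bayes = mu/2 = d' * sigma / 2}).
#'     Equivalent to \code{"power"} with \code{gamma = 1}.}
#'   \item{\code{"misbelief_bayes"}}{a Bayesian observer who sets the optimal
#'     criterion under a wrong belief about how much the noise changed: at the
#'     reference noise they use \code{k_ref}; at any other noise level they
#'     believe the noise grew by \code{believed_sigma_ratio} and use
#'     \code{k_ref * believed_sigma_ratio}. With a believed ratio of 1 this is
#'     exactly the fixed policy; with the believed ratio equal to the true
#'     ratio it is exactly the Bayes-optimal policy.}
#' }
#'
#' @param kind One of \code{"fixed"}, \code{"power"}, \code{"bayes_optimal"},
#'   \code{"misbelief_bayes"}.
#' @param k_ref Criterion at the reference noise level, measurement units.
#' @param sigma_ref Reference noise level, > 0.
#' @param gamma Scaling exponent, required for \code{kind = "power"}.
#' @param believed_sigma_ratio Observer's believed noise ratio relative to the
#'   reference condition, required for \code{kind = "misbelief_bayes"}; > 0.
#' @return An object of class \code{"criterion_policy"}.
#' @seealso [policy_criterion()], [signature_under_policy()]
#' @examples
#' sqrt_obs <- criterion_policy("power", k_ref = 1, sigma_ref = 1, gamma = 0.5)
#' policy_criterion(sqrt_obs, sigma = 2)  # sqrt(2)
#' @export
criterion_policy <- function(kind = c("fixed", "power", "bayes_optimal",
                                      "misbelief_bayes"),
                             k_ref, sigma_ref = 1, gamma = NULL,
                             believed_sigma_ratio = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(k_ref), length(k_ref) == 1L, is.finite(k_ref),
            is.numeric(sigma_ref), length(sigma_ref) == 1L)
  if (sigma_ref <= 0) stop("'sigma_ref' must be > 0")
  if (kind == "power") {
    stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  } else if (!is.null(gamma)) {
    stop("'gamma' applies only to kind = \"power\"")
  }
  if (kind == "misbelief_bayes") {
    stopifnot(is.numeric(believed_sigma_ratio),
              length(believed_sigma_ratio) == 1L)
    if (believed_sigma_ratio <= 0)
      stop("'believed_sigma_ratio' must be > 0")
  } else if (!is.null(believed_sigma_ratio)) {
    stop("'believed_sigma_ratio' applies only to kind = \"misbelief_bayes\"")
  }
  structure(list(kind = kind, k_ref = k_ref, sigma_ref = sigma_ref,
                 gamma = gamma, believed_sigma_ratio = believed_sigma_ratio),
            class = "criterion_policy")
}

#' @export
print.criterion_policy <- function(x, ...) {
  extra <- switch(x$kind,
                  power = sprintf(", gamma = %g", x$gamma),
                  misbelief_bayes = sprintf(", believed sigma ratio = %g",
                                            x$believed_sigma_ratio),
                  "")
  cat(sprintf("Criterion policy '%s': k_ref = %g at sigma_ref = %g%s\n",
              x$kind, x$k_ref, x$sigma_ref, extra))
  invisible(x)
}

# effective power-law exponent of a policy, NA when not a pure power law
policy_gamma <- function(policy) {
  switch(policy$kind,
         fixed = 0,
         power = policy$gamma,
         bayes_optimal = 1,
         misbelief_bayes = NA_real_)
}

#' Evaluate a criterion policy at given noise levels
#'
#' @param policy A [criterion_policy()].
#' @param sigma Noise level(s), > 0.
#' @param prior_present Prior probability of "present"; with unequal priors the
#'   Bayes-optimal policy falls back to the full closed form via
#'   [bayes_criterion()], which then also needs \code{d_prime} to set
#'   \code{mu = d_prime * sigma} per condition.
#' @param d_prime Matched discriminability; only used for the unequal-prior
#'   Bayes-optimal path.
#' @return Absolute criterion k at each \code{sigma}, measurement units.
#' @export
policy_criterion <- function(policy, sigma, prior_present = 0.5,
                             d_prime = NULL) {
  stopifnot(inherits(policy, "criterion_policy"), is.numeric(sigma))
  if (any(sigma <= 0)) stop("'sigma' must be > 0")
  if (policy$kind == "bayes_optimal" && prior_present != 0.5) {
    if (is.null(d_prime))
      stop("unequal priors: supply 'd_prime' so that mu = d_prime * sigma per condition")
    return(vapply(sigma, function(s) {
      bayes_criterion(detection_model(d_prime * s, s, prior_present))$k
    }, numeric(1)))
  }
  switch(policy$kind,
         fixed = rep(policy$k_ref, length(sigma)),
         power = policy$k_ref * (sigma / policy$sigma_ref)^policy$gamma,
         bayes_optimal = policy$k_ref * (sigma / policy$sigma_ref),
         misbelief_bayes = ifelse(sigma == policy$sigma_ref, policy$k_ref,
                                  policy$k_ref * policy$believed_sigma_ratio))
}

check_condition_pair <- function(sigma_val, sigma_inv, k_val, k_inv) {
  stopifnot(is.numeric(sigma_val), is.numeric(sigma_inv),
            is.numeric(k_val), is.numeric(k_inv))
  if (any(sigma_val <= 0) || any(sigma_inv <= sigma_val))
    stop("condition pair requires sigma_inv > sigma_val > 0")
  if (any(k_val <= 0))
    stop("condition pair requires k_val > 0")
  invisible(TRUE)
}

#' Does a criterion pair account for the inflation signature?
#'
#' Classifies a valid/invalid condition pair against the inequality that the
#' inflation signature (matched d', lower relative criterion when noise is
#' higher) imposes on absolute criteria:
#' \code{k_inv < (sigma_inv / sigma_val) * k_val}, given \code{k_val > 0}.
#' Every pair strictly inside this region reproduces the signature — the fixed
#' criterion (ratio 1) is only one member of the family.
#'
#' @param sigma_val,sigma_inv Noise SDs with \code{sigma_inv > sigma_val > 0}.
#' @param k_val,k_inv Absolute criteria with \code{k_val > 0}.
#' @param tol Boundary tolerance in criterion-ratio units.
#' @return One of \code{"strictly_inside"}, \code{"boundary"},
#'   \code{"outside"} (vectorised over the inputs).
#' @examples
#' iarf_satisfied(1, 2, k_val = 1, k_inv = 1)        # strictly_inside
#' iarf_satisfied(1, 2, k_val = 1, k_inv = sqrt(2))  # strictly_inside
#' iarf_satisfied(1, 2, k_val = 1, k_inv = 2)        # boundary
#' @export
iarf_satisfied <- function(sigma_val, sigma_inv, k_val, k_inv, tol = 1e-9) {
  check_condition_pair(sigma_val, sigma_inv, k_val, k_inv)
  classify_iarf(sigma_inv / sigma_val, k_inv / k_val, tol)
}

# classification on ratio scale; sigma_ratio < 1 is the caller's problem
classify_iarf <- function(sigma_ratio, k_ratio, tol = 1e-9) {
  ifelse(abs(k_ratio - sigma_ratio) <= tol, "boundary",
         ifelse(k_ratio < sigma_ratio, "strictly_inside", "outside"))
}

#' Map of the criterion-ratio solution space
#'
#' Evaluates, over a grid of noise ratios (sigma_inv/sigma_val) and criterion
#' ratios (k_inv/k_val), whether each combination accounts for the inflation
#' signature. The Bayes-optimal (linear) policy traces the region boundary
#' (k ratio = sigma ratio); the fixed policy is the horizontal line at
#' criterion ratio 1; everything below the boundary is consistent with the
#' signature. Noise ratios below 1 would mean less noise without attention and
#' are flagged invalid.
#'
#' @param sigma_ratio_grid Noise ratios, > 0; default \code{seq(1, 3,
#'   length.out = 251)}.
#' @param k_ratio_grid Criterion ratios, >= 0; default \code{seq(0, 2.5,
#'   length.out = 251)}.
#' @param tol Boundary tolerance, ratio units.
#' @return A long data frame with columns \code{sigma_ratio}, \code{k_ratio},
#'   \code{status} (\code{"strictly_inside"}, \code{"boundary"},
#'   \code{"outside"}, or \code{"invalid"}).
#' @export
iarf_region <- function(sigma_ratio_grid = seq(1, 3, length.out = 251),
                        k_ratio_grid = seq(0, 2.5, length.out = 251),
                        tol = 1e-9) {
  stopifnot(is.numeric(sigma_ratio_grid), is.numeric(k_ratio_grid))
  if (length(sigma_ratio_grid) == 0L || length(k_ratio_grid) == 0L)
    stop("empty grid")
  if (any(sigma_ratio_grid <= 0) || any(k_ratio_grid < 0))
    stop("grids must be positive (k ratios may include 0)")
  grid <- expand.grid(sigma_ratio = sigma_ratio_grid,
                      k_ratio = k_ratio_grid,
                      KEEP.OUT.ATTRS = FALSE)
  status <- classify_iarf(grid$sigma_ratio, grid$k_ratio, tol)
  status[grid$sigma_ratio < 1] <- "invalid"
  grid$status <- status
  grid
}

#' Relative-criterion signature of a policy under d'-matching
#'
#' For a valid/invalid pair with matched d' (mu = d' * sigma in each
#' condition), computes the relative criterion each condition shows when the
#' absolute criterion follows the given policy. Sub-linear policies
#' (gamma < 1, k_val > 0) produce c_inv < c_val — the inflation signature —
#' while the linear (Bayes-optimal) policy leaves c unchanged; the signature
#' therefore cannot single out the fixed policy.
#'
#' @param policy A [criterion_policy()]; its reference noise should be
#'   \code{sigma_val} for the anchoring to mean what it says.
#' @param sigma_val,sigma_inv Noise SDs, \code{sigma_inv > sigma_val > 0}.
#' @param d_prime Matched discriminability, > 0.
#' @return Named numeric vector \code{c(c_val =, c_inv =)}.
#' @examples
#' fixed <- criterion_policy("fixed", k_ref = 1, sigma_ref = 1)
#' signature_under_policy(fixed, 1, 2, d_prime = 1)  # c(0.5, 0)
#' @export
signature_under_policy <- function(policy, sigma_val, sigma_inv, d_prime) {
  stopifnot(inherits(policy, "criterion_policy"),
            is.numeric(d_prime), d_prime > 0)
  if (!(sigma_inv > sigma_val && sigma_val > 0))
    stop("requires sigma_inv > sigma_val > 0")
  k <- policy_criterion(policy, c(sigma_val, sigma_inv))
  c(c_val = relative_from_absolute(k[1], d_prime * sigma_val, sigma_val),
    c_inv = relative_from_absolute(k[2], d_prime * sigma_inv, sigma_inv))
}
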