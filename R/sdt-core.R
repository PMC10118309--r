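#' Generative model of one detection condition
#'
#' Constructs the equal-variance signal detection model of a yes/no detection
#' task: the stimulus is absent (value 0) or present (value \code{mu}), and the
#' observer's internal measurement is the stimulus value corrupted by zero-mean
#' Gaussian noise with standard deviation \code{sigma}. One object describes
#' one attention condition; conditions differ only in \code{sigma} (and, under
#' d'-matching, in \code{mu}).
#'
#' @param mu Stimulus magnitude when present, in measurement units. Must be
#'   >= 0; absent is defined as 0, so negative signal means are rejected.
#' @param sigma Measurement-noise standard deviation, same units. Must be > 0.
#' @param prior_present Prior probability that the stimulus is present,
#'   strictly between 0 and 1. Defaults to equal presentation rates.
#'
#' @return An object of class \code{"detection_model"}: a list with elements
#'   \code{mu}, \code{sigma}, \code{prior_present}.
#' @seealso [rates_from_params()], [bayes_criterion()], [simulate_detection()]
#' @examples
#' m <- detection_model(mu = 1, sigma = 1)
#' rates_from_params(m, k = 0.5)
#' @export
detection_model <- function(mu, sigma, prior_present = 0.5) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma),
            is.numeric(prior_present), length(prior_present) == 1L)
  if (mu < 0)
    stop("'mu' must be >= 0: the absent stimulus is defined as 0 and the present stimulus as mu")
  if (sigma <= 0)
    stop("'sigma' must be > 0")
  if (prior_present <= 0 || prior_present >= 1)
    stop("'prior_present' must lie strictly between 0 and 1")
  structure(list(mu = mu, sigma = sigma, prior_present = prior_present),
            class = "detection_model")
}

#' @export
print.detection_model <- function(x, ...) {
  cat("Detection model (equal-variance SDT)\n")
  cat(sprintf("  mu = %g, sigma = %g, prior(present) = %g\n",
              x$mu, x$sigma, x$prior_present))
  cat(sprintf("  d' = mu/sigma = %g\n", x$mu / x$sigma))
  invisible(x)
}

stop_degenerate_mu <- function() {
  stop("degenerate model: mu = 0 leaves the log posterior ratio constant in x, so no criterion on x is defined",
       call. = FALSE)
}

#' Log posterior ratio of "present" over "absent"
#'
#' The decision variable of the Bayesian observer: the log ratio of the
#' posterior probabilities of the two stimulus states given a measurement
#' \code{x}. Under the Gaussian generative model it is affine in the
#' measurement, \code{log(p1/p0) + (mu/sigma^2) * (x - mu/2)}, so thresholding
#' the measurement itself is an equivalent decision rule.
#'
#' @param x Measurement value(s), measurement units.
#' @param model A [detection_model()] with \code{mu > 0}.
#' @return Numeric vector of log posterior ratios, unitless.
#' @examples
#' log_posterior_ratio(1.5, detection_model(1, 1))  # 1
#' @export
log_posterior_ratio <- function(x, model) {
  stopifnot(inherits(model, "detection_model"), is.numeric(x))
  if (model$mu == 0) stop_degenerate_mu()
  log(model$prior_present / (1 - model$prior_present)) +
    (model$mu / model$sigma^2) * (x - model$mu / 2)
}

#' Convert an absolute criterion to the relative criterion
#'
#' The relative criterion \code{c} re-expresses the threshold in noise-SD
#' units, measured from the midpoint of the absent and present means:
#' \code{c = (k - mu/2) / sigma}.
#'
#' @param k Absolute criterion, measurement units.
#' @param mu Present-stimulus mean, measurement units.
#' @param sigma Measurement-noise SD, > 0.
#' @return Relative criterion, unitless.
#' @seealso [absolute_from_relative()] for the inverse map.
#' @export
relative_from_absolute <- function(k, mu, sigma) {
  stopifnot(is.numeric(k), is.numeric(mu), is.numeric(sigma))
  if (any(sigma <= 0)) stop("'sigma' must be > 0")
  (k - mu / 2) / sigma
}

#' Convert a relative criterion back to measurement units
#'
#' Given the two relative quantities an experiment measures (d' and c) and a
#' choice of noise level, recovers the absolute criterion
#' \code{k = sigma * (c + d'/2)}. Inverse of [relative_from_absolute()] when
#' \code{mu = d' * sigma}.
#'
#' @param c_rel Relative criterion, unitless.
#' @param d_prime Discriminability, unitless.
#' @param sigma Measurement-noise SD, > 0.
#' @return Absolute criterion \code{k}, measurement units.
#' @export
absolute_from_relative <- function(c_rel, d_prime, sigma) {
  stopifnot(is.numeric(c_rel), is.numeric(d_prime), is.numeric(sigma))
  if (any(sigma <= 0)) stop("'sigma' must be > 0")
  sigma * (c_rel + d_prime / 2)
}

#' Analytic hit and false-alarm rates of a threshold observer
#'
#' An observer who responds "present" whenever the measurement exceeds \code{k}
#' has hit rate \code{H = pnorm((mu - k) / sigma)} and false-alarm rate
#' \code{F = pnorm(-k / sigma)}.
#'
#' @param model A [detection_model()].
#' @param k Absolute criterion, measurement units; may be a vector.
#' @return A data frame with columns \code{k}, \code{H}, \code{F}.
#' @export
rates_from_params <- function(model, k) {
  stopifnot(inherits(model, "detection_model"), is.numeric(k))
  data.frame(k = k,
             H = stats::pnorm((model$mu - k) / model$sigma),
             F = stats::pnorm(-k / model$sigma))
}

#' SDT summary statistics from hit and false-alarm rates
#'
#' The standard z-transform summaries: \code{d' = z(H) - z(F)} and
#' \code{c = -(z(H) + z(F)) / 2}, with \code{z} the standard-normal quantile
#' function. Rates of exactly 0 or 1 have infinite z-scores; empirical rates
#' should be boundary-corrected first (see [estimate_summary()], which applies
#' the 1/(2N) rule) — here they raise an error rather than propagate
#' infinities.
#'
#' @param H Hit rate(s), strictly inside (0, 1).
#' @param F False-alarm rate(s), strictly inside (0, 1).
#' @return An object of class \code{"sdt_summary"}: a data frame with columns
#'   \code{H}, \code{F}, \code{d_prime}, \code{c}.
#' @examples
#' summary_from_rates(pnorm(0.5), pnorm(-0.5))  # d' = 1, c = 0
#' @export
summary_from_rates <- function(H, F) {
  stopifnot(is.numeric(H), is.numeric(F), length(H) == length(F))
  if (any(H <= 0 | H >= 1 | F <= 0 | F >= 1))
    stop("boundary rate: H and F must lie strictly inside (0, 1); apply a finite-sample correction such as the 1/(2N) rule before summarising")
  zH <- stats::qnorm(H)
  zF <- stats::qnorm(F)
  structure(data.frame(H = H, F = F,
                       d_prime = zH - zF,
                       c = -(zH + zF) / 2),
            class = c("sdt_summary", "data.frame"))
}

#' Bayes-optimal criterion on the measurement
#'
#' The measurement threshold at which the log posterior ratio crosses zero:
#' \code{k_Bayes = mu/2 - (sigma^2/mu) * log(p1/p0)}, with relative form
#' \code{c_Bayes = -(sigma/mu) * log(p1/p0)}. With equal priors the absolute
#' criterion sits at the midpoint \code{mu/2} and the relative criterion is 0,
#' whatever \code{mu} and \code{sigma} are. This threshold maximises expected
#' response accuracy under the generative model.
#'
#' @param model A [detection_model()] with \code{mu > 0}.
#' @return A list with elements \code{k} (measurement units) and \code{c}
#'   (unitless).
#' @examples
#' bayes_criterion(detection_model(1, 1))  # k = 0.5, c = 0
#' @export
bayes_criterion <- function(model) {
  stopifnot(inherits(model, "detection_model"))
  if (model$mu == 0) stop_degenerate_mu()
  lpo <- log(model$prior_present / (1 - model$prior_present))
  list(k = model$mu / 2 - (model$sigma^2 / model$mu) * lpo,
       c = -(model$sigma / model$mu) * lpo)
}

#' The solution family consistent with one (d', c) pair
#'
#' An experiment measures two relative quantities, d' and c, but the generative
#' account has three absolute unknowns (mu, sigma, k). For every choice of
#' sigma the triple \code{mu = d' * sigma}, \code{k = sigma * (c + d'/2)}
#' reproduces exactly the same hit and false-alarm rates, so the absolute
#' criterion is unidentifiable from detection performance alone.
#'
#' @param d_prime Measured discriminability.
#' @param c_rel Measured relative criterion.
#' @param sigma Noise-SD choice(s), > 0; may be a vector.
#' @return A data frame with one row per \code{sigma}: columns \code{sigma},
#'   \code{mu}, \code{k}.
#' @seealso [degeneracy_report()] for the annotated version with implied rates.
#' @export
params_family_from_summary <- function(d_prime, c_rel, sigma) {
  stopifnot(is.numeric(d_prime), length(d_prime) == 1L,
            is.numeric(c_rel), length(c_rel) == 1L, is.numeric(sigma))
  if (any(sigma <= 0)) stop("'sigma' must be > 0")
  data.frame(sigma = sigma,
             mu = d_prime * sigma,
             k = absolute_from_relative(c_rel, d_prime, sigma))
}
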