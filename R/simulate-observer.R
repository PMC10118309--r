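#' Generative model of the embedded-category task
#'
#' In the embedded-category task the stimulus orientation is drawn from one of
#' two zero-mean Gaussian distributions: a narrow one (category 1) and a broad
#' one (category 2). The observer sees the orientation through Gaussian
#' measurement noise. Because the categories differ in spread rather than
#' mean, the ideal decision boundary moves outward as measurement noise grows
#' — which is what makes the absolute criterion identifiable in this task.
#'
#' Orientations are treated as unbounded reals; wrap-around at +/-90 degrees is
#' ignored, which is harmless while the SDs stay small. A warning is issued if
#' \code{sigma_broad} or \code{sigma_m} exceeds 30 degrees.
#'
#' @param sigma_narrow SD of the category-1 orientation distribution, degrees;
#'   > 0.
#' @param sigma_broad SD of the category-2 distribution, degrees; must exceed
#'   \code{sigma_narrow}.
#' @param sigma_m Measurement-noise SD, degrees; >= 0.
#' @param prior_cat1 Prior probability of category 1, strictly in (0, 1).
#' @return An object of class \code{"embedded_category_model"}.
#' @seealso [optimal_embedded_criterion()], [simulate_embedded_category()]
#' @export
embedded_category_model <- function(sigma_narrow = 3, sigma_broad = 12,
                                    sigma_m = 4, prior_cat1 = 0.5) {
  stopifnot(is.numeric(sigma_narrow), length(sigma_narrow) == 1L,
            is.numeric(sigma_broad), length(sigma_broad) == 1L,
            is.numeric(sigma_m), length(sigma_m) == 1L,
            is.numeric(prior_cat1), length(prior_cat1) == 1L)
  if (!(sigma_narrow > 0 && sigma_broad > sigma_narrow))
    stop("requires 0 < sigma_narrow < sigma_broad")
  if (sigma_m < 0) stop("'sigma_m' must be >= 0")
  if (prior_cat1 <= 0 || prior_cat1 >= 1)
    stop("'prior_cat1' must lie strictly between 0 and 1")
  if (sigma_broad > 30 || sigma_m > 30)
    warning("SD exceeds 30 degrees; the no-wrap-around Gaussian approximation for orientation may be poor")
  structure(list(sigma_narrow = sigma_narrow, sigma_broad = sigma_broad,
                 sigma_m = sigma_m, prior_cat1 = prior_cat1),
            class = "embedded_category_model")
}

#' @export
print.embedded_category_model <- function(x, ...) {
  cat("Embedded-category model (zero-mean categories, unequal SD)\n")
  cat(sprintf("  sigma_narrow = %g deg, sigma_broad = %g deg\n",
              x$sigma_narrow, x$sigma_broad))
  cat(sprintf("  measurement noise sigma_m = %g deg, prior(cat 1) = %g\n",
              x$sigma_m, x$prior_cat1))
  invisible(x)
}

# Run code with a deterministic RNG stream derived from (seed, stream id),
# restoring the caller's RNG state afterwards. Stream ids keep operations'
# draws independent under one global seed; the derived seed stays within
# 32-bit integer range.
with_local_seed <- function(seed, stream, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed((as.integer(seed) %% 1000003L) * 2011L + stream,
           kind = "Mersenne-Twister")
  force(code)
}

#' Match discriminability across noise conditions
#'
#' Returns the signal means that equate d' across two noise levels:
#' \code{mu = d' * sigma} in each condition (the analytic counterpart of
#' titrating stimulus strength until performance matches).
#'
#' @param sigma_val,sigma_inv Noise SDs, > 0.
#' @param d_prime_target Common discriminability, >= 0.
#' @return Named numeric vector \code{c(mu_val =, mu_inv =)}.
#' @examples
#' match_dprime(1, 2, 1)  # c(1, 2)
#' @export
match_dprime <- function(sigma_val, sigma_inv, d_prime_target) {
  stopifnot(sigma_val > 0, sigma_inv > 0, d_prime_target >= 0)
  c(mu_val = d_prime_target * sigma_val,
    mu_inv = d_prime_target * sigma_inv)
}

new_trial_table <- function(df, task, seed) {
  structure(df, task = task, seed = seed,
            class = c("trial_table", "data.frame"))
}

#' Simulate a cued detection experiment
#'
#' Generates trial-level data for the valid (attended) and invalid
#' (unattended) conditions of a detection task. On each trial the stimulus is
#' present with the condition's prior; the measurement is the stimulus value
#' plus Gaussian noise with the condition's SD; the response is "present"
#' exactly when the measurement exceeds the criterion the policy assigns to
#' that noise level (ties count as "absent").
#'
#' @param models Named list with [detection_model()] elements \code{val} and
#'   \code{inv} (a single unnamed model simulates one condition labelled
#'   \code{"single"}).
#' @param policy A [criterion_policy()] mapping each condition's sigma to its
#'   absolute criterion.
#' @param n_per_condition Trials per condition, >= 1.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return A \code{trial_table} data frame with columns \code{trial},
#'   \code{condition}, \code{truth} ("present"/"absent"), \code{stimulus}
#'   (the stimulus value s), \code{response} (1 = "present"). The criterion
#'   used per condition is recorded in \code{attr(x, "criteria")}.
#' @examples
#' mods <- list(val = detection_model(1, 1), inv = detection_model(2, 2))
#' pol <- criterion_policy("fixed", k_ref = 1, sigma_ref = 1)
#' head(simulate_detection(mods, pol, n_per_condition = 100, seed = 1))
#' @export
simulate_detection <- function(models, policy, n_per_condition, seed) {
  if (inherits(models, "detection_model")) models <- list(single = models)
  stopifnot(is.list(models), length(models) >= 1L,
            all(vapply(models, inherits, logical(1), "detection_model")),
            inherits(policy, "criterion_policy"))
  if (is.null(names(models)) || any(names(models) == ""))
    stop("'models' must be a named list of detection models")
  n_per_condition <- as.integer(n_per_condition)
  if (is.na(n_per_condition) || n_per_condition < 1L)
    stop("'n_per_condition' must be >= 1")

  with_local_seed(seed, stream = 1L, {
    pieces <- lapply(names(models), function(cond) {
      m <- models[[cond]]
      k <- policy_criterion(policy, m$sigma, prior_present = m$prior_present,
                            d_prime = if (m$sigma > 0) m$mu / m$sigma)
      present <- stats::runif(n_per_condition) < m$prior_present
      s <- ifelse(present, m$mu, 0)
      x <- stats::rnorm(n_per_condition, mean = s, sd = m$sigma)
      data.frame(condition = cond,
                 truth = ifelse(present, "present", "absent"),
                 stimulus = s,
                 response = as.integer(x > k))
    })
    out <- do.call(rbind, pieces)
    out <- cbind(trial = seq_len(nrow(out)), out)
    criteria <- vapply(names(models), function(cond) {
      m <- models[[cond]]
      policy_criterion(policy, m$sigma, prior_present = m$prior_present,
                       d_prime = m$mu / m$sigma)
    }, numeric(1))
    tab <- new_trial_table(out, task = "detection", seed = seed)
    attr(tab, "criteria") <- criteria
    tab
  })
}

#' Simulate the embedded-category observer
#'
#' Per trial: a category is drawn with probability \code{prior_cat1}; the
#' stimulus orientation s is drawn from that category's zero-mean Gaussian;
#' the measurement is \code{x ~ Normal(s, sigma_m)}; the observer responds
#' "category 2" exactly when \code{|x| > k} (the symmetric two-sided rule the
#' task's symmetry about 0 degrees forces; the tie \code{|x| = k} counts as
#' category 1).
#'
#' @param model An [embedded_category_model()].
#' @param k Absolute decision boundary, degrees; >= 0.
#' @param n_trials Number of trials, >= 1.
#' @param seed Integer seed.
#' @return A \code{trial_table} data frame with columns \code{trial},
#'   \code{condition} (\code{"single"}), \code{truth} ("cat1"/"cat2"),
#'   \code{stimulus} (true orientation, degrees), \code{response}
#'   (1 = "category 2").
#' @export
simulate_embedded_category <- function(model, k, n_trials, seed) {
  stopifnot(inherits(model, "embedded_category_model"),
            is.numeric(k), length(k) == 1L)
  if (k < 0) stop("'k' must be >= 0")
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L) stop("'n_trials' must be >= 1")

  with_local_seed(seed, stream = 2L, {
    cat1 <- stats::runif(n_trials) < model$prior_cat1
    s <- stats::rnorm(n_trials, mean = 0,
                      sd = ifelse(cat1, model$sigma_narrow, model$sigma_broad))
    x <- stats::rnorm(n_trials, mean = s, sd = model$sigma_m)
    df <- data.frame(trial = seq_len(n_trials),
                     condition = "single",
                     truth = ifelse(cat1, "cat1", "cat2"),
                     stimulus = s,
                     response = as.integer(abs(x) > k))
    tab <- new_trial_table(df, task = "embedded", seed = seed)
    attr(tab, "criteria") <- c(single = k)
    tab
  })
}

#' Read and write trial tables as CSV
#'
#' The on-disk dialect is a plain CSV with header columns \code{trial},
#' \code{condition}, \code{truth}, \code{stimulus}, \code{response}.
#'
#' @param trials A \code{trial_table} (or compatible data frame).
#' @param path File path.
#' @return \code{read_trials()} returns a \code{trial_table};
#'   \code{write_trials()} returns \code{path} invisibly.
#' @export
write_trials <- function(trials, path) {
  cols <- c("trial", "condition", "truth", "stimulus", "response")
  stopifnot(all(cols %in% names(trials)))
  utils::write.csv(as.data.frame(trials)[cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("trial", "condition", "truth", "stimulus", "response")
  if (!all(cols %in% names(df)))
    stop("trial CSV must have columns: ", paste(cols, collapse = ", "))
  new_trial_table(df[cols], task = NA_character_, seed = NA_integer_)
}
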