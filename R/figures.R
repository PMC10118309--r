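policy_colors <- c(fixed = "#7e3f9d", sqrt = "#e08214", optimal = "#1b7837")

#' Curve data behind the criterion-vs-noise figure
#'
#' Computes, for the fixed (gamma 0), square-root (gamma 0.5) and
#' Bayes-optimal (gamma 1) policies, the absolute criterion as a function of
#' noise (panel A), the relative criterion under d'-matching (panel B), the
#' admissible-region map in ratio space (panel C), and the condition-wise
#' measurement distributions with each policy's criterion marked (panel D).
#' All numbers are produced here; the plotting functions only draw them.
#'
#' @param sigma_val,sigma_inv Valid/invalid noise SDs; defaults 1 and 2.
#' @param d_prime Matched discriminability; default 1.
#' @param k_ref Criterion anchor at \code{sigma_val}. Defaults to the
#'   Bayes-optimal criterion in the valid condition,
#'   \code{d_prime * sigma_val / 2}, so the fixed observer happens to be
#'   optimal when attended.
#' @param sigma_max Upper end of the noise sweep for panels A/B.
#' @param n_sigma Points on the noise sweep.
#' @return A list of data frames: \code{curves} (sigma, policy, k, c),
#'   \code{region} (sigma_ratio, k_ratio, status), \code{distributions}
#'   (condition, x, present, density), \code{criteria} (condition, policy, k).
#' @export
figure1_data <- function(sigma_val = 1, sigma_inv = 2, d_prime = 1,
                         k_ref = d_prime * sigma_val / 2, sigma_max = 3,
                         n_sigma = 121) {
  stopifnot(sigma_inv > sigma_val, sigma_val > 0, d_prime > 0, k_ref > 0)
  gammas <- c(fixed = 0, sqrt = 0.5, optimal = 1)
  sigmas <- seq(sigma_val, sigma_max, length.out = n_sigma)
  curves <- do.call(rbind, lapply(names(gammas), function(nm) {
    pol <- criterion_policy("power", k_ref = k_ref, sigma_ref = sigma_val,
                            gamma = gammas[[nm]])
    k <- policy_criterion(pol, sigmas)
    data.frame(policy = nm, sigma = sigmas, k = k,
               c = relative_from_absolute(k, d_prime * sigmas, sigmas))
  }))
  region <- iarf_region()
  xs <- seq(-3 * sigma_inv, d_prime * sigma_inv + 3 * sigma_inv,
            length.out = 301)
  conds <- c(val = sigma_val, inv = sigma_inv)
  distributions <- do.call(rbind, lapply(names(conds), function(cond) {
    sg <- conds[[cond]]
    rbind(data.frame(condition = cond, x = xs, present = 0L,
                     density = stats::dnorm(xs, 0, sg)),
          data.frame(condition = cond, x = xs, present = 1L,
                     density = stats::dnorm(xs, d_prime * sg, sg)))
  }))
  criteria <- do.call(rbind, lapply(names(gammas), function(nm) {
    pol <- criterion_policy("power", k_ref = k_ref, sigma_ref = sigma_val,
                            gamma = gammas[[nm]])
    data.frame(condition = c("val", "inv"), policy = nm,
               k = policy_criterion(pol, c(sigma_val, sigma_inv)))
  }))
  list(curves = curves, region = region, distributions = distributions,
       criteria = criteria)
}

#' Draw the criterion-vs-noise figure from precomputed curve data
#'
#' @param dat A list of data frames as returned by [figure1_data()] (or read
#'   back from the CSVs it was saved to).
#' @export
plot_figure1 <- function(dat) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  draw_curves <- function(yvar, ylab) {
    sp <- split(dat$curves, dat$curves$policy)
    graphics::plot(range(dat$curves$sigma), range(dat$curves[[yvar]]),
                   type = "n", xlab = expression(sigma), ylab = ylab)
    for (nm in names(sp))
      graphics::lines(sp[[nm]]$sigma, sp[[nm]][[yvar]],
                      col = policy_colors[[nm]], lwd = 2)
    graphics::legend("topleft", legend = names(sp), bty = "n",
                     col = policy_colors[names(sp)], lwd = 2, cex = 0.8)
  }
  draw_curves("k", "absolute criterion k")
  draw_curves("c", "relative criterion c")

  reg <- dat$region
  sr <- sort(unique(reg$sigma_ratio))
  kr <- sort(unique(reg$k_ratio))
  code <- matrix(match(reg$status, c("strictly_inside", "boundary",
                                     "outside", "invalid")),
                 nrow = length(sr))
  graphics::image(sr, kr, code, col = c("#d9f0d3", "#1b7837",
                                        "#f7f7f7", "#bdbdbd"),
                  xlab = expression(sigma["inv"] / sigma["val"]),
                  ylab = expression(k["inv"] / k["val"]))
  graphics::abline(h = 1, col = policy_colors["fixed"], lwd = 2)
  graphics::lines(sr, sqrt(sr), col = policy_colors["sqrt"], lwd = 2)
  graphics::lines(sr, sr, col = policy_colors["optimal"], lwd = 2)

  dist <- dat$distributions
  graphics::plot(range(dist$x), c(0, max(dist$density) * 1.05), type = "n",
                 xlab = "measurement x", ylab = "density")
  lt <- c(val = 1, inv = 2)
  for (cond in unique(dist$condition)) for (pr in 0:1) {
    dd <- dist[dist$condition == cond & dist$present == pr, ]
    graphics::lines(dd$x, dd$density, lty = lt[[cond]])
  }
  for (i in seq_len(nrow(dat$criteria)))
    graphics::abline(v = dat$criteria$k[i],
                     col = policy_colors[[dat$criteria$policy[i]]],
                     lty = lt[[dat$criteria$condition[i]]])
  invisible(dat)
}

#' Boundary trajectories for the two category-task geometries
#'
#' Panel A: the symmetric offset task (categories at -mu and +mu with equal
#' variance), where the ideal boundary bisects the means and never moves with
#' noise — no incentive to shift. Panel B: the embedded-category task, where
#' the fixed, square-root and ideal boundaries are traced over a
#' measurement-noise sweep; only here do the policies separate.
#'
#' @param model An [embedded_category_model()]; its \code{sigma_m} anchors the
#'   sweep start and the policies' reference point.
#' @param sigma_m_max Upper end of the measurement-noise sweep; default
#'   3 times the model's \code{sigma_m}.
#' @param n_sigma Points on the sweep.
#' @return A list of data frames: \code{offset} (sigma_m, k_opt) and
#'   \code{embedded} (sigma_m, policy, k).
#' @export
figure2_data <- function(model = embedded_category_model(),
                         sigma_m_max = 3 * model$sigma_m, n_sigma = 61) {
  stopifnot(inherits(model, "embedded_category_model"), model$sigma_m > 0,
            sigma_m_max > model$sigma_m)
  sms <- seq(model$sigma_m, sigma_m_max, length.out = n_sigma)
  offset <- data.frame(sigma_m = sms, k_opt = 0)
  k_ref <- optimal_embedded_criterion(model)
  k_opt <- vapply(sms, function(sm) {
    optimal_embedded_criterion(
      embedded_category_model(model$sigma_narrow, model$sigma_broad, sm,
                              model$prior_cat1))
  }, numeric(1))
  embedded <- rbind(
    data.frame(policy = "fixed", sigma_m = sms, k = k_ref),
    data.frame(policy = "sqrt", sigma_m = sms,
               k = k_ref * sqrt(sms / model$sigma_m)),
    data.frame(policy = "optimal", sigma_m = sms, k = k_opt))
  list(offset = offset, embedded = embedded)
}

#' Draw the category-task boundary figure from precomputed data
#'
#' @param dat A list as returned by [figure2_data()].
#' @export
plot_figure2 <- function(dat) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(dat$offset$sigma_m, dat$offset$k_opt, type = "l", lwd = 2,
                 col = policy_colors["optimal"],
                 xlab = expression(sigma[m]), ylab = "ideal boundary (deg)",
                 ylim = c(-1, 1), main = "symmetric offset task")
  sp <- split(dat$embedded, dat$embedded$policy)
  ylim <- c(-1, 1) * max(dat$embedded$k) * 1.05
  graphics::plot(range(dat$embedded$sigma_m), ylim, type = "n",
                 xlab = expression(sigma[m]), ylab = "boundary +/-k (deg)",
                 main = "embedded-category task")
  for (nm in names(sp)) {
    graphics::lines(sp[[nm]]$sigma_m, sp[[nm]]$k,
                    col = policy_colors[[nm]], lwd = 2)
    graphics::lines(sp[[nm]]$sigma_m, -sp[[nm]]$k,
                    col = policy_colors[[nm]], lwd = 2)
  }
  graphics::legend("topleft", legend = names(sp), bty = "n",
                   col = policy_colors[names(sp)], lwd = 2, cex = 0.8)
  invisible(dat)
}

write_stage_csvs <- function(dat, out_dir, prefix) {
  paths <- character(0)
  for (nm in names(dat)) {
    p <- file.path(out_dir, paste0(prefix, "_", nm, ".csv"))
    utils::write.csv(dat[[nm]], p, row.names = FALSE, quote = FALSE)
    paths[nm] <- p
  }
  paths
}

read_stage_csvs <- function(paths) {
  out <- lapply(paths, utils::read.csv, stringsAsFactors = FALSE)
  names(out) <- names(paths)
  out
}

#' Render the criterion-vs-noise figure and its underlying CSVs
#'
#' Computes the curve data with [figure1_data()], writes each component as
#' CSV under \code{out_dir}, then renders the figure to PDF from the CSVs it
#' just wrote (so the plot can always be regenerated from the CSVs alone).
#'
#' @param out_dir Output directory; created if missing.
#' @param ... Passed to [figure1_data()].
#' @return Invisibly, the named vector of file paths written.
#' @export
run_figure1 <- function(out_dir, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_stage_csvs(figure1_data(...), out_dir, "figure1")
  pdf_path <- file.path(out_dir, "figure1.pdf")
  grDevices::pdf(pdf_path, width = 9, height = 7)
  on.exit(grDevices::dev.off())
  plot_figure1(read_stage_csvs(paths))
  invisible(c(paths, pdf = pdf_path))
}

#' Render the category-task boundary figure and its underlying CSVs
#'
#' @param out_dir Output directory; created if missing.
#' @param ... Passed to [figure2_data()].
#' @return Invisibly, the named vector of file paths written.
#' @export
run_figure2 <- function(out_dir, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_stage_csvs(figure2_data(...), out_dir, "figure2")
  pdf_path <- file.path(out_dir, "figure2.pdf")
  grDevices::pdf(pdf_path, width = 9, height = 4.5)
  on.exit(grDevices::dev.off())
  plot_figure2(read_stage_csvs(paths))
  invisible(c(paths, pdf = pdf_path))
}

#' Read an experiment configuration from a YAML file
#'
#' The config dialect is plain YAML with keys matching the simulator and
#' model constructors (for detection: \code{sigma_val}, \code{sigma_inv},
#' \code{d_prime}, \code{prior_present}, policy fields \code{kind},
#' \code{k_ref}, \code{sigma_ref}, \code{gamma}; for the embedded task:
#' \code{sigma_narrow}, \code{sigma_broad}, \code{sigma_m}, \code{prior_cat1},
#' \code{k}; plus \code{n_trials} and \code{seed}).
#'
#' @param path YAML file path.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  cfg
}

pipeline_log <- function(seed, stage, ...) {
  message(sprintf("[seed %s] %s: %s", seed, stage, sprintf(...)))
}

#' Run the full detection or embedded-category pipeline
#'
#' Detection: builds d'-matched valid/invalid models, simulates the observer
#' under the given policy, recovers per-condition SDT summaries, classifies
#' the criterion pair against the signature inequality, and writes the
#' degeneracy report for the measured summary. Embedded: simulates the
#' observer at two measurement-noise levels (criterion set by the policy at
#' each level), fits each dataset by maximum likelihood, and compares the
#' fitted boundaries — the comparison a detection task cannot make. All
#' stage outputs are written as CSV with a YAML run manifest.
#'
#' @param out_dir Output directory; created if missing.
#' @param task \code{"detection"} or \code{"embedded"}.
#' @param policy A [criterion_policy()].
#' @param n_trials Trials per condition / noise level, >= 1.
#' @param seed Integer seed; echoed in the manifest and logs.
#' @param sigma_val,sigma_inv,d_prime,prior_present Detection-task settings.
#' @param model An [embedded_category_model()] for the embedded task.
#' @param sigma_m_levels Two measurement-noise levels for the embedded task;
#'   default the model's \code{sigma_m} and twice it.
#' @return An object of class \code{"flexcrit_pipeline"}: a list with the
#'   stage results and output paths.
#' @export
run_pipeline <- function(out_dir, task = c("detection", "embedded"), policy,
                         n_trials = 10000, seed = 1,
                         sigma_val = 1, sigma_inv = 2, d_prime = 1,
                         prior_present = 0.5,
                         model = embedded_category_model(),
                         sigma_m_levels = model$sigma_m * c(1, 2)) {
  task <- match.arg(task)
  stopifnot(inherits(policy, "criterion_policy"))
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L)
    stop("'n_trials' must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (task == "detection") {
    mus <- match_dprime(sigma_val, sigma_inv, d_prime)
    models <- list(val = detection_model(mus[["mu_val"]], sigma_val,
                                         prior_present),
                   inv = detection_model(mus[["mu_inv"]], sigma_inv,
                                         prior_present))
    pipeline_log(seed, "simulate", "detection, %d trials per condition",
                 n_trials)
    trials <- simulate_detection(models, policy, n_trials, seed)
    write_trials(trials, file.path(out_dir, "trials.csv"))
    pipeline_log(seed, "estimate", "per-condition SDT summaries")
    summ <- estimate_summary(trials)
    ks <- attr(trials, "criteria")
    summ$k <- unname(ks[summ$condition])
    summ$sigma <- vapply(summ$condition,
                         function(cn) models[[cn]]$sigma, numeric(1))
    utils::write.csv(as.data.frame(summ),
                     file.path(out_dir, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
    pipeline_log(seed, "classify", "criterion pair against the signature bound")
    status <- iarf_satisfied(sigma_val, sigma_inv,
                             k_val = ks[["val"]], k_inv = ks[["inv"]])
    report <- degeneracy_report(
      d_prime = summ$d_prime[summ$condition == "val"],
      c_rel = summ$c[summ$condition == "val"],
      sigma_ratio = sigma_inv / sigma_val)
    utils::write.csv(report$family, file.path(out_dir, "degeneracy_family.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(report$pair, file.path(out_dir, "degeneracy_pair.csv"),
                     row.names = FALSE, quote = FALSE)
    c_val <- summ$c[summ$condition == "val"]
    c_inv <- summ$c[summ$condition == "inv"]
    result <- list(task = task, summary = summ, iarf_status = status,
                   signature_reproduced = c_inv < c_val,
                   degeneracy = report)
  } else {
    fits <- list()
    for (i in seq_along(sigma_m_levels)) {
      sm <- sigma_m_levels[i]
      m_i <- embedded_category_model(model$sigma_narrow, model$sigma_broad,
                                     sm, model$prior_cat1)
      k_i <- policy_criterion(policy, sm)
      pipeline_log(seed, "simulate",
                   "embedded, sigma_m = %g, k = %g, %d trials", sm, k_i,
                   n_trials)
      tr <- simulate_embedded_category(m_i, k_i, n_trials,
                                       seed = seed + i - 1L)
      write_trials(tr, file.path(out_dir, sprintf("trials_level%d.csv", i)))
      pipeline_log(seed, "fit", "maximum-likelihood observer fit, level %d", i)
      fits[[i]] <- fit_embedded_observer(tr)
    }
    est <- do.call(rbind, lapply(seq_along(fits), function(i) {
      data.frame(level = i, sigma_m_true = sigma_m_levels[i],
                 k_true = policy_criterion(policy, sigma_m_levels[i]),
                 k_hat = coef(fits[[i]])[["k"]],
                 sigma_m_hat = coef(fits[[i]])[["sigma_m"]],
                 se_k = sqrt(vcov(fits[[i]])["k", "k"]))
    }))
    utils::write.csv(est, file.path(out_dir, "fits.csv"),
                     row.names = FALSE, quote = FALSE)
    dk <- abs(diff(est$k_hat))
    se_dk <- sqrt(sum(est$se_k^2))
    result <- list(task = task, fits = fits, estimates = est,
                   k_shift = unname(dk), k_shift_se = unname(se_dk),
                   k_differs = unname(dk > 1.96 * se_dk))
  }

  manifest <- list(package = "flexcrit",
                   version = as.character(utils::packageVersion("flexcrit")),
                   task = task, seed = seed, n_trials = n_trials,
                   policy = policy[!vapply(policy, is.null, logical(1))])
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  pipeline_log(seed, "done", "artifacts in %s", out_dir)
  structure(c(result, list(out_dir = out_dir, seed = seed)),
            class = "flexcrit_pipeline")
}

#' @export
print.flexcrit_pipeline <- function(x, ...) {
  cat(sprintf("Pipeline run (%s task), seed %s -> %s\n",
              x$task, x$seed, x$out_dir))
  if (x$task == "detection") {
    print(x$summary, row.names = FALSE)
    cat(sprintf("inflation signature (c_inv < c_val): %s; criterion pair: %s\n",
                x$signature_reproduced, x$iarf_status))
  } else {
    print(x$estimates, row.names = FALSE)
    cat(sprintf("fitted boundary shift %.4f (SE %.4f): criteria %s\n",
                x$k_shift, x$k_shift_se,
                if (x$k_differs) "distinguishably flexible"
                else "indistinguishable across noise levels"))
  }
  invisible(x)
}
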