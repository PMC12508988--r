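#' Specification of a synthetic melting experiment
#'
#' Ground-truth parameters, temperature grid, noise level and seed for a
#' simulated CD or DSC melting curve. The forward model is the same code
#' path the fitting modes use (long-chain helicity for `cd_long`,
#' finite-chain helicity for `cd_short`, per-residue excess heat capacity
#' for `dsc`); noise is additive homoscedastic Gaussian, the assumption
#' implicit in unweighted least squares.
#'
#' The package-default cooperative fixture is
#' `zb_params(t0 = 200, h = 3000, hps = 2500, Q = 100, q = 16, N = 100)` on
#' 100 points over `[280, 370]` K: a single sharp heat-denaturation
#' sigmoid with melting temperature near 331.3 K, chosen so that both tails
#' and the full transition sit inside the grid.
#'
#' @param truth A [zb_params()] object (the ground truth).
#' @param kind `"cd_long"`, `"cd_short"` or `"dsc"`.
#' @param t_min,t_max Grid limits (K), `t_min > truth$t0`.
#' @param n_points Number of grid points (>= 10).
#' @param noise_sd Standard deviation of the additive Gaussian noise, in
#'   units of the signal (helicity degree, or J mol-1 K-1 per residue).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `"zb_synthetic_spec"`.
#' @export
synthetic_spec <- function(truth, kind = c("cd_long", "cd_short", "dsc"),
                           t_min, t_max, n_points, noise_sd = 0,
                           seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(truth, "zb_params"))
  if (t_min <= truth$t0)
    stop("`t_min` must exceed the ground-truth t0.", call. = FALSE)
  if (t_max <= t_min) stop("`t_max` must exceed `t_min`.", call. = FALSE)
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 10L)
    stop("`n_points` must be at least 10.", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0.", call. = FALSE)
  structure(list(truth = truth, kind = kind, t_min = t_min, t_max = t_max,
                 n_points = n_points, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "zb_synthetic_spec")
}

#' Generate a synthetic melting curve
#'
#' Evaluates the forward model of `spec$kind` on a uniform temperature grid
#' and adds seeded Gaussian noise. With `noise_sd = 0` the curve equals the
#' forward model exactly; the same seed always reproduces the same curve.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `"zb_synthetic"` with elements `curve` (a
#'   [thermal_curve()]), `truth` (the ground-truth parameters), `ideal`
#'   (the noiseless model values) and `spec`.
#' @export
generate_curve <- function(spec) {
  stopifnot(inherits(spec, "zb_synthetic_spec"))
  temps <- seq(spec$t_min, spec$t_max, length.out = spec$n_points)
  truth <- spec$truth
  ideal <- switch(spec$kind,
                  cd_long = helicity(temps, truth, mode = "long"),
                  cd_short = helicity(temps, truth, mode = "finite"),
                  dsc = heat_capacity(temps, truth, mode = "long",
                                      per_residue = TRUE))
  values <- if (spec$noise_sd > 0) {
    withr::with_seed(spec$seed,
                     ideal + stats::rnorm(length(ideal), 0, spec$noise_sd))
  } else ideal
  kind <- if (spec$kind == "dsc") "dsc" else "cd"
  if (kind == "cd") values <- pmin(pmax(values, -0.05), 1.05)
  curve <- thermal_curve(temps, values, kind = kind,
                         source_units = list(temperature = "K",
                                             value = if (kind == "cd") "1"
                                                     else "J/(mol K)"))
  structure(list(curve = curve, truth = truth, ideal = ideal, spec = spec),
            class = "zb_synthetic")
}

#' Seeded parameter-recovery experiment
#'
#' Repeats generate-then-fit `n_replicates` times with seeds
#' `spec$seed + i`, scoring each replicate's recovered parameters against
#' the ground truth. A replicate whose fit fails is recorded as
#' unconverged, not fatal. Deterministic given `spec` and `config`.
#'
#' @param spec A [synthetic_spec()].
#' @param n_replicates Number of replicates (>= 1).
#' @param config A [fit_config()] used for every replicate.
#' @return A list of class `"zb_recovery"` with `replicates` (a data frame
#'   of recovered parameters, relative errors, `R^2` and convergence flags)
#'   and `summary` (per-parameter median relative error and bias, median
#'   `R^2`, failure count).
#' @export
recovery_experiment <- function(spec, n_replicates, config) {
  stopifnot(inherits(spec, "zb_synthetic_spec"),
            inherits(config, "zb_fit_config"))
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1L)
    stop("`n_replicates` must be >= 1.", call. = FALSE)
  truth <- unlist(spec$truth[c("t0", "h", "hps", "Q")])
  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    spec_i <- spec
    spec_i$seed <- spec$seed + i
    sim <- generate_curve(spec_i)
    fit <- tryCatch(fit_curve(sim$curve, config), error = function(e) NULL)
    if (is.null(fit)) {
      rows[[i]] <- data.frame(replicate = i, converged = FALSE,
                              t0 = NA_real_, h = NA_real_, hps = NA_real_,
                              Q = NA_real_, rel_t0 = NA_real_,
                              rel_h = NA_real_, rel_hps = NA_real_,
                              rel_Q = NA_real_, r_squared = NA_real_)
    } else {
      est <- unlist(fit$params[c("t0", "h", "hps", "Q")])
      rel <- abs(est - truth) / abs(truth)
      rows[[i]] <- data.frame(replicate = i, converged = TRUE,
                              t0 = est["t0"], h = est["h"],
                              hps = est["hps"], Q = est["Q"],
                              rel_t0 = rel["t0"], rel_h = rel["h"],
                              rel_hps = rel["hps"], rel_Q = rel["Q"],
                              r_squared = fit$r_squared)
    }
  }
  reps <- do.call(rbind, rows)
  rownames(reps) <- NULL
  ok <- reps$converged
  med <- function(x) stats::median(x[ok], na.rm = TRUE)
  summary <- list(
    median_rel_error = c(t0 = med(reps$rel_t0), h = med(reps$rel_h),
                         hps = med(reps$rel_hps), Q = med(reps$rel_Q)),
    bias = c(t0 = med(reps$t0) - truth["t0"], h = med(reps$h) - truth["h"],
             hps = med(reps$hps) - truth["hps"],
             Q = med(reps$Q) - truth["Q"]),
    median_r_squared = med(reps$r_squared),
    n_failed = sum(!ok))
  structure(list(replicates = reps, summary = summary, truth = truth,
                 spec = spec), class = "zb_recovery")
}

#' @export
print.zb_recovery <- function(x, ...) {
  cat("Parameter-recovery experiment (", x$spec$kind, ", ",
      nrow(x$replicates), " replicates, noise sd ", x$spec$noise_sd,
      ")\n", sep = "")
  mre <- x$summary$median_rel_error
  for (nm in names(mre))
    cat(sprintf("  %-4s median |rel err| = %.3g%%\n", nm, 100 * mre[nm]))
  cat(sprintf("  median R^2 = %.6g, failed fits: %d\n",
              x$summary$median_r_squared, x$summary$n_failed))
  invisible(x)
}
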