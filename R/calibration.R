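#' True effect decomposition implied by a generator configuration
#'
#' Evaluates the closed-form decomposition at the data-generating
#' coefficients, giving the ground truth that calibration experiments
#' compare estimates against.
#'
#' @param config A [cohort_config()].
#' @param spec A [causal_spec()].
#' @return An `effect_point` vector.
#' @export
true_effects <- function(config, spec) {
  theta <- config$outcome_coefficients[spec$outcome, ]
  beta <- config$mediator_coefficients[spec$mediators, , drop = FALSE]
  closed_form_effects(theta, beta, contrast = spec$contrast,
                      exposure = spec$exposure)
}

#' Simulation-based calibration of the mediation estimator
#'
#' Replicated generate-fit-estimate experiments against the generator truth:
#' per replicate, a fresh cohort is drawn from `config`, both structural
#' models are refit, and the quasi-Bayesian effect estimates are computed.
#' The report aggregates, per effect: mean bias, RMSE, empirical coverage of
#' the percentile interval at `conf_level`, and rejection rates of the
#' draw-based p-value at `alpha` and at any extra `thresholds` (e.g. the
#' Bonferroni thresholds of a [significance_scheme()]).
#'
#' Calibration should be run with clipping and rounding off
#' ([calibration_config()]) so the configured structural equations are the
#' exact truth.
#'
#' @param config A [cohort_config()].
#' @param spec A [causal_spec()].
#' @param n_reps Number of replicates (>= 1).
#' @param J Quasi-Bayesian draws per replicate.
#' @param seed Master integer seed.
#' @param conf_level Interval level whose coverage is assessed.
#' @param alpha Nominal test level for rejection rates.
#' @param thresholds Optional named vector of extra rejection thresholds.
#' @return An object of class `calibration_report`: a list with `per_effect`
#'   (data.frame of truth, bias, rmse, coverage, rejection rates), `points`
#'   (n_reps x 6 matrix of estimates), and metadata.
#' @export
run_calibration <- function(config, spec, n_reps = 200, J = 300, seed,
                            conf_level = 0.95, alpha = 0.05,
                            thresholds = NULL) {
  if (n_reps < 1) stop("`n_reps` must be at least 1")
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory")
  truth <- true_effects(config, spec)
  enames <- names(truth)
  ne <- length(enames)

  points <- matrix(NA_real_, n_reps, ne, dimnames = list(NULL, enames))
  lo <- hi <- pv <- points
  for (r in seq_len(n_reps)) {
    cohort <- generate_cohort(config, seed = derive_seed(seed, r))
    ofit <- fit_outcome_model(cohort, spec)
    mfit <- fit_mediator_system(cohort, spec)
    est <- estimate_effects(ofit, mfit, spec, J = J,
                            seed = derive_seed(seed, n_reps + r),
                            conf_level = conf_level)$estimates
    points[r, ] <- est$estimate
    lo[r, ] <- est$ci_lo
    hi[r, ] <- est$ci_hi
    pv[r, ] <- est$p
  }

  per_effect <- data.frame(
    effect = enames,
    truth = as.numeric(truth),
    bias = colMeans(points) - as.numeric(truth),
    rmse = sqrt(colMeans(sweep(points, 2L, as.numeric(truth))^2)),
    coverage = vapply(seq_len(ne), function(j) {
      mean(lo[, j] <= truth[j] & truth[j] <= hi[, j])
    }, numeric(1)),
    rejection = colMeans(pv < alpha),
    row.names = NULL
  )
  if (!is.null(thresholds)) {
    for (nm in names(thresholds)) {
      per_effect[[paste0("rejection_", nm)]] <- colMeans(pv < thresholds[[nm]])
    }
  }
  structure(
    list(per_effect = per_effect, points = points, ci_lo = lo, ci_hi = hi,
         pvalues = pv, n_reps = as.integer(n_reps), n = as.integer(config$n),
         J = as.integer(J), seed = seed, conf_level = conf_level,
         alpha = alpha, config = config, spec = spec),
    class = "calibration_report"
  )
}

#' @export
print.calibration_report <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Calibration: %d replicates at n = %d, J = %d (nominal %g%% intervals)\n",
    x$n_reps, x$n, x$J, 100 * x$conf_level))
  df <- x$per_effect
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}
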