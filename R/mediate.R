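#' Fit a multiple-mediator causal mediation model
#'
#' The package's central fitting function. For one exposure--outcome pair it
#' fits (1) the linear outcome model given the exposure, all mediators and
#' the confounders and (2) the linear models of the mediators given the
#' exposure and confounders, estimating the mediators' residual covariance;
#' it then propagates coefficient uncertainty with a quasi-Bayesian
#' algorithm (J draws from the asymptotic sampling distributions) to
#' estimate the total causal effect, the average direct effect (ADE), the
#' mediator-specific average causal mediation effects (ACME) and their joint
#' ACME, each with a percentile confidence interval and a draw-based
#' p-value. Effects are on the outcome scale, per `contrast[2] -
#' contrast[1]` units of the exposure.
#'
#' Identification rests on the assumed causal structure: sequential
#' ignorability given the confounders, and mediators that are correlated
#' through residual covariance but do not causally affect one another.
#'
#' @param data Participant-level `data.frame` (see [generate_cohort()] or
#'   [read_cohort_csv()] for the canonical columns).
#' @param exposure,outcome,mediators,confounders,contrast Passed to
#'   [causal_spec()].
#' @param J Number of quasi-Bayesian draws (default 1000).
#' @param seed Integer seed (mandatory; all randomness flows from it).
#' @param method `"closed_form"` (product-of-coefficients reduction,
#'   default) or `"counterfactual"` (direct simulation of counterfactual
#'   outcome compositions; slower, used as the definitional cross-check).
#' @param n_mc Monte-Carlo replicates per draw for the counterfactual path.
#' @param conf_level Confidence level for percentile intervals.
#' @return An object of class `mediate_multi`; see [summary.mediate_multi()],
#'   [coef.mediate_multi()], [confint.mediate_multi()],
#'   [plot.mediate_multi()].
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 184), seed = 7)
#' fit <- mediate_multi(cohort, exposure = "temps_anxious",
#'                      outcome = "edi_dt", J = 500, seed = 7)
#' fit
#' coef(fit)
mediate_multi <- function(data,
                          exposure,
                          outcome,
                          mediators = c("stai_trait", "stai_state", "bdi"),
                          confounders = c("age", "bmi"),
                          contrast = c(0, 1),
                          J = 1000,
                          seed,
                          method = c("closed_form", "counterfactual"),
                          n_mc = 50,
                          conf_level = 0.95) {
  method <- match.arg(method)
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory")
  spec <- causal_spec(exposure, outcome, mediators, confounders, contrast)
  ofit <- fit_outcome_model(data, spec)
  mfit <- fit_mediator_system(data, spec)
  est <- estimate_effects(ofit, mfit, spec, J = J, seed = seed,
                          method = method, cohort = data, n_mc = n_mc,
                          conf_level = conf_level)
  structure(
    list(spec = spec, outcome_fit = ofit, mediator_fit = mfit,
         effects = est, call = match.call()),
    class = "mediate_multi"
  )
}

#' @export
print.mediate_multi <- function(x, digits = 3, ...) {
  cat("Multiple-mediator causal mediation model\n")
  cat(sprintf("  %s -> (%s) -> %s, adjusted for %s\n",
              x$spec$exposure, paste(x$spec$mediators, collapse = ", "),
              x$spec$outcome, paste(x$spec$confounders, collapse = ", ")))
  print(x$effects, digits = digits)
  invisible(x)
}

#' Summarise a fitted mediation model
#'
#' @param object A [mediate_multi()] fit.
#' @param ... Unused.
#' @return The object, invisibly, after printing the effect table and the
#'   underlying structural fits.
#' @export
summary.mediate_multi <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$outcome_fit)
  cat("\n")
  print(object$mediator_fit)
  invisible(object)
}

#' Point estimates of the mediation effects
#'
#' @param object A [mediate_multi()] fit.
#' @param ... Unused.
#' @return Named numeric vector: `total`, `acme_<mediator>` per mediator,
#'   `acme_joint`, `ade`.
#' @export
coef.mediate_multi <- function(object, ...) {
  stats::setNames(object$effects$estimates$estimate,
                  object$effects$estimates$effect)
}

#' Percentile confidence intervals of the mediation effects
#'
#' @param object A [mediate_multi()] fit.
#' @param parm Effect names to keep (default all).
#' @param level Interval level; must equal the level the draws were
#'   summarised at.
#' @param ... Unused.
#' @return A two-column matrix of interval bounds.
#' @export
confint.mediate_multi <- function(object, parm = NULL, level = NULL, ...) {
  level <- level %||% object$effects$conf_level
  if (abs(level - object$effects$conf_level) > 1e-12) {
    alpha <- 1 - level
    ci <- t(apply(object$effects$draws, 2L, stats::quantile,
                  probs = c(alpha / 2, 1 - alpha / 2), names = FALSE))
  } else {
    ci <- as.matrix(object$effects$estimates[, c("ci_lo", "ci_hi")])
    rownames(ci) <- object$effects$estimates$effect
  }
  colnames(ci) <- sprintf("%g %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Forest plot of the mediation effects
#'
#' Point estimates with percentile intervals for the six effects, in
#' results-table order (total at the top, then per-mediator and joint
#' ACMEs, then the ADE), with a reference line at zero.
#'
#' @param x A [mediate_multi()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mediate_multi <- function(x, ...) {
  df <- x$effects$estimates
  k <- rev(seq_len(nrow(df)))
  xlim <- range(0, df$ci_lo, df$ci_hi)
  graphics::plot(df$estimate, k, xlim = xlim, yaxt = "n",
                 xlab = sprintf("effect on %s (outcome units)",
                                x$spec$outcome),
                 ylab = "", pch = 19, ...)
  graphics::axis(2, at = k, labels = df$effect, las = 1)
  graphics::segments(df$ci_lo, k, df$ci_hi, k)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' @export
as.data.frame.mediate_multi <- function(x, ...) {
  out <- x$effects$estimates
  out$exposure <- x$spec$exposure
  out$outcome <- x$spec$outcome
  out[, c("exposure", "outcome", setdiff(names(out),
                                         c("exposure", "outcome")))]
}
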