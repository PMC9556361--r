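effect_label <- function(effect, mediators) {
  labels <- c(total = "Total",
              stats::setNames(
                paste0("ACME:", toupper(gsub("_", "-", mediators))),
                paste0("acme_", mediators)),
              acme_joint = "ACME:JOINT",
              ade = "ADE")
  unname(labels[effect])
}

#' Two-tier Bonferroni significance scheme
#'
#' Family-wise error control at level `alpha` on two nested families: an
#' intermediate (per-analysis) threshold `alpha / m_local` over the tests
#' within one mediation analysis, and a global threshold `alpha / m_global`
#' over the full battery. With the default 6 tests per analysis (total, ADE,
#' joint ACME, three mediator ACMEs) and a 10-analysis battery these are
#' 0.05/6 = 0.0083 and 0.05/60 = 0.00083.
#'
#' @param alpha Nominal family-wise level.
#' @param m_local Tests per analysis.
#' @param m_global Total tests in the battery (>= `m_local`).
#' @return An object of class `significance_scheme` with the two thresholds.
#' @export
#' @examples
#' significance_scheme()
significance_scheme <- function(alpha = 0.05, m_local = 6, m_global = 60) {
  stopifnot(alpha > 0, alpha < 1, m_local >= 1, m_global >= m_local)
  structure(
    list(alpha = alpha, m_local = as.integer(m_local),
         m_global = as.integer(m_global),
         threshold_intermediate = alpha / m_local,
         threshold_global = alpha / m_global),
    class = "significance_scheme"
  )
}

#' @export
print.significance_scheme <- function(x, ...) {
  cat(sprintf("Two-tier Bonferroni scheme (alpha = %g)\n", x$alpha))
  cat(sprintf("  intermediate: %g / %d = %.2g\n",
              x$alpha, x$m_local, x$threshold_intermediate))
  cat(sprintf("  global:       %g / %d = %.2g\n",
              x$alpha, x$m_global, x$threshold_global))
  invisible(x)
}

#' Run the full exposure-by-outcome mediation battery
#'
#' One independent mediation analysis per (exposure, outcome) pair, each
#' refitting both structural models on the cohort and drawing fresh
#' quasi-Bayesian samples (per-analysis seeds derived from the master seed).
#' Rows are emitted in a deterministic order: exposures in the order given
#' (TEMPS-A order by default: depressive, cyclothymic, hyperthymic,
#' irritable, anxious), outcomes drive-for-thinness then body
#' dissatisfaction, and within an analysis the results-table effect order
#' (Total, per-mediator ACMEs, joint ACME, ADE). Two-tier Bonferroni flags
#' are attached via [apply_significance_thresholds()].
#'
#' @param cohort Participant-level `data.frame`.
#' @param exposures,outcomes,mediators,confounders Column names.
#' @param J Quasi-Bayesian draws per analysis.
#' @param seed Master integer seed.
#' @param contrast Exposure contrast `c(a_star, a)`.
#' @param scheme A [significance_scheme()]; by default `m_local` is the
#'   number of effects per analysis and `m_global` scales with the number
#'   of analyses.
#' @param conf_level Interval level.
#' @return A `data.frame` of class `mediation_battery` with one row per
#'   (exposure, outcome, effect) and columns `estimate`, `ci_lo`, `ci_hi`,
#'   `p`, `p_floor`, `sig_raw`, `sig_intermediate`, `sig_global`, `marker`.
#' @export
run_battery <- function(cohort,
                        exposures = temperament_columns(),
                        outcomes = outcome_columns(),
                        mediators = c("stai_trait", "stai_state", "bdi"),
                        confounders = c("age", "bmi"),
                        J = 1000,
                        seed,
                        contrast = c(0, 1),
                        scheme = NULL,
                        conf_level = 0.95) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory")
  stopifnot(length(exposures) >= 1L, length(outcomes) >= 1L)
  n_effects <- length(mediators) + 3L
  n_analyses <- length(exposures) * length(outcomes)
  scheme <- scheme %||% significance_scheme(
    alpha = 0.05, m_local = n_effects, m_global = n_effects * n_analyses)

  rows <- list()
  idx <- 0L
  for (ex in exposures) {
    for (out in outcomes) {
      idx <- idx + 1L
      fit <- tryCatch(
        mediate_multi(cohort, exposure = ex, outcome = out,
                      mediators = mediators, confounders = confounders,
                      contrast = contrast, J = J,
                      seed = derive_seed(seed, idx),
                      conf_level = conf_level),
        error = function(e) {
          stop(sprintf("analysis '%s' ~ '%s' failed: %s",
                       ex, out, conditionMessage(e)), call. = FALSE)
        }
      )
      df <- fit$effects$estimates
      rows[[idx]] <- data.frame(
        exposure = ex, outcome = out,
        effect = effect_label(df$effect, mediators),
        estimate = df$estimate, ci_lo = df$ci_lo, ci_hi = df$ci_hi,
        p = df$p, p_floor = df$p_floor, row.names = NULL
      )
    }
  }
  res <- do.call(rbind, rows)
  res <- apply_significance_thresholds(res, scheme)
  attr(res, "scheme") <- scheme
  attr(res, "J") <- as.integer(J)
  attr(res, "seed") <- seed
  attr(res, "mediators") <- mediators
  class(res) <- c("mediation_battery", "data.frame")
  res
}

#' Attach two-tier Bonferroni significance flags
#'
#' Adds the three monotone significance flags (strict inequality against
#' each threshold): `sig_raw` at the nominal level, `sig_intermediate` at
#' `alpha / m_local`, `sig_global` at `alpha / m_global`, plus the
#' results-table footnote `marker` ("a" for intermediate-only, "b" for
#' global). P-values at the draw floor are compared at their floor value.
#'
#' @param results A results `data.frame` with a populated `p` column.
#' @param scheme A [significance_scheme()].
#' @return `results` with the flag columns (re)computed.
#' @export
apply_significance_thresholds <- function(results, scheme) {
  stopifnot(inherits(scheme, "significance_scheme"), "p" %in% names(results))
  results$sig_raw <- results$p < scheme$alpha
  results$sig_intermediate <- results$p < scheme$threshold_intermediate
  results$sig_global <- results$p < scheme$threshold_global
  results$marker <- ifelse(results$sig_global, "b",
                           ifelse(results$sig_intermediate, "a", ""))
  results
}

#' Format a battery results table for display or CSV export
#'
#' Fixed column order, estimates and interval bounds rounded to `decimals`,
#' p-values below the draw floor printed with `<`, and footnote markers
#' `^a` (intermediate threshold) / `^b` (global threshold) appended to the
#' p column.
#'
#' @param results A [run_battery()] table.
#' @param decimals Decimal places for estimates and CI bounds.
#' @return A `data.frame` of character columns ready for printing or CSV.
#' @export
format_results_table <- function(results, decimals = 2) {
  J <- attr(results, "J")
  floor_value <- if (!is.null(J)) 2 / J else NA_real_
  fmt <- function(v) sprintf(paste0("%.", decimals, "f"), v)
  p_str <- mapply(function(p, fl, mk) {
    s <- format_pvalue(p, floor = isTRUE(fl), floor_value = floor_value)
    if (nzchar(mk)) paste0(s, "^", mk) else s
  }, results$p, results$p_floor %||% FALSE, results$marker %||% "")
  data.frame(
    exposure = results$exposure,
    outcome = results$outcome,
    effect = results$effect,
    estimate = fmt(results$estimate),
    ci = sprintf("%s, %s", fmt(results$ci_lo), fmt(results$ci_hi)),
    p = unname(p_str),
    row.names = NULL
  )
}

#' @export
print.mediation_battery <- function(x, decimals = 2, ...) {
  scheme <- attr(x, "scheme")
  cat(sprintf("Mediation battery: %d analyses, %d effect rows (J = %d)\n",
              length(unique(paste(x$exposure, x$outcome))), nrow(x),
              attr(x, "J")))
  print(format_results_table(x, decimals = decimals), row.names = FALSE)
  if (!is.null(scheme)) {
    cat(sprintf(
      "^a p < %.3g (intermediate Bonferroni), ^b p < %.3g (global Bonferroni)\n",
      scheme$threshold_intermediate, scheme$threshold_global))
  }
  invisible(x)
}
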