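#' Canonical column names of a psychometric cohort table
#'
#' The five TEMPS-A affective-temperament subscales (Yes/No item counts),
#' the three mediators (STAI state and trait anxiety, 20--80; BDI, 0--39),
#' the two EDI-2 outcomes (drive for thinness, body dissatisfaction) and the
#' two confounders (age in years, BMI in kg/m^2).
#'
#' @name cohort-columns
#' @keywords internal
NULL

temperament_columns <- function() {
  c("temps_depressive", "temps_cyclothymic", "temps_hyperthymic",
    "temps_irritable", "temps_anxious")
}

mediator_columns <- function() c("stai_trait", "stai_state", "bdi")

outcome_columns <- function() c("edi_dt", "edi_bd")

confounder_columns <- function() c("age", "bmi")

analysis_columns <- function() {
  c(temperament_columns(), mediator_columns(), outcome_columns(),
    confounder_columns())
}

default_scale_bounds <- function() {
  list(
    temps_depressive  = c(0, 22),
    temps_cyclothymic = c(0, 20),
    temps_hyperthymic = c(0, 21),
    temps_irritable   = c(0, 21),
    temps_anxious     = c(0, 26),
    stai_state        = c(20, 80),
    stai_trait        = c(20, 80),
    bdi               = c(0, 39),
    edi_dt            = c(0, 21),
    edi_bd            = c(0, 27),
    age               = c(14, 60),
    bmi               = c(10, 18.5)
  )
}

default_exposure_params <- function() {
  list(
    temps_depressive  = c(mean = 13, sd = 4),
    temps_cyclothymic = c(mean = 11, sd = 4.5),
    temps_hyperthymic = c(mean = 8,  sd = 4),
    temps_irritable   = c(mean = 7,  sd = 4),
    temps_anxious     = c(mean = 13, sd = 5)
  )
}

default_confounder_params <- function() {
  list(age = c(mean = 23.7, sd = 8.7), bmi = c(mean = 14.4, sd = 1.8))
}

default_mediator_coefficients <- function() {
  cols <- c("(Intercept)", temperament_columns(), confounder_columns())
  b <- rbind(
    stai_trait = c(50, 0.25, 0.20, -0.20, 0.20, 0.35, 0.05, -0.40),
    stai_state = c(52, 0.30, 0.25, -0.25, 0.25, 0.40, 0.05, -0.60),
    bdi        = c(16, 0.25, 0.20, -0.20, 0.20, 0.25, 0.02, -0.30)
  )
  colnames(b) <- cols
  b
}

default_mediator_residual_cov <- function() {
  sds <- c(stai_trait = 8, stai_state = 9, bdi = 6)
  r <- matrix(0.5, 3, 3, dimnames = list(names(sds), names(sds)))
  diag(r) <- 1
  r * tcrossprod(sds)
}

default_outcome_coefficients <- function() {
  cols <- c("(Intercept)", temperament_columns(), mediator_columns(),
            confounder_columns())
  th <- rbind(
    edi_dt = c(2, 0.20, 0.10, 0.05, 0.05, 0.25, 0.03, 0.12, 0.12, 0.02, -0.35),
    edi_bd = c(4, 0.10, 0.05, 0.05, 0.02, 0.18, 0.02, 0.10, 0.14, 0.02, -0.30)
  )
  colnames(th) <- cols
  th
}

#' Configure the synthetic psychometric cohort generator
#'
#' Builds the full parameterisation of the data-generating process the
#' mediation analysis assumes: bounded exposures and confounders, mediators
#' that are linear in the exposures and confounders with jointly multivariate
#' normal residuals (covariance `mediator_residual_cov`, the source of the
#' mediators' residual correlation), and outcomes that are linear in
#' exposures, mediators and confounders with independent noise.
#'
#' Defaults are calibrated to an inpatient anorexia nervosa cohort:
#' age 23.7 +/- 8.7 years, admission BMI 14.4 +/- 1.8 kg/m^2, a 70.1%/29.9%
#' restricting/binge-purging subtype split, TEMPS-A subscales bounded by
#' their item counts (22/20/21/21/26), STAI scores in 20--80 and BDI in
#' 0--39. EDI-2 subscale bounds default to conventional ranges, 0--21 for
#' drive for thinness and 0--27 for body dissatisfaction.
#'
#' @param n Number of participants (>= 1).
#' @param exposure_params Named list, one entry per temperament column, each
#'   `c(mean =, sd =)`; draws are truncated normal within `scale_bounds`.
#' @param confounder_params Same structure for `age` and `bmi`.
#' @param mediators Mediator column names, in model order.
#' @param mediator_coefficients K x p matrix of mediator-model coefficients;
#'   columns `(Intercept)`, the five temperaments, `age`, `bmi`.
#' @param mediator_residual_cov K x K symmetric PSD residual covariance of
#'   the mediator equations.
#' @param outcomes Outcome column names.
#' @param outcome_coefficients Outcome-model coefficient matrix; columns
#'   `(Intercept)`, temperaments, mediators, `age`, `bmi`.
#' @param outcome_residual_sd Named vector of outcome residual SDs (>= 0).
#' @param scale_bounds Named list of `c(lo, hi)` per bounded column.
#' @param subtype_prob Probability of the restricting (R-AN) subtype.
#' @param clip Clip generated values into `scale_bounds`? Clipping introduces
#'   slight bias at the margins, so estimator-calibration experiments default
#'   to clipping off (see [calibration_config()]).
#' @param round Round instrument scores (temperaments, STAI, BDI, EDI) to
#'   integers? Age and BMI are never rounded.
#'
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()], [calibration_config()]
#' @export
cohort_config <- function(n = 184,
                          exposure_params = default_exposure_params(),
                          confounder_params = default_confounder_params(),
                          mediators = mediator_columns(),
                          mediator_coefficients = default_mediator_coefficients(),
                          mediator_residual_cov = default_mediator_residual_cov(),
                          outcomes = outcome_columns(),
                          outcome_coefficients = default_outcome_coefficients(),
                          outcome_residual_sd = c(edi_dt = 4, edi_bd = 4.5),
                          scale_bounds = default_scale_bounds(),
                          subtype_prob = 0.701,
                          clip = TRUE,
                          round = TRUE) {
  cfg <- structure(
    list(
      n = n,
      exposure_params = exposure_params,
      confounder_params = confounder_params,
      mediators = mediators,
      mediator_coefficients = as.matrix(mediator_coefficients),
      mediator_residual_cov = as.matrix(mediator_residual_cov),
      outcomes = outcomes,
      outcome_coefficients = as.matrix(outcome_coefficients),
      outcome_residual_sd = outcome_residual_sd,
      scale_bounds = scale_bounds,
      subtype_prob = subtype_prob,
      clip = isTRUE(clip),
      round = isTRUE(round)
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

#' Generator configuration for estimator-calibration experiments
#'
#' The default cohort configuration with clipping and rounding switched off,
#' so the linear-normal data-generating equations hold exactly and estimator
#' bias/coverage can be assessed against the configured truth.
#'
#' @param n Number of participants.
#' @param ... Further overrides passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
calibration_config <- function(n = 300, ...) {
  cohort_config(n = n, clip = FALSE, round = FALSE, ...)
}

validate_cohort_config <- function(cfg) {
  if (!is.numeric(cfg$n) || length(cfg$n) != 1L || cfg$n < 1) {
    stop("`n` must be a single count >= 1")
  }
  for (nm in names(cfg$scale_bounds)) {
    b <- cfg$scale_bounds[[nm]]
    if (length(b) != 2L || !(b[1L] < b[2L])) {
      stop(sprintf("scale bounds for '%s' must satisfy lo < hi", nm))
    }
  }
  all_params <- c(cfg$exposure_params, cfg$confounder_params)
  sds <- c(vapply(all_params, function(p) p[["sd"]], numeric(1)),
           cfg$outcome_residual_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (!is_psd(cfg$mediator_residual_cov)) {
    stop("mediator residual covariance must be symmetric positive semi-definite")
  }
  K <- length(cfg$mediators)
  if (nrow(cfg$mediator_coefficients) != K) {
    stop("mediator_coefficients must have one row per mediator")
  }
  if (nrow(cfg$outcome_coefficients) != length(cfg$outcomes)) {
    stop("outcome_coefficients must have one row per outcome")
  }
  if (cfg$subtype_prob < 0 || cfg$subtype_prob > 1) {
    stop("subtype_prob must lie in [0, 1]")
  }
  invisible(cfg)
}

#' Generate a synthetic psychometric cohort
#'
#' Draws a participant-level table from the data-generating process described
#' by `config`: truncated-normal confounders and temperament exposures,
#' mediators built as linear functions of all exposures and confounders plus
#' jointly multivariate-normal residuals, and outcomes built as linear
#' functions of exposures, mediators and confounders plus independent noise.
#' With `clip = FALSE` and `round = FALSE` the structural equations hold
#' exactly for the drawn residuals.
#'
#' The generator is a pure function of `(config, seed)`: identical inputs
#' yield identical tables, and the caller's RNG state is left untouched.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (mandatory).
#' @return A `data.frame`, one row per participant, with the canonical
#'   cohort columns plus a `subtype` label (`"R-AN"`/`"BP-AN"`).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 50), seed = 1)
#' summary(cohort$bmi)
generate_cohort <- function(config, seed) {
  validate_cohort_config(config)
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory")
  n <- as.integer(config$n)
  eval_with_seed(seed, {
    draw_bounded <- function(nm, params) {
      b <- config$scale_bounds[[nm]] %||% c(-Inf, Inf)
      rtruncnorm(n, params[["mean"]], params[["sd"]], b[1L], b[2L])
    }
    conf <- lapply(names(config$confounder_params), function(nm) {
      draw_bounded(nm, config$confounder_params[[nm]])
    })
    names(conf) <- names(config$confounder_params)
    expo <- lapply(names(config$exposure_params), function(nm) {
      draw_bounded(nm, config$exposure_params[[nm]])
    })
    names(expo) <- names(config$exposure_params)
    subtype <- ifelse(stats::runif(n) < config$subtype_prob, "R-AN", "BP-AN")

    tab <- as.data.frame(c(expo, conf), optional = TRUE)

    # Mediators: M = X beta' + E, E ~ MVN(0, Sigma), rows independent.
    bmat <- config$mediator_coefficients
    X <- cbind(`(Intercept)` = 1, as.matrix(tab))[, colnames(bmat), drop = FALSE]
    E <- rmvnorm_psd(n, rep(0, length(config$mediators)),
                     config$mediator_residual_cov)
    M <- X %*% t(bmat) + E
    colnames(M) <- config$mediators
    tab <- cbind(tab, as.data.frame(M))

    # Outcomes: Y = W theta' + eps, independent noise per outcome.
    tmat <- config$outcome_coefficients
    W <- cbind(`(Intercept)` = 1, as.matrix(tab))[, colnames(tmat), drop = FALSE]
    Y <- W %*% t(tmat)
    for (j in seq_along(config$outcomes)) {
      Y[, j] <- Y[, j] + stats::rnorm(n, 0, config$outcome_residual_sd[[j]])
    }
    colnames(Y) <- config$outcomes
    tab <- cbind(tab, as.data.frame(Y))

    instrument_cols <- intersect(
      c(names(config$exposure_params), config$mediators, config$outcomes),
      names(tab)
    )
    if (config$clip) {
      for (nm in intersect(names(tab), names(config$scale_bounds))) {
        b <- config$scale_bounds[[nm]]
        tab[[nm]] <- pmin(pmax(tab[[nm]], b[1L]), b[2L])
      }
    }
    if (config$round) {
      for (nm in instrument_cols) tab[[nm]] <- round(tab[[nm]])
    }
    tab$subtype <- subtype
    rownames(tab) <- NULL
    tab
  })
}

#' Recruitment flow accounting
#'
#' Applies mutually exclusive exclusion tallies to an initial candidate pool
#' and returns the enrolled count, either from aggregate counts or from
#' per-candidate logical flags.
#'
#' @param initial Initial candidate count (aggregate form).
#' @param exclusions Named non-negative counts of exclusions, e.g.
#'   `c(inclusion = 9, consent = 4, incomplete = 12)`.
#' @param flags Alternatively, a data.frame of per-candidate logical columns
#'   (e.g. `fails_inclusion`, `invalid_consent`, `incomplete_assessment`);
#'   at most one flag may be set per candidate.
#' @return A list of class `recruitment_flow` with elements `initial`,
#'   `exclusions` (named tally) and `enrolled`.
#' @export
#' @examples
#' recruitment_filter(209, c(inclusion = 9, consent = 4, incomplete = 12))
recruitment_filter <- function(initial = NULL, exclusions = NULL, flags = NULL) {
  if (!is.null(flags)) {
    flags <- as.data.frame(flags)
    if (!all(vapply(flags, is.logical, logical(1)))) {
      stop("per-candidate flags must all be logical columns")
    }
    if (any(rowSums(flags) > 1L)) {
      stop("exclusion categories must be mutually exclusive per candidate")
    }
    initial <- nrow(flags)
    exclusions <- colSums(flags)
  }
  if (is.null(initial)) stop("supply either aggregate counts or flags")
  exclusions <- exclusions %||% stats::setNames(numeric(0), character(0))
  if (initial < 0 || any(exclusions < 0)) stop("counts must be non-negative")
  if (sum(exclusions) > initial) {
    stop("total exclusions exceed the initial sample")
  }
  structure(
    list(initial = as.integer(initial),
         exclusions = exclusions,
         enrolled = as.integer(initial - sum(exclusions))),
    class = "recruitment_flow"
  )
}

#' @export
print.recruitment_flow <- function(x, ...) {
  cat("Recruitment flow:", x$initial, "candidates\n")
  if (length(x$exclusions)) {
    for (nm in names(x$exclusions)) {
      cat(sprintf("  excluded (%s): %d\n", nm, as.integer(x$exclusions[[nm]])))
    }
  }
  cat("  enrolled:", x$enrolled, "\n")
  invisible(x)
}

#' Summarise a cohort table
#'
#' Per-variable descriptives: mean, SD (n-1 denominator), min and max for
#' numeric columns; counts and percentages (one decimal) for categorical
#' columns.
#'
#' @param cohort A cohort `data.frame` (non-empty).
#' @return An object of class `cohort_summary` with elements `numeric`
#'   (a data.frame of descriptives) and `categorical` (a list of
#'   count/percentage tables), plus `n`.
#' @export
summarize_cohort <- function(cohort) {
  cohort <- as.data.frame(cohort)
  if (nrow(cohort) == 0L) stop("cohort is empty")
  is_num <- vapply(cohort, is.numeric, logical(1))
  num <- NULL
  if (any(is_num)) {
    num <- do.call(rbind, lapply(names(cohort)[is_num], function(nm) {
      x <- cohort[[nm]]
      data.frame(variable = nm, mean = mean(x), sd = stats::sd(x),
                 min = min(x), max = max(x))
    }))
    rownames(num) <- NULL
  }
  cat_cols <- names(cohort)[!is_num]
  cats <- lapply(cat_cols, function(nm) {
    tb <- table(cohort[[nm]])
    data.frame(level = names(tb),
               count = as.integer(tb),
               percent = round(100 * as.integer(tb) / nrow(cohort), 1))
  })
  names(cats) <- cat_cols
  structure(list(n = nrow(cohort), numeric = num, categorical = cats),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, digits = 2, ...) {
  cat("Cohort summary (n =", x$n, ")\n")
  if (!is.null(x$numeric)) {
    num <- x$numeric
    num[-1] <- lapply(num[-1], round, digits = digits)
    print(num, row.names = FALSE)
  }
  for (nm in names(x$categorical)) {
    cat("\n", nm, ":\n", sep = "")
    print(x$categorical[[nm]], row.names = FALSE)
  }
  invisible(x)
}
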