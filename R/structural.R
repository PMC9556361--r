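#' Causal specification of a single mediation analysis
#'
#' Names the roles of the variables in one analysis and records the causal
#' assumptions the estimator relies on: the exposure may affect each mediator
#' and the outcome; the mediators may affect the outcome but not one another
#' (they are "uncausally related" -- correlated only through residual
#' covariance); the confounders may affect every node; and sequential
#' ignorability is assumed so that natural direct and indirect effects are
#' identified.
#'
#' @param exposure Exposure column name (a single continuous variable, in
#'   raw scale units).
#' @param outcome Outcome column name.
#' @param mediators Ordered mediator column names (K >= 1).
#' @param confounders Confounder column names.
#' @param contrast Numeric `c(a_star, a)` exposure values; effects are
#'   reported per contrast `a - a_star` (default one unit of the exposure).
#' @return An object of class `causal_spec`.
#' @export
#' @examples
#' causal_spec("temps_anxious", "edi_dt")
causal_spec <- function(exposure,
                        outcome,
                        mediators = c("stai_trait", "stai_state", "bdi"),
                        confounders = c("age", "bmi"),
                        contrast = c(0, 1)) {
  stopifnot(is.character(exposure), length(exposure) == 1L,
            is.character(outcome), length(outcome) == 1L,
            is.character(mediators), length(mediators) >= 1L)
  nms <- c(exposure, outcome, mediators, confounders)
  if (anyDuplicated(nms)) {
    stop("exposure, outcome, mediators and confounders must be distinct")
  }
  if (length(contrast) != 2L || contrast[1L] == contrast[2L]) {
    stop("`contrast` must be c(a_star, a) with a != a_star")
  }
  structure(
    list(exposure = exposure, outcome = outcome, mediators = mediators,
         confounders = confounders, contrast = as.numeric(contrast)),
    class = "causal_spec"
  )
}

#' @export
print.causal_spec <- function(x, ...) {
  cat("Causal specification (linear, no exposure-mediator interaction)\n")
  cat("  exposure:   ", x$exposure, "\n")
  cat("  mediators:  ", paste(x$mediators, collapse = ", "),
      " (correlated residuals, no mediator-to-mediator effects)\n", sep = "")
  cat("  outcome:    ", x$outcome, "\n")
  cat("  confounders:", paste(x$confounders, collapse = ", "), "\n")
  cat(sprintf("  contrast:    a* = %g -> a = %g\n",
              x$contrast[1L], x$contrast[2L]))
  invisible(x)
}

# Complete-case subset on the spec's columns, with a logged drop count.
complete_case_subset <- function(cohort, spec) {
  cols <- c(spec$outcome, spec$exposure, spec$mediators, spec$confounders)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  sub <- cohort[, cols, drop = FALSE]
  ok <- stats::complete.cases(sub)
  if (any(!ok)) {
    message(sprintf("dropping %d incomplete row(s) of %d", sum(!ok), nrow(sub)))
  }
  sub[ok, , drop = FALSE]
}

# Stop with the names of aliased columns if the design is rank deficient.
check_full_rank <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  qx
}

#' Fit the linear outcome model of a mediation analysis
#'
#' Ordinary least squares for the outcome given the exposure, all mediators
#' and the confounders (no exposure-mediator interaction). The coefficient
#' sampling covariance is the classical homoskedastic estimator
#' `s^2 (X'X)^{-1}` with `s^2` on `n - p` degrees of freedom.
#'
#' @param cohort Cohort `data.frame`; rows with missing values in any model
#'   column are dropped (count logged).
#' @param spec A [causal_spec()].
#' @return An object of class `outcome_fit` with elements `theta` (named
#'   coefficients, order: intercept, exposure, mediators, confounders),
#'   `theta_vcov`, `residual_sd`, `n_used` and `columns`.
#' @export
fit_outcome_model <- function(cohort, spec) {
  dat <- complete_case_subset(cohort, spec)
  rhs <- c(spec$exposure, spec$mediators, spec$confounders)
  if (nrow(dat) <= length(rhs) + 2L) {
    stop("insufficient rows to fit the outcome model")
  }
  f <- stats::reformulate(rhs, response = spec$outcome)
  X <- stats::model.matrix(f, dat)
  check_full_rank(X)
  fit <- stats::lm(f, data = dat)
  s2 <- sum(stats::residuals(fit)^2) / (nrow(X) - ncol(X))
  vcov_theta <- s2 * chol2inv(chol(crossprod(X)))
  dimnames(vcov_theta) <- list(colnames(X), colnames(X))
  structure(
    list(theta = stats::coef(fit),
         theta_vcov = vcov_theta,
         residual_sd = sqrt(s2),
         n_used = nrow(dat),
         columns = names(stats::coef(fit)),
         spec = spec),
    class = "outcome_fit"
  )
}

#' Fit the mediator system of a mediation analysis
#'
#' Equation-by-equation least squares for each mediator given the exposure
#' and confounders. All equations share the same regressors, so per-equation
#' OLS is jointly efficient (it coincides with the seemingly-unrelated-
#' regressions estimator). The residual covariance `sigma` across mediator
#' equations is estimated from residual cross-products on `n - p` degrees of
#' freedom, and the sampling covariance of the stacked coefficient vector
#' (equation-major order) is `sigma %x% (X'X)^{-1}`.
#'
#' @inheritParams fit_outcome_model
#' @return An object of class `mediator_fit` with elements `beta` (K x p
#'   coefficient matrix, rows = mediators, columns = intercept, exposure,
#'   confounders), `beta_stacked` (equation-major vector), `beta_vcov`,
#'   `sigma` (K x K residual covariance) and `n_used`.
#' @export
fit_mediator_system <- function(cohort, spec) {
  dat <- complete_case_subset(cohort, spec)
  rhs <- c(spec$exposure, spec$confounders)
  if (nrow(dat) <= length(rhs) + 2L) {
    stop("insufficient rows to fit the mediator system")
  }
  const <- spec$mediators[vapply(spec$mediators,
                                 function(m) stats::sd(dat[[m]]) == 0,
                                 logical(1))]
  if (length(const)) {
    stop("mediator(s) with zero variance: ", paste(const, collapse = ", "))
  }
  X <- stats::model.matrix(stats::reformulate(rhs), dat)
  check_full_rank(X)
  M <- as.matrix(dat[, spec$mediators, drop = FALSE])
  n <- nrow(X)
  p <- ncol(X)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  B <- xtx_inv %*% crossprod(X, M)            # p x K
  resid <- M - X %*% B
  sigma <- crossprod(resid) / (n - p)
  dimnames(sigma) <- list(spec$mediators, spec$mediators)
  beta <- t(B)                                # K x p, spec orientation
  dimnames(beta) <- list(spec$mediators, colnames(X))
  stacked <- as.vector(B)                     # equation-major blocks
  names(stacked) <- as.vector(outer(colnames(X), spec$mediators,
                                    function(cf, m) paste(m, cf, sep = ":")))
  beta_vcov <- kronecker(sigma, xtx_inv)
  dimnames(beta_vcov) <- list(names(stacked), names(stacked))
  structure(
    list(beta = beta,
         beta_stacked = stacked,
         beta_vcov = beta_vcov,
         sigma = sigma,
         n_used = n,
         columns = colnames(X),
         spec = spec),
    class = "mediator_fit"
  )
}

#' @export
print.outcome_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Outcome model: %s ~ %s (n = %d, residual SD = %.*g)\n",
              x$spec$outcome,
              paste(x$columns[-1L], collapse = " + "),
              x$n_used, digits, x$residual_sd))
  print(round(x$theta, digits))
  invisible(x)
}

#' @export
print.mediator_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Mediator system: %d equation(s) on %s (n = %d)\n",
              nrow(x$beta), paste(x$columns[-1L], collapse = " + "),
              x$n_used))
  print(round(x$beta, digits))
  cat("Residual covariance:\n")
  print(round(x$sigma, digits))
  invisible(x)
}

#' Serialise a fitted model component to JSON
#'
#' Audit-friendly JSON of the coefficients, sampling covariance, residual
#' (co)variance and design column order of an [fit_outcome_model()] or
#' [fit_mediator_system()] result.
#'
#' @param fit An `outcome_fit` or `mediator_fit`.
#' @param path Optional file path; if omitted the JSON string is returned.
#' @return A JSON string (invisibly, when written to `path`).
#' @export
fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, c("outcome_fit", "mediator_fit")))
  payload <- unclass(fit)
  payload$spec <- unclass(payload$spec)
  js <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                         matrix = "rowmajor")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
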