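effect_names <- function(mediators) {
  c("total", paste0("acme_", mediators), "acme_joint", "ade")
}

#' Quasi-Bayesian parameter draws
#'
#' Simulates the outcome-model and mediator-system coefficients from their
#' asymptotic sampling distributions: `theta ~ MVN(theta_hat, theta_vcov)`
#' and the stacked mediator coefficients `~ MVN(beta_hat, sigma %x%
#' (X'X)^{-1})`. The mediator residual covariance `sigma` is held at its
#' estimate. Draws are deterministic under a fixed seed and leave the
#' caller's RNG state untouched.
#'
#' @param ofit An [fit_outcome_model()] result.
#' @param mfit A [fit_mediator_system()] result.
#' @param J Number of draws (>= 2).
#' @param seed Integer seed (mandatory).
#' @return An object of class `parameter_draws` with matrices `theta`
#'   (J x length(theta)) and `beta` (J x K*p, equation-major columns).
#' @export
draw_parameters <- function(ofit, mfit, J = 1000, seed) {
  stopifnot(inherits(ofit, "outcome_fit"), inherits(mfit, "mediator_fit"))
  if (J < 2) stop("`J` must be at least 2")
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory")
  if (!all(mfit$spec$mediators %in% ofit$columns)) {
    stop("outcome fit lacks coefficients for the mediators in the system")
  }
  eval_with_seed(seed, {
    th <- rmvnorm_psd(J, ofit$theta, ofit$theta_vcov)
    colnames(th) <- ofit$columns
    be <- rmvnorm_psd(J, mfit$beta_stacked, mfit$beta_vcov)
    colnames(be) <- names(mfit$beta_stacked)
    structure(
      list(theta = th, beta = be, J = as.integer(J), seed = seed,
           mediators = mfit$spec$mediators, exposure = mfit$spec$exposure,
           mediator_columns = mfit$columns),
      class = "parameter_draws"
    )
  })
}

#' Closed-form effect decomposition for the linear no-interaction model
#'
#' Reduces the counterfactual effect definitions to products of
#' coefficients: per contrast `delta = a - a_star`, the mediator-specific
#' ACME is `theta[M_k] * beta[k, exposure] * delta`, the joint ACME is their
#' sum, the ADE is `theta[exposure] * delta` and the total effect is
#' ADE + joint ACME. All effects are on the outcome scale.
#'
#' @param theta Named outcome-model coefficient vector (must contain the
#'   exposure and every mediator).
#' @param beta Mediator-model coefficient matrix, rows named by mediator,
#'   columns including the exposure.
#' @param contrast Numeric `c(a_star, a)`.
#' @param exposure Exposure name (defaults to the single column of `beta`
#'   that is neither `"(Intercept)"` nor a confounder-free guess; pass it
#'   explicitly in programmatic use).
#' @return A named numeric vector of class `effect_point` with elements
#'   `total`, `acme_<mediator>`, `acme_joint`, `ade`.
#' @export
#' @examples
#' theta <- c(`(Intercept)` = 0, x = 0.5, m1 = 1, m2 = 1, m3 = 2)
#' beta <- matrix(c(0, 0.3, 0, 0.2, 0, 0.1), nrow = 3, byrow = TRUE,
#'                dimnames = list(c("m1", "m2", "m3"), c("(Intercept)", "x")))
#' closed_form_effects(theta, beta, contrast = c(0, 1), exposure = "x")
closed_form_effects <- function(theta, beta, contrast = c(0, 1),
                                exposure = NULL) {
  beta <- as.matrix(beta)
  mediators <- rownames(beta)
  if (is.null(mediators)) stop("`beta` must have mediator row names")
  if (is.null(exposure)) {
    cand <- setdiff(colnames(beta), "(Intercept)")
    exposure <- cand[cand %in% names(theta)][1L]
    if (is.na(exposure)) stop("cannot infer the exposure; pass `exposure`")
  }
  if (!exposure %in% names(theta) || !exposure %in% colnames(beta)) {
    stop(sprintf("exposure '%s' absent from theta or beta", exposure))
  }
  if (!all(mediators %in% names(theta))) {
    stop("theta lacks coefficients for some mediators")
  }
  delta <- contrast[2L] - contrast[1L]
  acme <- unname(theta[mediators] * beta[, exposure]) * delta
  ade <- unname(theta[exposure]) * delta
  joint <- sum(acme)
  structure(
    stats::setNames(c(ade + joint, acme, joint, ade), effect_names(mediators)),
    class = "effect_point"
  )
}

#' Counterfactual-simulation effect decomposition
#'
#' The definitional implementation of the effects: for each participant and
#' Monte-Carlo replicate, joint mediator residual vectors are drawn from
#' `MVN(0, sigma)` and potential mediator values `M(a)` and `M(a_star)` are
#' formed, sharing the residual draw across the two exposure arms (common
#' random numbers; the expectation is unchanged and the Monte-Carlo variance
#' reduced). Effects are averages over participants and replicates of
#' differences of model-predicted counterfactual outcomes:
#' total `Y(a, M(a)) - Y(a*, M(a*))`, direct `Y(a, M(a*)) - Y(a*, M(a*))`,
#' joint ACME `Y(a, M(a)) - Y(a, M(a*))`, and per-mediator ACME
#' `Y(a, M_k(a), M_-k(a*)) - Y(a, M(a*))` (the target mediator switched,
#' non-targets held at their `a_star` potential values; under the
#' no-interaction model the alternative convention coincides).
#'
#' Must agree with [closed_form_effects()] up to Monte-Carlo error; with
#' `sigma = 0` the agreement is exact.
#'
#' @param theta Named outcome-model coefficient vector.
#' @param beta Mediator-model coefficient matrix (rows = mediators; columns
#'   = intercept, exposure, confounders).
#' @param sigma K x K mediator residual covariance.
#' @param cohort Cohort `data.frame` supplying the confounder distribution.
#' @param spec A [causal_spec()].
#' @param n_mc Monte-Carlo replicates per participant (>= 1).
#' @param seed Integer seed.
#' @param common_rng Share residual draws across exposure arms (default
#'   TRUE).
#' @return An `effect_point` vector.
#' @export
simulate_counterfactual_effects <- function(theta, beta, sigma, cohort, spec,
                                            n_mc = 100, seed,
                                            common_rng = TRUE) {
  if (n_mc < 1) stop("`n_mc` must be at least 1")
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory")
  beta <- as.matrix(beta)
  K <- nrow(beta)
  mediators <- rownames(beta)
  if (!is_psd(sigma)) stop("`sigma` must be symmetric positive semi-definite")
  a_star <- spec$contrast[1L]
  a <- spec$contrast[2L]
  n <- nrow(cohort)

  conf <- as.matrix(cohort[, spec$confounders, drop = FALSE])
  # Participant-level mediator means net of the exposure term.
  base_cols <- setdiff(colnames(beta), spec$exposure)
  Xb <- cbind(`(Intercept)` = rep(1, n), conf)[, base_cols, drop = FALSE]
  m_base <- Xb %*% t(beta[, base_cols, drop = FALSE])   # n x K
  b_exp <- beta[, spec$exposure]

  th_m <- theta[mediators]
  th_e <- theta[[spec$exposure]]
  # Outcome terms that are identical across counterfactual compositions
  # cancel in every effect difference, so only exposure and mediator terms
  # matter; participant intercept/confounder terms are retained for clarity.
  th_base_cols <- intersect(names(theta), c("(Intercept)", spec$confounders))
  y_base <- as.vector(cbind(`(Intercept)` = rep(1, n),
                            conf)[, th_base_cols, drop = FALSE] %*%
                        theta[th_base_cols])

  eval_with_seed(seed, {
    acc <- numeric(length(effect_names(mediators)))
    for (r in seq_len(n_mc)) {
      eps_a_star <- rmvnorm_psd(n, rep(0, K), sigma)
      eps_a <- if (common_rng) eps_a_star else rmvnorm_psd(n, rep(0, K), sigma)
      M_a_star <- m_base + rep(a_star, n) %o% b_exp + eps_a_star
      M_a <- m_base + rep(a, n) %o% b_exp + eps_a
      y <- function(x, M) y_base + th_e * x + as.vector(M %*% th_m)
      y_aa <- y(a, M_a)              # Y(a, M(a))
      y_ss <- y(a_star, M_a_star)    # Y(a*, M(a*))
      y_as <- y(a, M_a_star)         # Y(a, M(a*))
      total <- mean(y_aa - y_ss)
      ade <- mean(y_as - y_ss)
      joint <- mean(y_aa - y_as)
      acme <- vapply(seq_len(K), function(k) {
        Mk <- M_a_star
        Mk[, k] <- M_a[, k]
        mean(y(a, Mk) - y_as)
      }, numeric(1))
      acc <- acc + c(total, acme, joint, ade)
    }
    structure(stats::setNames(acc / n_mc, effect_names(mediators)),
              class = "effect_point")
  })
}

#' Two-sided p-value from quasi-Bayesian draws
#'
#' The draw-based two-sided tail probability
#' `p = max(2 * min(#\{draw <= 0\}, #\{draw >= 0\}) / J, 2/J)`. The floor
#' `2/J` is attached as attributes `floor` (logical: is the value at the
#' floor, i.e. should be reported as "< 2/J") and `floor_value`.
#'
#' @param draws Numeric vector of an effect across J >= 2 draws.
#' @return The p-value in (0, 1], with floor attributes.
#' @export
#' @examples
#' pvalue_from_draws(c(rep(1, 600), rep(-1, 400)))  # 0.8
pvalue_from_draws <- function(draws) {
  J <- length(draws)
  if (J < 2L) stop("at least two draws are required")
  if (anyNA(draws)) stop("draws contain missing values")
  m <- min(sum(draws <= 0), sum(draws >= 0))
  floor_value <- 2 / J
  p <- max(2 * m / J, floor_value)
  structure(p, floor = m == 0L, floor_value = floor_value)
}

format_pvalue <- function(p, floor = isTRUE(attr(p, "floor")),
                          floor_value = attr(p, "floor_value"), digits = 3) {
  force(floor)
  force(floor_value)
  p <- as.numeric(p)
  if (floor) {
    paste("<", format(floor_value %||% p, digits = 2))
  } else if (p < 10^-digits) {
    sprintf("%.1e", p)
  } else {
    format(round(p, digits), nsmall = digits)
  }
}

#' Quasi-Bayesian effect estimates with intervals and p-values
#'
#' Propagates coefficient sampling uncertainty into the effect decomposition:
#' J parameter draws are taken via [draw_parameters()], an effect
#' decomposition is computed per draw (closed form by default; the
#' counterfactual-simulation path is retained as the definitional
#' cross-check), and each effect is summarised by the mean of its draws, the
#' percentile interval at `conf_level`, and [pvalue_from_draws()].
#'
#' @inheritParams draw_parameters
#' @param spec A [causal_spec()] (defaults to the one carried by the fits).
#' @param method `"closed_form"` (default) or `"counterfactual"`.
#' @param cohort Required when `method = "counterfactual"`.
#' @param n_mc Monte-Carlo replicates per draw for the counterfactual path.
#' @param conf_level Interval level (default 0.95).
#' @return An object of class `effect_estimates`: a list with `estimates`
#'   (data.frame: effect, estimate, ci_lo, ci_hi, p, p_floor), `draws`
#'   (J x 6 matrix), and metadata (`J`, `seed`, `method`, `contrast`,
#'   `n_used`, `conf_level`).
#' @export
estimate_effects <- function(ofit, mfit, spec = NULL, J = 1000, seed,
                             method = c("closed_form", "counterfactual"),
                             cohort = NULL, n_mc = 50, conf_level = 0.95) {
  method <- match.arg(method)
  spec <- spec %||% ofit$spec
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory")
  draws <- draw_parameters(ofit, mfit, J = J, seed = seed)
  K <- length(spec$mediators)
  p_m <- length(mfit$columns)
  delta <- spec$contrast[2L] - spec$contrast[1L]
  enames <- effect_names(spec$mediators)

  if (method == "closed_form") {
    exp_pos <- match(spec$exposure, mfit$columns)
    acme <- vapply(seq_len(K), function(k) {
      draws$theta[, spec$mediators[k]] *
        draws$beta[, (k - 1L) * p_m + exp_pos] * delta
    }, numeric(J))
    ade <- draws$theta[, spec$exposure] * delta
    joint <- rowSums(acme)
    emat <- cbind(ade + joint, acme, joint, ade)
  } else {
    if (is.null(cohort)) {
      stop("`cohort` is required for the counterfactual method")
    }
    emat <- t(vapply(seq_len(J), function(j) {
      bmat <- matrix(draws$beta[j, ], nrow = K, byrow = TRUE,
                     dimnames = list(spec$mediators, mfit$columns))
      simulate_counterfactual_effects(
        theta = stats::setNames(draws$theta[j, ], colnames(draws$theta)),
        beta = bmat, sigma = mfit$sigma, cohort = cohort, spec = spec,
        n_mc = n_mc, seed = derive_seed(seed, j)
      )
    }, numeric(K + 3L)))
  }
  colnames(emat) <- enames

  alpha <- 1 - conf_level
  ci <- apply(emat, 2L, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2),
              names = FALSE)
  pvals <- apply(emat, 2L, pvalue_from_draws)
  est <- data.frame(
    effect = enames,
    estimate = colMeans(emat),
    ci_lo = ci[1L, ],
    ci_hi = ci[2L, ],
    p = as.numeric(pvals),
    p_floor = vapply(enames, function(e) {
      m <- min(sum(emat[, e] <= 0), sum(emat[, e] >= 0))
      m == 0L
    }, logical(1)),
    row.names = NULL
  )
  structure(
    list(estimates = est, draws = emat, J = as.integer(J), seed = seed,
         method = method, contrast = spec$contrast,
         n_used = ofit$n_used, conf_level = conf_level, spec = spec),
    class = "effect_estimates"
  )
}

#' @export
print.effect_estimates <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Quasi-Bayesian mediation effects (%s, J = %d, n = %d, contrast %g -> %g)\n",
    x$method, x$J, x$n_used, x$contrast[1L], x$contrast[2L]))
  df <- x$estimates
  out <- data.frame(
    effect = df$effect,
    estimate = round(df$estimate, digits),
    ci = sprintf("[%.*f, %.*f]", digits, df$ci_lo, digits, df$ci_hi),
    p = mapply(format_pvalue, df$p, df$p_floor,
               MoreArgs = list(floor_value = 2 / x$J))
  )
  names(out)[3L] <- sprintf("%g%% CI", 100 * x$conf_level)
  print(out, row.names = FALSE)
  invisible(x)
}
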