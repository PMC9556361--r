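# Shared fixtures and independent oracles for the test suite.

# Brute-force OLS oracle via the explicit normal equations (deliberately
# naive, independent of the qr/lm-based implementation path).
ols_oracle <- function(X, y) {
  xtx_inv <- solve(t(X) %*% X)
  coef <- xtx_inv %*% (t(X) %*% y)
  resid <- y - X %*% coef
  s2 <- sum(resid^2) / (nrow(X) - ncol(X))
  list(coef = drop(coef), vcov = s2 * xtx_inv, resid = drop(resid),
       residual_sd = sqrt(s2))
}

# Two-pass standard deviation oracle (n - 1 denominator).
sd_two_pass <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

temps5 <- c("temps_depressive", "temps_cyclothymic", "temps_hyperthymic",
            "temps_irritable", "temps_anxious")

# Generator configuration with a single active exposure (anxious
# temperament) and fully known structural coefficients; clipping and
# rounding off so the configured equations are the exact truth.
# Defaults give ACMEs (0.3, 0.2, 0.2), joint 0.7, ADE 0.5, total 1.2.
toy_config <- function(n = 500,
                       beta_exp = c(0.3, 0.2, 0.1),
                       theta_exp = 0.5,
                       theta_med = c(1, 1, 2),
                       med_sd = c(1, 1, 1),
                       med_cor = 0.3,
                       out_sd = 1,
                       med_intercepts = c(10, 40, 5)) {
  mediators <- c("stai_trait", "stai_state", "bdi")
  bcols <- c("(Intercept)", temps5, "age", "bmi")
  b <- matrix(0, 3, length(bcols), dimnames = list(mediators, bcols))
  b[, "(Intercept)"] <- med_intercepts
  b[, "temps_anxious"] <- beta_exp
  r <- matrix(med_cor, 3, 3)
  diag(r) <- 1
  sigma <- r * tcrossprod(med_sd)
  dimnames(sigma) <- list(mediators, mediators)
  tcols <- c("(Intercept)", temps5, mediators, "age", "bmi")
  th <- matrix(0, 2, length(tcols),
               dimnames = list(c("edi_dt", "edi_bd"), tcols))
  th["edi_dt", "(Intercept)"] <- 1
  th["edi_dt", "temps_anxious"] <- theta_exp
  th["edi_dt", mediators] <- theta_med
  th["edi_bd", "(Intercept)"] <- 1
  cohort_config(n = n,
                mediator_coefficients = b,
                mediator_residual_cov = sigma,
                outcome_coefficients = th,
                outcome_residual_sd = c(edi_dt = out_sd, edi_bd = out_sd),
                clip = FALSE, round = FALSE)
}

toy_spec <- function(contrast = c(0, 1)) {
  causal_spec("temps_anxious", "edi_dt", contrast = contrast)
}

# Small hand-built table for exact-fit checks: one exposure, one or two
# mediators, one confounder, eight rows.
hand_fixture <- function() {
  data.frame(
    x  = c(0, 1, 2, 3, 4, 5, 6, 7),
    m1 = c(2.0, 2.8, 4.1, 4.9, 6.2, 6.8, 8.1, 9.0),
    m2 = c(1.0, 1.4, 2.1, 2.3, 3.2, 3.3, 4.2, 4.4),
    c1 = c(0.5, -0.2, 0.3, 0.8, -0.5, 0.1, 0.4, -0.3),
    y  = c(3.1, 4.0, 5.2, 6.1, 7.3, 7.9, 9.2, 10.1)
  )
}
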