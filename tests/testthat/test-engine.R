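test_that("draw-based p-values follow the two-sided sign convention", {
  p <- pvalue_from_draws(c(rep(1, 600), rep(-1, 400)))
  expect_equal(as.numeric(p), 0.8)
  expect_false(attr(p, "floor"))

  p_floor <- pvalue_from_draws(rep(1, 1000))
  expect_equal(as.numeric(p_floor), 0.002)
  expect_true(attr(p_floor, "floor"))
  expect_equal(attr(p_floor, "floor_value"), 0.002)
  expect_match(corrmediate:::format_pvalue(p_floor), "^< 0.002$")

  p_half <- pvalue_from_draws(c(rep(1, 500), rep(-1, 500)))
  expect_equal(as.numeric(p_half), 1)

  expect_error(pvalue_from_draws(numeric(0)), "two draws")
  expect_error(pvalue_from_draws(1), "two draws")
})

test_that("closed-form decomposition is the product of coefficients", {
  theta <- c(`(Intercept)` = 0, x = 0.5, m1 = 1, m2 = 1, m3 = 2)
  beta <- matrix(c(1, 0.3, 2, 0.2, 3, 0.1), nrow = 3, byrow = TRUE,
                 dimnames = list(c("m1", "m2", "m3"), c("(Intercept)", "x")))
  eff <- closed_form_effects(theta, beta, contrast = c(0, 1), exposure = "x")
  expect_equal(unname(eff[c("acme_m1", "acme_m2", "acme_m3")]),
               c(0.3, 0.2, 0.2))
  expect_equal(unname(eff["acme_joint"]), 0.7)
  expect_equal(unname(eff["ade"]), 0.5)
  expect_equal(unname(eff["total"]), 1.2)

  # no mediation limit
  beta0 <- beta
  beta0[, "x"] <- 0
  eff0 <- closed_form_effects(theta, beta0, exposure = "x")
  expect_equal(unname(eff0[grep("acme", names(eff0))]), rep(0, 4))
  expect_equal(unname(eff0["total"]), unname(eff0["ade"]))

  # linearity in the contrast
  eff2 <- closed_form_effects(theta, beta, contrast = c(0, 2),
                              exposure = "x")
  expect_equal(unname(eff2), 2 * unname(eff))
})

test_that("parameter draws honour the sampling distributions", {
  cohort <- generate_cohort(toy_config(n = 150), seed = 12)
  spec <- toy_spec()
  ofit <- fit_outcome_model(cohort, spec)
  mfit <- fit_mediator_system(cohort, spec)

  d1 <- draw_parameters(ofit, mfit, J = 50, seed = 1)
  d2 <- draw_parameters(ofit, mfit, J = 50, seed = 1)
  expect_identical(d1$theta, d2$theta)
  expect_identical(d1$beta, d2$beta)

  # degenerate covariances collapse every draw onto the point estimates
  ofit0 <- ofit
  ofit0$theta_vcov[] <- 0
  mfit0 <- mfit
  mfit0$beta_vcov[] <- 0
  d0 <- draw_parameters(ofit0, mfit0, J = 10, seed = 2)
  expect_equal(unname(d0$theta),
               matrix(ofit$theta, 10, length(ofit$theta), byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(d0$beta[1, ]), unname(mfit$beta_stacked),
               tolerance = 1e-12)

  # sampled variance of a scalar coefficient matches its standard error
  d <- draw_parameters(ofit, mfit, J = 10000, seed = 3)
  v <- ofit$theta_vcov[spec$exposure, spec$exposure]
  expect_lt(abs(var(d$theta[, spec$exposure]) / v - 1), 0.10)

  expect_error(draw_parameters(ofit, mfit, J = 1, seed = 1), "at least 2")
  ofit_bad <- ofit
  ofit_bad$theta_vcov[1, 2] <- ofit_bad$theta_vcov[1, 2] + 1e3
  expect_error(draw_parameters(ofit_bad, mfit, J = 5, seed = 1))
})

test_that("counterfactual simulation agrees with the closed form", {
  cohort <- generate_cohort(toy_config(n = 200, med_cor = 0.5), seed = 13)
  spec <- toy_spec()
  ofit <- fit_outcome_model(cohort, spec)
  mfit <- fit_mediator_system(cohort, spec)
  cf <- closed_form_effects(ofit$theta, mfit$beta, spec$contrast,
                            spec$exposure)

  # zero residual covariance: deterministic mediators, exact agreement
  sim0 <- simulate_counterfactual_effects(ofit$theta, mfit$beta,
                                          sigma = diag(0, 3), cohort, spec,
                                          n_mc = 3, seed = 1)
  expect_equal(unname(sim0), unname(cf), tolerance = 1e-10)

  # shared residual draws across arms: exact agreement by construction
  sim_crn <- simulate_counterfactual_effects(ofit$theta, mfit$beta,
                                             mfit$sigma, cohort, spec,
                                             n_mc = 5, seed = 2)
  expect_equal(unname(sim_crn), unname(cf), tolerance = 1e-10)

  # independent draws per arm: within 4 Monte-Carlo SEs of the closed form
  reps <- vapply(1:10, function(s) {
    simulate_counterfactual_effects(ofit$theta, mfit$beta, mfit$sigma,
                                    cohort, spec, n_mc = 200, seed = 100 + s,
                                    common_rng = FALSE)
  }, numeric(6))
  for (k in seq_len(6)) {
    mc_se <- sd(reps[k, ]) / sqrt(10)
    expect_lt(abs(mean(reps[k, ]) - cf[k]), 4 * mc_se + 1e-12)
  }

  # null contrast: all effects vanish
  spec_null <- spec
  spec_null$contrast <- c(1, 1)
  sim_null <- simulate_counterfactual_effects(ofit$theta, mfit$beta,
                                              mfit$sigma, cohort, spec_null,
                                              n_mc = 3, seed = 4)
  expect_equal(unname(sim_null), rep(0, 6))

  expect_error(
    simulate_counterfactual_effects(ofit$theta, mfit$beta,
                                    matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3),
                                    cohort, spec, n_mc = 2, seed = 1),
    "positive semi-definite")
})

test_that("effect estimates are deterministic, coherent and decomposable", {
  cohort <- generate_cohort(toy_config(n = 250), seed = 14)
  spec <- toy_spec()
  ofit <- fit_outcome_model(cohort, spec)
  mfit <- fit_mediator_system(cohort, spec)

  e1 <- estimate_effects(ofit, mfit, spec, J = 400, seed = 5)
  e2 <- estimate_effects(ofit, mfit, spec, J = 400, seed = 5)
  expect_identical(e1, e2)

  # per-draw additivity identities
  d <- e1$draws
  scale <- pmax(abs(d[, "total"]), 1)
  expect_lt(max(abs(d[, "total"] - d[, "ade"] - d[, "acme_joint"]) / scale),
            1e-10)
  acme_sum <- rowSums(d[, grep("^acme_(stai|bdi)", colnames(d))])
  expect_lt(max(abs(d[, "acme_joint"] - acme_sum) / scale), 1e-10)

  # interval coherence
  est <- e1$estimates
  expect_true(all(est$ci_lo <= est$ci_hi))
  for (k in seq_len(nrow(est))) {
    expect_gte(est$estimate[k], min(d[, k]))
    expect_lte(est$estimate[k], max(d[, k]))
  }
  expect_true(all(est$p > 0 & est$p <= 1))
})

test_that("effects are invariant to the baseline exposure level", {
  cohort <- generate_cohort(toy_config(n = 200), seed = 15)
  ofit <- fit_outcome_model(cohort, toy_spec())
  mfit <- fit_mediator_system(cohort, toy_spec())
  e_low <- estimate_effects(ofit, mfit, toy_spec(c(0, 1)), J = 300, seed = 6)
  e_high <- estimate_effects(ofit, mfit, toy_spec(c(10, 11)), J = 300,
                             seed = 6)
  expect_equal(e_low$estimates, e_high$estimates, tolerance = 1e-12)
})

test_that("degenerate parameter uncertainty collapses intervals to the point", {
  cohort <- generate_cohort(toy_config(n = 150), seed = 16)
  ofit <- fit_outcome_model(cohort, toy_spec())
  mfit <- fit_mediator_system(cohort, toy_spec())
  ofit$theta_vcov[] <- 0
  mfit$beta_vcov[] <- 0
  e <- estimate_effects(ofit, mfit, toy_spec(), J = 100, seed = 7)
  est <- e$estimates
  expect_equal(est$ci_lo, est$estimate, tolerance = 1e-12)
  expect_equal(est$ci_hi, est$estimate, tolerance = 1e-12)
  expect_true(all(est$p == 2 / 100))
  expect_true(all(est$p_floor))
})

test_that("counterfactual and closed-form estimation paths coincide per draw", {
  cohort <- generate_cohort(toy_config(n = 150, med_cor = 0.4), seed = 17)
  spec <- toy_spec()
  ofit <- fit_outcome_model(cohort, spec)
  mfit <- fit_mediator_system(cohort, spec)
  e_cf <- estimate_effects(ofit, mfit, spec, J = 60, seed = 8)
  e_sim <- estimate_effects(ofit, mfit, spec, J = 60, seed = 8,
                            method = "counterfactual", cohort = cohort,
                            n_mc = 3)
  # same parameter draws + common random numbers => per-draw equality
  expect_equal(e_sim$draws, e_cf$draws, tolerance = 1e-8)
  expect_error(estimate_effects(ofit, mfit, spec, J = 10, seed = 1,
                                method = "counterfactual"),
               "cohort")
})

test_that("generator truth is recovered on a large synthetic cohort", {
  cfg <- toy_config(n = 2000)
  cohort <- generate_cohort(cfg, seed = 18)
  spec <- toy_spec()
  truth <- true_effects(cfg, spec)
  expect_equal(unname(truth[c("acme_stai_trait", "acme_stai_state",
                              "acme_bdi")]),
               c(0.3, 0.2, 0.2))
  ofit <- fit_outcome_model(cohort, spec)
  mfit <- fit_mediator_system(cohort, spec)
  e <- estimate_effects(ofit, mfit, spec, J = 1000, seed = 9)
  draw_sd <- apply(e$draws, 2, sd)
  expect_true(all(abs(e$estimates$estimate - unname(truth)) <= 3 * draw_sd))
})
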