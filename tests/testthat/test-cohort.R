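test_that("noiseless generator reproduces the structural equations exactly", {
  cfg <- toy_config(n = 20, beta_exp = c(0, 0, 0), theta_exp = 0,
                    theta_med = c(0, 0, 0), med_sd = c(0, 0, 0),
                    med_cor = 0, out_sd = 0, med_intercepts = c(10, 40, 5))
  cohort <- generate_cohort(cfg, seed = 1)
  expect_equal(unique(cohort$stai_trait), 10)
  expect_equal(unique(cohort$stai_state), 40)
  expect_equal(unique(cohort$bdi), 5)
  expect_equal(unique(cohort$edi_dt), 1)  # outcome intercept only

  # With noise on but clipping/rounding off, the mediator equation holds
  # exactly for the drawn residuals: regressing mediator 1 on the design
  # leaves residuals that reproduce the table when added back.
  cfg2 <- toy_config(n = 50)
  tab <- generate_cohort(cfg2, seed = 2)
  X <- cbind(1, as.matrix(tab[, c(temps5, "age", "bmi")]))
  eta <- X %*% c(10, 0, 0, 0, 0, 0.3, 0, 0)
  resid <- tab$stai_trait - eta
  expect_equal(as.numeric(eta + resid), tab$stai_trait, tolerance = 1e-12)
})

test_that("generation is a pure, seed-deterministic function", {
  cfg <- cohort_config(n = 40)
  a <- generate_cohort(cfg, seed = 1)
  b <- generate_cohort(cfg, seed = 1)
  expect_identical(a, b)
  c2 <- generate_cohort(cfg, seed = 2)
  expect_true(any(as.matrix(a[, 1:12]) != as.matrix(c2[, 1:12])))
  # caller's RNG stream is untouched
  set.seed(99)
  u1 <- runif(3)
  set.seed(99)
  invisible(generate_cohort(cfg, seed = 5))
  expect_identical(runif(3), u1)
  expect_error(generate_cohort(cfg), "seed")
})

test_that("configured exposure slope is recovered by an independent refit", {
  cfg <- toy_config(n = 5000, beta_exp = c(0.4, 0.2, 0.1))
  tab <- generate_cohort(cfg, seed = 11)
  X <- cbind(1, tab$temps_anxious, tab$age, tab$bmi)
  fit <- ols_oracle(X, tab$stai_trait)
  se <- sqrt(diag(fit$vcov))[2]
  expect_lt(abs(fit$coef[2] - 0.4), 4 * se)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n = 0), "n")
  bad_sigma <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3, 3)  # not PSD
  expect_error(cohort_config(mediator_residual_cov = bad_sigma),
               "positive semi-definite")
  cfg <- cohort_config()
  cfg$scale_bounds$bdi <- c(10, 5)
  expect_error(generate_cohort(cfg, seed = 1), "lo < hi")
})

test_that("clipping and rounding respect the declared instrument scales", {
  cohort <- generate_cohort(cohort_config(n = 500), seed = 3)
  bounds <- list(temps_depressive = c(0, 22), temps_cyclothymic = c(0, 20),
                 temps_hyperthymic = c(0, 21), temps_irritable = c(0, 21),
                 temps_anxious = c(0, 26), stai_state = c(20, 80),
                 stai_trait = c(20, 80), bdi = c(0, 39), edi_dt = c(0, 21),
                 edi_bd = c(0, 27), age = c(14, 60), bmi = c(10, 18.5))
  for (nm in names(bounds)) {
    expect_true(all(cohort[[nm]] >= bounds[[nm]][1]), label = nm)
    expect_true(all(cohort[[nm]] <= bounds[[nm]][2]), label = nm)
  }
  instruments <- setdiff(names(bounds), c("age", "bmi"))
  for (nm in instruments) {
    expect_identical(cohort[[nm]], round(cohort[[nm]]), label = nm)
  }
})

test_that("mediator residual covariance matches the configured Sigma", {
  # 200 replicates at n = 1000; entrywise Monte-Carlo check at +/- 4 SE of
  # the replicate spread, after regressing out exposure and confounders.
  cfg <- toy_config(n = 1000, med_sd = c(1, 1.2, 0.8), med_cor = 0.4)
  sigma_true <- cfg$mediator_residual_cov
  reps <- 200
  ests <- array(NA_real_, c(reps, 3, 3))
  for (r in seq_len(reps)) {
    tab <- generate_cohort(cfg, seed = 1000 + r)
    X <- cbind(1, as.matrix(tab[, c(temps5, "age", "bmi")]))
    qx <- qr(X)
    E <- qr.resid(qx, as.matrix(tab[, c("stai_trait", "stai_state", "bdi")]))
    ests[r, , ] <- crossprod(E) / (nrow(X) - ncol(X))
  }
  for (i in 1:3) for (j in 1:3) {
    m <- mean(ests[, i, j])
    se <- sd(ests[, i, j]) / sqrt(reps)
    expect_lt(abs(m - sigma_true[i, j]), 4 * se)
  }
})

test_that("recruitment accounting conserves and validates counts", {
  flow <- recruitment_filter(209, c(inclusion = 9, consent = 4,
                                    incomplete = 12))
  expect_equal(flow$enrolled, 184)
  expect_equal(sum(flow$exclusions) + flow$enrolled, flow$initial)
  expect_equal(recruitment_filter(50)$enrolled, 50)
  expect_equal(recruitment_filter(10, c(inclusion = 10))$enrolled, 0)
  expect_error(recruitment_filter(10, c(inclusion = -1)), "non-negative")
  expect_error(recruitment_filter(10, c(inclusion = 11)), "exceed")

  # per-candidate flag form, with mutual exclusivity enforced
  flags <- data.frame(fails_inclusion = c(TRUE, FALSE, FALSE, FALSE),
                      invalid_consent = c(FALSE, TRUE, FALSE, FALSE),
                      incomplete_assessment = rep(FALSE, 4))
  flow2 <- recruitment_filter(flags = flags)
  expect_equal(flow2$enrolled, 2)
  flags$invalid_consent[1] <- TRUE
  expect_error(recruitment_filter(flags = flags), "mutually exclusive")
})

test_that("cohort summaries follow the one-decimal percentage convention", {
  cohort <- data.frame(
    score = 1:6,
    constant = rep(7, 6),
    subtype = c(rep("R-AN", 4), rep("BP-AN", 2))
  )
  smry <- summarize_cohort(cohort)
  num <- smry$numeric
  expect_equal(num$mean[num$variable == "score"], 3.5)
  expect_equal(num$sd[num$variable == "score"], sd_two_pass(1:6))
  expect_equal(num$sd[num$variable == "constant"], 0)

  big <- data.frame(subtype = c(rep("R-AN", 129), rep("BP-AN", 55)))
  pct <- summarize_cohort(big)$categorical$subtype
  expect_equal(pct$percent[pct$level == "R-AN"], 70.1)
  expect_equal(pct$percent[pct$level == "BP-AN"], 29.9)
  expect_lt(abs(sum(pct$percent) - 100), 0.1 + 1e-9)

  expect_error(summarize_cohort(data.frame()), "empty")
})
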