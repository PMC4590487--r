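# LMM engine ---------------------------------------------------------------

test_that("with no between-group variance the LMM collapses to OLS", {
  set.seed(81)
  d <- data.frame(g = rep(letters[1:10], each = 4),
                  x = rnorm(40))
  d$y <- 1 + 2 * d$x + rnorm(40)   # no group effect in truth
  fit <- suppressWarnings(fit_lmm(d, "y", "x", "g"))
  ols <- lm(y ~ x, d)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-4)
})

test_that("balanced two-condition within-pair design reproduces the paired t-test", {
  set.seed(82)
  n <- 18
  d <- data.frame(pair = rep(sprintf("p%02d", 1:n), each = 2),
                  cond = rep(c("A", "B"), n))
  pair_eff <- rep(rnorm(n, 0, 2), each = 2)
  d$y <- 5 + 1.5 * (d$cond == "B") + pair_eff + rnorm(2 * n, 0, 1)
  fit <- fit_lmm(d, "y", "cond", "pair")
  tt <- t.test(d$y[d$cond == "B"] - d$y[d$cond == "A"])
  row <- fit$coefficients[fit$coefficients$term == "condB", ]
  expect_equal(row$statistic, unname(tt$statistic), tolerance = 1e-6)
  expect_equal(row$p, tt$p.value, tolerance = 1e-6)
  expect_equal(row$estimate, unname(tt$estimate), tolerance = 1e-9)
})

test_that("LMM confidence intervals cover simulated truth at ~95%", {
  set.seed(83)
  n_pairs <- 60
  cover <- vapply(1:200, function(r) {
    d <- data.frame(pair = rep(seq_len(n_pairs), each = 2),
                    cond = rep(c("A", "B"), n_pairs))
    d$y <- 2 + 0.8 * (d$cond == "B") + rep(rnorm(n_pairs, 0, 1), each = 2) +
      rnorm(2 * n_pairs, 0, 0.7)
    fit <- fit_lmm(d, "y", "cond", "pair")
    row <- fit$coefficients[fit$coefficients$term == "condB", ]
    crit <- qt(0.975, row$df)
    (row$estimate - crit * row$se) <= 0.8 &&
      (row$estimate + crit * row$se) >= 0.8
  }, logical(1))
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("the ML log-likelihood sits at a local optimum", {
  set.seed(84)
  n <- 40
  d <- data.frame(pair = rep(seq_len(n), each = 2),
                  cond = rep(c("A", "B"), n))
  d$y <- 1 + 0.5 * (d$cond == "B") + rep(rnorm(n, 0, 1), each = 2) +
    rnorm(2 * n, 0, 0.8)
  fit <- fit_lmm(d, "y", "cond", "pair", method = "ML")
  # independent marginal Gaussian log-likelihood of the random-intercept model
  loglik <- function(beta, sg, sr) {
    X <- model.matrix(~ cond, d)
    mu <- as.numeric(X %*% beta)
    ll <- 0
    for (p in unique(d$pair)) {
      i <- d$pair == p
      V <- diag(sr^2, sum(i)) + sg^2
      ll <- ll + mvtnorm_dmvnorm(d$y[i] - mu[i], V)
    }
    ll
  }
  beta_hat <- fit$coefficients$estimate
  ll_hat <- loglik(beta_hat, fit$random_effect_sd, fit$residual_sd)
  expect_equal(ll_hat, as.numeric(logLik(fit$model)), tolerance = 1e-6)
  for (k in 1:50) {
    pert <- loglik(beta_hat + rnorm(2, 0, 0.05),
                   fit$random_effect_sd * exp(rnorm(1, 0, 0.05)),
                   fit$residual_sd * exp(rnorm(1, 0, 0.05)))
    expect_lte(pert, ll_hat + 1e-8)
  }
})

test_that("singular fixed-effect designs are reported", {
  d <- data.frame(g = rep(1:5, each = 2), x = rnorm(10))
  d$x2 <- d$x
  d$y <- rnorm(10)
  expect_error(fit_lmm(d, "y", c("x", "x2"), "g"), "singular|aliased")
})

# Logistic engine -----------------------------------------------------------

test_that("two-arm logistic fit equals the closed-form 2x2 log odds ratio", {
  d <- data.frame(arm = rep(c("a", "b"), times = c(30, 25)),
                  y = c(rep(c(1, 0), c(9, 21)), rep(c(1, 0), c(16, 9))))
  fit <- fit_logistic(d, "y", "arm")
  lor <- log((16 / 9) / (9 / 21))
  row <- fit$coefficients[fit$coefficients$term == "armb", ]
  expect_equal(row$estimate, lor, tolerance = 1e-6)
  # Wald z matches the delta-method standard error of a 2x2 table
  se <- sqrt(1 / 9 + 1 / 21 + 1 / 16 + 1 / 9)
  expect_equal(row$se, se, tolerance = 1e-4)
  expect_equal(row$statistic, row$estimate / row$se, tolerance = 1e-9)
})

test_that("degenerate and separated responses are flagged", {
  d <- data.frame(y = rep(1, 10), x = rnorm(10))
  expect_warning(fit_logistic(d, "y", "x"), "constant")
  d2 <- data.frame(x = c(1:5, 11:15), y = rep(c(0, 1), each = 5))
  expect_warning(fit_logistic(d2, "y", "x"), "separation")
})

# Backward elimination -------------------------------------------------------

test_that("a fully significant model is returned unchanged", {
  set.seed(85)
  d <- data.frame(g = rep(1:30, each = 2), x = rnorm(60), z = rnorm(60))
  d$y <- 1 + 2 * d$x + 1.5 * d$z + rep(rnorm(30, 0, 0.5), each = 2) + rnorm(60, 0, 0.5)
  el <- backward_eliminate(lmm_fitter("y", "g"), d, c("x", "z"))
  expect_equal(nrow(el$trace), 0)
  expect_setequal(el$final$fixed_terms, c("x", "z"))
})

test_that("pure-noise covariates are eliminated at close to the nominal rate", {
  set.seed(86)
  dropped <- vapply(1:100, function(r) {
    d <- data.frame(g = rep(1:20, each = 2), x = rnorm(40), noise = rnorm(40))
    d$y <- 1 + 2 * d$x + rep(rnorm(20, 0, 1), each = 2) + rnorm(40, 0, 1)
    el <- backward_eliminate(lmm_fitter("y", "g"), d, c("x", "noise"),
                             protected = "x")
    !"noise" %in% el$final$fixed_terms
  }, logical(1))
  expect_gte(mean(dropped), 0.90)
})

test_that("trials generated with only model-type effects converge on that model", {
  all_dropped <- vapply(1:30, function(r) {
    es <- experiment_spec(seed = 870 + r)
    trials <- generate_aggression_trials(es)
    trials$model_type <- factor(trials$model_type)
    trials$model_replicate <- factor(trials$model_replicate)
    trials$nest_stage <- factor(trials$nest_stage)
    el <- backward_eliminate(
      lmm_fitter("mobbing_seconds", "pair_id"), trials,
      c("model_type", "presentation_order", "model_replicate", "nest_stage"),
      protected = "model_type")
    expect_true("model_type" %in% el$final$fixed_terms)
    identical(el$final$fixed_terms, "model_type")
  }, logical(1))
  # three null nuisance terms, each retained ~5% of the time, so all three
  # drop in ~86% of replicates
  expect_gte(mean(all_dropped), 0.7)
})

# Reference rotation ----------------------------------------------------------

test_that("rotation yields all pairwise contrasts, antisymmetric and additive", {
  es <- experiment_spec(seed = 88)
  trials <- generate_aggression_trials(es)
  fitter <- lmm_fitter("mobbing_seconds", "pair_id")
  ctr <- rotate_reference(fitter, trials, "model_type", "model_type")
  expect_equal(nrow(ctr), 6)  # 4 levels -> 6 unique pairs

  # additivity: c(A,C) = c(A,B) + c(B,C)
  est <- function(a, b) {
    r <- ctr[ctr$level_a == a & ctr$level_b == b, ]
    if (nrow(r)) r$estimate else -ctr[ctr$level_a == b & ctr$level_b == a, ]$estimate
  }
  lv <- sort(unique(trials$model_type))
  expect_equal(est(lv[1], lv[3]), est(lv[1], lv[2]) + est(lv[2], lv[3]),
               tolerance = 1e-8)

  # two-level case: single contrast, same magnitude from either reference
  d2 <- trials[trials$model_type %in% lv[1:2], ]
  ctr2 <- rotate_reference(fitter, d2, "model_type", "model_type")
  expect_equal(nrow(ctr2), 1)
  d2r <- d2
  d2r$model_type <- factor(d2r$model_type, levels = rev(lv[1:2]))
  ctr2r <- rotate_reference(fitter, d2r, "model_type", "model_type")
  expect_equal(abs(ctr2$estimate), abs(ctr2r$estimate), tolerance = 1e-8)
  expect_equal(ctr2$p, ctr2r$p, tolerance = 1e-8)
})

test_that("reference rotation leaves fitted values unchanged", {
  es <- experiment_spec(seed = 89)
  trials <- generate_aggression_trials(es)
  fitter <- lmm_fitter("alarm_calls", "pair_id")
  lv <- sort(unique(trials$model_type))
  fits <- lapply(lv, function(ref) {
    dd <- trials
    dd$model_type <- relevel(factor(dd$model_type, levels = lv), ref = ref)
    fitted(fitter(dd, "model_type")$model)
  })
  for (k in 2:4)
    expect_equal(unname(fits[[1]]), unname(fits[[k]]), tolerance = 1e-9)
})

# run_study_models -----------------------------------------------------------

test_that("all-zero aggression data give null contrasts", {
  es <- experiment_spec(seed = 90)
  trials <- generate_aggression_trials(es)
  trials$alarm_calls <- 0
  trials$mobbing_seconds <- 0
  res <- suppressWarnings(run_study_models(trial_table = trials))
  ctr <- res$aggression$mobbing$contrasts
  expect_equal(ctr$estimate, rep(0, 6), tolerance = 1e-9)
})

test_that("rejection analysis retains model type and the colour effect", {
  es <- experiment_spec(arms = c(female_cuckoo_finch = 120, female_bishop = 120,
                                 male_bishop = 120),
                        arm_rejection_probs = c(female_cuckoo_finch = 0.582,
                                                female_bishop = 0.625,
                                                male_bishop = 0.389),
                        seed = 91)
  eg <- generate_egg_experiment(es, full_artifacts = FALSE)
  rt <- eg$rejection_table
  rt$pattern_diff <- rnorm(nrow(rt))   # pure-noise artifact covariates
  rt$shape_diff <- rnorm(nrow(rt))
  rt$volume_diff <- rnorm(nrow(rt))
  res <- run_study_models(rejection_table = rt)
  expect_true("model_type" %in% res$rejection$final$fixed_terms)
  expect_true("colour_jnd" %in% res$rejection$final$fixed_terms)
})
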