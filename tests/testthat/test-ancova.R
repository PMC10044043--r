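test_that("least-squares fit reproduces exact and null signals", {
  rec <- toy_ancova_records()
  spec <- model_spec("y", factors = c("a", "b"), interactions = list(),
                     covariates = c(x = 1))
  fit <- fit_linear_model(rec, spec)
  g <- goodness_of_fit(fit)
  expect_true(g$r_squared > 0 && g$r_squared <= 1)
  expect_lte(g$adj_r_squared, g$r_squared)

  # exact signal: y = Xb with no noise -> RSS 0, R2 1
  rec2 <- rec
  rec2$y <- 1 + 2 * (rec2$a == "a2") + 0.5 * rec2$x
  fit2 <- fit_linear_model(rec2, spec)
  expect_lt(fit2$rss, 1e-20)
  g2 <- goodness_of_fit(fit2)
  expect_equal(g2$r_squared, 1)
  expect_equal(g2$mse, 0)

  # intercept-only model -> R2 = 0
  spec0 <- model_spec("y", factors = character(0), interactions = list(),
                      covariates = NULL)
  fit0 <- fit_linear_model(rec, spec0)
  expect_equal(goodness_of_fit(fit0)$r_squared, 0)

  expect_error(fit_linear_model(rec[1:2, ], spec), "must exceed")
})

test_that("coefficient recovery on simulated records is within sampling error", {
  set.seed(8)
  n <- 2000
  farms <- paste0("f", 1:10)
  f_eff <- stats::setNames(rnorm(10, 0, 0.6), farms)
  rec <- data.frame(farm = sample(farms, n, replace = TRUE),
                    x = rnorm(n))
  rec$y <- 4 + f_eff[rec$farm] + 0.3 * rec$x + rnorm(n, 0, 0.5)
  spec <- model_spec("y", factors = "farm", interactions = list(),
                     covariates = c(x = 1))
  fit <- fit_linear_model(rec, spec)
  # sum-to-zero coding: coefficient k is f_k - mean(f)
  vc <- solve(crossprod(fit$X)) * fit$rss / fit$df_residual
  se <- sqrt(diag(vc))
  lv <- levels(factor(rec$farm))   # alphabetical, f10 second
  truth <- c(4 + mean(f_eff),
             unname(f_eff[lv[1:9]] - mean(f_eff)), 0.3)
  z <- (unname(fit$coefficients) - truth) / se
  expect_lt(max(abs(z)), 4)
  expect_lt(mean(abs(z) > 2), 0.3)
})

test_that("Type III equals sequential SS in balanced designs and the refit oracle generally", {
  set.seed(10)
  bal <- data.frame(g = rep(c("g1", "g2", "g3"), each = 20))
  bal$y <- rnorm(60) + (bal$g == "g2") * 0.7
  spec <- model_spec("y", factors = "g", interactions = list(),
                     covariates = NULL)
  fit <- fit_linear_model(bal, spec)
  t3 <- type_iii_table(fit)
  a1 <- stats::anova(stats::lm(y ~ g, bal))
  expect_equal(t3$sum_sq[t3$term == "g"], a1["g", "Sum Sq"],
               tolerance = 1e-10)
  expect_equal(t3$df[t3$term == "g"], a1["g", "Df"])

  # unbalanced two-factor + covariate: agree with car::Anova type III
  skip_if_not_installed("car")
  rec <- toy_ancova_records()
  spec2 <- model_spec("y", factors = c("a", "b"), interactions = list(),
                      covariates = c(x = 1))
  fit2 <- fit_linear_model(rec, spec2)
  t32 <- type_iii_table(fit2)
  lm2 <- stats::lm(y ~ a + b + x, data = rec,
                   contrasts = list(a = "contr.sum", b = "contr.sum"))
  ref <- car::Anova(lm2, type = 3)
  for (tm in c("a", "b", "x")) {
    expect_equal(t32$sum_sq[t32$term == tm], ref[tm, "Sum Sq"],
                 tolerance = 1e-8, info = tm)
    expect_equal(t32$p_value[t32$term == tm], ref[tm, "Pr(>F)"],
                 tolerance = 1e-8, info = tm)
  }
})

test_that("null-term Type III p-values are approximately uniform", {
  set.seed(11)
  n_sim <- 300
  pv <- vapply(seq_len(n_sim), function(i) {
    df <- data.frame(g = sample(c("u", "v", "w"), 40, replace = TRUE),
                     x = rnorm(40))
    df$y <- 0.5 * df$x + rnorm(40)   # g has zero true effect
    fit <- fit_linear_model(df, model_spec("y", factors = "g",
                                           interactions = list(),
                                           covariates = c(x = 1)))
    t3 <- type_iii_table(fit)
    t3$p_value[t3$term == "g"]
  }, 0)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.035)
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("goodness-of-fit panel behaves at the limits", {
  rec <- toy_ancova_records()
  spec <- model_spec("y", factors = c("a", "b"), interactions = list(),
                     covariates = c(x = 1))
  fit <- fit_linear_model(rec, spec)
  g <- goodness_of_fit(fit)
  expect_true(g$durbin_watson >= 0 && g$durbin_watson <= 4)
  expect_equal(g$rmse, sqrt(g$mse))
  # iid residuals -> DW near 2 (big sample)
  set.seed(12)
  big <- data.frame(x = rnorm(4000))
  big$y <- big$x + rnorm(4000)
  fitb <- fit_linear_model(big, model_spec("y", factors = character(0),
                                           interactions = list(),
                                           covariates = c(x = 1)))
  expect_lt(abs(goodness_of_fit(fitb)$durbin_watson - 2), 0.15)
  # perfectly positively autocorrelated residual ordering -> DW ~ 0
  ord <- order(fitb$residuals)
  expect_lt(goodness_of_fit(fitb, order = ord)$durbin_watson, 0.05)
  # PRESS/pred-R2 matches the closed-form leave-one-out identity on a
  # small case computed by brute force
  small <- toy_ancova_records(n_per_cell = c(3, 3, 3, 3, 3, 3), seed = 5)
  fits <- fit_linear_model(small, spec)
  gs <- goodness_of_fit(fits)
  loo <- vapply(seq_len(nrow(small)), function(i) {
    m <- stats::lm(y ~ a + b + x, data = small[-i, ])
    small$y[i] - unname(stats::predict(m, small[i, ]))
  }, 0)
  expect_equal(gs$press, sum(loo^2), tolerance = 1e-8)
})

test_that("predicted R2 never improves on average when pure noise is added", {
  set.seed(13)
  diffs <- replicate(200, {
    df <- data.frame(x = rnorm(60))
    df$y <- df$x + rnorm(60)
    df$junk <- rnorm(60)
    base <- goodness_of_fit(fit_linear_model(
      df, model_spec("y", factors = character(0), interactions = list(),
                     covariates = c(x = 1))))$pred_r_squared
    noisy <- goodness_of_fit(fit_linear_model(
      df, model_spec("y", factors = character(0), interactions = list(),
                     covariates = c(x = 1, junk = 1))))$pred_r_squared
    noisy - base
  })
  expect_lt(mean(diffs), 0)
})

test_that("studentized-residual flags follow the 5% rule and are scale invariant", {
  set.seed(14)
  n <- 10000
  df <- data.frame(x = rnorm(n))
  df$y <- df$x + rnorm(n)
  spec <- model_spec("y", factors = character(0), interactions = list(),
                     covariates = c(x = 1))
  fl <- flag_residuals(fit_linear_model(df, spec))
  expect_lt(abs(fl$outlier_fraction - 5), 1)
  expect_true(fl$pass)
  # affine rescaling of the response leaves the flags unchanged
  df2 <- df
  df2$y <- 100 * df$y - 7
  fl2 <- flag_residuals(fit_linear_model(df2, spec))
  expect_identical(fl$flags, fl2$flags)
  # heavy-tailed (double-exponential) errors exceed the 5% rule; note
  # that internal studentization scales by the inflated overall SD, so
  # the exceedance probability is the distribution's own
  # P(|e| > 1.96 sd), about 6.3% for the Laplace
  df3 <- df
  df3$y <- df$x + rexp(n) * sample(c(-1, 1), n, replace = TRUE)
  fl3 <- flag_residuals(fit_linear_model(df3, spec))
  expect_gt(fl3$outlier_fraction, 5)
  expect_false(fl3$pass)
})

test_that("run_ancova produces the published table shapes", {
  herd <- recovery_herd(0.3, seed = 15, n_founders = 60,
                        offspring_per_generation = 200,
                        n_generations = 2)
  res <- run_ancova(herd$records, "y",
                    spec_for = function(tr) recovery_spec(tr))
  expect_equal(res$model_table$trait, "y")
  expect_true(all(c("df", "statistic", "p_value", "rss", "rms") %in%
                    names(res$model_table)))
  expect_true(all(c("pred_r_squared", "adj_r_squared", "mse", "rmse",
                    "durbin_watson") %in% names(res$fit_table)))
  expect_true(res$fit_table$pred_r_squared <= res$fit_table$adj_r_squared +
                0.05)
})
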