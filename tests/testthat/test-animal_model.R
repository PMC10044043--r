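test_that("build_design wires records to the pedigree correctly", {
  herd <- recovery_herd(0.3, seed = 20, n_founders = 20,
                        offspring_per_generation = 30, n_generations = 1)
  d <- build_design(herd$records, recovery_spec(), herd$pedigree)
  expect_equal(nrow(d$Z), nrow(herd$records))
  expect_equal(ncol(d$Z), nrow(herd$pedigree))
  expect_true(all(Matrix::rowSums(d$Z) == 1))
  expect_equal(qr(d$X)$rank, ncol(d$X))

  bad <- herd$records
  bad$animal[1] <- "ghost"
  expect_error(build_design(bad, recovery_spec(), herd$pedigree), "ghost")

  # covariates are centered: age column has mean ~0 and finite conditioning
  spec_cov <- model_spec("y", factors = "farm", interactions = list(),
                         covariates = c(age = 2))
  d2 <- build_design(herd$records, spec_cov, herd$pedigree)
  expect_lt(abs(mean(d2$X[, "age"])), 1e-10)
  expect_true(is.finite(kappa(crossprod(d2$X))))
})

test_that("starting values split phenotypic (co)variance 20/80", {
  sv <- starting_values(1.15511)
  expect_equal(as.numeric(sv$G0), 0.231022)
  expect_equal(as.numeric(sv$E0), 0.924088)
  sv2 <- starting_values(c(1, 1))
  expect_equal(sv2$G0, 0.2 * diag(2))
  # rho = 1 pair: singular implied P, bending warning
  expect_warning(starting_values(c(1, 1), matrix(c(1, 1, 1, 1), 2, 2)),
                 "bent")
})

test_that("EM-REML iterations never decrease the restricted likelihood", {
  herd <- recovery_herd(0.3, seed = 21, n_founders = 60,
                        offspring_per_generation = 120, n_generations = 2)
  d <- build_design(herd$records, recovery_spec(), herd$pedigree)
  fit <- reml_univariate(d$y, d$X, d$Z, d$Ainv, max_iter = 40,
                         compute_se = FALSE)
  tr <- fit$em_trace
  expect_gt(nrow(tr), 3)
  expect_true(all(diff(tr[, "neg2logL"]) <= 1e-8))
})

test_that("REML matches the paternal half-sib ANOVA estimator on a balanced design", {
  set.seed(22)
  n_sires <- 80
  n_dau <- 15
  h2_true <- 0.3
  sires <- paste0("S", seq_len(n_sires))
  dams <- paste0("D", seq_len(n_sires * n_dau))
  kids <- paste0("K", seq_len(n_sires * n_dau))
  ped <- pedigree(id = c(sires, dams, kids),
                  sire = c(rep(NA, length(sires) + length(dams)),
                           rep(sires, each = n_dau)),
                  dam = c(rep(NA, length(sires) + length(dams)), dams))
  s_eff <- rnorm(n_sires, 0, sqrt(h2_true / 4))
  y <- rep(s_eff, each = n_dau) +
    rnorm(n_sires * n_dau, 0, sqrt(1 - h2_true / 4))
  rec <- data.frame(animal = kids, y = y,
                    sire = rep(sires, each = n_dau))

  # half-sib ANOVA oracle: h2 = 4 sigma2_s / (sigma2_s + sigma2_w)
  av <- stats::anova(stats::lm(y ~ sire, rec))
  ms_s <- av["sire", "Mean Sq"]
  ms_w <- av["Residuals", "Mean Sq"]
  s2_s <- (ms_s - ms_w) / n_dau
  h2_anova <- 4 * s2_s / (s2_s + ms_w)

  spec <- model_spec("y", factors = character(0), interactions = list(),
                     covariates = NULL)
  d <- build_design(rec, spec, ped)
  fit <- reml_univariate(d$y, d$X, d$Z, d$Ainv, em_limit = 0,
                         compute_se = FALSE)
  expect_lt(abs(fit$h2 - h2_anova), 0.05)
  # the design's own sampling error on h2 is ~0.1; loose truth check only
  expect_lt(abs(fit$h2 - h2_true), 0.2)
})

test_that("null heritability lands on the boundary with a flag", {
  herd <- recovery_herd(1e-6, seed = 23, n_founders = 100,
                        offspring_per_generation = 200, n_generations = 2)
  d <- build_design(herd$records, recovery_spec(), herd$pedigree)
  fit <- reml_univariate(d$y, d$X, d$Z, d$Ainv, em_limit = 0,
                         compute_se = FALSE)
  expect_lt(fit$h2, 0.05)
})

test_that("information-matrix SEs are on the scale of the sampling spread", {
  h2_hat <- numeric(6)
  se_hat <- numeric(6)
  for (i in seq_along(h2_hat)) {
    herd <- recovery_herd(0.3, seed = 400 + i, n_founders = 150,
                          offspring_per_generation = 250,
                          n_generations = 2)
    d <- build_design(herd$records, recovery_spec(), herd$pedigree)
    fit <- reml_univariate(d$y, d$X, d$Z, d$Ainv, em_limit = 0)
    h2_hat[i] <- fit$h2
    se_hat[i] <- fit$se[["h2"]]
  }
  emp <- stats::sd(h2_hat)
  expect_gt(mean(se_hat), emp / 3)
  expect_lt(mean(se_hat), emp * 3)
})

test_that("bivariate REML recovers degenerate genetic correlations", {
  # sigma_a12 = 0 -> r_g near 0
  herd0 <- recovery_herd2(0.35, 0.35, r_g = 0, r_e = 0.2, seed = 24)
  d <- build_design(herd0$records, recovery_spec("y1"), herd0$pedigree)
  Y <- as.matrix(herd0$records[, c("y1", "y2")])
  f0 <- reml_bivariate(Y, d$X, d$Z, d$Ainv, tol = 1e-10, max_eval = 800)
  expect_lt(abs(f0$r_g), 0.3)

  # perfect pleiotropy (rank-1 G) -> r_g near 1
  herd1 <- recovery_herd2(0.4, 0.4, r_g = 1, r_e = 0.1, seed = 25)
  d1 <- build_design(herd1$records, recovery_spec("y1"), herd1$pedigree)
  Y1 <- as.matrix(herd1$records[, c("y1", "y2")])
  f1 <- reml_bivariate(Y1, d1$X, d1$Z, d1$Ainv, tol = 1e-10,
                       max_eval = 800)
  expect_gt(f1$r_g, 0.8)
})

test_that("MME solutions match the dense GLS oracle and shrink correctly", {
  herd <- recovery_herd(0.4, seed = 26, n_founders = 40,
                        offspring_per_generation = 80, n_generations = 2)
  d <- build_design(herd$records, recovery_spec(), herd$pedigree)
  s2a <- 0.4
  s2e <- 0.6
  sol <- solve_mme(d$y, d$X, d$Z, d$Ainv, s2a, s2e, reliabilities = TRUE,
                   f = inbreeding(herd$pedigree))

  # dense GLS oracle: V = s2a Z A Z' + s2e I
  A <- relationship_matrix(herd$pedigree)
  Zd <- as.matrix(d$Z)
  V <- s2a * Zd %*% A %*% t(Zd) + s2e * diag(nrow(Zd))
  Vi <- solve(V)
  Xd <- d$X
  b_gls <- solve(t(Xd) %*% Vi %*% Xd, t(Xd) %*% Vi %*% d$y)
  u_gls <- s2a * A %*% t(Zd) %*% Vi %*% (d$y - Xd %*% b_gls)
  expect_lt(max(abs(sol$blue - b_gls)), 1e-8)
  expect_lt(max(abs(sol$blup - u_gls)), 1e-8)
  expect_true(all(sol$reliability >= 0 & sol$reliability <= 1))

  # animals with no record and no scored relatives predict to 0
  lone <- pedigree(id = c(herd$pedigree$id, "L1"),
                   sire = c(herd$pedigree$sire, NA),
                   dam = c(herd$pedigree$dam, NA))
  d2 <- build_design(herd$records, recovery_spec(), lone)
  sol2 <- solve_mme(d2$y, d2$X, d2$Z, d2$Ainv, s2a, s2e)
  expect_equal(unname(sol2$blup[["L1"]]), 0)

  # lambda -> infinity shrinks every breeding value to 0
  sol_inf <- solve_mme(d$y, d$X, d$Z, d$Ainv, 1e-10, 1)
  expect_lt(max(abs(sol_inf$blup)), 1e-6)
})

test_that("noise-free fixed-effect data reproduce BLUEs exactly", {
  set.seed(27)
  ped <- random_pedigree(10, 20, seed = 28)
  rec <- data.frame(animal = ped$id[11:30],
                    farm = rep(c("f1", "f2"), 10))
  rec$y <- 3 + (rec$farm == "f2") * 1.5
  spec <- model_spec("y", factors = "farm", interactions = list(),
                     covariates = NULL)
  d <- build_design(rec, spec, ped)
  sol <- solve_mme(d$y, d$X, d$Z, d$Ainv, 1e-8, 1)
  expect_equal(unname(sol$blue[["(Intercept)"]]), 3, tolerance = 1e-4)
  expect_equal(unname(sol$blue[["farm.f2"]]), 1.5, tolerance = 1e-4)
})
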