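test_that("simulated pedigrees respect the demographic contract", {
  cfg <- sim_config("desk", n_founders = 10, offspring_per_generation = 30,
                    n_generations = 1, prop_male_founders = 0.3, seed = 1)
  ped <- simulate_pedigree(cfg)
  gen <- attr(ped, "generation")
  # one generation of random mating among unrelated founders: no inbreeding
  expect_true(all(inbreeding(ped) == 0))
  expect_equal(sum(gen == 0), 10)
  expect_equal(sum(gen == 1), 30)

  # determinism: same seed, byte-identical pedigree
  ped2 <- simulate_pedigree(cfg)
  expect_identical(as.data.frame(ped), as.data.frame(ped2))

  # repeated half-sib structure accumulates inbreeding over generations
  cfg_hs <- sim_config("desk", n_founders = 12,
                       offspring_per_generation = 40, n_generations = 3,
                       mating = "half_sib", n_sires_active = 1,
                       prop_male_founders = 0.25, seed = 2)
  ped_hs <- simulate_pedigree(cfg_hs)
  f <- inbreeding(ped_hs)
  g <- attr(ped_hs, "generation")
  mean_f <- tapply(f, g, mean)
  expect_true(all(diff(mean_f) >= 0))
  expect_gt(mean_f[["3"]], 0)

  cfg_bad <- sim_config("desk", n_founders = 5, prop_male_founders = 0,
                        seed = 3)
  cfg_bad$prop_male_founders <- 0
  expect_error(simulate_pedigree(cfg_bad), "no males")
})

test_that("breeding values follow the additive covariance model", {
  # founders draw from N(0, G)
  cfg <- sim_config("desk", n_founders = 6000,
                    offspring_per_generation = 10, n_generations = 1,
                    seed = 4)
  G <- matrix(c(1, 0.5, 0.5, 2), 2, 2,
              dimnames = list(c("u", "v"), c("u", "v")))
  ped <- simulate_pedigree(cfg)
  bv <- simulate_breeding_values(ped, G, seed = 5)
  founders <- is.na(ped$sire)
  emp <- stats::cov(bv[founders, ])
  expect_lt(max(abs(emp - G)), 0.15)

  # G = 0 -> all breeding values zero
  bv0 <- simulate_breeding_values(ped, matrix(0, 1, 1), seed = 6)
  expect_true(all(bv0 == 0))

  # Mendelian sampling: repeated offspring of one non-inbred pair have
  # variance G/2 around the parent average
  ped_fam <- pedigree(id = c("S", "D", paste0("K", 1:4000)),
                      sire = c(NA, NA, rep("S", 4000)),
                      dam = c(NA, NA, rep("D", 4000)))
  bvf <- simulate_breeding_values(ped_fam, G, seed = 7)
  kids <- bvf[-(1:2), ]
  dev <- sweep(kids, 2, (bvf["S", ] + bvf["D", ]) / 2)
  expect_lt(max(abs(stats::cov(dev) - G / 2)), 0.12)
})

test_that("records decompose into stored truth plus residual noise", {
  cfg <- sim_config("desk", n_founders = 100,
                    offspring_per_generation = 300, n_generations = 2,
                    seed = 8)
  herd <- simulate_herd(cfg)
  expect_equal(nrow(herd$records), 600)       # one record per scored animal
  expect_false(anyDuplicated(herd$records$animal) > 0)

  # stored truths reproduce each record's expected value exactly
  resid <- herd$records$trait1 - herd$truth$fixed - herd$truth$a_trait1
  expect_equal(resid, herd$truth$e_trait1, tolerance = 1e-12)

  # zero-noise, zero-effect config: records equal breeding values
  cfg0 <- sim_config("desk", n_founders = 50,
                     offspring_per_generation = 100, n_generations = 1,
                     mu = 0, farm_sd = 0, month_sd = 0, farm_year_sd = 0,
                     b_dim = 0, b_age = 0, b_age2 = 0,
                     lactation_effects = c(primipara = 0, multipara = 0),
                     E = matrix(1e-18, 1, 1,
                                dimnames = list("trait1", "trait1")),
                     seed = 9)
  herd0 <- simulate_herd(cfg0)
  expect_equal(herd0$records$trait1,
               unname(herd0$breeding_values[herd0$records$animal, 1]),
               tolerance = 1e-6)

  # phenotypic variance decomposes as sigma2_a + sigma2_e + fixed-structure
  cfgv <- sim_config("desk", n_founders = 3000,
                     offspring_per_generation = 9000, n_generations = 1,
                     farm_sd = 0.3, month_sd = 0.2, farm_year_sd = 0.25,
                     b_dim = 0, b_age = 0, b_age2 = 0,
                     lactation_effects = c(primipara = 0, multipara = 0),
                     seed = 10)
  herdv <- simulate_herd(cfgv)
  v_emp <- stats::var(herdv$records$trait1)
  v_expected <- 0.2 + 0.8 + 0.3^2 + 0.2^2 + 0.25^2
  expect_lt(abs(v_emp - v_expected) / v_expected, 0.1)
})

test_that("LAS rounding attenuates, never inflates, the usable variance", {
  # rounding to 1-9 points adds discretization noise: the correlation of
  # rounded with continuous records drops below 1 but stays high
  cfg <- sim_config("desk", n_founders = 200,
                    offspring_per_generation = 600, n_generations = 1,
                    mu = 5, seed = 11)
  herd_c <- simulate_herd(cfg)
  cfg_r <- cfg
  cfg_r$round_to_las <- TRUE
  herd_r <- simulate_herd(cfg_r)
  expect_true(all(herd_r$records$trait1 %in% 1:9))
  r <- stats::cor(herd_c$records$trait1, herd_r$records$trait1)
  expect_gt(r, 0.9)
  expect_lt(r, 1)
})

test_that("herds round-trip losslessly through the text writers", {
  herd <- simulate_herd(sim_config("desk", n_founders = 20,
                                   offspring_per_generation = 40,
                                   n_generations = 1, seed = 12))
  dir <- withr::local_tempdir()
  write_herd(herd, dir)
  back <- read_herd(dir)
  expect_equal(back$pedigree$id, herd$pedigree$id)
  expect_equal(back$records$trait1, herd$records$trait1)
  expect_equal(back$truth$a_trait1, herd$truth$a_trait1)
})

test_that("the caprigran preset carries the published 17-trait structure", {
  cfg <- sim_config("caprigran", seed = 13)
  expect_equal(cfg$n_farms, 76)
  expect_length(cfg$traits, 17)
  expect_equal(dim(cfg$G), c(17, 17))
  evG <- eigen(cfg$G, symmetric = TRUE, only.values = TRUE)$values
  evE <- eigen(cfg$E, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(evG), -1e-8)
  expect_gt(min(evE), -1e-8)
})
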