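#' Heritability recovery study
#'
#' The package's core validation loop: simulate a multi-generation herd
#' with a known single-trait heritability (unit phenotypic variance, farm
#' and kidding-month fixed effects), fit the univariate animal model by
#' REML, repeat over seeds and average. Defaults reproduce the desk-scale
#' study design: 300 founders, three generations of 400 offspring
#' (1,500 pedigree animals, 1,200 scored).
#'
#' @param h2_true simulated heritability.
#' @param n_rep number of replicates (>= 10 for the headline checks).
#' @param seed base seed; replicate r uses `seed * 1000 + r`.
#' @param n_founders,offspring_per_generation,n_generations pedigree shape.
#' @return list: `mean_h2`, `estimates`, `n_records`, `n_animals`.
#' @export
recover_h2 <- function(h2_true, n_rep = 10, seed = 1, n_founders = 300,
                       offspring_per_generation = 400, n_generations = 3) {
  est <- numeric(n_rep)
  n_rec <- n_ani <- NA_integer_
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(
      "desk", n_founders = n_founders,
      offspring_per_generation = offspring_per_generation,
      n_generations = n_generations,
      G = matrix(h2_true, 1, 1, dimnames = list("y", "y")),
      E = matrix(1 - h2_true, 1, 1, dimnames = list("y", "y")),
      traits = "y", farm_sd = 0.3, farm_year_sd = 0,
      b_dim = 0, b_age = 0, b_age2 = 0,
      lactation_effects = c(primipara = 0),
      seed = seed * 1000 + r)
    herd <- simulate_herd(cfg)
    spec <- model_spec("y", factors = c("farm", "kidding_month"),
                       interactions = list(), covariates = NULL)
    d <- build_design(herd$records, spec, herd$pedigree)
    fit <- reml_univariate(d$y, d$X, d$Z, d$Ainv, em_limit = 0,
                           compute_se = FALSE)
    est[r] <- fit$h2
    n_rec <- nrow(herd$records)
    n_ani <- nrow(herd$pedigree)
  }
  list(mean_h2 = mean(est), estimates = est, n_records = n_rec,
       n_animals = n_ani)
}

#' Simulation truth for a published trait pair
#'
#' Builds the 2x2 G and E of a trait pair on the unit-phenotypic-variance
#' scale from the published heritabilities and genetic/phenotypic
#' correlations: `g12 = r_g sqrt(h1 h2)`, `e12 = r_p - g12`, so the
#' implied phenotypic correlation equals the published `r_p`.
#'
#' @param trait1,trait2 trait names from [reference_components()].
#' @param r_g,r_p optional overrides of the published correlations.
#' @return list with `G`, `E`, `h2` (length 2), `r_g`, `r_p`, `r_e`.
#' @export
pair_truth <- function(trait1, trait2, r_g = NULL, r_p = NULL) {
  comp <- reference_components()
  corr <- reference_correlations()
  h1 <- comp$h2[comp$trait == trait1]
  h2 <- comp$h2[comp$trait == trait2]
  if (!length(h1) || !length(h2)) stop("unknown trait")
  if (is.null(r_g)) r_g <- corr$r_g[trait1, trait2]
  if (is.null(r_p)) r_p <- corr$r_p[trait1, trait2]
  g12 <- r_g * sqrt(h1 * h2)
  e12 <- r_p - g12
  G <- matrix(c(h1, g12, g12, h2), 2, 2,
              dimnames = list(c(trait1, trait2), c(trait1, trait2)))
  E <- matrix(c(1 - h1, e12, e12, 1 - h2), 2, 2, dimnames = dimnames(G))
  stopifnot(min(eigen(G, only.values = TRUE)$values) > 0,
            min(eigen(E, only.values = TRUE)$values) > 0)
  list(G = G, E = E, h2 = c(h1, h2), r_g = r_g, r_p = r_p,
       r_e = e12 / sqrt((1 - h1) * (1 - h2)))
}

#' Genetic/phenotypic correlation recovery study
#'
#' Bivariate analogue of [recover_h2()]: simulate the pair under a
#' [pair_truth()] (or explicit G/E), fit bivariate REML per replicate and
#' average the estimated genetic and phenotypic correlations.
#'
#' @param truth a [pair_truth()]-shaped list with `G` and `E`.
#' @param n_rep,seed as in [recover_h2()].
#' @param n_founders,offspring_per_generation pedigree shape; the default
#'   (2,600 animals, 2,100 records) is larger than the univariate study
#'   because correlation estimates at moderate heritability are the
#'   noisiest quantities in the pipeline.
#' @param tol REML convergence criterion.
#' @return list: `mean_r_g`, `mean_r_p`, `r_g`, `r_p` (per replicate),
#'   `n_records`, `n_animals`.
#' @export
recover_pair <- function(truth, n_rep = 10, seed = 1, n_founders = 500,
                         offspring_per_generation = 700, tol = 1e-12) {
  rg <- rp <- numeric(n_rep)
  n_rec <- n_ani <- NA_integer_
  traits <- rownames(truth$G)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(
      "desk", n_founders = n_founders,
      offspring_per_generation = offspring_per_generation,
      n_generations = 3, G = truth$G, E = truth$E, traits = traits,
      farm_sd = 0.3, farm_year_sd = 0, b_dim = 0, b_age = 0, b_age2 = 0,
      lactation_effects = c(primipara = 0), seed = seed * 1000 + r)
    herd <- simulate_herd(cfg)
    spec <- model_spec(traits[1], factors = c("farm", "kidding_month"),
                       interactions = list(), covariates = NULL)
    d <- build_design(herd$records, spec, herd$pedigree)
    fit <- reml_bivariate(as.matrix(herd$records[, traits]),
                          d$X, d$Z, d$Ainv, tol = tol)
    rg[r] <- fit$r_g
    rp[r] <- fit$r_p
    n_rec <- nrow(herd$records)
    n_ani <- nrow(herd$pedigree)
  }
  list(mean_r_g = mean(rg), mean_r_p = mean(rp), r_g = rg, r_p = rp,
       n_records = n_rec, n_animals = n_ani)
}
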