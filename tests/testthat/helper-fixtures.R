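# Shared fixtures, built in code.

# Pedigree with a full-sib mating: X = (C x D), C and D full sibs of A x B.
trio_fullsib_pedigree <- function() {
  pedigree(id = c("A", "B", "C", "D", "X"),
           sire = c(NA, NA, "A", "A", "C"),
           dam = c(NA, NA, "B", "B", "D"))
}

# Half-sib mating: S mated to two unrelated dams, offspring mated together.
halfsib_offspring_pedigree <- function() {
  pedigree(id = c("S", "D1", "D2", "H1", "H2", "X"),
           sire = c(NA, NA, NA, "S", "S", "H1"),
           dam = c(NA, NA, NA, "D1", "D2", "H2"))
}

random_pedigree <- function(n_founders = 20, n_offspring = 80, seed = 1) {
  cfg <- sim_config("desk", n_founders = n_founders,
                    offspring_per_generation = n_offspring,
                    n_generations = 2, prop_male_founders = 0.3,
                    seed = seed)
  simulate_pedigree(cfg)
}

# Single-trait herd with only farm + month fixed effects and unit
# phenotypic variance; the workhorse of the recovery tests.
recovery_herd <- function(h2, seed, n_founders = 300,
                          offspring_per_generation = 400,
                          n_generations = 3) {
  cfg <- sim_config(
    "desk", n_founders = n_founders,
    offspring_per_generation = offspring_per_generation,
    n_generations = n_generations,
    G = matrix(h2, 1, 1, dimnames = list("y", "y")),
    E = matrix(1 - h2, 1, 1, dimnames = list("y", "y")),
    traits = "y", farm_sd = 0.3, farm_year_sd = 0,
    b_dim = 0, b_age = 0, b_age2 = 0,
    lactation_effects = c(primipara = 0), seed = seed)
  simulate_herd(cfg)
}

recovery_spec <- function(trait = "y") {
  model_spec(trait, factors = c("farm", "kidding_month"),
             interactions = list(), covariates = NULL)
}

# Two-trait herd with configurable genetic/residual correlations; unit
# phenotypic variances.
recovery_herd2 <- function(h2_1, h2_2, r_g, r_e, seed, n_founders = 300,
                           offspring_per_generation = 400) {
  g12 <- r_g * sqrt(h2_1 * h2_2)
  e12 <- r_e * sqrt((1 - h2_1) * (1 - h2_2))
  G <- matrix(c(h2_1, g12, g12, h2_2), 2, 2,
              dimnames = list(c("y1", "y2"), c("y1", "y2")))
  E <- matrix(c(1 - h2_1, e12, e12, 1 - h2_2), 2, 2,
              dimnames = dimnames(G))
  cfg <- sim_config(
    "desk", n_founders = n_founders,
    offspring_per_generation = offspring_per_generation,
    n_generations = 3, G = G, E = E, traits = c("y1", "y2"),
    farm_sd = 0.3, farm_year_sd = 0, b_dim = 0, b_age = 0, b_age2 = 0,
    lactation_effects = c(primipara = 0), seed = seed)
  simulate_herd(cfg)
}

# Balanced unbalanced-cell toy records for the ANCOVA layer.
toy_ancova_records <- function(n_per_cell = c(4, 7, 3, 9, 5, 6), seed = 3) {
  set.seed(seed)
  cells <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2", "b3"),
                       stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(a = cells$a[i], b = cells$b[i],
               x = stats::rnorm(n_per_cell[i]))
  }))
  rows$y <- 2 + (rows$a == "a2") * 0.8 + (rows$b == "b2") * 0.5 -
    (rows$b == "b3") * 0.4 + 0.3 * rows$x + stats::rnorm(nrow(rows), 0, 1)
  rows
}
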