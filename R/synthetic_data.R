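#' Simulation configuration for a synthetic herd
#'
#' Captures the demographic and model structure the appraisal analysis
#' assumes: discrete-generation pedigree, farms, primipara/multipara
#' lactation stages, kidding months and farm-by-kidding-year levels, a
#' days-in-milk linear covariate, age linear + quadratic covariates, and
#' multivariate additive-genetic (G) and residual (E) covariances across
#' traits.
#'
#' Two presets: `"desk"` (validation scale: 10-20 farms, a few thousand
#' animals, traits selectable) and `"caprigran"` (the full CAPRIGRAN programme
#' shape: 76 farms, all 17 traits with the published G/E defaults, bent to
#' PSD). Covariate distributions follow the published cohort description:
#' DIM uniform on 30-210 d, primipara age ~ N(1.61, 0.35), multipara age
#' ~ N(3.96, 1.74) truncated at first kidding.
#'
#' @param preset `"desk"` or `"caprigran"`.
#' @param ... overrides for any field.
#' @return `caprigen_sim_config` list.
#' @export
sim_config <- function(preset = c("desk", "caprigran"), ...) {
  preset <- match.arg(preset)
  base <- list(
    n_founders = 200,
    n_generations = 3,
    offspring_per_generation = 400,
    prop_male_founders = 0.1,
    mating = "random",              # or "half_sib" (sires reused heavily)
    n_sires_active = NULL,          # half_sib: number of sires per generation
    n_farms = 15,
    kidding_years = 2015:2019,
    kidding_months = 1:12,
    mu = 5,
    farm_sd = 0.5,
    lactation_effects = c(primipara = 0, multipara = 0.3),
    month_sd = 0.2,
    farm_year_sd = 0.3,
    b_dim = 0.002,
    b_age = 0.15,
    b_age2 = -0.015,
    dim_range = c(30, 210),
    age_primipara = c(mean = 1.61, sd = 0.35),
    age_multipara = c(mean = 3.96, sd = 1.74),
    age_min = 1,
    traits = "trait1",
    G = matrix(0.2, 1, 1, dimnames = list("trait1", "trait1")),
    E = matrix(0.8, 1, 1, dimnames = list("trait1", "trait1")),
    round_to_las = FALSE,
    seed = 1
  )
  if (preset == "caprigran") {
    cov <- reference_covariances()
    base$n_farms <- 76
    base$n_founders <- 600
    base$offspring_per_generation <- 800
    base$kidding_years <- 2005:2019
    base$traits <- rownames(cov$G)
    base$G <- cov$G
    base$E <- cov$E
  }
  over <- list(...)
  base[names(over)] <- over
  stopifnot(base$n_farms >= 1,
            all(diag(base$G) >= 0), all(diag(base$E) > 0))
  structure(base, class = "caprigen_sim_config")
}

#' Simulate a discrete-generation pedigree
#'
#' Founders (generation 0) are unrelated; each later generation samples a
#' sire and dam per offspring from the previous generation. Under
#' `mating = "random"` parents are drawn uniformly; `"half_sib"` restricts
#' to a few active sires (paternal half-sib families, the classic
#' variance-component design). Inbreeding arises naturally once relatives
#' mate. Offspring sex is assigned 50/50.
#'
#' @param config a [sim_config()].
#' @return a [caprigen_pedigree] with a `generation` attribute.
#' @export
simulate_pedigree <- function(config) {
  set.seed(config$seed)
  nf <- config$n_founders
  if (nf < 2 || config$n_generations < 1) {
    stop("need n_founders >= 2 and n_generations >= 1")
  }
  n_males <- round(nf * config$prop_male_founders)
  id <- paste0("F", seq_len(nf))
  sex <- c(rep("M", n_males), rep("F", nf - n_males))
  sire <- dam <- rep(NA_character_, nf)
  gen <- rep(0L, nf)
  for (g in seq_len(config$n_generations)) {
    prev <- which(gen == g - 1L)
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    if (!length(males) || !length(females)) {
      stop("infeasible mating scheme: generation ", g - 1L,
           " has no ", if (!length(males)) "males" else "females")
    }
    if (config$mating == "half_sib") {
      k <- config$n_sires_active %||% max(1L, length(males) %/% 4L)
      males <- males[seq_len(min(k, length(males)))]
    }
    no <- config$offspring_per_generation
    s <- sample(males, no, replace = TRUE)
    d <- sample(females, no, replace = TRUE)
    id <- c(id, paste0("G", g, "_", seq_len(no)))
    sire <- c(sire, id[s])
    dam <- c(dam, id[d])
    sex <- c(sex, sample(c("M", "F"), no, replace = TRUE))
    gen <- c(gen, rep(g, no))
  }
  ped <- pedigree(id = id, sire = sire, dam = dam, sex = sex)
  attr(ped, "generation") <- gen[match(ped$id, id)]
  ped
}

#' Simulate multivariate breeding values down a pedigree
#'
#' Founders draw `a ~ N(0, G)`; a non-founder receives the parent average
#' plus a Mendelian-sampling deviation with covariance
#' `G (1/2)(1 - (F_s + F_d)/2)`; with an unknown parent the missing parental
#' half is drawn at founder scale, giving deviation covariance
#' `G (3/4 - F_known/4)`.
#'
#' @param ped a [caprigen_pedigree].
#' @param G additive covariance matrix (PSD), traits in rows/cols.
#' @param seed RNG seed (optional; caller may manage the stream).
#' @return matrix animals x traits of true breeding values.
#' @export
simulate_breeding_values <- function(ped, G, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- as.matrix(G)
  k <- ncol(G)
  ev <- eigen(G, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values))) stop("G not PSD")
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k)
  n <- nrow(ped)
  pi <- parent_index(ped)
  f <- inbreeding(ped)
  a <- matrix(0, n, k, dimnames = list(ped$id, colnames(G)))
  z <- matrix(stats::rnorm(n * k), n, k)
  for (i in seq_len(n)) {
    s <- pi$sire[i]
    d <- pi$dam[i]
    pa <- numeric(k)
    if (!is.na(s)) pa <- pa + a[s, ] / 2
    if (!is.na(d)) pa <- pa + a[d, ] / 2
    vscale <- if (!is.na(s) && !is.na(d)) {
      0.5 * (1 - (f[s] + f[d]) / 2)
    } else if (!is.na(s)) {
      0.75 - f[s] / 4
    } else if (!is.na(d)) {
      0.75 - f[d] / 4
    } else 1
    a[i, ] <- pa + sqrt(vscale) * drop(L %*% z[i, ])
  }
  a
}

#' Simulate appraisal records over a pedigree
#'
#' One record per scored animal (animals are appraised once in their
#' lifetime): `y = mu + farm + lactation_stage + kidding_month +
#' farm:kidding_year + b1 DIM + b2 age + b3 age^2 + a + e`, residuals
#' `e ~ N(0, E)` across traits. All true effect contributions are stored
#' alongside the record so recovery can be checked exactly. Scored animals
#' default to every non-founder; founders carry breeding values but no
#' record (their BLUP must come through relatives).
#'
#' @param ped a [caprigen_pedigree] from [simulate_pedigree()].
#' @param bv breeding-value matrix from [simulate_breeding_values()].
#' @param config the same [sim_config()].
#' @param scored optional character vector of animal ids to score.
#' @return list with `records` (data frame), `effects` (true effect tables),
#'   `truth` (per-record true fixed + genetic contributions).
#' @export
simulate_records <- function(ped, bv, config, scored = NULL) {
  set.seed(config$seed + 1L)
  gen <- attr(ped, "generation")
  if (is.null(scored)) {
    scored <- if (is.null(gen)) ped$id else ped$id[gen > 0]
  }
  m <- length(scored)
  k <- length(config$traits)
  farms <- paste0("farm", seq_len(config$n_farms))
  farm_eff <- stats::setNames(stats::rnorm(config$n_farms, 0,
                                           config$farm_sd), farms)
  months <- config$kidding_months
  month_eff <- stats::setNames(stats::rnorm(length(months), 0,
                                            config$month_sd),
                               paste0("m", months))
  years <- config$kidding_years
  fy_levels <- as.vector(outer(farms, years, paste, sep = ":"))
  fy_eff <- stats::setNames(stats::rnorm(length(fy_levels), 0,
                                         config$farm_year_sd), fy_levels)

  farm <- sample(farms, m, replace = TRUE)
  month <- sample(months, m, replace = TRUE)
  year <- sample(years, m, replace = TRUE)
  stage <- sample(names(config$lactation_effects), m, replace = TRUE)
  dim_v <- stats::runif(m, config$dim_range[1], config$dim_range[2])
  age <- ifelse(
    stage == "primipara",
    stats::rnorm(m, config$age_primipara["mean"], config$age_primipara["sd"]),
    stats::rnorm(m, config$age_multipara["mean"], config$age_multipara["sd"]))
  age <- pmax(age, config$age_min)

  fixed <- config$mu +
    farm_eff[farm] +
    config$lactation_effects[stage] +
    month_eff[paste0("m", month)] +
    fy_eff[paste(farm, year, sep = ":")] +
    config$b_dim * dim_v + config$b_age * age + config$b_age2 * age^2

  E <- as.matrix(config$E)
  Le <- chol(bend_psd(E)$mat)
  e <- matrix(stats::rnorm(m * k), m, k) %*% Le
  a <- bv[scored, , drop = FALSE]
  y <- matrix(fixed, m, k) + a + e
  colnames(y) <- config$traits
  if (config$round_to_las) {
    y <- apply(y, 2, function(col) pmin(pmax(round_half_away(col), 1), 9))
  }
  records <- data.frame(animal = scored, farm = farm,
                        lactation_stage = stage, kidding_month = month,
                        kidding_year = year,
                        farm_year = paste(farm, year, sep = ":"),
                        dim = dim_v, age = age,
                        stringsAsFactors = FALSE)
  records <- cbind(records, as.data.frame(y))
  truth <- data.frame(animal = scored, fixed = unname(fixed))
  truth <- cbind(truth,
                 stats::setNames(as.data.frame(a),
                                 paste0("a_", config$traits)),
                 stats::setNames(as.data.frame(e),
                                 paste0("e_", config$traits)))
  list(records = records,
       effects = list(farm = farm_eff, month = month_eff,
                      farm_year = fy_eff,
                      lactation = config$lactation_effects),
       truth = truth)
}

#' Simulate a complete synthetic herd
#'
#' Pedigree + breeding values + single-record appraisal table in one call,
#' fully determined by the config's seed.
#'
#' @param config a [sim_config()].
#' @return list: `pedigree`, `breeding_values`, `records`, `effects`,
#'   `truth`, `config`.
#' @export
simulate_herd <- function(config = sim_config()) {
  ped <- simulate_pedigree(config)
  bv <- simulate_breeding_values(ped, config$G)
  rec <- simulate_records(ped, bv, config)
  list(pedigree = ped, breeding_values = bv, records = rec$records,
       effects = rec$effects, truth = rec$truth, config = config)
}

#' Write / read a synthetic herd as delimited text
#'
#' Pedigree, records and truth tables round-trip losslessly through
#' tab-separated files under `dir`.
#'
#' @param herd a [simulate_herd()] result.
#' @param dir output directory (created).
#' @export
write_herd <- function(herd, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  wr(as.data.frame(herd$pedigree), "pedigree.tsv")
  wr(herd$records, "records.tsv")
  wr(herd$truth, "truth.tsv")
  invisible(dir)
}

#' @rdname write_herd
#' @export
read_herd <- function(dir) {
  rd <- function(file) {
    utils::read.table(file.path(dir, file), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  }
  pedtab <- rd("pedigree.tsv")
  list(pedigree = pedigree(pedtab$id, pedtab$sire, pedtab$dam,
                           sex = pedtab$sex),
       records = rd("records.tsv"),
       truth = rd("truth.tsv"))
}
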