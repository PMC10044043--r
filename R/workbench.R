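#' Run configuration for the appraisal-genetics pipeline
#'
#' One auditable object holding every analysis setting: input paths (or an
#' in-memory herd), the fixed-effects model, the screening thresholds
#' (VIF 5, Spearman |rho| 0.5, residual bound 1.96), the REML convergence
#' criterion (1e-12), the scale set / inversion policy and the seed.
#'
#' @param pedigree_file,records_file input paths (optional when `herd`
#'   supplies the data directly).
#' @param herd an in-memory [simulate_herd()] result (optional).
#' @param traits trait columns to analyse.
#' @param trait_pairs list of character pairs for bivariate REML (default:
#'   none).
#' @param factors,interactions,covariates forwarded to [model_spec()].
#' @param predictors columns screened before modelling (default: the
#'   factors + covariates).
#' @param vif_threshold,rho_threshold,residual_bound,tol thresholds.
#' @param scale_set,invert_policy forwarded to the scoring stage.
#' @param seed integer seed logged and used by every stochastic step.
#' @param out_dir output directory for [run_pipeline()].
#' @return `caprigen_run_config` list.
#' @export
run_config <- function(pedigree_file = NULL, records_file = NULL,
                       herd = NULL, traits, trait_pairs = list(),
                       factors = c("farm", "lactation_stage",
                                   "kidding_month"),
                       interactions = list(c("farm", "kidding_year")),
                       covariates = c(dim = 1, age = 2),
                       predictors = NULL,
                       vif_threshold = 5, rho_threshold = 0.5,
                       residual_bound = 1.96, tol = 1e-12,
                       scale_set = "classic", invert_policy = FALSE,
                       seed = 1, out_dir = tempfile("caprigen_run_")) {
  stopifnot(vif_threshold > 0, rho_threshold > 0, residual_bound > 0,
            tol > 0)
  if (is.null(herd)) {
    for (fp in c(pedigree_file, records_file)) {
      if (is.null(fp) || !file.exists(fp)) {
        stop("input file missing: ", fp %||% "(not given)")
      }
    }
  }
  if (is.null(predictors)) {
    predictors <- c(factors, names(covariates))
  }
  structure(list(pedigree_file = pedigree_file,
                 records_file = records_file, herd = herd, traits = traits,
                 trait_pairs = trait_pairs, factors = factors,
                 interactions = interactions, covariates = covariates,
                 predictors = predictors, vif_threshold = vif_threshold,
                 rho_threshold = rho_threshold,
                 residual_bound = residual_bound, tol = tol,
                 scale_set = scale_set, invert_policy = invert_policy,
                 seed = seed, out_dir = out_dir),
            class = "caprigen_run_config")
}

#' Run the full pipeline: screen, ANCOVA, REML, BLUE/BLUP, reports
#'
#' Mirrors the published analysis order: pre-model screening, per-trait
#' fixed-effects ANCOVA, univariate REML per trait, bivariate REML for the
#' requested pairs, then mixed-model solutions at the converged components.
#' Every artifact is written under `config$out_dir` and listed in the run
#' manifest (with the seed and input digests) so a rerun with the same
#' config is byte-comparable.
#'
#' @param config a [run_config()].
#' @return the manifest (list), invisibly also written as JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "caprigen_run_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$herd)) {
    ped <- config$herd$pedigree
    records <- config$herd$records
    digests <- list(source = "in-memory herd",
                    seed_herd = config$herd$config$seed)
  } else {
    ped <- read_pedigree(config$pedigree_file)
    records <- utils::read.table(config$records_file, header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE)
    digests <- as.list(tools::md5sum(c(config$pedigree_file,
                                       config$records_file)))
  }
  artifacts <- list()

  screening <- screen_records(records, responses = config$traits,
                              predictors = config$predictors,
                              vif_threshold = config$vif_threshold,
                              rho_threshold = config$rho_threshold)
  artifacts$screening <- write_json_artifact(
    screening_report(screening), file.path(config$out_dir,
                                           "screening.json"))

  keep_factor <- intersect(config$factors, screening$retained)
  spec_for <- function(tr) {
    model_spec(tr, factors = keep_factor,
               interactions = config$interactions,
               covariates = config$covariates[
                 names(config$covariates) %in% screening$retained])
  }
  anc <- run_ancova(records, config$traits, spec_for)
  artifacts <- c(artifacts, emit_reports(anc, NULL, NULL, config$out_dir))

  uni <- lapply(stats::setNames(config$traits, config$traits),
                function(tr) {
    d <- build_design(records, spec_for(tr), ped)
    fit <- reml_univariate(d$y, d$X, d$Z, d$Ainv, tol = config$tol)
    sol <- solve_mme(d$y, d$X, d$Z, d$Ainv,
                     max(fit$sigma2_a, 1e-8 * fit$sigma2_p), fit$sigma2_e)
    list(fit = fit, blue = sol$blue, blup = sol$blup)
  })
  biv <- lapply(config$trait_pairs, function(pr) {
    d <- build_design(records, spec_for(pr[1]), ped)
    Y <- as.matrix(records[, pr])
    c(list(pair = pr),
      reml_bivariate(Y, d$X, d$Z, d$Ainv, tol = config$tol))
  })
  artifacts <- c(artifacts,
                 emit_reports(NULL, uni, biv, config$out_dir))

  blup_tab <- data.frame(animal = names(uni[[1]]$blup))
  for (tr in config$traits) blup_tab[[tr]] <- unname(uni[[tr]]$blup)
  path <- file.path(config$out_dir, "blup_solutions.tsv")
  utils::write.table(blup_tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  artifacts$blup <- path

  manifest <- list(
    package_version = as.character(utils::packageVersion("caprigen") %||%
                                     "dev"),
    seed = config$seed,
    thresholds = list(vif = config$vif_threshold,
                      rho = config$rho_threshold,
                      residual_bound = config$residual_bound,
                      tol = config$tol),
    inputs = digests,
    n_records = nrow(records), n_pedigree = nrow(ped),
    traits = config$traits,
    artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(manifest,
              list(screening = screening, ancova = anc, univariate = uni,
                   bivariate = biv)))
}

screening_report <- function(screening) {
  list(
    diagnostics = lapply(screening$diagnostics, function(d)
      d[c("skewness", "excess_kurtosis", "label")]),
    vif = as.list(screening$vif$vif),
    retained = screening$retained,
    discarded = if (is.null(screening$discarded)) list()
                else screening$discarded)
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Emit report tables in the published layouts
#'
#' Writes delimited files shaped like the evaluation's summary tables:
#' the per-trait Type III panel (term, df, F, p), the goodness-of-fit panel
#' (predicted/adjusted R2, MSE, RMSE, DW), the variance-component /
#' heritability table, and the combined correlation matrix with genetic
#' correlations above and phenotypic below the diagonal (diagonal blank).
#'
#' @param ancova [run_ancova()] result, or NULL to skip.
#' @param univariate named list of univariate REML results, or NULL.
#' @param bivariate list of bivariate results (each with `pair`), or NULL.
#' @param dir output directory.
#' @return named list of written paths.
#' @export
emit_reports <- function(ancova, univariate, bivariate, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  wr <- function(df, file) {
    p <- file.path(dir, file)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }
  if (!is.null(ancova)) {
    t3 <- do.call(rbind, lapply(names(ancova$type_iii), function(tr) {
      cbind(trait = tr, ancova$type_iii[[tr]])
    }))
    out$type_iii <- wr(t3, "type_iii.tsv")
    out$model_table <- wr(ancova$model_table, "model_table.tsv")
    out$goodness_of_fit <- wr(ancova$fit_table, "goodness_of_fit.tsv")
    out$residuals <- wr(ancova$residual_table, "residual_flags.tsv")
  }
  if (!is.null(univariate)) {
    comp <- do.call(rbind, lapply(names(univariate), function(tr) {
      f <- univariate[[tr]]$fit
      data.frame(trait = tr, sigma2_a = f$sigma2_a,
                 sigma2_p = f$sigma2_p, sigma2_e = f$sigma2_e, h2 = f$h2,
                 se_h2 = unname(f$se["h2"]), boundary = f$boundary)
    }))
    out$components <- wr(comp, "variance_components.tsv")
    blue <- do.call(rbind, lapply(names(univariate), function(tr) {
      b <- univariate[[tr]]$blue
      data.frame(trait = tr, level = names(b), estimate = unname(b))
    }))
    out$blue <- wr(blue, "blue_solutions.tsv")
  }
  if (!is.null(bivariate) && length(bivariate)) {
    traits <- unique(unlist(lapply(bivariate, `[[`, "pair")))
    k <- length(traits)
    m <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
    for (b in bivariate) {
      i <- match(b$pair[1], traits)
      j <- match(b$pair[2], traits)
      lo <- min(i, j); hi <- max(i, j)
      m[lo, hi] <- b$r_g   # genetic above the diagonal
      m[hi, lo] <- b$r_p   # phenotypic below
    }
    tab <- as.data.frame(m)
    tab <- cbind(trait = traits, tab)
    out$correlations <- wr(tab, "correlations.tsv")
  }
  out
}
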