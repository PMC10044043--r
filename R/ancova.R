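#' Specify the environmental (fixed-effects) model
#'
#' The analysis-of-covariance layer fits, per trait,
#' `y = mu + farm + lactation_stage + kidding_month + farm:kidding_year
#'  + b1 DIM + b2 age + b3 age^2 + e`.
#' `model_spec()` captures which factors, interactions and polynomial
#' covariates enter; the same spec later drives the fixed part of the animal
#' model.
#'
#' @param response trait column name.
#' @param factors character vector of factor columns.
#' @param interactions list of character pairs combined into a single
#'   interaction factor (e.g. `list(c("farm", "kidding_year"))`).
#' @param covariates named integer vector: column name -> polynomial degree
#'   (e.g. `c(dim = 1, age = 2)`); covariates are centered before powers.
#' @param intercept keep the overall mean (default TRUE).
#' @return a `caprigen_model_spec` list.
#' @export
model_spec <- function(response,
                       factors = c("farm", "lactation_stage",
                                   "kidding_month"),
                       interactions = list(c("farm", "kidding_year")),
                       covariates = c(dim = 1, age = 2),
                       intercept = TRUE) {
  if (anyDuplicated(factors)) stop("duplicated factor")
  structure(list(response = response, factors = factors,
                 interactions = interactions, covariates = covariates,
                 intercept = intercept),
            class = "caprigen_model_spec")
}

# Expand a spec into a model frame of factor/covariate columns plus the
# term label of each.
spec_terms <- function(records, spec) {
  terms <- list()
  for (f in spec$factors) {
    v <- factor(records[[f]])
    v <- droplevels(v)
    terms[[f]] <- v
  }
  for (ia in spec$interactions) {
    lab <- paste(ia, collapse = ":")
    terms[[lab]] <- droplevels(interaction(records[ia], drop = TRUE,
                                           sep = ":"))
  }
  if (length(spec$covariates)) {
    for (nm in names(spec$covariates)) {
      x <- records[[nm]]
      if (any(!is.finite(x))) stop("non-finite covariate: ", nm)
      xc <- x - mean(x)
      for (d in seq_len(spec$covariates[[nm]])) {
        lab <- if (d == 1) nm else paste0(nm, "^", d)
        terms[[lab]] <- xc^d
      }
    }
  }
  terms
}

# Sum-to-zero design matrix columns for one term.
term_columns <- function(v, label) {
  if (is.factor(v)) {
    if (nlevels(v) < 2) return(NULL)
    X <- stats::model.matrix(~ v, contrasts.arg = list(v = "contr.sum"))
    X <- X[, -1, drop = FALSE]
    colnames(X) <- paste0(label, seq_len(ncol(X)))
    X
  } else {
    matrix(v, ncol = 1, dimnames = list(NULL, label))
  }
}

#' Fit the per-trait environmental linear model
#'
#' Least squares via rank-revealing QR on a sum-to-zero (effects-coded)
#' design. Aliased columns (rank deficiencies, e.g. empty interaction
#' cells) are detected and reported; the fit uses the estimable subspace.
#'
#' @param records appraisal record data frame.
#' @param spec a [model_spec()].
#' @return `caprigen_ancova_fit`: design bookkeeping, coefficients,
#'   residuals, fitted values, rank, residual df, term assignment.
#' @export
fit_linear_model <- function(records, spec) {
  y <- records[[spec$response]]
  if (!is.numeric(y)) stop("response must be numeric")
  tl <- spec_terms(records, spec)
  blocks <- lapply(names(tl), function(nm) term_columns(tl[[nm]], nm))
  keep <- !vapply(blocks, is.null, TRUE)
  blocks <- blocks[keep]
  labels <- names(tl)[keep]
  assign <- rep(labels, vapply(blocks, ncol, 0L))
  X <- do.call(cbind, blocks)
  if (spec$intercept) {
    X <- cbind("(Intercept)" = rep(1, length(y)), X)
    assign <- c("(Intercept)", assign)
  } else if (is.null(X)) {
    stop("empty model: no intercept and no terms")
  }
  n <- nrow(X)
  qrX <- qr(X)
  r <- qrX$rank
  if (n <= r) stop("n (", n, ") must exceed model rank (", r, ")")
  aliased <- if (r < ncol(X)) colnames(X)[qrX$pivot[(r + 1):ncol(X)]]
             else character(0)
  beta <- qr.coef(qrX, y)
  fitted <- qr.fitted(qrX, y)
  resid <- y - fitted
  structure(list(y = y, X = X, qr = qrX, assign = assign,
                 coefficients = beta, fitted = fitted, residuals = resid,
                 rank = r, df_residual = n - r, aliased = aliased,
                 spec = spec, n = n,
                 rss = sum(resid^2),
                 sst = sum((y - mean(y))^2)),
            class = "caprigen_ancova_fit")
}

rss_of <- function(X, y) {
  q <- qr(X)
  sum(qr.resid(q, y)^2)
}

#' Type III (marginal) sum-of-squares table
#'
#' Each term is tested by the partial hypothesis: the model is refitted with
#' that term's effects-coded columns deleted while every other term stays,
#' and `SS = RSS_reduced - RSS_full`. With sum-to-zero coding this is the
#' classical Type III test. `F = (SS/df) / MS_resid`, p from the F
#' distribution. Terms whose deletion does not change the model rank
#' (fully aliased) are reported `NA`.
#'
#' @param fit a [fit_linear_model()] result.
#' @return data frame: term, df, sum_sq, mean_sq, statistic (F), p_value.
#' @export
type_iii_table <- function(fit) {
  stopifnot(inherits(fit, "caprigen_ancova_fit"))
  terms <- setdiff(unique(fit$assign), "(Intercept)")
  mse <- fit$rss / fit$df_residual
  rows <- lapply(terms, function(tm) {
    keep <- fit$assign != tm
    Xr <- fit$X[, keep, drop = FALSE]
    rr <- qr(Xr)$rank
    df <- fit$rank - rr
    if (df <= 0) {
      return(data.frame(term = tm, df = NA_integer_, sum_sq = NA_real_,
                        mean_sq = NA_real_, statistic = NA_real_,
                        p_value = NA_real_,
                        note = "non-estimable (aliased)"))
    }
    ss <- rss_of(Xr, fit$y) - fit$rss
    ss <- max(ss, 0)
    Fv <- (ss / df) / mse
    data.frame(term = tm, df = df, sum_sq = ss, mean_sq = ss / df,
               statistic = Fv,
               p_value = stats::pf(Fv, df, fit$df_residual,
                                   lower.tail = FALSE),
               note = "")
  })
  out <- do.call(rbind, rows)
  attr(out, "residual") <- c(df = fit$df_residual, rss = fit$rss, mse = mse)
  out
}

#' Goodness-of-fit panel
#'
#' R2, adjusted R2 `1 - (1-R2)(n-1)/(n-p-1)`, predicted R2 from the PRESS
#' statistic (leave-one-out residuals `e/(1-h)` via the hat diagonal), MSE
#' (`RSS/df_resid`), RMSE and the Durbin-Watson statistic over a declared
#' record ordering (default: input order; the appraisal pipeline sorts by
#' farm, date, animal before fitting).
#'
#' @param fit a [fit_linear_model()] result.
#' @param order optional integer ordering for the DW statistic.
#' @return list: r_squared, adj_r_squared, pred_r_squared, press, mse, rmse,
#'   durbin_watson, n_press_excluded.
#' @export
goodness_of_fit <- function(fit, order = NULL) {
  stopifnot(inherits(fit, "caprigen_ancova_fit"))
  r2 <- 1 - fit$rss / fit$sst
  p <- fit$rank - as.integer("(Intercept)" %in% fit$assign)
  n <- fit$n
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  h <- hat_diagonal(fit)
  ok <- h < 1 - 1e-10
  if (any(!ok)) {
    warning(sum(!ok), " observation(s) with hat diagonal 1 excluded from ",
            "PRESS")
  }
  press <- sum((fit$residuals[ok] / (1 - h[ok]))^2)
  pred <- 1 - press / fit$sst
  e <- if (is.null(order)) fit$residuals else fit$residuals[order]
  dw <- sum(diff(e)^2) / sum(e^2)
  mse <- fit$rss / fit$df_residual
  list(r_squared = r2, adj_r_squared = adj, pred_r_squared = pred,
       press = press, mse = mse, rmse = sqrt(mse), durbin_watson = dw,
       n_press_excluded = sum(!ok))
}

hat_diagonal <- function(fit) {
  Q <- qr.Q(fit$qr)[, seq_len(fit$rank), drop = FALSE]
  rowSums(Q^2)
}

#' Standardized-residual outlier flagging
#'
#' Internally studentized residuals `e / (s sqrt(1 - h))`; under a correct
#' normal-errors model 95% should fall inside +/-1.96, so the check passes
#' when the fraction outside `bound` is at most 5%.
#'
#' @param fit a [fit_linear_model()] result.
#' @param bound flag residuals with `|r| > bound` (default 1.96).
#' @return list: `standardized` residuals, logical `flags`,
#'   `outlier_fraction` (percent), `pass` at the 5% rule.
#' @export
flag_residuals <- function(fit, bound = 1.96) {
  stopifnot(inherits(fit, "caprigen_ancova_fit"))
  h <- pmin(hat_diagonal(fit), 1 - 1e-10)
  s <- sqrt(fit$rss / fit$df_residual)
  std <- fit$residuals / (s * sqrt(1 - h))
  flags <- abs(std) > bound
  frac <- 100 * mean(flags)
  list(standardized = std, flags = flags, outlier_fraction = frac,
       pass = frac <= 5)
}

#' Run the ANCOVA layer over a set of traits
#'
#' Fits the environmental model per trait and assembles the Type III and
#' goodness-of-fit report tables in the layout of the published evaluation
#' (one row per trait: df, F, p, residual SS/MS; and the R2 panel).
#'
#' @param records appraisal record data frame.
#' @param traits character vector of trait columns.
#' @param spec_for function(trait) -> [model_spec()]; default builds the
#'   standard environmental spec for each trait.
#' @return list with `fits`, `type_iii` (per-trait tables),
#'   `model_table` (one summary row per trait), `fit_table` (goodness of
#'   fit), `residual_table`.
#' @export
run_ancova <- function(records, traits,
                       spec_for = function(tr) model_spec(tr)) {
  fits <- lapply(stats::setNames(traits, traits), function(tr) {
    fit_linear_model(records, spec_for(tr))
  })
  t3 <- lapply(fits, type_iii_table)
  model_table <- do.call(rbind, lapply(traits, function(tr) {
    fit <- fits[[tr]]
    tab <- t3[[tr]]
    mdl_df <- sum(tab$df, na.rm = TRUE)
    ssm <- fit$sst - fit$rss
    Fv <- (ssm / (fit$rank - 1)) / (fit$rss / fit$df_residual)
    data.frame(trait = tr, df = fit$rank - 1, statistic = Fv,
               p_value = stats::pf(Fv, fit$rank - 1, fit$df_residual,
                                   lower.tail = FALSE),
               error_df = fit$df_residual, rss = fit$rss,
               rms = fit$rss / fit$df_residual, terms_df = mdl_df)
  }))
  fit_table <- do.call(rbind, lapply(traits, function(tr) {
    g <- goodness_of_fit(fits[[tr]])
    data.frame(trait = tr, df = fits[[tr]]$df_residual,
               pred_r_squared = g$pred_r_squared,
               adj_r_squared = g$adj_r_squared, mse = g$mse,
               rmse = g$rmse, durbin_watson = g$durbin_watson)
  }))
  residual_table <- do.call(rbind, lapply(traits, function(tr) {
    fl <- flag_residuals(fits[[tr]])
    data.frame(trait = tr, n = fits[[tr]]$n, n_flagged = sum(fl$flags),
               outlier_percent = fl$outlier_fraction, pass = fl$pass)
  }))
  list(fits = fits, type_iii = t3, model_table = model_table,
       fit_table = fit_table, residual_table = residual_table)
}
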