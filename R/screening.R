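#' Distribution shape diagnostics
#'
#' Sample skewness `m3 / m2^(3/2)` and excess kurtosis `m4 / m2^2 - 3`
#' (moment estimators), with the usual shape label: platykurtic when excess
#' kurtosis < 0, leptokurtic when > 0, mesokurtic at 0.
#'
#' @param x numeric vector, `n >= 4`; constant vectors are an error.
#' @return list with `skewness`, `excess_kurtosis`, `label`, `n`.
#' @export
distribution_diagnostics <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) stop("need at least 4 finite observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("constant vector: moments undefined")
  skew <- mean((x - m)^3) / m2^1.5
  exk <- mean((x - m)^4) / m2^2 - 3
  label <- if (exk < 0) "platykurtic" else if (exk > 0) "leptokurtic" else
           "mesokurtic"
  list(skewness = skew, excess_kurtosis = exk, label = label, n = n)
}

hoeffding_d_stat <- function(r, s) {
  n <- length(r)
  # bivariate midrank: Q_i = 1 + #{both strictly below} + 1/2 #{one tied,
  # other below} + 1/4 #{both tied} (self pair contributes 1/4 via ties)
  Q <- vapply(seq_len(n), function(i) {
    cr <- sign(r[i] - r)  # 1 below, 0 tied, -1 above
    cs <- sign(s[i] - s)
    u <- (cr + 1) / 2     # 1 below, 0.5 tied, 0 above
    v <- (cs + 1) / 2
    sum(u * v) + 0.75     # add 3/4: self term must count 1, not 1/4
  }, 0)
  D1 <- sum((Q - 1) * (Q - 2))
  D2 <- sum((r - 1) * (r - 2) * (s - 1) * (s - 2))
  D3 <- sum((r - 2) * (s - 2) * (Q - 1))
  30 * ((n - 2) * (n - 3) * D1 + D2 - 2 * (n - 2) * D3) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}

#' Hoeffding's D test of independence
#'
#' The joint-rank statistic of Hoeffding, computed with midranks for ties:
#' `D = 30 [ (n-2)(n-3) D1 + D2 - 2 (n-2) D3 ] / (n(n-1)(n-2)(n-3)(n-4))`
#' with `D1 = sum (Q-1)(Q-2)`, `D2 = sum (R-1)(R-2)(S-1)(S-2)`,
#' `D3 = sum (R-2)(S-2)(Q-1)` over the marginal ranks `R`, `S` and bivariate
#' ranks `Q`. D measures dependence of any form, not direction. The p-value
#' comes from a seeded label-permutation null rather than the asymptotic
#' table approximation.
#'
#' @param x,y numeric vectors of equal length, `n >= 5`.
#' @param n_perm number of permutations (>= 999 recommended; the p-value is
#'   `(1 + #\{D_perm >= D_obs\}) / (n_perm + 1)`).
#' @param seed RNG seed for the permutation null.
#' @return list with `D`, `p_value`, `n`, `n_perm`.
#' @export
hoeffding_d <- function(x, y, n_perm = 999, seed = 1) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 5) stop("Hoeffding's D requires n >= 5")
  r <- rank(x)
  s <- rank(y)
  D <- hoeffding_d_stat(r, s)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (hoeffding_d_stat(r, sample(s)) >= D) hits <- hits + 1L
  }
  list(D = D, p_value = (1 + hits) / (n_perm + 1), n = n, n_perm = n_perm)
}

one_hot <- function(df) {
  stopifnot(is.data.frame(df))
  cols <- lapply(names(df), function(nm) {
    v <- df[[nm]]
    if (is.numeric(v)) {
      out <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
    } else {
      f <- factor(v)
      if (nlevels(f) < 2) {
        return(matrix(numeric(0), nrow = length(v), ncol = 0))
      }
      out <- stats::model.matrix(~ f)[, -1, drop = FALSE]
      colnames(out) <- paste0(nm, ".", levels(f)[-1])
    }
    out
  })
  do.call(cbind, cols)
}

vif_values <- function(mat) {
  p <- ncol(mat)
  vapply(seq_len(p), function(j) {
    yj <- mat[, j]
    Xj <- cbind(1, mat[, -j, drop = FALSE])
    fit <- stats::lm.fit(Xj, yj)
    sst <- sum((yj - mean(yj))^2)
    ssr <- sum(fit$residuals^2)
    if (sst == 0) return(Inf)
    r2 <- 1 - ssr / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
}

#' Variance-inflation-factor multicollinearity filter
#'
#' `VIF_j = 1 / (1 - R2_j)` from regressing predictor `j` on all the others
#' (categorical predictors enter one-hot encoded with the reference level
#' dropped; a factor is judged by the largest VIF among its dummies).
#' Predictors are dropped greedily, largest VIF first (perfect collinearity,
#' VIF = Inf, goes before anything finite), until all remaining VIFs are at
#' or below `threshold`.
#'
#' @param design data frame of predictors (numeric or factor/character).
#' @param threshold drop while any VIF exceeds this (default 5).
#' @return list: `retained` (names), `dropped` (data frame name/vif/reason),
#'   `vif` (named vector for the retained set).
#' @export
vif_filter <- function(design, threshold = 5) {
  stopifnot(is.data.frame(design), threshold > 0)
  vars <- names(design)
  dropped <- data.frame(name = character(), vif = numeric(),
                        reason = character(), stringsAsFactors = FALSE)
  repeat {
    if (length(vars) < 2) break
    mat <- one_hot(design[vars])
    groups <- sub("\\..*$", "", colnames(mat))
    # numeric columns keep their exact name
    groups[colnames(mat) %in% vars] <- colnames(mat)[colnames(mat) %in% vars]
    v <- vif_values(mat)
    per_var <- vapply(vars, function(nm) {
      idx <- which(groups == nm)
      if (!length(idx)) NA_real_ else max(v[idx])
    }, 0)
    worst <- which.max(per_var)
    if (is.na(per_var[worst]) || per_var[worst] <= threshold) break
    dropped <- rbind(dropped, data.frame(
      name = vars[worst], vif = per_var[worst],
      reason = "vif_gt_threshold", stringsAsFactors = FALSE))
    vars <- vars[-worst]
  }
  final_vif <- if (length(vars) >= 2) {
    mat <- one_hot(design[vars])
    groups <- sub("\\..*$", "", colnames(mat))
    groups[colnames(mat) %in% vars] <- colnames(mat)[colnames(mat) %in% vars]
    v <- vif_values(mat)
    vapply(vars, function(nm) max(v[groups == nm]), 0)
  } else {
    stats::setNames(rep(1, length(vars)), vars)
  }
  list(retained = vars, dropped = dropped, vif = final_vif)
}

#' Spearman redundancy filter
#'
#' Flags predictor pairs with `|rho| >= threshold` (Spearman rank
#' correlation) and drops, per flagged pair, the member with the larger mean
#' `|rho|` against all other remaining variables (tie: the later column).
#' Constant columns are excluded up front since their ranks are undefined.
#'
#' @param vars data frame of numeric (or ordinal-coded) variables.
#' @param threshold redundancy threshold on `|rho|` (default 0.5).
#' @return list: `retained`, `dropped` (name/reason/partner), `rho` (full
#'   Spearman matrix on the input), `decisions` (data frame of every flagged
#'   pair and the drop taken).
#' @export
spearman_redundancy <- function(vars, threshold = 0.5) {
  stopifnot(is.data.frame(vars), ncol(vars) >= 2)
  nm <- names(vars)
  num <- as.data.frame(lapply(vars, function(v) {
    if (is.numeric(v)) v else as.numeric(factor(v))
  }))
  const <- vapply(num, function(v) stats::var(v, na.rm = TRUE) == 0 ||
                    !is.finite(stats::var(v, na.rm = TRUE)), TRUE)
  dropped <- data.frame(name = nm[const],
                        reason = rep("constant", sum(const)),
                        partner = rep(NA_character_, sum(const)),
                        stringsAsFactors = FALSE)
  keep <- nm[!const]
  rho <- suppressWarnings(stats::cor(num, method = "spearman",
                                     use = "pairwise.complete.obs"))
  decisions <- data.frame(var1 = character(), var2 = character(),
                          rho = numeric(), dropped = character(),
                          stringsAsFactors = FALSE)
  repeat {
    if (length(keep) < 2) break
    sub <- abs(rho[keep, keep, drop = FALSE])
    diag(sub) <- 0
    mx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    if (sub[mx[1], mx[2]] < threshold) break
    a <- keep[mx[1]]
    b <- keep[mx[2]]
    others <- setdiff(keep, c(a, b))
    mean_abs <- function(v) if (length(others)) mean(sub[v, others]) else 0
    drop_var <- if (mean_abs(a) > mean_abs(b)) a
                else if (mean_abs(b) > mean_abs(a)) b
                else keep[max(mx)]  # tie: the later column
    decisions <- rbind(decisions, data.frame(
      var1 = a, var2 = b, rho = rho[a, b], dropped = drop_var,
      stringsAsFactors = FALSE))
    dropped <- rbind(dropped, data.frame(
      name = drop_var, reason = "spearman_redundant",
      partner = setdiff(c(a, b), drop_var), stringsAsFactors = FALSE))
    keep <- setdiff(keep, drop_var)
  }
  list(retained = keep, dropped = dropped, rho = rho, decisions = decisions)
}

#' Normality and homoscedasticity gatekeepers
#'
#' Thin wrappers over the standard routines the screening stage reports
#' (they gate, they are not re-derived here): Kolmogorov-Smirnov against a
#' fitted normal, and Levene's test across groups via `car::leveneTest`.
#'
#' @param x numeric vector.
#' @return list with `statistic` and `p_value`.
#' @export
ks_normality <- function(x) {
  x <- x[is.finite(x)]
  res <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' @rdname ks_normality
#' @param g grouping factor for Levene's test.
#' @export
levene_homoscedasticity <- function(x, g) {
  if (!requireNamespace("car", quietly = TRUE)) {
    stop("levene_homoscedasticity requires the 'car' package")
  }
  res <- car::leveneTest(x, factor(g))
  list(statistic = res[1, "F value"], p_value = res[1, "Pr(>F)"])
}

#' Full pre-model screening report
#'
#' Runs [distribution_diagnostics()] per response, [vif_filter()] then
#' [spearman_redundancy()] over the predictor set, and returns a single
#' report object with every retained/discarded predictor and its
#' machine-readable reason.
#'
#' @param records data frame of appraisal records.
#' @param responses character vector of trait columns to diagnose.
#' @param predictors character vector of candidate model predictors.
#' @param vif_threshold,rho_threshold filter thresholds (defaults 5, 0.5).
#' @return list with `diagnostics`, `vif`, `spearman`, `retained`,
#'   `discarded`.
#' @export
screen_records <- function(records, responses, predictors,
                           vif_threshold = 5, rho_threshold = 0.5) {
  diagnostics <- lapply(stats::setNames(responses, responses), function(tr) {
    distribution_diagnostics(records[[tr]])
  })
  vif <- vif_filter(records[predictors], threshold = vif_threshold)
  sp <- spearman_redundancy(records[vif$retained],
                            threshold = rho_threshold)
  discarded <- rbind(
    if (nrow(vif$dropped)) cbind(vif$dropped[, c("name", "reason")],
                                 partner = NA_character_),
    if (nrow(sp$dropped)) sp$dropped[, c("name", "reason", "partner")]
  )
  list(diagnostics = diagnostics, vif = vif, spearman = sp,
       retained = sp$retained, discarded = discarded)
}
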