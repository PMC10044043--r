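#' Build animal-model design matrices
#'
#' Assembles, from an appraisal record table and a pedigree, the pieces of
#' the single-record animal model
#' `y = X b + Z a + e`, `var(a) = A sigma2_a`, `var(e) = I sigma2_e`:
#' the fixed-effects design `X` (reduced to full column rank; aliased
#' columns are reported, not silently dropped), the sparse record-to-animal
#' incidence `Z` over the full pedigree (animals without records receive
#' breeding values through relatives), and the sparse `A` inverse.
#'
#' @param records data frame; must contain `animal` plus every column the
#'   spec names.
#' @param spec a [model_spec()] describing the fixed part.
#' @param ped a [caprigen_pedigree]; every record animal must appear in it.
#' @return list: `y`, `X` (dense, full rank), `Z` (sparse n x q), `Ainv`,
#'   `animal_ids`, `aliased` (dropped column names), `rank_report`.
#' @export
build_design <- function(records, spec, ped) {
  missing_ids <- setdiff(records$animal, ped$id)
  if (length(missing_ids)) {
    stop("record animal(s) absent from pedigree: ",
         paste(utils::head(missing_ids, 10), collapse = ", "),
         if (length(missing_ids) > 10) ", ..." else "")
  }
  y <- records[[spec$response]]
  if (any(!is.finite(y))) stop("non-finite response values")
  tl <- spec_terms(records, spec)
  blocks <- lapply(names(tl), function(nm) {
    v <- tl[[nm]]
    if (is.factor(v)) {
      if (nlevels(v) < 2) return(NULL)
      X <- stats::model.matrix(~ v)[, -1, drop = FALSE]
      colnames(X) <- paste0(nm, ".", levels(v)[-1])
      X
    } else {
      matrix(v, ncol = 1, dimnames = list(NULL, nm))
    }
  })
  blocks <- blocks[!vapply(blocks, is.null, TRUE)]
  X <- cbind("(Intercept)" = rep(1, length(y)), do.call(cbind, blocks))
  qrX <- qr(X)
  aliased <- character(0)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  n <- nrow(X)
  q <- nrow(ped)
  Z <- Matrix::sparseMatrix(i = seq_len(n),
                            j = match(records$animal, ped$id),
                            x = 1, dims = c(n, q),
                            dimnames = list(NULL, ped$id))
  list(y = y, X = X, Z = Z, Ainv = a_inverse(ped), animal_ids = ped$id,
       aliased = aliased,
       rank_report = c(n = n, p = ncol(X), q = q,
                       dropped = length(aliased)))
}

#' REML starting values from phenotypic moments
#'
#' The conventional start of the appraisal evaluations: 20% of the
#' phenotypic (co)variance to the additive component and 80% to the
#' environmental one, element-wise on the covariance scale built from the
#' supplied variances and correlations. A non-PSD implied P is bent first
#' (with a warning).
#'
#' @param phenotypic_var named vector of phenotypic variances (> 0).
#' @param phenotypic_corr correlation matrix (defaults to identity).
#' @return list with matrices `G0` and `E0` (1x1 for a single trait).
#' @export
starting_values <- function(phenotypic_var, phenotypic_corr = NULL) {
  stopifnot(all(phenotypic_var > 0))
  k <- length(phenotypic_var)
  if (is.null(phenotypic_corr)) phenotypic_corr <- diag(k)
  stopifnot(all(abs(phenotypic_corr) <= 1))
  s <- sqrt(phenotypic_var)
  P0 <- outer(s, s) * phenotypic_corr
  b <- bend_psd(P0, eps = max(diag(P0)) * 1e-8)
  if (b$bent) {
    warning("implied phenotypic covariance not PSD; bent (shift ",
            signif(b$shift, 3), ")")
    P0 <- b$mat
  }
  list(G0 = 0.2 * P0, E0 = 0.8 * P0)
}

# Sparse symmetric solve helpers -------------------------------------------

logdet_A_of <- function(Ainv) {
  ld <- attr(Ainv, "logdet_A")
  if (!is.null(ld)) return(ld)
  ch <- Matrix::Cholesky(Ainv, LDL = FALSE)
  -2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
}

# Mixed-model pieces reused across likelihood evaluations. With W = [X Z],
# C0 = W'W and D0 = blkdiag(0, Ainv), the MME coefficient matrix at ratio
# lambda is C0 + lambda D0; the bivariate system (ordering b1,u1,b2,u2) is
# kron(Einv, C0) + kron(Ginv, D0). One symbolic Cholesky per sparsity
# pattern is computed up front and numerically updated per evaluation.
mme_parts <- function(y, X, Z, Ainv) {
  X <- as.matrix(X)
  W <- cbind(Matrix::Matrix(X, sparse = TRUE), Z)
  C0 <- Matrix::forceSymmetric(Matrix::crossprod(W))
  p <- ncol(X)
  q <- ncol(Z)
  D0 <- Matrix::forceSymmetric(Matrix::bdiag(
    Matrix::Matrix(0, p, p, sparse = TRUE), Ainv))
  chol0 <- Matrix::Cholesky(Matrix::forceSymmetric(C0 + D0), LDL = FALSE,
                            perm = TRUE, super = TRUE)
  list(X = X, Z = Z, W = W, Ainv = Ainv,
       Ainv_g = as(Ainv, "generalMatrix"), y = y,
       C0 = C0, D0 = D0, chol0 = chol0, chol2 = NULL,
       Wty = as.numeric(Matrix::crossprod(W, y)),
       Xty = crossprod(X, y),
       Zty = as.numeric(Matrix::crossprod(Z, y)), yty = sum(y * y),
       n = length(y), p = p, q = q,
       logdet_A = logdet_A_of(Ainv))
}

mme_matrix <- function(parts, lambda) {
  Matrix::forceSymmetric(parts$C0 + lambda * parts$D0)
}

# Solve the MME at ratio lambda; returns solution (fixed effects first,
# then one entry per pedigree animal), log|M| and the residual quadratic
# form SSR = y'y - sol' rhs.
mme_solve_lambda <- function(parts, lambda, keep_matrix = FALSE) {
  M <- mme_matrix(parts, lambda)
  ch <- Matrix::update(parts$chol0, M)
  rhs <- parts$Wty
  sol <- as.numeric(Matrix::solve(ch, rhs))
  logdetM <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
  list(sol = sol, logdetM = logdetM,
       ssr = parts$yty - sum(sol * rhs),
       M = if (keep_matrix) M else NULL, chol = ch)
}

# -2 restricted log-likelihood (constant dropped) at (sigma2_a, sigma2_e).
neg2_reml_uni <- function(parts, sigma2_a, sigma2_e) {
  lambda <- sigma2_e / sigma2_a
  ms <- mme_solve_lambda(parts, lambda)
  (parts$n - parts$p - parts$q) * log(sigma2_e) +
    parts$q * log(sigma2_a) + parts$logdet_A + ms$logdetM +
    ms$ssr / sigma2_e
}

# Profiled -2logL over heritability; sigma2_e is profiled analytically.
neg2_profiled <- function(parts, h2) {
  lambda <- (1 - h2) / h2
  ms <- mme_solve_lambda(parts, lambda)
  s2e <- ms$ssr / (parts$n - parts$p)
  val <- (parts$n - parts$p) * (log(s2e) + 1) - parts$q * log(lambda) +
    parts$logdet_A + ms$logdetM
  attr(val, "sigma2_e") <- s2e
  val
}

# One EM-REML sweep (dense): returns updated components. Requires the dense
# inverse of M, so only used on small systems.
em_step_uni <- function(parts, sigma2_a, sigma2_e) {
  lambda <- sigma2_e / sigma2_a
  M <- as.matrix(mme_matrix(parts, lambda))
  Minv <- chol2inv(chol(M))
  rhs <- parts$Wty
  sol <- Minv %*% rhs
  u <- sol[(parts$p + 1):(parts$p + parts$q)]
  uAu <- as.numeric(crossprod(u, as.numeric(parts$Ainv %*% u)))
  Muu <- Minv[(parts$p + 1):(parts$p + parts$q),
              (parts$p + 1):(parts$p + parts$q)]
  trAinvMuu <- sum(parts$Ainv_g * Muu)
  s2a <- (uAu + sigma2_e * trAinvMuu) / parts$q
  s2e <- (parts$yty - sum(sol * rhs)) / (parts$n - parts$p)
  c(sigma2_a = s2a, sigma2_e = s2e)
}

#' Univariate animal-model REML
#'
#' Estimates additive and residual variances of a single trait under
#' `y = X b + Z a + e`, `var(a) = A sigma2_a`. Expectation-maximization
#' sweeps (monotone in the restricted likelihood, but needing a dense MME
#' inverse, so gated to small systems) precede a derivative-free Brent
#' search on the likelihood profiled over the heritability, run to a
#' relative-change criterion of `tol` (default 1e-12) in -2 logL. Standard
#' errors come from the finite-difference observed information with
#' delta-method propagation to `h2`.
#'
#' @param y,X,Z,Ainv from [build_design()].
#' @param start optional list with `G0`, `E0` (1x1 matrices or scalars) as
#'   from [starting_values()]; default 0.2/0.8 of the sample variance.
#' @param tol convergence criterion on the relative change of -2 logL and of
#'   the components (default 1e-12).
#' @param max_iter EM iteration cap.
#' @param em_limit run EM sweeps only when `p + q` is at most this
#'   (default 600); the Brent stage does not need them.
#' @param compute_se numerical-information standard errors (default TRUE).
#' @return `caprigen_reml` list: `sigma2_a`, `sigma2_e`, `sigma2_p`, `h2`,
#'   `se` (named vector), `logL` (-2 logL at optimum, constant dropped),
#'   `boundary` flag, `em_trace` (matrix of EM iterates, possibly 0 rows),
#'   `n`, `p`, `q`.
#' @export
reml_univariate <- function(y, X, Z, Ainv, start = NULL, tol = 1e-12,
                            max_iter = 50L, em_limit = 600L,
                            compute_se = TRUE) {
  parts <- mme_parts(y, X, Z, Ainv)
  if (is.null(start)) {
    sv <- starting_values(stats::var(y))
    start <- list(G0 = sv$G0, E0 = sv$E0)
  }
  s2a <- as.numeric(start$G0)[1]
  s2e <- as.numeric(start$E0)[1]
  if (s2a <= 0 || s2e <= 0) stop("starting components must be positive")

  em_trace <- NULL
  if (parts$p + parts$q <= em_limit && max_iter > 0) {
    tr <- matrix(NA_real_, max_iter, 3,
                 dimnames = list(NULL, c("sigma2_a", "sigma2_e", "neg2logL")))
    for (it in seq_len(max_iter)) {
      val <- neg2_reml_uni(parts, s2a, s2e)
      tr[it, ] <- c(s2a, s2e, val)
      upd <- em_step_uni(parts, s2a, s2e)
      rel <- max(abs(upd - c(s2a, s2e)) / pmax(abs(c(s2a, s2e)), 1e-12))
      s2a <- upd[["sigma2_a"]]
      s2e <- upd[["sigma2_e"]]
      if (rel < 1e-6) break  # hand over to the profiled search
    }
    em_trace <- tr[!is.na(tr[, 1]), , drop = FALSE]
  }

  # Brent on h2, then quadratic refinement to the 1e-12 criterion
  f <- function(h2) as.numeric(neg2_profiled(parts, h2))
  lo <- 1e-6
  hi <- 1 - 1e-6
  opt <- stats::optimize(f, c(lo, hi), tol = 1e-9)
  h2 <- opt$minimum
  fval <- opt$objective
  delta <- 1e-5
  for (it in seq_len(60)) {
    hm <- max(h2 - delta, lo)
    hp <- min(h2 + delta, hi)
    fm <- f(hm)
    fp <- f(hp)
    denom <- (fp - 2 * fval + fm)
    if (!is.finite(denom) || denom <= 0) break
    step <- 0.5 * (fm - fp) / denom * (hp - hm) / 2
    h2_new <- min(max(h2 + step, lo), hi)
    f_new <- f(h2_new)
    moved <- abs(f_new - fval) / max(abs(fval), 1)
    if (f_new < fval) {
      h2 <- h2_new
      fval <- f_new
    }
    delta <- delta / 4
    if (moved < tol && it > 2) break
  }
  prof <- neg2_profiled(parts, h2)
  s2e <- attr(prof, "sigma2_e")
  s2a <- s2e * h2 / (1 - h2)
  boundary <- h2 <= lo * 2
  if (boundary) {
    h2 <- 0
    s2a <- 0
  }

  se <- c(sigma2_a = NA_real_, sigma2_e = NA_real_, sigma2_p = NA_real_,
          h2 = NA_real_)
  if (compute_se && !boundary) {
    V <- reml_vcov(function(th) neg2_reml_uni(parts, th[1], th[2]),
                   c(s2a, s2e))
    if (!is.null(V)) {
      sp <- s2a + s2e
      grad_h2 <- c(s2e, -s2a) / sp^2
      se <- c(sigma2_a = sqrt(V[1, 1]), sigma2_e = sqrt(V[2, 2]),
              sigma2_p = sqrt(sum(V)),
              h2 = sqrt(drop(t(grad_h2) %*% V %*% grad_h2)))
    }
  }
  structure(list(sigma2_a = s2a, sigma2_e = s2e, sigma2_p = s2a + s2e,
                 h2 = if (boundary) 0 else s2a / (s2a + s2e),
                 se = se, logL = as.numeric(fval), boundary = boundary,
                 em_trace = em_trace, n = parts$n, p = parts$p,
                 q = parts$q),
            class = "caprigen_reml")
}

# Covariance of variance-component estimates from the finite-difference
# Hessian of -2 logL (observed information = H/2; vcov = 2 H^-1).
reml_vcov <- function(neg2fun, theta, rel_step = 1e-4) {
  k <- length(theta)
  h <- pmax(abs(theta), 1e-6) * rel_step
  H <- matrix(0, k, k)
  f0 <- neg2fun(theta)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        tp <- theta; tp[i] <- tp[i] + h[i]
        tm <- theta; tm[i] <- tm[i] - h[i]
        H[i, i] <- (neg2fun(tp) - 2 * f0 + neg2fun(tm)) / h[i]^2
      } else {
        tpp <- theta; tpp[c(i, j)] <- tpp[c(i, j)] + h[c(i, j)]
        tpm <- theta; tpm[i] <- tpm[i] + h[i]; tpm[j] <- tpm[j] - h[j]
        tmp <- theta; tmp[i] <- tmp[i] - h[i]; tmp[j] <- tmp[j] + h[j]
        tmm <- theta; tmm[c(i, j)] <- tmm[c(i, j)] - h[c(i, j)]
        H[i, j] <- H[j, i] <-
          (neg2fun(tpp) - neg2fun(tpm) - neg2fun(tmp) + neg2fun(tmm)) /
          (4 * h[i] * h[j])
      }
    }
  }
  V <- try(2 * solve(H), silent = TRUE)
  if (inherits(V, "try-error") || any(!is.finite(V)) ||
      any(diag(V) <= 0)) return(NULL)
  V
}

# Bivariate -2 logL (constant dropped); shared X and Z across the two
# traits. biv holds the precomputed pieces: general-storage C0/D0, the
# cross-products with both traits, and the shared symbolic factor.
biv_parts <- function(parts, Y) {
  C0g <- as(parts$C0, "generalMatrix")
  D0g <- as(parts$D0, "generalMatrix")
  B <- matrix(c(1, 0.3, 0.3, 1), 2, 2)  # pattern-complete PD multiplier
  pat <- Matrix::forceSymmetric(kronecker(B, C0g) + kronecker(B, D0g))
  list(C0g = C0g, D0g = D0g,
       chol2 = Matrix::Cholesky(pat, LDL = FALSE, perm = TRUE,
                                super = TRUE),
       WtY = as.matrix(Matrix::crossprod(parts$W, Y)),
       YtY = crossprod(Y))
}

neg2_reml_biv <- function(parts, biv, G, E) {
  Einv <- try(solve(E), silent = TRUE)
  Ginv <- try(solve(G), silent = TRUE)
  if (inherits(Einv, "try-error") || inherits(Ginv, "try-error")) {
    return(1e10)
  }
  C <- Matrix::forceSymmetric(kronecker(Einv, biv$C0g) +
                                kronecker(Ginv, biv$D0g))
  ch <- tryCatch(suppressWarnings(Matrix::update(biv$chol2, C)),
                 error = function(e) NULL)
  if (is.null(ch)) return(1e10)  # outside the PD region numerically
  rhs <- as.vector(biv$WtY %*% Einv)
  sol <- as.numeric(Matrix::solve(ch, rhs))
  logdetC <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
  yRy <- sum(Einv * biv$YtY)
  val <- parts$n * as.numeric(determinant(E)$modulus) +
    parts$q * as.numeric(determinant(G)$modulus) +
    2 * parts$logdet_A + logdetC + yRy - sum(sol * rhs)
  attr(val, "sol") <- sol
  val
}

biv_theta_to_mats <- function(phi) {
  # clamp so extreme optimizer excursions cannot make G or E singular
  v <- pmin(pmax(phi[c(1, 2, 4, 5)], -25), 25)
  z <- pmin(pmax(phi[c(3, 6)], -8), 8)
  g11 <- exp(v[1]); g22 <- exp(v[2]); rg <- tanh(z[1])
  e11 <- exp(v[3]); e22 <- exp(v[4]); re <- tanh(z[2])
  list(G = matrix(c(g11, rg * sqrt(g11 * g22),
                    rg * sqrt(g11 * g22), g22), 2, 2),
       E = matrix(c(e11, re * sqrt(e11 * e22),
                    re * sqrt(e11 * e22), e22), 2, 2))
}

#' Bivariate animal-model REML
#'
#' Two traits measured on the same records share `X` and `Z`; the 2x2
#' genetic (G) and residual (E) covariance matrices are estimated by
#' direct restricted-likelihood maximization over a log-variance /
#' Fisher-z parameterization (which keeps every iterate inside the
#' admissible cone, so no mid-iteration bending is needed). Starting
#' values default to univariate REML fits of each trait with the sample
#' phenotypic correlation split between G and E.
#'
#' @param Y numeric matrix n x 2 (one column per trait).
#' @param X,Z,Ainv from [build_design()].
#' @param start optional list with `G0`, `E0` 2x2 matrices.
#' @param tol relative convergence criterion on -2 logL (default 1e-12).
#' @param max_eval Nelder-Mead evaluation budget.
#' @param compute_se delta-method SEs for the correlations (numerical
#'   information over the six covariance parameters).
#' @return list: `G`, `E`, `P`, `r_g`, `r_p`, `r_e`, `h2` (length 2),
#'   `se` (for r_g, r_p, r_e when computed), `logL`, `convergence`.
#' @export
reml_bivariate <- function(Y, X, Z, Ainv, start = NULL, tol = 1e-12,
                           max_eval = 1500L, compute_se = FALSE) {
  Y <- as.matrix(Y)
  stopifnot(ncol(Y) == 2)
  parts <- mme_parts(Y[, 1], X, Z, Ainv)
  biv <- biv_parts(parts, Y)

  if (is.null(start)) {
    u1 <- reml_univariate(Y[, 1], X, Z, Ainv, compute_se = FALSE,
                          em_limit = 0)
    u2 <- reml_univariate(Y[, 2], X, Z, Ainv, compute_se = FALSE,
                          em_limit = 0)
    rp <- stats::cor(Y[, 1], Y[, 2])
    g11 <- max(u1$sigma2_a, 1e-4 * stats::var(Y[, 1]))
    g22 <- max(u2$sigma2_a, 1e-4 * stats::var(Y[, 2]))
    start <- list(
      G0 = matrix(c(g11, rp * sqrt(g11 * g22),
                    rp * sqrt(g11 * g22), g22), 2, 2),
      E0 = matrix(c(u1$sigma2_e, rp * sqrt(u1$sigma2_e * u2$sigma2_e),
                    rp * sqrt(u1$sigma2_e * u2$sigma2_e), u2$sigma2_e),
                  2, 2))
  }
  cor0 <- function(m) {
    r <- m[1, 2] / sqrt(m[1, 1] * m[2, 2])
    min(max(r, -0.99), 0.99)
  }
  phi0 <- c(log(start$G0[1, 1]), log(start$G0[2, 2]), atanh(cor0(start$G0)),
            log(start$E0[1, 1]), log(start$E0[2, 2]), atanh(cor0(start$E0)))
  fn <- function(phi) {
    m <- biv_theta_to_mats(phi)
    as.numeric(neg2_reml_biv(parts, biv, m$G, m$E))
  }
  # stage 1: Nelder-Mead to a coarse basin; stage 2: quasi-Newton with
  # central-difference gradients pushed past the tol criterion on -2 logL
  # (an order of magnitude cheaper than asking the simplex for 1e-12)
  nm <- stats::optim(phi0, fn, method = "Nelder-Mead",
                     control = list(maxit = min(max_eval, 250L),
                                    reltol = 1e-4))
  bf <- stats::optim(nm$par, fn, method = "BFGS",
                     control = list(maxit = 150,
                                    reltol = min(tol, 1e-15),
                                    ndeps = rep(1e-5, length(nm$par))))
  opt <- if (bf$value <= nm$value) bf else nm
  m <- biv_theta_to_mats(opt$par)
  G <- m$G
  E <- m$E
  P <- G + E
  r_g <- G[1, 2] / sqrt(G[1, 1] * G[2, 2])
  r_p <- P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  r_e <- E[1, 2] / sqrt(E[1, 1] * E[2, 2])
  se <- NULL
  if (compute_se) {
    pack <- function(th) {
      Gm <- matrix(c(th[1], th[2], th[2], th[3]), 2, 2)
      Em <- matrix(c(th[4], th[5], th[5], th[6]), 2, 2)
      as.numeric(neg2_reml_biv(parts, biv, Gm, Em))
    }
    th0 <- c(G[1, 1], G[1, 2], G[2, 2], E[1, 1], E[1, 2], E[2, 2])
    V <- reml_vcov(pack, th0)
    if (!is.null(V)) {
      num_grad <- function(g) {
        vapply(seq_along(th0), function(i) {
          h <- pmax(abs(th0[i]), 1e-6) * 1e-5
          tp <- th0; tp[i] <- tp[i] + h
          tm <- th0; tm[i] <- tm[i] - h
          (g(tp) - g(tm)) / (2 * h)
        }, 0)
      }
      corr_of <- function(th, which) {
        Gm <- matrix(c(th[1], th[2], th[2], th[3]), 2, 2)
        Em <- matrix(c(th[4], th[5], th[5], th[6]), 2, 2)
        Pm <- Gm + Em
        switch(which,
               r_g = Gm[1, 2] / sqrt(Gm[1, 1] * Gm[2, 2]),
               r_p = Pm[1, 2] / sqrt(Pm[1, 1] * Pm[2, 2]),
               r_e = Em[1, 2] / sqrt(Em[1, 1] * Em[2, 2]))
      }
      se <- vapply(c(r_g = "r_g", r_p = "r_p", r_e = "r_e"), function(w) {
        gr <- num_grad(function(th) corr_of(th, w))
        sqrt(max(drop(t(gr) %*% V %*% gr), 0))
      }, 0)
    }
  }
  list(G = G, E = E, P = P, r_g = r_g, r_p = r_p, r_e = r_e,
       h2 = diag(G) / diag(P), se = se, logL = opt$value,
       convergence = opt$convergence)
}

#' Solve the mixed-model equations at given components
#'
#' Sparse symmetric solve of
#' `[X'X  X'Z; Z'X  Z'Z + lambda Ainv] [b; a] = [X'y; Z'y]`,
#' `lambda = sigma2_e / sigma2_a`, yielding BLUE fixed-effect solutions
#' (under the full-rank coding `build_design` produced) and BLUP breeding
#' values for every pedigree animal. Reliabilities
#' `1 - PEV_i / (sigma2_a (1 + F_i))` need the diagonal of the inverse and
#' are only computed when the system is small enough to invert densely.
#'
#' @param y,X,Z,Ainv from [build_design()].
#' @param sigma2_a,sigma2_e converged variance components.
#' @param reliabilities compute per-animal reliabilities (dense inverse;
#'   refused above `rel_limit`).
#' @param rel_limit dense-inverse guard (default 3000 equations).
#' @param f optional inbreeding vector for the reliability denominator
#'   (defaults to 0, i.e. `a_ii = 1`).
#' @return list: `blue` (named), `blup` (named, all pedigree animals),
#'   `reliability` (or NULL).
#' @export
solve_mme <- function(y, X, Z, Ainv, sigma2_a, sigma2_e,
                      reliabilities = FALSE, rel_limit = 3000L, f = NULL) {
  stopifnot(sigma2_a > 0, sigma2_e > 0)
  parts <- mme_parts(y, X, Z, Ainv)
  ms <- mme_solve_lambda(parts, sigma2_e / sigma2_a,
                         keep_matrix = reliabilities)
  b <- ms$sol[seq_len(parts$p)]
  names(b) <- colnames(X)
  u <- ms$sol[(parts$p + 1):(parts$p + parts$q)]
  names(u) <- colnames(Z)
  rel <- NULL
  if (reliabilities) {
    if (parts$p + parts$q > rel_limit) {
      stop("system too large for dense reliabilities (", parts$p + parts$q,
           " > rel_limit)")
    }
    Minv <- chol2inv(chol(as.matrix(ms$M)))
    pev <- sigma2_e * diag(Minv)[(parts$p + 1):(parts$p + parts$q)]
    aii <- 1 + (if (is.null(f)) 0 else f)
    rel <- pmax(0, pmin(1, 1 - pev / (sigma2_a * aii)))
    names(rel) <- colnames(Z)
  }
  list(blue = b, blup = u, reliability = rel)
}
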