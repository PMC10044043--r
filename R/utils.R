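#' Round half away from zero
#'
#' Commercial rounding: 0.5 -> 1, -0.5 -> -1. Used wherever a continuous
#' quantity is mapped onto integer appraisal points, since [base::round()]
#' rounds half to even.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bend a covariance matrix to the nearest positive semidefinite matrix
#'
#' Eigenvalues below `eps` are raised to `eps` and the matrix rebuilt.
#' Published variance/correlation tables assembled pairwise are routinely
#' indefinite; bending is the standard repair before they can be used as a
#' simulation truth or REML start.
#'
#' @param m symmetric numeric matrix.
#' @param eps smallest admissible eigenvalue (default 1e-8 times the largest).
#' @return list with `mat` (bent matrix), `shift` (largest eigenvalue raise
#'   applied, 0 when `m` was already PSD) and `bent` (logical).
#' @export
bend_psd <- function(m, eps = NULL) {
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE)
  if (is.null(eps)) eps <- max(ev$values) * 1e-8
  bad <- ev$values < eps
  if (!any(bad)) {
    return(list(mat = m, shift = 0, bent = FALSE))
  }
  shift <- max(eps - ev$values[bad])
  vals <- pmax(ev$values, eps)
  out <- ev$vectors %*% (vals * t(ev$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(m)
  list(mat = out, shift = shift, bent = TRUE)
}
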