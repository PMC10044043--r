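#' Pedigree objects
#'
#' A `caprigen_pedigree` is a data frame with columns `id`, `sire`, `dam`
#' (character; `NA` for unknown parents), optional `birth_date` (`Date`) and
#' `sex` (`"M"`, `"F"` or `NA`), sorted so every parent precedes its
#' offspring. Animals appearing only as parents are inserted as founders.
#'
#' @name caprigen_pedigree
NULL

new_pedigree <- function(df) {
  structure(df, class = c("caprigen_pedigree", "data.frame"))
}

#' Validate and topologically sort a pedigree
#'
#' @param id,sire,dam character vectors; unknown parents as `NA`, `""` or `"0"`.
#' @param birth_date optional `Date` vector.
#' @param sex optional vector, normalized to `"M"`/`"F"` (anything starting
#'   with m/M male, f/F or h/H (hembra) female, otherwise `NA`).
#' @return a [caprigen_pedigree] sorted parents-before-offspring.
#' @details Duplicated ids and ancestry cycles are hard errors naming the
#'   offending animals. Parents never listed as animals are auto-inserted as
#'   founders with a warning.
#' @export
pedigree <- function(id, sire = NA, dam = NA, birth_date = NULL, sex = NULL) {
  id <- as.character(id)
  norm_parent <- function(p) {
    p <- as.character(p)
    p[!is.na(p) & (p == "" | p == "0")] <- NA_character_
    p
  }
  sire <- rep_len(norm_parent(sire), length(id))
  dam <- rep_len(norm_parent(dam), length(id))
  if (anyDuplicated(id)) {
    stop("duplicated animal id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  sex <- if (is.null(sex)) rep(NA_character_, length(id)) else normalize_sex(sex)
  if (is.null(birth_date)) birth_date <- rep(as.Date(NA), length(id))

  df <- data.frame(id = id, sire = sire, dam = dam,
                   birth_date = as.Date(birth_date), sex = sex,
                   stringsAsFactors = FALSE)

  parents <- setdiff(stats::na.omit(c(df$sire, df$dam)), df$id)
  if (length(parents)) {
    warning("inserting ", length(parents),
            " parent(s) never listed as animals as founders: ",
            paste(utils::head(parents, 5), collapse = ", "),
            if (length(parents) > 5) ", ..." else "")
    df <- rbind(data.frame(id = parents, sire = NA_character_,
                           dam = NA_character_, birth_date = as.Date(NA),
                           sex = NA_character_, stringsAsFactors = FALSE),
                df)
  }
  new_pedigree(toposort_pedigree(df))
}

normalize_sex <- function(sex) {
  s <- toupper(substr(as.character(sex), 1, 1))
  out <- rep(NA_character_, length(s))
  out[s %in% "M"] <- "M"
  out[s %in% c("F", "H")] <- "F"
  out
}

# Kahn's algorithm; reports a cycle (the unplaceable residue) on failure.
toposort_pedigree <- function(df) {
  n <- nrow(df)
  idx <- seq_len(n)
  names(idx) <- df$id
  si <- unname(idx[df$sire])
  di <- unname(idx[df$dam])
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  order <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    i <- queue[1]
    queue <- queue[-1]
    order <- c(order, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(order) < n) {
    stuck <- df$id[setdiff(seq_len(n), order)]
    stop("pedigree contains a cycle involving: ",
         paste(stuck, collapse = " <-> "))
  }
  df <- df[order, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a pedigree file
#'
#' Delimited text (comma or tab autodetected), header required. Unknown
#' parents may be coded `0` or left empty.
#'
#' @param path file path.
#' @param columns named character vector mapping the roles `id`, `sire`,
#'   `dam` and optionally `birth_date`, `sex` to column names in the file.
#' @param date_format passed to [as.Date()]; default ISO `"%Y-%m-%d"`.
#' @return a [caprigen_pedigree].
#' @export
read_pedigree <- function(path,
                          columns = c(id = "id", sire = "sire", dam = "dam"),
                          date_format = "%Y-%m-%d") {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("id", "sire", "dam")
  missing_roles <- setdiff(need, names(columns))
  if (length(missing_roles)) {
    stop("column mapping must name: ", paste(missing_roles, collapse = ", "))
  }
  absent <- setdiff(unname(columns), names(tab))
  if (length(absent)) {
    stop("columns not present in file: ", paste(absent, collapse = ", "))
  }
  bd <- if ("birth_date" %in% names(columns)) {
    as.Date(tab[[columns[["birth_date"]]]], format = date_format)
  } else NULL
  sx <- if ("sex" %in% names(columns)) tab[[columns[["sex"]]]] else NULL
  pedigree(id = tab[[columns[["id"]]]],
           sire = tab[[columns[["sire"]]]],
           dam = tab[[columns[["dam"]]]],
           birth_date = bd, sex = sx)
}

parent_index <- function(ped) {
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$id
  list(sire = unname(idx[ped$sire]), dam = unname(idx[ped$dam]))
}

#' Numerator relationship matrix (tabular method)
#'
#' Wright's additive relationships computed recursively in pedigree order:
#' `a_ii = 1 + a_sd / 2`, `a_ij = (a_js + a_jd) / 2` for `j < i`, with unknown
#' parents contributing zero. Dense; refuse pedigrees beyond `max_animals`
#' (the matrix is quadratic — large pedigrees only ever need the sparse
#' inverse, see [a_inverse()]).
#'
#' @param ped a [caprigen_pedigree].
#' @param max_animals dense-size guard, default 5000.
#' @return symmetric matrix with dimnames = animal ids. Diagonal is `1 + F`.
#' @export
relationship_matrix <- function(ped, max_animals = 5000) {
  n <- nrow(ped)
  if (n > max_animals) {
    stop("refusing to build a dense ", n, "x", n,
         " relationship matrix (max_animals = ", max_animals, ")")
  }
  pi <- parent_index(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- pi$sire[i]
    d <- pi$dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (is.na(s)) 0 else A[j, s]
      ad_ <- if (is.na(d)) 0 else A[j, d]
      A[j, i] <- A[i, j] <- (as_ + ad_) / 2
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else A[s, d] / 2
  }
  A
}

#' Inbreeding coefficients without materializing A
#'
#' `F_i` is the kinship of the parents, computed by recursive coancestry with
#' memoization; founders and animals with an unknown parent get `F = 0`
#' (unknown parents are treated as unique unrelated founders).
#'
#' @param ped a [caprigen_pedigree].
#' @return named numeric vector of inbreeding coefficients in pedigree order.
#' @export
inbreeding <- function(ped) {
  n <- nrow(ped)
  pi <- parent_index(ped)
  si <- pi$sire
  di <- pi$dam
  memo <- new.env(hash = TRUE, parent = emptyenv())
  Fcoef <- numeric(n)

  kin <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste0(i, ":", j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (i == j) {
      (1 + kin(si[i], di[i])) / 2
    } else {
      # j is the later-born animal: recurse through j's parents
      (kin(i, si[j]) + kin(i, di[j])) / 2
    }
    memo[[key]] <- val
    val
  }

  for (i in seq_len(n)) {
    Fcoef[i] <- if (is.na(si[i]) || is.na(di[i])) 0 else kin(si[i], di[i])
  }
  names(Fcoef) <- ped$id
  Fcoef
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with Quaas' inbreeding adjustment. Per animal the
#' Mendelian-sampling variance is
#' `d = 1/2 - (F_s + F_d)/4` (both parents known), `3/4 - F_p/4` (one known)
#' or `1` (founder); contributions `1/d` on `(i,i)`, `-1/(2d)` on `(i,parent)`
#' and `1/(4d)` among known parents are accumulated into a sparse matrix.
#'
#' @param ped a [caprigen_pedigree].
#' @param f optional precomputed [inbreeding()] vector.
#' @return a [Matrix::dsCMatrix] with attribute `"logdet_A"` holding
#'   `log|A| = sum(log d_i)` (free by-product, used by the REML routines).
#' @export
a_inverse <- function(ped, f = NULL) {
  n <- nrow(ped)
  if (is.null(f)) f <- inbreeding(ped)
  pi <- parent_index(ped)
  ii <- jj <- integer(0)
  xx <- numeric(0)
  dvec <- numeric(n)
  for (i in seq_len(n)) {
    s <- pi$sire[i]
    d <- pi$dam[i]
    ks <- !is.na(s)
    kd <- !is.na(d)
    dm <- 1 - 0.25 * ((if (ks) 1 + f[s] else 0) + (if (kd) 1 + f[d] else 0))
    dvec[i] <- dm
    w <- 1 / dm
    ii <- c(ii, i); jj <- c(jj, i); xx <- c(xx, w)
    for (p in c(if (ks) s, if (kd) d)) {
      ii <- c(ii, i, p); jj <- c(jj, p, i); xx <- c(xx, -w / 2, -w / 2)
    }
    if (ks) { ii <- c(ii, s); jj <- c(jj, s); xx <- c(xx, w / 4) }
    if (kd) { ii <- c(ii, d); jj <- c(jj, d); xx <- c(xx, w / 4) }
    if (ks && kd) {
      ii <- c(ii, s, d); jj <- c(jj, d, s); xx <- c(xx, w / 4, w / 4)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  Ainv <- Matrix::forceSymmetric(Ainv)
  attr(Ainv, "logdet_A") <- sum(log(dvec))
  Ainv
}

#' Gene-dropping estimate of inbreeding
#'
#' Monte-Carlo oracle: founder animals receive two unique alleles, each
#' descendant inherits one allele per parent uniformly; `F` is the frequency
#' of identical-by-descent allele pairs across drops. Used to validate the
#' deterministic pedigree algebra.
#'
#' @param ped a [caprigen_pedigree].
#' @param n_drops number of replicate gene drops.
#' @param seed RNG seed.
#' @return named vector of Monte-Carlo inbreeding estimates.
#' @export
gene_drop_inbreeding <- function(ped, n_drops = 1e5, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  pi <- parent_index(ped)
  a1 <- matrix(0L, n, n_drops)
  a2 <- matrix(0L, n, n_drops)
  next_allele <- 1L
  for (i in seq_len(n)) {
    s <- pi$sire[i]
    d <- pi$dam[i]
    if (is.na(s)) {
      a1[i, ] <- next_allele
      next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      a1[i, ] <- ifelse(pick, a1[s, ], a2[s, ])
    }
    if (is.na(d)) {
      a2[i, ] <- next_allele
      next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      a2[i, ] <- ifelse(pick, a1[d, ], a2[d, ])
    }
  }
  out <- rowMeans(a1 == a2)
  names(out) <- ped$id
  out
}
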