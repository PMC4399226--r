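#' Standardize genotype dosages
#'
#' Centres and scales each marker column to unit variance under
#' Hardy-Weinberg expectations: `w_std = (w - 2p) / sqrt(2 p (1 - p))` with
#' `p` the allele frequency of the marker. Monomorphic markers (p = 0 or 1 in
#' the standardising population) cannot be scaled and are excluded and
#' flagged.
#'
#' @param g a [genotype_set()].
#' @param freq optional per-marker allele frequencies to standardise against
#'   (e.g. training-population frequencies when standardising validation
#'   animals). Default: frequencies computed from `g` itself, in which case
#'   every kept column has mean zero.
#' @return object of class `std_genotypes`: list with `W` (animals x kept
#'   markers), `freq` (kept frequencies), `kept` (logical mask over the input
#'   markers), `map` (kept marker map), `dosages` (kept raw dosages), `breed`.
#' @export
standardize_genotypes <- function(g, freq = NULL) {
  stopifnot(inherits(g, "genotype_set"))
  own <- is.null(freq)
  if (own) freq <- colMeans(g$dosages) / 2
  if (length(freq) != ncol(g$dosages)) {
    stop("freq length must match marker count", call. = FALSE)
  }
  kept <- freq > 0 & freq < 1
  if (!any(kept)) stop("all markers are monomorphic", call. = FALSE)
  p <- freq[kept]
  W <- sweep(g$dosages[, kept, drop = FALSE], 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  structure(list(W = W, freq = p, kept = kept, map = g$map[kept, ],
                 dosages = g$dosages[, kept, drop = FALSE], breed = g$breed),
            class = "std_genotypes")
}

#' Genomic relationship matrix
#'
#' Off-diagonals are always the mean cross-product of standardized genotypes,
#' `G_jk = (1/m) sum_l w_jl w_kl`. Two diagonals are offered: `"plain"` uses
#' the same cross-product (G = WW'/m exactly), while `"yang"` replaces the
#' self-relationship with `1 + f_hat`, `f_hat = (1/m) sum_l (x^2 - (1+2p)x +
#' 2p^2) / (2p(1-p))` computed from raw dosages `x` — an estimator whose
#' expectation removes the sampling inflation of the plain diagonal.
#'
#' @param sg a [standardize_genotypes()] result.
#' @param method `"yang"` (default) or `"plain"`.
#' @return object of class `grm`: list with `G`, marker count `m`, `method`,
#'   animal `ids`.
#' @export
compute_grm <- function(sg, method = c("yang", "plain")) {
  method <- match.arg(method)
  m <- ncol(sg$W)
  if (m < 1) stop("need at least one kept marker", call. = FALSE)
  G <- tcrossprod(sg$W) / m
  if (method == "yang") {
    x <- sg$dosages
    p <- sg$freq
    num <- x^2 - sweep(x, 2, 1 + 2 * p, "*") +
      matrix(rep(2 * p^2, each = nrow(x)), nrow(x))
    fhat <- rowMeans(sweep(num, 2, 2 * p * (1 - p), "/"))
    diag(G) <- 1 + fhat
  }
  structure(list(G = (G + t(G)) / 2, m = m, method = method,
                 ids = rownames(sg$W)),
            class = "grm")
}

#' Invert a GRM with ridge stabilisation if needed
#'
#' @param grm a [compute_grm()] result.
#' @param ridge diagonal added when the matrix is numerically singular.
#' @return inverse matrix.
#' @export
invert_grm <- function(grm, ridge = 1e-6) {
  G <- grm$G
  inv <- tryCatch(chol2inv(chol(G)), error = function(e) NULL)
  if (is.null(inv)) {
    message("GRM numerically singular; adding ridge ", ridge, " to diagonal")
    inv <- chol2inv(chol(G + diag(ridge, nrow(G))))
  }
  dimnames(inv) <- dimnames(G)
  inv
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Recursive tabular construction including inbreeding: processing animals in
#' topological order, `A[j, i] = 0.5 (A[j, s] + A[j, d])` for `j < i` and
#' `A[i, i] = 1 + 0.5 A[s, d]` (unknown parents contribute 0).
#'
#' @param ped pedigree tibble (sorted or not; sorted internally).
#' @return object of class `nrm`: list with dense `A`, inbreeding vector `f`,
#'   and `ids` in sorted pedigree order.
#' @export
compute_nrm <- function(ped) {
  ped <- sort_pedigree(ped)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$animal_id)
  si <- unname(idx[ped$sire_id]); di <- unname(idx[ped$dam_id])
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      as_ <- if (is.na(s)) 0 else A[j, s]
      ad_ <- if (is.na(d)) 0 else A[j, d]
      A[j, i] <- A[i, j] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d]
  }
  dimnames(A) <- list(ped$animal_id, ped$animal_id)
  structure(list(A = A, f = diag(A) - 1, ids = ped$animal_id), class = "nrm")
}

#' Sparse inverse of the numerator relationship matrix (Henderson's rules)
#'
#' Builds A-inverse directly from the pedigree with inbreeding accounted for:
#' each animal contributes `alpha = 1/d_i` where `d_i` is its Mendelian
#' sampling variance, `d_i = 0.5 - 0.25 (F_s + F_d)` with both parents known,
#' `0.75 - 0.25 F_p` with one, `1` with none. Inbreeding coefficients come
#' from the tabular A diagonal.
#'
#' @param ped pedigree tibble.
#' @return list with sparse `Ainv` (`Matrix::dsCMatrix`), `ids`, `f`.
#' @export
compute_nrm_inverse <- function(ped) {
  ped <- sort_pedigree(ped)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$animal_id)
  si <- unname(idx[ped$sire_id]); di <- unname(idx[ped$dam_id])
  f <- compute_nrm(ped)$f
  ii <- integer(0); jj <- integer(0); xx <- double(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    dm <- if (!is.na(s) && !is.na(d)) 0.5 - 0.25 * (f[s] + f[d])
    else if (!is.na(s)) 0.75 - 0.25 * f[s]
    else if (!is.na(d)) 0.75 - 0.25 * f[d]
    else 1
    al <- 1 / dm
    add(i, i, al)
    for (p in c(s, d)) {
      if (!is.na(p)) {
        add(i, p, -al / 2); add(p, i, -al / 2)
        add(p, p, al / 4)
      }
    }
    if (!is.na(s) && !is.na(d)) {
      add(s, d, al / 4); add(d, s, al / 4)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal_id, ped$animal_id))
  list(Ainv = Matrix::forceSymmetric(Ainv), ids = ped$animal_id, f = f)
}

#' Export a GRM as a long-format lower-triangle TSV
#'
#' One row per ordered pair (`id1`, `id2`, `value`), diagonal included
#' (GCTA-style id pairs).
#'
#' @param grm a [compute_grm()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_grm_tsv <- function(grm, path) {
  n <- nrow(grm$G)
  lt <- which(lower.tri(grm$G, diag = TRUE), arr.ind = TRUE)
  out <- tibble(id1 = grm$ids[lt[, 1]], id2 = grm$ids[lt[, 2]],
                value = grm$G[lt])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
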