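#' Fixed-effect design matrix: mean, breed, sex nested within breed
#'
#' Treatment (reference-level) coding with the first level dropped; columns
#' that are linearly dependent after the drop (e.g. a breed with a single sex)
#' are removed so the design is full column rank.
#'
#' @param phenos phenotype tibble with `breed` and `sex` columns.
#' @return numeric design matrix with an intercept.
#' @export
fixed_design <- function(phenos) {
  breed <- factor(phenos$breed)
  sex <- factor(phenos$sex)
  df <- data.frame(breed = breed, sex = sex)
  if (nlevels(breed) > 1 && nlevels(sex) > 1) {
    X <- model.matrix(~ breed + breed:sex, df)
  } else if (nlevels(breed) > 1) {
    X <- model.matrix(~ breed, df)
  } else if (nlevels(sex) > 1) {
    X <- model.matrix(~ sex, df)
  } else {
    X <- matrix(1, nrow(phenos), 1, dimnames = list(NULL, "(Intercept)"))
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  X
}

incidence <- function(ids, levels) {
  j <- match(ids, levels)
  if (anyNA(j)) {
    stop("record animal '", ids[which(is.na(j))[1]],
         "' not found among effect levels", call. = FALSE)
  }
  Z <- matrix(0, length(ids), length(levels))
  Z[cbind(seq_along(ids), j)] <- 1
  colnames(Z) <- levels
  Z
}

#' Solve the weighted mixed-model equations
#'
#' Solves the (up to) three-block system for fixed effects `b`, pedigree
#' polygenic values `a` and genomic values `g` in
#' `y = Xb + Za + Qg + e`, `a ~ N(0, A sigma2_a)`, `g ~ N(0, G sigma2_g)`,
#' `e ~ N(0, E sigma2_e)`, i.e. the normal equations with
#' `R^-1 = E^-1 sigma2_e^-1`, `A^-1 sigma2_a^-1` and `G^-1 sigma2_g^-1` added
#' to the respective diagonal blocks. Either random block may be omitted.
#'
#' @param y phenotype vector (length n).
#' @param X fixed design (n x p, full column rank).
#' @param weights per-record weights `w_i` (`E_ii = 1/w_i`); default 1.
#' @param sigma2_e residual variance.
#' @param Z,Ainv,sigma2_a polygenic block: n x q incidence, sparse or dense
#'   A-inverse, polygenic variance. All NULL to omit.
#' @param Q,Ginv,sigma2_g genomic block: n x ng incidence, GRM inverse,
#'   genomic variance. All NULL to omit.
#' @return list with `b`, `a`, `g` (named numeric vectors; zero-length when a
#'   block is absent) and `residual_max`, the largest absolute residual of the
#'   assembled normal equations at the solution.
#' @export
solve_mme <- function(y, X, weights = NULL, sigma2_e,
                      Z = NULL, Ainv = NULL, sigma2_a = NULL,
                      Q = NULL, Ginv = NULL, sigma2_g = NULL) {
  n <- length(y)
  X <- as.matrix(X)
  if (is.null(weights)) weights <- rep(1, n)
  d <- weights / sigma2_e  # R^-1 diagonal
  has_a <- !is.null(Z)
  has_g <- !is.null(Q)
  blocks <- list(X = X)
  if (has_a) blocks$Z <- as.matrix(Z)
  if (has_g) blocks$Q <- as.matrix(Q)
  nb <- length(blocks)
  sizes <- vapply(blocks, ncol, 0L)
  C <- matrix(0, sum(sizes), sum(sizes))
  rhs <- numeric(sum(sizes))
  off <- c(0, cumsum(sizes))
  for (i in seq_len(nb)) {
    ri <- (off[i] + 1):off[i + 1]
    rhs[ri] <- crossprod(blocks[[i]], d * y)
    for (j in i:nb) {
      rj <- (off[j] + 1):off[j + 1]
      Cij <- crossprod(blocks[[i]], d * blocks[[j]])
      C[ri, rj] <- Cij
      if (j > i) C[rj, ri] <- t(Cij)
    }
  }
  if (has_a) {
    ia <- which(names(blocks) == "Z")
    ri <- (off[ia] + 1):off[ia + 1]
    C[ri, ri] <- C[ri, ri] + as.matrix(Ainv) / sigma2_a
  }
  if (has_g) {
    ig <- which(names(blocks) == "Q")
    ri <- (off[ig] + 1):off[ig + 1]
    C[ri, ri] <- C[ri, ri] + as.matrix(Ginv) / sigma2_g
  }
  if (nrow(C) > 20000) {
    stop("mixed-model system exceeds 20000 equations; this solver is ",
         "dense-direct only - reduce the model or use a dedicated solver",
         call. = FALSE)
  }
  sol <- tryCatch(solve(C, rhs), error = function(e) {
    stop("singular mixed-model coefficient matrix; check the design for ",
         "rank deficiency or add a small ridge to G", call. = FALSE)
  })
  residual_max <- max(abs(C %*% sol - rhs))
  out <- list(b = setNames(sol[(off[1] + 1):off[2]], colnames(X)),
              a = numeric(0), g = numeric(0), residual_max = residual_max)
  if (has_a) {
    ia <- which(names(blocks) == "Z")
    out$a <- setNames(sol[(off[ia] + 1):off[ia + 1]], colnames(blocks$Z))
  }
  if (has_g) {
    ig <- which(names(blocks) == "Q")
    out$g <- setNames(sol[(off[ig] + 1):off[ig + 1]], colnames(blocks$Q))
  }
  out
}

#' Back-solve SNP effects from genomic breeding values
#'
#' `v_hat = (1/m) W' G^-1 g_hat`. With the plain cross-product GRM
#' (`G = WW'/m`) the reconstruction `W v_hat = g_hat` is exact; with the
#' Yang-adjusted diagonal it is approximate, so plain is the recommended GRM
#' mode when effects are to be back-solved.
#'
#' @param g_hat genomic breeding values for the animals in `sg`/`grm` order.
#' @param sg the [standardize_genotypes()] result used to build the GRM.
#' @param grm the [compute_grm()] result.
#' @return named vector of per-marker effects.
#' @export
backsolve_snp_effects <- function(g_hat, sg, grm) {
  if (length(g_hat) != nrow(sg$W)) {
    stop("length(g_hat) must equal the number of animals in the ",
         "standardized genotypes", call. = FALSE)
  }
  if (nrow(grm$G) != nrow(sg$W) || grm$m != ncol(sg$W)) {
    stop("GRM was not built from these standardized genotypes",
         call. = FALSE)
  }
  Ginv <- invert_grm(grm)
  setNames(as.numeric(crossprod(sg$W, Ginv %*% g_hat)) / grm$m,
           colnames(sg$W))
}

#' Weighted GBLUP for one trait
#'
#' End-to-end fit: record weights, standardized genotypes and GRM from the
#' reference animals, EM-REML variance components (unless supplied), the
#' mixed-model equations, and back-solved SNP effects.
#'
#' @param genotypes a [genotype_set()] covering at least the phenotyped
#'   animals. Allele frequencies are computed from all animals supplied
#'   (reference plus any validation animals present).
#' @param phenotypes phenotype tibble; only rows for `trait` are used.
#' @param trait trait name to analyse.
#' @param pedigree optional pedigree tibble; supplying it adds the polygenic
#'   `a` term.
#' @param params trait parameters (tibble `trait`, `h2`, `t`); defaults to
#'   presets.
#' @param vc optional named variance components
#'   (`c(g = ..., e = ...[, a = ...])`) to skip REML.
#' @param grm_method `"plain"` (default, exact back-solving) or `"yang"`.
#' @param reml_args list passed on to [estimate_variance_components()].
#' @return object of class `gblup_fit`.
#' @export
gblup <- function(genotypes, phenotypes, trait, pedigree = NULL,
                  params = NULL, vc = NULL, grm_method = c("plain", "yang"),
                  reml_args = list()) {
  grm_method <- match.arg(grm_method)
  ph <- dplyr::filter(phenotypes, .data$trait == !!trait)
  if (!nrow(ph)) stop("no phenotype records for trait '", trait, "'",
                      call. = FALSE)
  ph <- residual_weights(ph, params)
  miss <- setdiff(ph$animal_id, rownames(genotypes$dosages))
  if (length(miss)) {
    stop("phenotyped animal(s) not genotyped: ",
         paste(head(miss, 3), collapse = ", "), call. = FALSE)
  }
  sg_all <- standardize_genotypes(genotypes)
  ref_ids <- ph$animal_id
  sg <- subset_std(sg_all, ref_ids)
  grm <- compute_grm(sg, method = grm_method)
  X <- fixed_design(ph)
  y <- ph$value
  w <- ph$w
  has_a <- !is.null(pedigree)
  Z <- NULL; Ainv <- NULL; ped_ids <- character(0)
  if (has_a) {
    ped <- sort_pedigree(pedigree)
    miss <- setdiff(ref_ids, ped$animal_id)
    if (length(miss)) {
      stop("phenotyped animal(s) missing from pedigree: ",
           paste(head(miss, 3), collapse = ", "), call. = FALSE)
    }
    nrm_inv <- compute_nrm_inverse(ped)
    ped_ids <- nrm_inv$ids
    Ainv <- as.matrix(nrm_inv$Ainv)
    Z <- incidence(ref_ids, ped_ids)
  }
  Q <- incidence(ref_ids, ref_ids)
  ZGZ <- grm$G  # Q is identity on reference order
  if (is.null(vc)) {
    random <- list(g = ZGZ)
    qvec <- c(g = length(ref_ids))
    if (has_a) {
      A <- compute_nrm(pedigree)$A[ref_ids, ref_ids]
      random <- c(list(a = A), random)
      qvec <- c(a = length(ref_ids), qvec)
    }
    vfit <- do.call(estimate_variance_components,
                    c(list(y = y, X = X, random = random, q = qvec,
                           e_diag = ph$e_diag), reml_args))
    vc <- setNames(vfit$components$estimate, vfit$components$term)
  } else {
    vfit <- NULL
    need <- c("g", "e", if (has_a) "a")
    if (!all(need %in% names(vc))) {
      stop("supplied vc must name components: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
  }
  Ginv <- invert_grm(grm)
  sol <- solve_mme(y, X, weights = w, sigma2_e = vc[["e"]],
                   Z = Z, Ainv = Ainv,
                   sigma2_a = if (has_a) vc[["a"]],
                   Q = Q, Ginv = Ginv, sigma2_g = vc[["g"]])
  v_hat <- backsolve_snp_effects(sol$g, sg, grm)
  structure(list(
    trait = trait,
    b = tibble(term = names(sol$b), estimate = unname(sol$b)),
    a = tibble(animal_id = names(sol$a), estimate = unname(sol$a)),
    g = tibble(animal_id = names(sol$g), gebv = unname(sol$g)),
    v = tibble(marker_id = names(v_hat), effect = unname(v_hat)),
    vc = vc, reml = vfit, freq = sg_all$freq, kept = sg_all$kept,
    map = sg$map, grm_method = grm_method,
    n = length(y), m = grm$m, mme_residual_max = sol$residual_max
  ), class = "gblup_fit")
}

#' Subset standardized genotypes by animal ids
#'
#' Keeps the standardisation (centring/scaling and kept-marker mask) of the
#' full set; use it to pull the reference or validation rows out of one
#' jointly standardized genotype set.
#'
#' @param sg a [standardize_genotypes()] result.
#' @param ids animal ids to keep, in the order given.
#' @return a `std_genotypes` object restricted to those animals.
#' @export
subset_std <- function(sg, ids) {
  i <- match(ids, rownames(sg$W))
  if (anyNA(i)) stop("animal(s) missing from standardized genotypes",
                     call. = FALSE)
  structure(list(W = sg$W[i, , drop = FALSE], freq = sg$freq, kept = sg$kept,
                 map = sg$map, dosages = sg$dosages[i, , drop = FALSE],
                 breed = sg$breed[i]), class = "std_genotypes")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat("<gblup_fit> trait", x$trait, "-", x$n, "records,", x$m, "markers;",
      "GRM:", x$grm_method, "\n")
  cat("variance components:",
      paste(names(x$vc), signif(unname(x$vc), 4), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' @rdname gblup
#' @param x a `gblup_fit`.
#' @param ... unused.
#' @export
tidy.gblup_fit <- function(x, ...) {
  dplyr::left_join(x$v, x$map, by = "marker_id")
}

#' @rdname gblup
#' @export
glance.gblup_fit <- function(x, ...) {
  tibble(trait = x$trait, n = x$n, m = x$m,
         sigma2_g = unname(x$vc["g"]), sigma2_e = unname(x$vc["e"]),
         sigma2_a = if ("a" %in% names(x$vc)) unname(x$vc["a"]) else NA_real_,
         mme_residual_max = x$mme_residual_max,
         reml_converged = if (is.null(x$reml)) NA else x$reml$converged)
}
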