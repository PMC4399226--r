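#' Mixture specification for the BayesR prior
#'
#' SNP effects are a priori drawn from a K-component normal mixture whose
#' component variances are fixed multiples of `sigma2_a2`, the additive
#' genetic variance explained by the pedigree. The default four components
#' use multipliers 0, 0.0001, 0.001 and 0.01; the zero component is an exact
#' point mass. Mixture proportions get a Dirichlet prior with one marker's
#' worth of prior count per component (`alpha = 1`).
#'
#' @param multipliers non-decreasing variance multipliers, first exactly 0.
#' @param alpha Dirichlet prior counts, all > 0.
#' @return object of class `mixture_spec`.
#' @export
mixture_spec <- function(multipliers = c(0, 1e-4, 1e-3, 1e-2),
                         alpha = rep(1, length(multipliers))) {
  if (multipliers[1] != 0) {
    stop("first mixture component must have multiplier 0 (the point mass)",
         call. = FALSE)
  }
  if (is.unsorted(multipliers)) {
    stop("mixture multipliers must be non-decreasing", call. = FALSE)
  }
  if (length(alpha) != length(multipliers) || any(alpha <= 0)) {
    stop("alpha must be positive and match the number of components",
         call. = FALSE)
  }
  structure(list(multipliers = as.numeric(multipliers),
                 alpha = as.numeric(alpha)),
            class = "mixture_spec")
}

# ---- full-conditional draws (reference R implementations) -------------------
# These mirror the C++ chain step for step; the unit tests check them against
# closed forms and Monte-Carlo moments, and the chain is checked end-to-end
# against the ridge and MME oracles.

#' Draw the residual variance from its full conditional
#'
#' Scaled inverse chi-squared draw `sigma2_e = e' E^-1 e / chisq_df` with
#' `E^-1 = diag(weights)`; `df = n - 2` by default. A zero quadratic form
#' returns 0 (degenerate scale); a negative one signals numerical corruption.
#'
#' @param e current residual vector.
#' @param weights per-record weights `w_i` (default 1).
#' @param df degrees of freedom (default `length(e) - 2`).
#' @return one draw.
#' @export
draw_error_variance <- function(e, weights = NULL, df = length(e) - 2) {
  if (is.null(weights)) weights <- rep(1, length(e))
  S <- sum(weights * e^2)
  if (S < 0 || !is.finite(S)) {
    stop("numerical corruption: e'E^-1 e = ", S, call. = FALSE)
  }
  if (S == 0) return(0)
  S / rchisq(1, df)
}

#' Draw the polygenic variance from its full conditional
#'
#' `sigma2_a = a' Ainv a / chisq_df`, `df = q - 2` by default.
#'
#' @param a current polygenic effects.
#' @param Ainv inverse numerator relationship matrix.
#' @param df degrees of freedom (default `length(a) - 2`).
#' @return one draw.
#' @export
draw_polygenic_variance <- function(a, Ainv, df = length(a) - 2) {
  S <- as.numeric(crossprod(a, as.matrix(Ainv) %*% a))
  if (S < 0 || !is.finite(S)) {
    stop("numerical corruption: a'A^-1 a = ", S, call. = FALSE)
  }
  if (S == 0) return(0)
  S / rchisq(1, df)
}

#' Draw the fixed effects jointly from their full conditional
#'
#' `b ~ N([X'R^-1X]^-1 X'R^-1 y*, [X'R^-1X]^-1)` where `y*` is the phenotype
#' corrected for all other model terms and `R^-1 = diag(weights) / sigma2_e`.
#'
#' @param X fixed design matrix (full column rank).
#' @param ystar corrected phenotype.
#' @param sigma2_e residual variance.
#' @param weights per-record weights (default 1).
#' @return one draw of the coefficient vector.
#' @export
draw_fixed_effects <- function(X, ystar, sigma2_e, weights = NULL) {
  X <- as.matrix(X)
  if (is.null(weights)) weights <- rep(1, nrow(X))
  d <- weights / sigma2_e
  M <- crossprod(X, d * X)
  U <- chol(M)
  mean <- solve(M, crossprod(X, d * ystar))
  as.numeric(mean + backsolve(U, rnorm(ncol(X))))
}

#' One single-site sweep of polygenic-effect draws
#'
#' For each pedigree animal i the conditional is normal with precision
#' `z_i'R^-1 z_i + Ainv_ii / sigma2_a` and mean
#' `[z_i'R^-1 y*_i - (sum_{j != i} Ainv_ij a_j) / sigma2_a] / precision`;
#' animals without records have `z_i = 0` and shrink to the pedigree
#' expectation.
#'
#' @param ystar phenotype corrected for everything except the polygenic term.
#' @param zidx integer index of each record's animal in pedigree order.
#' @param a current polygenic effects (length q), updated in sweep order.
#' @param Ainv inverse numerator relationship matrix (q x q).
#' @param sigma2_a,sigma2_e current variances.
#' @param weights per-record weights (default 1).
#' @return the updated effect vector after one sweep.
#' @export
draw_polygenic_effects <- function(ystar, zidx, a, Ainv, sigma2_a, sigma2_e,
                                   weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(ystar))
  Ainv <- as.matrix(Ainv)
  q <- length(a)
  for (i in seq_len(q)) {
    ri <- which(zidx == i)
    zRz <- sum(weights[ri]) / sigma2_e
    zRy <- sum(weights[ri] * ystar[ri]) / sigma2_e
    off <- sum(Ainv[i, -i] * a[-i]) / sigma2_a
    lhs <- zRz + Ainv[i, i] / sigma2_a
    a[i] <- rnorm(1, (zRy - off) / lhs, sqrt(1 / lhs))
  }
  a
}

#' Per-component log-scores and conditional moments for one marker
#'
#' For marker j with `wRw = W_j'R^-1 W_j` and `rhs = W_j'R^-1 y*` (y*
#' excluding marker j's own contribution), component k of the mixture has
#' conditional mean `v_jk = rhs / (wRw + 1/sigma2_k)`, conditional variance
#' `1 / (wRw + 1/sigma2_k)` and log-score
#' `-0.5 [log(1 + wRw sigma2_k) - rhs v_jk] + log(pr_k)`; the term `y*'R^-1
#' y*`, constant in k, is dropped. The zero component has mean 0, variance 0
#' and log-score `log(pr_1)`.
#'
#' @param wRw scalar `W_j'R^-1 W_j`.
#' @param rhs scalar `W_j'R^-1 y*`.
#' @param spec a [mixture_spec()].
#' @param sigma2_a2 prior scale (pedigree additive variance).
#' @param pr current mixture proportions.
#' @return tibble `component`, `sigma2_k`, `log_score`, `cond_mean`,
#'   `cond_var`.
#' @export
snp_component_scores <- function(wRw, rhs, spec, sigma2_a2, pr) {
  s2 <- spec$multipliers * sigma2_a2
  K <- length(s2)
  log_score <- cond_mean <- cond_var <- numeric(K)
  for (k in seq_len(K)) {
    if (s2[k] <= 0) {
      log_score[k] <- log(pr[k])
    } else {
      prec <- wRw + 1 / s2[k]
      cond_mean[k] <- rhs / prec
      cond_var[k] <- 1 / prec
      log_score[k] <- -0.5 * (log1p(wRw * s2[k]) - rhs * cond_mean[k]) +
        log(pr[k])
    }
  }
  tibble(component = seq_len(K), sigma2_k = s2, log_score = log_score,
         cond_mean = cond_mean, cond_var = cond_var)
}

#' Sample a mixture component and an effect for one marker
#'
#' The component is drawn with probabilities `softmax(log_score)` computed by
#' log-sum-exp; the effect is then drawn from
#' `N(cond_mean_k, cond_var_k)` (exactly 0 for the point-mass component).
#'
#' @param scores output of [snp_component_scores()].
#' @return list `component`, `effect`.
#' @export
draw_snp_effect <- function(scores) {
  ls <- scores$log_score
  if (all(!is.finite(ls))) stop("non-finite component scores", call. = FALSE)
  p <- exp(ls - max(ls[is.finite(ls)]))
  p[!is.finite(p)] <- 0
  k <- sample.int(length(p), 1, prob = p)
  effect <- if (scores$sigma2_k[k] <= 0) 0 else
    rnorm(1, scores$cond_mean[k], sqrt(scores$cond_var[k]))
  list(component = k, effect = effect)
}

#' Draw mixture proportions from their Dirichlet full conditional
#'
#' `pr ~ Dirichlet(alpha + beta)` with `beta` the current per-component
#' marker counts; realised as normalised Gamma draws.
#'
#' @param beta per-component marker counts.
#' @param spec a [mixture_spec()].
#' @return proportion vector summing to 1.
#' @export
draw_mixture_proportions <- function(beta, spec) {
  g <- rgamma(length(beta), shape = spec$alpha + beta, rate = 1)
  g / sum(g)
}

as_dgc <- function(A) {
  # the chain takes a general column-sparse A-inverse; accept dense or any
  # Matrix flavour
  if (is.matrix(A) && nrow(A) == 0) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = double(0),
                                dims = c(0, 0)))
  }
  methods::as(methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                                      "generalMatrix"), "CsparseMatrix"),
              "dMatrix")
}

# ---- data bundle and chain runners ------------------------------------------

#' Assemble the data bundle for a BayesR analysis
#'
#' Filters phenotypes to one trait, builds record weights, the fixed design,
#' standardized genotypes for the reference animals (allele frequencies from
#' all genotyped animals) and, when a pedigree is given, the sparse A-inverse
#' for the polygenic term. `sigma2_a2`, the prior scale of the mixture, is
#' either supplied or estimated up front by EM-REML on the pedigree model
#' `y = Xb + Za + e`.
#'
#' @param genotypes a [genotype_set()].
#' @param phenotypes phenotype tibble.
#' @param trait trait to analyse.
#' @param pedigree optional pedigree tibble (enables the polygenic term).
#' @param params trait parameters; defaults to presets.
#' @param sigma2_a2 prior scale, or `"estimate"` (default) to fit it by REML
#'   (pedigree model when a pedigree is given, GRM model otherwise).
#' @return object of class `bayesr_data`.
#' @export
bayesr_data <- function(genotypes, phenotypes, trait, pedigree = NULL,
                        params = NULL, sigma2_a2 = "estimate") {
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
  sg <- subset_std(sg_all, ph$animal_id)
  X <- fixed_design(ph)
  y <- ph$value
  zidx <- integer(length(y))
  Ainv <- matrix(0, 0, 0)
  ped_ids <- character(0)
  if (!is.null(pedigree)) {
    ped <- sort_pedigree(pedigree)
    miss <- setdiff(ph$animal_id, ped$animal_id)
    if (length(miss)) {
      stop("phenotyped animal(s) missing from pedigree: ",
           paste(head(miss, 3), collapse = ", "), call. = FALSE)
    }
    nrm_inv <- compute_nrm_inverse(ped)
    ped_ids <- nrm_inv$ids
    Ainv <- nrm_inv$Ainv
    zidx <- match(ph$animal_id, ped_ids)
  }
  if (identical(sigma2_a2, "estimate")) {
    if (!is.null(pedigree)) {
      A <- compute_nrm(pedigree)$A[ph$animal_id, ph$animal_id]
      vfit <- estimate_variance_components(
        y, X, random = list(a = A), q = c(a = length(y)), e_diag = ph$e_diag)
      sigma2_a2 <- vfit$components$estimate[vfit$components$term == "a"]
    } else {
      grm <- compute_grm(sg, method = "plain")
      vfit <- estimate_variance_components(
        y, X, random = list(g = grm$G), q = c(g = length(y)),
        e_diag = ph$e_diag)
      sigma2_a2 <- vfit$components$estimate[vfit$components$term == "g"]
    }
  }
  if (!is.numeric(sigma2_a2) || sigma2_a2 <= 0) {
    stop("sigma2_a2 must be a positive number (or \"estimate\")",
         call. = FALSE)
  }
  structure(list(y = y, X = X, W = sg$W, weights = ph$w, zidx = zidx,
                 Ainv = Ainv, ped_ids = ped_ids, sigma2_a2 = sigma2_a2,
                 animal_id = ph$animal_id, breed = ph$breed,
                 map = sg$map, freq = sg_all$freq, kept = sg_all$kept,
                 trait = trait),
            class = "bayesr_data")
}

#' Run one BayesR Gibbs chain
#'
#' Cycles the six full-conditional updates (residual variance, fixed effects,
#' polygenic effects, polygenic variance, SNP effects over a fresh random
#' marker permutation, mixture proportions) and averages the post burn-in
#' samples. Deterministic given `seed`.
#'
#' @param data a [bayesr_data()] bundle (or a compatible list with elements
#'   `y`, `X`, `W`, `weights`, `zidx`, `Ainv`, `sigma2_a2`).
#' @param spec a [mixture_spec()].
#' @param n_iter total iterations (default 30000).
#' @param burn_in iterations discarded (default 20000).
#' @param seed RNG seed.
#' @param update_pr sample the mixture proportions (default TRUE); FALSE
#'   freezes `pr_init`.
#' @param pr_init initial (or frozen) mixture proportions; default uniform.
#' @param permute_snps fresh random marker order each iteration (default
#'   TRUE); FALSE sweeps in map order (debugging).
#' @param refresh_every full residual recompute interval (default 1000).
#' @return object of class `chain_summary`: posterior means `v`, `b`, `a`,
#'   `sigma2_e`, `sigma2_a`, `pr`, mean per-component counts `class_counts`,
#'   per-marker inclusion frequencies `incl_freq`, variance traces, the seed,
#'   and `resid_drift_max` (largest cached-vs-recomputed residual gap).
#' @export
run_chain <- function(data, spec = mixture_spec(), n_iter = 30000,
                      burn_in = 20000, seed = 1, update_pr = TRUE,
                      pr_init = NULL, permute_snps = TRUE,
                      refresh_every = 1000) {
  K <- length(spec$multipliers)
  if (is.null(pr_init)) pr_init <- rep(1 / K, K)
  if (length(pr_init) != K) stop("pr_init length must match components",
                                 call. = FALSE)
  stopifnot(n_iter > burn_in, length(data$y) > 2)
  set.seed(as.integer(seed))
  res <- bayesr_chain_cpp(
    y = as.numeric(data$y), X = as.matrix(data$X), W = as.matrix(data$W),
    zidx = as.integer(ifelse(is.na(data$zidx), 0L, data$zidx)),
    Ainv = as_dgc(data$Ainv), wgt = as.numeric(data$weights),
    mult = spec$multipliers, alpha = spec$alpha,
    sigma2_a2 = data$sigma2_a2, n_iter = as.integer(n_iter),
    burn_in = as.integer(burn_in), update_pr = update_pr,
    pr = as.numeric(pr_init / sum(pr_init)), permute_snps = permute_snps,
    refresh_every = as.integer(refresh_every))
  structure(list(
    v = as.numeric(res$v_mean), b = as.numeric(res$b_mean),
    a = as.numeric(res$a_mean), sigma2_e = res$sigma2_e_mean,
    sigma2_a = res$sigma2_a_mean, pr = as.numeric(res$pr_mean),
    class_counts = as.numeric(res$count_mean), incl_freq = res$incl_freq,
    sigma2_e_trace = as.numeric(res$sigma2_e_trace),
    sigma2_a_trace = as.numeric(res$sigma2_a_trace),
    resid_drift_max = res$resid_drift_max, n_kept = res$n_kept,
    seed = seed, n_iter = n_iter, burn_in = burn_in
  ), class = "chain_summary")
}

#' Run replicate BayesR chains and average them
#'
#' Runs `n_chains` independent chains with seeds `seed + 0:(n_chains-1)` and
#' reports the across-chain average of every posterior mean alongside the
#' per-chain summaries.
#'
#' @inheritParams run_chain
#' @param n_chains number of replicate chains (default 5).
#' @param ... passed to [run_chain()].
#' @return object of class `bayesr_fit`.
#' @export
run_bayesr <- function(data, spec = mixture_spec(), n_chains = 5,
                       n_iter = 30000, burn_in = 20000, seed = 1, ...) {
  seeds <- as.integer(seed) + seq_len(n_chains) - 1L
  chains <- vector("list", n_chains)
  for (i in seq_len(n_chains)) {
    chains[[i]] <- tryCatch(
      run_chain(data, spec, n_iter = n_iter, burn_in = burn_in,
                seed = seeds[i], ...),
      error = function(e) {
        stop("chain ", i, " (seed ", seeds[i], ") failed: ",
             conditionMessage(e), call. = FALSE)
      })
  }
  avg <- function(fld) Reduce(`+`, lapply(chains, `[[`, fld)) / n_chains
  marker_id <- data$map$marker_id
  v <- avg("v")
  incl <- avg("incl_freq")
  colnames(incl) <- paste0("p_class", seq_len(ncol(incl)))
  structure(list(
    trait = data$trait,
    v = dplyr::bind_cols(
      tibble(marker_id = marker_id, effect = v), as_tibble(incl)),
    b = tibble(term = colnames(data$X), estimate = avg("b")),
    a = tibble(animal_id = data$ped_ids, estimate = avg("a")),
    sigma2_e = avg("sigma2_e"), sigma2_a = avg("sigma2_a"),
    pr = avg("pr"), class_counts = avg("class_counts"),
    chains = chains, seeds = seeds, spec = spec,
    sigma2_a2 = data$sigma2_a2, map = data$map, freq = data$freq,
    kept = data$kept, n = length(data$y), m = length(v)
  ), class = "bayesr_fit")
}

#' Fit the extended BayesR model
#'
#' Convenience wrapper: [bayesr_data()] then [run_bayesr()].
#'
#' @inheritParams bayesr_data
#' @inheritParams run_bayesr
#' @param ... passed to [run_bayesr()].
#' @return a `bayesr_fit`.
#' @export
bayesr <- function(genotypes, phenotypes, trait, pedigree = NULL,
                   params = NULL, sigma2_a2 = "estimate",
                   spec = mixture_spec(), n_chains = 5, n_iter = 30000,
                   burn_in = 20000, seed = 1, ...) {
  data <- bayesr_data(genotypes, phenotypes, trait, pedigree = pedigree,
                      params = params, sigma2_a2 = sigma2_a2)
  run_bayesr(data, spec, n_chains = n_chains, n_iter = n_iter,
             burn_in = burn_in, seed = seed, ...)
}

#' @export
print.bayesr_fit <- function(x, ...) {
  cat("<bayesr_fit> trait", x$trait, "-", x$n, "records,", x$m, "markers,",
      length(x$chains), "chain(s)\n")
  cat("posterior means: sigma2_e =", signif(x$sigma2_e, 4),
      " sigma2_a =", signif(x$sigma2_a, 4), "\n")
  cat("mean markers per class:",
      paste(signif(x$class_counts, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname bayesr
#' @param x a `bayesr_fit`.
#' @export
tidy.bayesr_fit <- function(x, ...) {
  dplyr::left_join(x$v, x$map, by = "marker_id")
}

#' @rdname bayesr
#' @export
glance.bayesr_fit <- function(x, ...) {
  cc <- setNames(as.list(x$class_counts),
                 paste0("n_class", seq_along(x$class_counts)))
  dplyr::bind_cols(
    tibble(trait = x$trait, n = x$n, m = x$m, n_chains = length(x$chains),
           sigma2_e = x$sigma2_e, sigma2_a = x$sigma2_a,
           sigma2_a2 = x$sigma2_a2),
    as_tibble(cc))
}

#' @rdname bayesr
#' @param object a `bayesr_fit`.
#' @export
autoplot.bayesr_fit <- function(object, ...) {
  df <- tidy(object)
  df$cum <- cumulative_bp(df, "pos")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cum / 1e6,
                                   y = abs(.data$effect),
                                   colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = "cumulative position (Mb)",
                  y = "|posterior mean SNP effect|",
                  title = paste("BayesR SNP effects -", object$trait)) +
    ggplot2::theme_minimal()
}

cumulative_bp <- function(df, poscol) {
  off <- df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data[[poscol]]), .groups = "drop") |>
    dplyr::mutate(offset = dplyr::lag(cumsum(.data$len), default = 0))
  df |>
    dplyr::left_join(off, by = "chrom") |>
    dplyr::pull(.data$offset) + df[[poscol]]
}
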