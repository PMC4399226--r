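#' EM-REML variance-component estimation
#'
#' Restricted maximum likelihood for the Gaussian mixed model
#' `y = Xb + sum_c u_c + e`, `u_c ~ N(0, V_c sigma2_c)`,
#' `e ~ N(0, E sigma2_e)` with `E = diag(e_diag)` the residual weight
#' structure. Each `V_c` is supplied as the record-level covariance structure
#' `Z K Z'` (e.g. `Z A Z'` for a pedigree polygenic term, `Z G Z'` for a
#' genomic term). The EM update
#' `sigma2_c <- sigma2_c + sigma2_c^2 (y'P V_c P y - tr(P V_c)) / q_c`
#' is monotone in the restricted log-likelihood; `q_c` is the number of
#' levels of the random effect (n for the residual). Standard errors come
#' from the inverse expected information `I_cd = 0.5 tr(P V_c P V_d)`.
#'
#' @param y numeric phenotype vector.
#' @param X fixed-effect design matrix (full column rank).
#' @param random named list of n x n covariance structures, possibly empty.
#' @param q named integer vector of random-effect dimensions (defaults to the
#'   number of distinct levels = n for record-level structures).
#' @param e_diag residual weight diagonal `E_ii = 1/w_i` (default all 1).
#' @param start optional named start values (including `"e"`).
#' @param tol relative convergence tolerance on every component (default
#'   1e-6).
#' @param max_iter iteration cap (default 200); non-convergence returns the
#'   last iterate with `converged = FALSE` and a warning.
#' @return object of class `vc_fit`: list with `components` (tibble `term`,
#'   `estimate`, `se`), `logLik` trace, `converged`, `iterations`,
#'   `degenerate` flag.
#' @export
estimate_variance_components <- function(y, X, random = list(),
                                         q = NULL, e_diag = NULL,
                                         start = NULL, tol = 1e-6,
                                         max_iter = 200) {
  y <- as.numeric(y)
  n <- length(y)
  X <- as.matrix(X)
  if (n <= qr(X)$rank + 2) {
    stop("need n > rank(X) + 2 records for REML", call. = FALSE)
  }
  if (is.null(e_diag)) e_diag <- rep(1, n)
  terms <- names(random)
  if (length(random) && is.null(terms)) {
    stop("'random' must be a named list", call. = FALSE)
  }
  if (is.null(q)) q <- setNames(rep(n, length(random)), terms)
  vy <- var(y)
  if (vy < 1e-12) {
    comp <- tibble(term = c(terms, "e"),
                   estimate = rep(0, length(terms) + 1),
                   se = NA_real_)
    return(structure(list(components = comp, logLik = numeric(0),
                          converged = TRUE, iterations = 0L,
                          degenerate = TRUE), class = "vc_fit"))
  }
  k <- length(terms)
  s2 <- if (is.null(start)) {
    setNames(rep(vy / (k + 1), k + 1), c(terms, "e"))
  } else {
    st <- setNames(rep(vy / (k + 1), k + 1), c(terms, "e"))
    st[names(start)] <- pmax(unlist(start), 1e-8 * vy)
    st
  }
  floor_v <- 1e-8 * vy
  structs <- c(random, list(e = diag(e_diag, n)))
  qq <- c(q, e = n)
  evaluate <- function(s2) {
    V <- matrix(0, n, n)
    for (tm in names(structs)) V <- V + s2[tm] * structs[[tm]]
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) {
      V <- V + diag(1e-8 * vy, n)
      cV <- chol(V)
    }
    Vinv <- chol2inv(cV)
    VinvX <- Vinv %*% X
    XtVX <- crossprod(X, VinvX)
    cXtVX <- chol(XtVX)
    P <- Vinv - VinvX %*% chol2inv(cXtVX) %*% t(VinvX)
    Py <- P %*% y
    list(P = P, Py = Py,
         ll = -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cXtVX))) +
                        sum(y * Py)))
  }
  em_step <- function(s2, ev) {
    s2_new <- s2
    for (tm in names(structs)) {
      Vc <- structs[[tm]]
      ypvpy <- as.numeric(crossprod(ev$Py, Vc %*% ev$Py))
      trpv <- sum(ev$P * Vc)
      s2_new[tm] <- max(s2[tm] + s2[tm]^2 * (ypvpy - trpv) / qq[tm], floor_v)
    }
    s2_new
  }
  ll <- numeric(0)
  converged <- FALSE
  it <- 0L
  hist <- list()  # last accepted states, for Aitken extrapolation
  ev <- evaluate(s2)
  while (it < max_iter) {
    it <- it + 1L
    ll <- c(ll, ev$ll)
    s2_new <- em_step(s2, ev)
    rel <- abs(s2_new - s2) / pmax(s2, floor_v)
    if (all(rel < tol)) {
      s2 <- s2_new
      converged <- TRUE
      break
    }
    hist <- c(hist, list(s2))
    if (length(hist) > 3) hist <- hist[-1]
    cand <- s2_new
    # safeguarded Aitken acceleration: geometric extrapolation of each
    # component, accepted only when the restricted logLik does not drop
    if (it %% 4 == 0 && length(hist) == 3) {
      d1 <- s2_new - hist[[3]]
      d2 <- hist[[3]] - hist[[2]]
      r <- ifelse(abs(d2) > 0, d1 / d2, 0)
      ok <- is.finite(r) & r > 0 & r < 0.99
      acc <- s2_new
      acc[ok] <- s2_new[ok] + d1[ok] * r[ok] / (1 - r[ok])
      acc <- pmax(acc, floor_v)
      if (any(acc != s2_new)) {
        ev_acc <- evaluate(acc)
        if (ev_acc$ll >= ev$ll) {
          cand <- acc
          ev <- ev_acc
          s2 <- cand
          next
        }
      }
    }
    s2 <- cand
    ev <- evaluate(s2)
  }
  ev <- evaluate(s2)  # information at the returned estimate
  P <- ev$P
  if (!converged) {
    warning("EM-REML did not converge in ", max_iter,
            " iterations; returning last iterate", call. = FALSE)
  }
  # expected information at the final iterate
  se <- rep(NA_real_, k + 1)
  info <- matrix(0, k + 1, k + 1)
  PV <- lapply(structs, function(Vc) P %*% Vc)
  for (a in seq_len(k + 1)) {
    for (b in a:(k + 1)) {
      info[a, b] <- info[b, a] <- 0.5 * sum(t(PV[[a]]) * PV[[b]])
    }
  }
  iinv <- tryCatch(solve(info), error = function(e) NULL)
  if (!is.null(iinv)) se <- sqrt(pmax(diag(iinv), 0))
  comp <- tibble(term = names(structs), estimate = unname(s2[names(structs)]),
                 se = se)
  structure(list(components = comp, logLik = ll, converged = converged,
                 iterations = it, degenerate = FALSE), class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("<vc_fit> EM-REML,", x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  print(x$components)
  invisible(x)
}

#' @rdname estimate_variance_components
#' @param x a `vc_fit` object.
#' @param ... unused.
#' @export
tidy.vc_fit <- function(x, ...) x$components

#' @rdname estimate_variance_components
#' @export
glance.vc_fit <- function(x, ...) {
  tibble(logLik = if (length(x$logLik)) tail(x$logLik, 1) else NA_real_,
         iterations = x$iterations, converged = x$converged,
         degenerate = x$degenerate)
}
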