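# Monte-Carlo and closed-form oracles for the full-conditional draws

test_that("error-variance draw is S / chisq_df with the right moments", {
  expect_identical(draw_error_variance(rep(0, 10)), 0)
  expect_error(draw_error_variance(c(NaN, 1)), "corruption")
  # S = 10, df = 100: mean of S/chisq_100 is S/98
  set.seed(1)
  e <- rep(sqrt(10 / 102), 102)  # S = sum(e^2) = 10, n = 102
  draws <- replicate(5e4, draw_error_variance(e))
  # Monte-Carlo oracle: mean S/(df-2), sd of the mean via sample sd
  expect_lt(abs(mean(draws) - 10 / 98), 4 * sd(draws) / sqrt(5e4))
  # weights scale the quadratic form
  set.seed(2)
  d1 <- draw_error_variance(c(1, 1), weights = c(2, 2), df = 5)
  set.seed(2)
  d2 <- draw_error_variance(c(sqrt(2), sqrt(2)), df = 5)
  expect_equal(d1, d2)
})

test_that("polygenic-variance draw matches its Monte-Carlo oracle", {
  a <- rep(sqrt(0.5), 100)  # sum a^2 = 50, A = I, df = 98
  set.seed(3)
  draws <- replicate(5e4, draw_polygenic_variance(a, diag(100)))
  expect_lt(abs(mean(draws) - 50 / 96), 4 * sd(draws) / sqrt(5e4))
  expect_identical(draw_polygenic_variance(rep(0, 5), diag(5)), 0)
  # permuting animals leaves the quadratic form unchanged
  set.seed(4); x <- rnorm(30)
  ped <- random_pedigree(30, seed = 4)
  Ainv <- as.matrix(compute_nrm_inverse(ped)$Ainv)
  perm <- sample(30)
  set.seed(5); d1 <- draw_polygenic_variance(x[perm],
                                             Ainv[perm, perm])
  set.seed(5); d2 <- draw_polygenic_variance(x, Ainv)
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("fixed-effect draws concentrate on the GLS solution", {
  set.seed(6)
  n <- 2000
  ystar <- rnorm(n, 5, 1)
  X <- matrix(1, n, 1)
  draws <- replicate(2000, draw_fixed_effects(X, ystar, sigma2_e = 1))
  post_sd <- 1 / sqrt(n)
  expect_lt(abs(mean(draws) - mean(ystar)), 3 * post_sd / sqrt(2000) +
              3 * post_sd)
  # zero-variance limit via huge weights: the draw pins to GLS
  w <- rep(1e10, 20)
  y2 <- rnorm(20)
  X2 <- cbind(1, seq_len(20))
  gls <- qr.coef(qr(X2 * sqrt(w)), y2 * sqrt(w))
  d <- draw_fixed_effects(X2, y2, sigma2_e = 1, weights = w)
  expect_equal(unname(d), unname(gls), tolerance = 1e-4)
  # orthogonal columns give a diagonal posterior covariance -> independent
  # coordinates; check empirically
  X3 <- cbind(rep(c(1, 0), each = 50), rep(c(0, 1), each = 50))
  y3 <- rnorm(100)
  dd <- replicate(4000, draw_fixed_effects(X3, y3, sigma2_e = 1))
  expect_lt(abs(cor(dd[1, ], dd[2, ])), 0.08)
})

test_that("single-site polygenic sweep has the closed-form shrinkage", {
  # unrelated animals, unit weights: conditional mean y* s2a/(s2a + s2e)
  set.seed(7)
  q <- 100
  ystar <- rnorm(q, 2, 1)
  sweep1 <- function() {
    draw_polygenic_effects(ystar, zidx = seq_len(q), a = rep(0, q),
                           Ainv = diag(q), sigma2_a = 1, sigma2_e = 1)
  }
  draws <- replicate(50, sweep1())
  shrunk <- ystar * 1 / (1 + 1)
  expect_lt(max(abs(rowMeans(draws) - shrunk)), 4 * sqrt(0.5 / 50) + 0.1)
  # sigma2_a -> 0 pins the draws at the prior mean 0
  a0 <- draw_polygenic_effects(ystar, seq_len(q), rep(1, q), diag(q),
                               sigma2_a = 1e-12, sigma2_e = 1)
  expect_lt(max(abs(a0)), 1e-4)
})

test_that("polygenic Gibbs long-run mean matches the MME oracle", {
  # 5-animal pedigree, fixed variances: the stationary mean of the single-site
  # sweep is the BLUP solution of [Z'Z/s2e + Ainv/s2a] a = Z'y/s2e
  ped <- tibble::tibble(animal_id = c("s", "d", "o1", "o2", "o3"),
                        sire_id = c(NA, NA, "s", "s", "s"),
                        dam_id = c(NA, NA, "d", "d", NA))
  Ainv <- as.matrix(compute_nrm_inverse(ped)$Ainv)
  set.seed(8)
  y <- c(1.2, -0.5, 0.8, 0.3, 1.0)
  s2a <- 0.5; s2e <- 1
  blup <- solve(diag(5) / s2e + Ainv / s2a, y / s2e)
  a <- rep(0, 5)
  total <- rep(0, 5)
  n_sweeps <- 4000
  for (i in seq_len(n_sweeps)) {
    a <- draw_polygenic_effects(y, 1:5, a, Ainv, s2a, s2e)
    total <- total + a
  }
  expect_lt(max(abs(total / n_sweeps - blup)), 5e-2)
})

test_that("SNP component scores follow the shrinkage algebra", {
  spec <- mixture_spec()
  # wRw = 10, sigma2_k = 1 via sigma2_a2 = 100 on the 0.01 class: mean 5/11
  sc <- snp_component_scores(wRw = 10, rhs = 5, spec = spec,
                             sigma2_a2 = 100, pr = rep(0.25, 4))
  expect_equal(sc$cond_mean[4], 5 / 11, tolerance = 1e-12)
  expect_equal(sc$cond_var[4], 1 / 11, tolerance = 1e-12)
  expect_equal(sc$cond_mean[1], 0)
  # orthogonal phenotype: the zero component dominates every other by
  # exactly 0.5 log(1 + wRw sigma2_k)
  sc0 <- snp_component_scores(wRw = 10, rhs = 0, spec = spec,
                              sigma2_a2 = 1, pr = rep(0.25, 4))
  gaps <- sc0$log_score[1] - sc0$log_score[-1]
  expect_equal(gaps, 0.5 * log1p(10 * spec$multipliers[-1]),
               tolerance = 1e-12)
  expect_true(all(gaps > 0))
})

test_that("component sampling is a softmax with exact-zero handling", {
  spec <- mixture_spec(multipliers = c(0, 0.01))
  # two equal scores -> selection frequency 1/2
  sc <- tibble::tibble(component = 1:2, sigma2_k = c(0, 1),
                       log_score = c(1.3, 1.3), cond_mean = c(0, 0.4),
                       cond_var = c(0, 0.25))
  set.seed(9)
  draws <- replicate(1e4, draw_snp_effect(sc)$component)
  expect_lt(abs(mean(draws == 1) - 0.5), 3 * sqrt(0.25 / 1e4))
  # vanishing prior probability removes a component
  spec4 <- mixture_spec()
  sc2 <- snp_component_scores(10, 5, spec4, 1, pr = c(0.5, 0.5, 0, 0))
  expect_equal(sc2$log_score[3:4], c(-Inf, -Inf))
  set.seed(10)
  comps <- replicate(500, draw_snp_effect(sc2)$component)
  expect_true(all(comps %in% 1:2))
  # point-mass component yields exactly zero effects
  zero_draws <- replicate(100, {
    d <- draw_snp_effect(sc)
    if (d$component == 1) d$effect else NA_real_
  })
  expect_true(all(zero_draws[!is.na(zero_draws)] == 0))
})

test_that("effect draws for a fixed component have the conditional variance", {
  spec <- mixture_spec(multipliers = c(0, 0.01))
  sc <- snp_component_scores(10, 5, spec, sigma2_a2 = 100,
                             pr = c(0, 1))  # forced into the non-zero class
  set.seed(11)
  effs <- replicate(5e4, draw_snp_effect(sc)$effect)
  expect_lt(abs(var(effs) - 1 / 11), 4 * (1 / 11) * sqrt(2 / 5e4))
  expect_lt(abs(mean(effs) - 5 / 11), 4 * sqrt(1 / 11 / 5e4))
})

test_that("Dirichlet proportion updates have the conjugate mean and sum to 1", {
  spec <- mixture_spec()
  set.seed(12)
  pr <- draw_mixture_proportions(c(997, 1, 1, 1), spec)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  # beta = (m-3,1,1,1), alpha = 1: E[pr_1] = 998/1004
  draws <- replicate(2e4, draw_mixture_proportions(c(997, 1, 1, 1), spec)[1])
  expect_lt(abs(mean(draws) - 998 / 1004), 4 * sd(draws) / sqrt(2e4))
  # no markers at all: prior-only mean alpha / sum(alpha)
  draws0 <- replicate(2e4, draw_mixture_proportions(rep(0, 4), spec)[1])
  expect_lt(abs(mean(draws0) - 0.25), 4 * sd(draws0) / sqrt(2e4))
})

test_that("mixture_spec validates its invariants", {
  expect_error(mixture_spec(multipliers = c(0.1, 0.2)), "point mass")
  expect_error(mixture_spec(multipliers = c(0, 0.01, 0.001)),
               "non-decreasing")
  expect_error(mixture_spec(alpha = c(1, 1)), "alpha")
})
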