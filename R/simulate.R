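#' Simulation configuration
#'
#' Defines the synthetic multi-breed study: two reference breeds (A, B) and a
#' third breed (C) that never enters the reference, mimicking a
#' Holstein/Jersey reference with a distinct validation-only red breed.
#' Genotypes are first-order-Markov LD haplotypes drifted through independent
#' per-breed bottleneck resampling; SNP effects follow the four-component
#' normal mixture; phenotypes are cow trait deviations (`r` own records) and
#' bull daughter trait deviations (`d` effective daughters) with
#' heterogeneous error variance, fixed breed and sex-within-breed effects and
#' an optional two-generation pedigree polygenic term.
#'
#' @param n_ref named counts of reference records:
#'   `c(A_bull, A_cow, B_bull, B_cow)`.
#' @param n_val named counts of validation animals:
#'   `c(A_bull, B_bull, C_bull, C_cow)`.
#' @param m total marker count.
#' @param n_chrom number of chromosomes (markers split evenly).
#' @param chrom_length_bp chromosome length; markers evenly spaced.
#' @param ld first-order haplotype LD parameter in `[0, 1)` (probability the
#'   latent uniform is copied from the previous marker).
#' @param n_founder_hap base haplotype pool size.
#' @param bottleneck_hap per-breed pool size during drift.
#' @param divergence_generations per-breed bottleneck resampling rounds.
#' @param c_divergence_multiplier extra drift for the validation-only breed C
#'   (its generations are multiplied by this; default 3). C emulates a breed
#'   of distinct ancestry, considerably further from the reference breeds
#'   than they are from each other.
#' @param recomb_rate expected crossovers per bp per meiosis during drift
#'   (default 1e-7, i.e. one crossover per 10 Mb chromosome: the genetic map
#'   is compressed so that LD decays over the simulated chromosome lengths
#'   the way it does over real cattle chromosomes).
#' @param n_per_class exact marker counts per mixture class (zero class
#'   filled to `m`); ignored when `proportions` is given. The default
#'   (100/30/20) reads the published class counts of dense-genotype dairy
#'   analyses scaled down to m = 5000; the markers then carry about a
#'   quarter of the additive variance and the polygenic layer the rest (at
#'   desk scale the published class counts and the published SNP share of
#'   genetic variance cannot both hold - see the methods vignette).
#' @param proportions optional per-class proportions (multinomial sampling).
#' @param sigma2_a2 mixture prior scale (per-class variances are the
#'   multipliers times this).
#' @param multipliers mixture variance multipliers.
#' @param h2,t trait heritability and repeatability (defaults: milk traits).
#' @param trait trait label.
#' @param poly_frac polygenic variance as a fraction of the marker genetic
#'   variance (0 disables the pedigree/polygenic layer). The default `NULL`
#'   calibrates it so that the expected total additive variance (markers +
#'   polygenic) equals `sigma2_a2`: the mixture-class variances are then true
#'   fractions of the trait's additive genetic variance - the quantity the
#'   prior-scale REML fit estimates - as in real populations, where the
#'   largest-effect classes account for only part of the additive variance.
#' @param n_parents founder (sire, dam) counts per breed for the pedigree.
#' @param breed_effects named fixed breed means (phenotype units).
#' @param sex_effect additive fixed effect of female sex, nested within each
#'   breed.
#' @param d_min,d_shape,d_scale bull effective-daughter distribution
#'   `d = d_min + round(Gamma(shape, scale))`.
#' @param r_probs cow record-count probabilities for r = 1, 2, 3.
#' @param seed RNG seed.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_ref = c(A_bull = 700, A_cow = 400, B_bull = 250,
                                 B_cow = 150),
                       n_val = c(A_bull = 150, B_bull = 80, C_bull = 60,
                                 C_cow = 60),
                       m = 5000, n_chrom = 5, chrom_length_bp = 1e7,
                       ld = 0.9, n_founder_hap = 400, bottleneck_hap = 200,
                       divergence_generations = 30,
                       c_divergence_multiplier = 3, recomb_rate = 1e-7,
                       n_per_class = c(100, 30, 20), proportions = NULL,
                       sigma2_a2 = 1,
                       multipliers = c(0, 1e-4, 1e-3, 1e-2),
                       h2 = 0.33, t = 0.56, trait = "FY", poly_frac = NULL,
                       n_parents = c(sires = 25, dams = 50),
                       breed_effects = c(A = 0, B = 0.6, C = 0.3),
                       sex_effect = 0.25,
                       d_min = 20, d_shape = 2, d_scale = 60,
                       r_probs = c(0.5, 0.3, 0.2), seed = 20260920) {
  stopifnot(all(n_ref > 0), all(n_val > 0), m > 0, n_chrom > 0,
            ld >= 0, ld < 1, h2 > 0, h2 <= t, t <= 1)
  if (is.null(poly_frac)) {
    # self-consistency: E[var(markers)] = sigma2_a2 * sum(counts * mult);
    # the polygenic layer supplies the remaining additive variance so that
    # total additive variance = sigma2_a2
    v_frac <- if (!is.null(proportions)) {
      m * sum(proportions * multipliers)
    } else {
      sum(n_per_class * multipliers[-1])
    }
    if (v_frac <= 0 || v_frac >= 1) {
      stop("cannot auto-calibrate poly_frac: the marker variance fraction (",
           signif(v_frac, 3), ") must lie in (0, 1); set poly_frac explicitly",
           call. = FALSE)
    }
    poly_frac <- (1 - v_frac) / v_frac
    attr(poly_frac, "auto") <- TRUE
  }
  stopifnot(poly_frac >= 0)
  if (!is.null(proportions)) {
    if (length(proportions) != length(multipliers) ||
        abs(sum(proportions) - 1) > 1e-8) {
      stop("proportions must match the multipliers and sum to 1",
           call. = FALSE)
    }
  } else if (length(n_per_class) != length(multipliers) - 1 ||
             sum(n_per_class) > m) {
    stop("n_per_class must give counts for the non-zero classes and fit ",
         "within m", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

sim_breed_counts <- function(cfg) {
  # per-animal breed / record-type / split layout, in a fixed order
  lay <- rbind(
    data.frame(breed = "A", sex = "M", type = "bull", split = "reference",
               n = cfg$n_ref[["A_bull"]]),
    data.frame(breed = "A", sex = "F", type = "cow", split = "reference",
               n = cfg$n_ref[["A_cow"]]),
    data.frame(breed = "B", sex = "M", type = "bull", split = "reference",
               n = cfg$n_ref[["B_bull"]]),
    data.frame(breed = "B", sex = "F", type = "cow", split = "reference",
               n = cfg$n_ref[["B_cow"]]),
    data.frame(breed = "A", sex = "M", type = "bull", split = "validation",
               n = cfg$n_val[["A_bull"]]),
    data.frame(breed = "B", sex = "M", type = "bull", split = "validation",
               n = cfg$n_val[["B_bull"]]),
    data.frame(breed = "C", sex = "M", type = "bull", split = "validation",
               n = cfg$n_val[["C_bull"]]),
    data.frame(breed = "C", sex = "F", type = "cow", split = "validation",
               n = cfg$n_val[["C_cow"]]))
  out <- lay[rep(seq_len(nrow(lay)), lay$n), c("breed", "sex", "type",
                                               "split")]
  out$animal_id <- sprintf("%s%04d", out$breed,
                           stats::ave(seq_len(nrow(out)), out$breed,
                                      FUN = seq_along))
  as_tibble(out)
}

sim_marker_map <- function(cfg) {
  per <- rep(cfg$m %/% cfg$n_chrom, cfg$n_chrom)
  per[seq_len(cfg$m %% cfg$n_chrom)] <- per[seq_len(cfg$m %% cfg$n_chrom)] + 1
  purrr::map_dfr(seq_len(cfg$n_chrom), function(ch) {
    spacing <- floor(cfg$chrom_length_bp / per[ch])
    tibble(marker_id = sprintf("snp%d_%d", ch, seq_len(per[ch])),
           chrom = as.character(ch),
           pos = spacing * seq_len(per[ch]))
  })
}

recombine_pool <- function(pool, map, rate) {
  # one drift generation: each new pool haplotype is a gamete of two randomly
  # drawn parents, with Poisson(len * rate) crossovers per chromosome
  n <- nrow(pool)
  out <- pool
  chroms <- unique(map$chrom)
  chrom_idx <- lapply(chroms, function(ch) which(map$chrom == ch))
  chrom_len <- vapply(chrom_idx, function(ii) max(map$pos[ii]), 0)
  p1 <- sample.int(n, n, replace = TRUE)
  p2 <- sample.int(n, n, replace = TRUE)
  nx <- matrix(rpois(n * length(chroms), chrom_len * rate),
               nrow = length(chroms))
  for (k in seq_len(n)) {
    h <- pool[p1[k], ]
    for (ci in seq_along(chroms)) {
      ii <- chrom_idx[[ci]]
      if (nx[ci, k] == 0L) {
        # no crossover: whole chromosome from a random parent
        if (runif(1) < 0.5) h[ii] <- pool[p2[k], ii]
      } else {
        cuts <- sort(runif(nx[ci, k], 0, chrom_len[ci]))
        seg <- findInterval(map$pos[ii], cuts)
        from2 <- (seg %% 2L == 0L) == (runif(1) < 0.5)
        h[ii[from2]] <- pool[p2[k], ii[from2]]
      }
    }
    out[k, ] <- h
  }
  out
}

markov_haplotypes <- function(n_hap, map, p_base, ld) {
  m <- nrow(map)
  H <- matrix(FALSE, n_hap, m)
  u <- runif(n_hap)
  chrom_prev <- ""
  for (j in seq_len(m)) {
    if (map$chrom[j] != chrom_prev) {
      u <- runif(n_hap)  # LD does not cross chromosome boundaries
      chrom_prev <- map$chrom[j]
    } else {
      fresh <- runif(n_hap) >= ld
      u[fresh] <- runif(sum(fresh))
    }
    H[, j] <- u < p_base[j]
  }
  H
}

#' Simulate multi-breed genotypes
#'
#' Founder haplotypes carry first-order Markov LD (a latent uniform is copied
#' from the previous marker with probability `ld`, so marginal frequencies
#' are preserved while adjacent markers correlate). Each breed then drifts
#' independently: its haplotype pool is bottleneck-resampled with replacement
#' for `divergence_generations` rounds, diverging allele frequencies and LD
#' phase between breeds. Diploid dosages are sums of two haplotypes drawn
#' from the final pool. Deterministic given `seed`.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed (default `cfg$seed`).
#' @return a [genotype_set()] with per-animal breed labels, plus attribute
#'   `"layout"` (tibble of breed/sex/type/split per animal).
#' @export
simulate_genotypes <- function(cfg, seed = cfg$seed) {
  set.seed(as.integer(seed))
  layout <- sim_breed_counts(cfg)
  map <- sim_marker_map(cfg)
  p_base <- runif(cfg$m, 0.1, 0.9)
  H <- markov_haplotypes(cfg$n_founder_hap, map, p_base, cfg$ld)
  dos <- matrix(0, nrow(layout), cfg$m)
  for (b in unique(layout$breed)) {
    pool <- H[sample.int(cfg$n_founder_hap, cfg$bottleneck_hap,
                         replace = TRUE), , drop = FALSE]
    gens <- cfg$divergence_generations
    cm <- cfg$c_divergence_multiplier
    if (b == "C" && !is.null(cm)) gens <- round(gens * cm)
    for (g in seq_len(gens)) {
      pool <- recombine_pool(pool, map, cfg$recomb_rate)
    }
    rows <- which(layout$breed == b)
    h1 <- pool[sample.int(cfg$bottleneck_hap, length(rows),
                          replace = TRUE), , drop = FALSE]
    h2 <- pool[sample.int(cfg$bottleneck_hap, length(rows),
                          replace = TRUE), , drop = FALSE]
    dos[rows, ] <- h1 + h2
  }
  rownames(dos) <- layout$animal_id
  g <- genotype_set(dos, map, breed = layout$breed)
  attr(g, "layout") <- layout
  g
}

#' Simulate mixture-distributed SNP effects
#'
#' Component labels come either from exact per-class counts
#' (`cfg$n_per_class`, randomly placed) or from per-marker multinomial
#' sampling of `cfg$proportions`. Effects in class k are
#' `N(0, multipliers[k] * sigma2_a2)`; the zero class is exactly 0.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed (default `cfg$seed + 1`).
#' @return tibble `marker`, `component` (1 = zero class), `effect`.
#' @export
simulate_effects <- function(cfg, seed = cfg$seed + 1) {
  set.seed(as.integer(seed))
  K <- length(cfg$multipliers)
  m <- cfg$m
  comp <- rep(1L, m)
  if (!is.null(cfg$proportions)) {
    comp <- sample.int(K, m, replace = TRUE, prob = cfg$proportions)
  } else {
    nz <- sum(cfg$n_per_class)
    where <- sample.int(m, nz)
    comp[where] <- rep(2:K, times = cfg$n_per_class)
  }
  sdk <- sqrt(cfg$multipliers * cfg$sigma2_a2)
  effect <- rnorm(m, 0, sdk[comp])
  effect[comp == 1L] <- 0
  tibble(marker = seq_len(m), component = comp, effect = effect)
}

sim_pedigree <- function(layout, n_parents) {
  # two generations per breed: unrelated founder sires/dams, genotyped
  # animals are their offspring (half/full-sib families)
  peds <- purrr::map_dfr(unique(layout$breed), function(b) {
    kids <- layout$animal_id[layout$breed == b]
    sires <- sprintf("%sS%03d", b, seq_len(n_parents[["sires"]]))
    dams <- sprintf("%sD%03d", b, seq_len(n_parents[["dams"]]))
    dplyr::bind_rows(
      tibble(animal_id = c(sires, dams), sire_id = NA_character_,
             dam_id = NA_character_),
      tibble(animal_id = kids,
             sire_id = sample(sires, length(kids), replace = TRUE),
             dam_id = sample(dams, length(kids), replace = TRUE)))
  })
  sort_pedigree(peds)
}

#' Simulate phenotypes with heterogeneous error variance
#'
#' Total genetic value is `g = W_std v` (markers polymorphic in the sample)
#' plus, when `cfg$poly_frac > 0`, a pedigree polygenic value over a
#' two-generation pedigree. Records are `y = Xb + g + a + e` with
#' `e ~ N(0, sigma2_e / w_i)`: cows draw `r` from `cfg$r_probs` and use the
#' cow weight; bulls draw `d` from the configured gamma and use the bull
#' weight (their records emulate daughter trait deviations directly — only
#' the weight structure matters to the estimators). `sigma2_e` is set from
#' the realised genetic variance so a single-record cow has heritability
#' `cfg$h2`.
#'
#' @param genos [simulate_genotypes()] output (layout attribute required).
#' @param effects [simulate_effects()] output.
#' @param cfg a [sim_config()].
#' @param seed RNG seed (default `cfg$seed + 2`).
#' @return list: `phenotypes` (tibble), `pedigree` (tibble or NULL), `truth`
#'   (list with `v`, `component`, `g_markers`, `a`, `g_total`, `sigma2_e`,
#'   `fixed`, `realized_h2`, per-animal `w`).
#' @export
simulate_phenotypes <- function(genos, effects, cfg, seed = cfg$seed + 2) {
  set.seed(as.integer(seed))
  layout <- attr(genos, "layout")
  if (is.null(layout)) {
    stop("genotype set lacks the simulation layout attribute", call. = FALSE)
  }
  n <- nrow(layout)
  sg <- standardize_genotypes(genos)
  g_mark <- as.numeric(sg$W %*% effects$effect[sg$kept])
  pedigree <- NULL
  a <- rep(0, n)
  if (cfg$poly_frac > 0) {
    pedigree <- sim_pedigree(layout, cfg$n_parents)
    # exact top-up when auto-calibrated: markers + polygenic = sigma2_a2 in
    # the realised data, so the prior-scale REML fit recovers the scale the
    # mixture classes are defined on. (A fractional poly_frac would let the
    # LD-driven wiggle in var(g_mark) leak into the total additive variance.)
    s2a <- if (isTRUE(attr(cfg$poly_frac, "auto"))) {
      max(cfg$sigma2_a2 - var(g_mark), 0.05 * cfg$sigma2_a2)
    } else {
      cfg$poly_frac * var(g_mark)
    }
    av <- setNames(rep(NA_real_, nrow(pedigree)), pedigree$animal_id)
    idx <- setNames(seq_len(nrow(pedigree)), pedigree$animal_id)
    for (i in seq_len(nrow(pedigree))) {
      s <- pedigree$sire_id[i]; d <- pedigree$dam_id[i]
      if (is.na(s) && is.na(d)) {
        av[i] <- rnorm(1, 0, sqrt(s2a))
      } else {
        # parent average + Mendelian sampling (non-inbred parents)
        pa <- 0.5 * ((if (!is.na(s)) av[idx[s]] else 0) +
                       (if (!is.na(d)) av[idx[d]] else 0))
        av[i] <- rnorm(1, pa, sqrt(0.5 * s2a))
      }
    }
    a <- unname(av[layout$animal_id])
  }
  g_total <- g_mark + a
  sigma2_e <- var(g_total) * (1 - cfg$h2) / cfg$h2
  d <- ifelse(layout$type == "bull",
              cfg$d_min + round(rgamma(n, cfg$d_shape, scale = cfg$d_scale)),
              NA_real_)
  r <- ifelse(layout$type == "cow",
              sample(seq_along(cfg$r_probs), n, replace = TRUE,
                     prob = cfg$r_probs), NA_real_)
  w <- ifelse(layout$type == "bull",
              bull_weight(ifelse(is.na(d), 0, d), cfg$h2),
              cow_weight(ifelse(is.na(r), 1, r), cfg$h2, cfg$t))
  xb <- unname(cfg$breed_effects[layout$breed]) +
    ifelse(layout$sex == "F", cfg$sex_effect, 0)
  e <- rnorm(n, 0, sqrt(sigma2_e / w))
  y <- xb + g_total + e
  phen <- tibble(animal_id = layout$animal_id, trait = cfg$trait, value = y,
                 record_type = layout$type, d = d, r = r,
                 breed = layout$breed, sex = layout$sex)
  cows1 <- layout$type == "cow" & !is.na(r) & r == 1
  realized_h2 <- if (sum(cows1) > 10) {
    var(g_total[cows1]) / var(y[cows1] - xb[cows1])
  } else NA_real_
  list(phenotypes = phen, pedigree = pedigree,
       truth = list(v = effects$effect, component = effects$component,
                    kept = sg$kept, g_markers = g_mark, a = a,
                    g_total = setNames(g_total, layout$animal_id),
                    sigma2_e = sigma2_e,
                    fixed = list(breed = cfg$breed_effects,
                                 sex = cfg$sex_effect),
                    realized_h2 = realized_h2, w = w))
}

#' Simulate a complete multi-breed study bundle
#'
#' Genotypes, mixture effects, phenotypes, pedigree, ground truth and the
#' reference/validation split (breed C is never in the reference). The split
#' manifest records every animal's role.
#'
#' @param cfg a [sim_config()].
#' @return object of class `sim_bundle`: list with `genotypes`,
#'   `phenotypes`, `pedigree`, `truth`, `manifest` (tibble `animal_id`,
#'   `breed`, `type`, `split`), `reference_ids`, `validation_ids`, `cfg`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  genos <- simulate_genotypes(cfg, seed = cfg$seed)
  effects <- simulate_effects(cfg, seed = cfg$seed + 1)
  sim <- simulate_phenotypes(genos, effects, cfg, seed = cfg$seed + 2)
  layout <- attr(genos, "layout")
  manifest <- layout[c("animal_id", "breed", "type", "split")]
  structure(list(genotypes = genos, phenotypes = sim$phenotypes,
                 pedigree = sim$pedigree, truth = sim$truth,
                 manifest = manifest,
                 reference_ids = manifest$animal_id[manifest$split ==
                                                      "reference"],
                 validation_ids = manifest$animal_id[manifest$split ==
                                                       "validation"],
                 cfg = cfg),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("<sim_bundle>", nrow(x$genotypes$dosages), "animals x",
      ncol(x$genotypes$dosages), "markers;",
      length(x$reference_ids), "reference /", length(x$validation_ids),
      "validation\n")
  invisible(x)
}
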