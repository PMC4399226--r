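# window geometry, local GEBV, calling, pleiotropy, merging, classification

test_that("window grid enumerates starts at the step size", {
  # chromosome extent 400 kb -> 4 windows at 0, 50k, 100k, 150k
  map <- tibble::tibble(marker_id = paste0("m", 1:8), chrom = "1",
                        pos = seq(50000, 400000, by = 50000))
  grid <- make_windows(map)
  expect_equal(nrow(grid), 4)
  expect_equal(grid$start, c(0, 50000, 100000, 150000))
  expect_equal(grid$stop, grid$start + 250000)
  expect_equal(diff(grid$start), rep(50000, 3))
  # extent exactly 250 kb -> one window
  map2 <- tibble::tibble(marker_id = "x", chrom = "2", pos = 250000)
  expect_equal(nrow(make_windows(map2)), 1)
  # shorter than the span -> single fallback window covering the chromosome
  map3 <- tibble::tibble(marker_id = "y", chrom = "3", pos = 100000)
  g3 <- make_windows(map3)
  expect_equal(nrow(g3), 1)
  expect_equal(c(g3$start, g3$stop), c(0, 100000))
  expect_error(make_windows(map[0, ]), "empty")
})

test_that("window marker ranges use half-open 0-based intervals", {
  # marker at pos 250000 (1-based) is pos0 = 249999 -> inside [0, 250000)
  map <- tibble::tibble(marker_id = c("a", "b"), chrom = "1",
                        pos = c(250000, 250001))
  grid <- make_windows(map, span = 250000, step = 250000)
  expect_equal(grid$n_markers[1], 1)
  expect_equal(grid$first_marker[1], 1)
})

test_that("local GEBV is additive over a disjoint tiling", {
  b <- small_bundle()
  sg <- standardize_genotypes(b$genotypes)
  grid <- make_windows(sg$map, span = 250000, step = 250000)  # disjoint
  set.seed(5)
  v <- rnorm(ncol(sg$W), 0, 0.02)
  lg <- local_gebv(sg, v, grid)
  expect_lt(max(abs(rowSums(lg$L) - as.numeric(sg$W %*% v))), 1e-10)
  # zero effects -> zero matrix
  lg0 <- local_gebv(sg, rep(0, ncol(sg$W)), grid)
  expect_true(all(lg0$L == 0))
  # single-marker window: local GEBV = effect * column, variance ~ effect^2
  grid1 <- make_windows(sg$map)
  j <- grid1$first_marker[1]
  v1 <- rep(0, ncol(sg$W)); v1[j] <- 3
  lg1 <- local_gebv(sg, v1, grid1)
  expect_equal(unname(lg1$L[, 1]), unname(3 * sg$W[, j]),
               tolerance = 1e-12)
  expect_equal(var(lg1$L[, 1]), 9 * var(sg$W[, j]), tolerance = 1e-10)
})

test_that("window variances split by breed and flag the right windows", {
  # constant local GEBV -> zero variance; symmetric breeds -> equal variance
  grid <- tibble::tibble(window = 1:3, chrom = "1",
                         start = c(0, 50000, 100000),
                         stop = c(250000, 300000, 350000),
                         midpoint = c(125000, 175000, 225000),
                         first_marker = 1:3, last_marker = 1:3,
                         n_markers = c(1L, 1L, 0L))
  L <- cbind(rep(1, 6), c(1, 2, 3, 1, 2, 3), rep(0, 6))
  lg <- structure(list(L = L, grid = grid,
                       breed = rep(c("A", "B"), each = 3),
                       ids = paste0("i", 1:6)), class = "local_gebv")
  wv <- window_variance(lg)
  expect_equal(wv$variance[wv$breed == "all" & wv$window == 1], 0)
  expect_equal(wv$variance[wv$breed == "A" & wv$window == 2],
               wv$variance[wv$breed == "B" & wv$window == 2])
  expect_equal(wv$variance[wv$breed == "A" & wv$window == 2], 1)
  # hand-computed 3-animal variance
  expect_equal(wv$variance[wv$breed == "all" & wv$window == 2],
               var(c(1, 2, 3, 1, 2, 3)))
  # empty windows are excluded from the mean variance
  expect_equal(unique(wv$mean_variance[wv$breed == "A"]), mean(c(0, 1)))
})

test_that("QTL calling is strict and breed-specificity is annotated", {
  # 100 windows: 99 at variance 1, one at 1000 -> ratio ~91, flagged
  mkvar <- function(vars, breed) {
    tibble::tibble(window = seq_along(vars), chrom = "1",
                   midpoint = 1e5 * seq_along(vars),
                   n_markers = 1L, breed = breed, variance = vars,
                   mean_variance = mean(vars), ratio = vars / mean(vars))
  }
  vars <- c(rep(1, 99), 1000)
  wv <- mkvar(vars, "all")
  called <- call_qtl_windows(wv)
  expect_equal(called$window, 100L)
  expect_equal(called$ratio, 1000 / mean(vars), tolerance = 1e-12)
  # all-equal variances -> ratio 1, nothing flagged
  expect_equal(nrow(call_qtl_windows(mkvar(rep(2, 10), "all"))), 0)
  # exactly at the threshold -> not flagged (strict inequality)
  at50 <- mkvar(c(rep(1, 49), 50 + 1e-9), "all")
  at50$ratio <- at50$variance / 1  # force mean 1 for an exact boundary
  at50$mean_variance <- 1
  at50$ratio[50] <- 50
  expect_equal(nrow(call_qtl_windows(at50)), 0)
  # flagged in one breed only -> breed-specific
  two <- dplyr::bind_rows(mkvar(c(rep(1, 9), 600), "A"),
                          mkvar(rep(1, 10), "B"))
  called2 <- call_qtl_windows(two)
  expect_true(all(called2$breed_specific))
})

synthetic_lg <- function(effA, effB, n = 300, m = 60, seed = 7,
                         traits = c("FY", "MY")) {
  # two-trait local-GEBV fixture on a shared grid: markers every 50 kb
  set.seed(seed)
  W <- scale(matrix(rnorm(n * m), n, m))
  map <- tibble::tibble(marker_id = paste0("m", 1:m), chrom = "1",
                        pos = 50000 * seq_len(m))
  sg <- structure(list(W = W, freq = rep(0.5, m), kept = rep(TRUE, m),
                       map = map, dosages = NULL, breed = rep("A", n)),
                  class = "std_genotypes")
  grid <- make_windows(map)
  out <- list(local_gebv(sg, effA, grid), local_gebv(sg, effB, grid))
  names(out) <- traits
  out
}

test_that("pleiotropy correlations report signed relations and filter", {
  m <- 60
  effA <- rep(0, m); effA[10] <- 1
  lgs <- synthetic_lg(effA, -effA)        # trait B = -(trait A)
  pc <- pleiotropy_correlations(lgs)
  hit <- pc[pc$pass, ]
  expect_true(nrow(hit) >= 1)
  expect_true(all(abs(hit$correlation + 1) < 1e-10))
  lgs2 <- synthetic_lg(effA, effA)        # identical -> +1
  pc2 <- pleiotropy_correlations(lgs2)
  expect_true(all(abs(pc2$correlation[pc2$pass] - 1) < 1e-10))
  # sub-threshold trait -> no correlation emitted for that window
  effB <- rep(0, m); effB[40] <- 1        # disjoint signals
  pc3 <- pleiotropy_correlations(synthetic_lg(effA, effB))
  expect_false(any(pc3$pass & is.na(pc3$correlation)))
  expect_true(all(is.na(pc3$correlation[!pc3$pass])))
  expect_true(any(!pc3$pass))
})

test_that("windows merge by midpoint gap and sign pattern", {
  m <- 60
  effA <- rep(0, m)
  effA[c(10, 11)] <- 0.8   # adjacent markers 50 kb apart, same windows chain
  effA[45] <- 0.9          # far signal > 0.5 Mb away
  lgs <- synthetic_lg(effA, effA * 0.5)
  wv <- window_variance(lgs[["FY"]], by_breed = FALSE)
  flagged <- call_qtl_windows(wv, threshold = 3)
  regions <- merge_windows_to_regions(flagged, lgs)
  expect_equal(nrow(regions), 2)
  # midpoints ~1.0 and ~1.4 Mb (gap < 0.5 Mb) with a shared pattern merge
  g <- lgs[[1]]$grid
  w1 <- g$window[which.min(abs(g$midpoint - 1.0e6))]
  w2 <- g$window[which.min(abs(g$midpoint - 1.4e6))]
  fl <- tibble::tibble(window = c(w1, w2))
  lg_uniform <- synthetic_lg(effA, effA)   # identical sign patterns
  r2 <- merge_windows_to_regions(fl, lg_uniform)
  expect_equal(nrow(r2), 1)
  # midpoints ~1.0 and ~1.6 Mb (gap >= 0.5 Mb) -> two regions
  w3 <- g$window[which.min(abs(g$midpoint - 1.65e6))]
  expect_gte(g$midpoint[g$window == w3] - g$midpoint[g$window == w1], 5e5)
  r3 <- merge_windows_to_regions(tibble::tibble(window = c(w1, w3)),
                                 lg_uniform)
  expect_equal(nrow(r3), 2)
})

test_that("adjacent windows with opposite correlation signs do not merge", {
  m <- 60
  effA <- rep(0, m); effA[c(20, 26)] <- 1
  effB <- rep(0, m); effB[20] <- 1; effB[26] <- -1
  lgs <- synthetic_lg(effA, effB)
  g <- lgs[[1]]$grid
  # windows holding only marker 20 vs only marker 26 sit ~0.3 Mb apart
  w20 <- g$window[g$start <= 50000 * 20 - 1 & 50000 * 20 - 1 < g$stop]
  w26 <- g$window[g$start <= 50000 * 26 - 1 & 50000 * 26 - 1 < g$stop]
  solo20 <- setdiff(w20, w26)[1]
  solo26 <- setdiff(w26, w20)[1]
  r <- merge_windows_to_regions(tibble::tibble(window = c(solo20, solo26)),
                                lgs)
  expect_equal(nrow(r), 2)
})

test_that("pleiotropy classes follow the nine-way rule", {
  m <- 60
  base <- rep(0, m); base[10] <- 1
  mk_region <- function(lgs) {
    wv <- window_variance(lgs[[1]], by_breed = FALSE)
    flagged <- call_qtl_windows(wv, threshold = 3)
    merge_windows_to_regions(flagged, lgs)
  }
  # FY dominant, MY negatively correlated -> FY-
  lgs <- synthetic_lg(base, -0.5 * base)
  r <- mk_region(lgs)
  expect_equal(classify_pleiotropy(r[1, ], lgs), "FY-")
  # FY dominant, MY positively correlated -> FY+
  lgs2 <- synthetic_lg(base, 0.5 * base)
  expect_equal(classify_pleiotropy(mk_region(lgs2)[1, ], lgs2), "FY+")
  # PY dominant, both other yields positive -> PY+. Variance ratios are
  # scale-invariant, so dominance must come from profile shape: FY and MY get
  # a diffuse background that lowers their peak ratio below PY's pure spike.
  set.seed(21)
  fy_eff <- 0.5 * base + rnorm(m, 0, 0.05)
  my_eff <- 0.5 * base + rnorm(m, 0, 0.05)
  m3 <- list(synthetic_lg(fy_eff, my_eff)[[1]],
             synthetic_lg(fy_eff, my_eff)[[2]],
             synthetic_lg(base, base)[[1]])
  names(m3) <- c("FY", "MY", "PY")
  r3 <- mk_region(m3["PY"])
  expect_equal(classify_pleiotropy(r3[1, ], m3), "PY+")
  # only a composition trait above threshold -> grouped with MYn
  set.seed(13)
  flatFY <- rnorm(m, 0, 1e-3)  # diffuse, no window passes the filter
  m4 <- list(synthetic_lg(flatFY, base)[[1]],
             synthetic_lg(base, base)[[2]])
  names(m4) <- c("FY", "P%")
  rp <- mk_region(m4["P%"])
  expect_equal(classify_pleiotropy(rp[1, ], m4), "MYn")
  # region far from any signal: nothing above threshold -> unclassified
  lgs_far <- synthetic_lg(base, 0.5 * base)
  far_windows <- lgs_far[[1]]$grid$window[30:31]
  fake_region <- tibble::tibble(windows = list(far_windows))
  expect_equal(classify_pleiotropy(fake_region, lgs_far), "unclassified")
})

test_that("map_qtl runs the full pipeline and finds a planted QTL", {
  b <- small_bundle()
  sg <- standardize_genotypes(b$genotypes)
  m <- ncol(sg$W)
  vFY <- rep(0, m); vFY[50] <- 0.3
  vMY <- -0.6 * vFY
  qm <- map_qtl(sg, list(FY = vFY, MY = vMY), qtl_threshold = 10)
  expect_gte(nrow(qm$regions), 1)
  top <- qm$regions[which.max(qm$regions$ratio_FY), ]
  pos0 <- sg$map$pos[50] - 1
  expect_true(top$chrom == sg$map$chrom[50] &&
                top$start <= pos0 && pos0 < top$stop)
  expect_equal(top$class, "FY-")
  td <- tidy(qm)
  expect_true(all(c("region", "chrom", "class") %in% names(td)))
  p <- autoplot(qm)
  expect_s3_class(p, "ggplot")
})
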