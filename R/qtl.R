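#' Sliding-window grid over a marker map
#'
#' Windows of `span` bp stepped by `step` bp along each chromosome, on
#' 0-based half-open internal coordinates (`pos0 = pos - 1`): windows
#' `[s, s + span)` for `s = 0, step, 2 step, ...` while `s + span <=`
#' chromosome extent. A chromosome shorter than `span` gets one window
#' covering it. Each window records the index range of its markers
#' (`start <= pos0 < stop`).
#'
#' @param map marker map tibble (`marker_id`, `chrom`, `pos`; 1-based bp).
#' @param span window span in bp (default 250000).
#' @param step window step in bp (default 50000).
#' @return tibble `window`, `chrom`, `start`, `stop`, `midpoint`,
#'   `first_marker`, `last_marker` (global marker indices; NA when empty),
#'   `n_markers`.
#' @export
make_windows <- function(map, span = 250000, step = 50000) {
  map <- validate_marker_map(map)
  if (!nrow(map)) stop("empty marker map", call. = FALSE)
  pos0 <- map$pos - 1
  out <- purrr::map_dfr(unique(map$chrom), function(ch) {
    sel <- which(map$chrom == ch)
    extent <- max(pos0[sel]) + 1
    starts <- if (extent < span) 0 else seq(0, extent - span, by = step)
    stops <- if (extent < span) extent else starts + span
    purrr::map2_dfr(starts, stops, function(s, e) {
      inw <- sel[pos0[sel] >= s & pos0[sel] < e]
      tibble(chrom = ch, start = s, stop = e, midpoint = (s + e) / 2,
             first_marker = if (length(inw)) min(inw) else NA_integer_,
             last_marker = if (length(inw)) max(inw) else NA_integer_,
             n_markers = length(inw))
    })
  })
  dplyr::bind_cols(tibble(window = seq_len(nrow(out))), out)
}

#' Local GEBV: per-window genomic values
#'
#' The portion of each animal's GEBV attributable to the markers inside each
#' window: `W[, j1:j2] %*% v_hat[j1:j2]`. Empty windows contribute 0.
#'
#' @param sg standardized genotypes of the animals to evaluate (typically the
#'   reference set, standardised with training frequencies).
#' @param v_hat per-marker effects aligned to `sg` columns.
#' @param grid window grid from [make_windows()] built on `sg$map`.
#' @return object of class `local_gebv`: list with `L` (animals x windows
#'   matrix), `grid`, `breed`, `ids`.
#' @export
local_gebv <- function(sg, v_hat, grid) {
  W <- sg$W
  if (length(v_hat) != ncol(W)) {
    stop("v_hat length must match the marker count", call. = FALSE)
  }
  L <- matrix(0, nrow(W), nrow(grid))
  for (k in seq_len(nrow(grid))) {
    if (grid$n_markers[k] == 0) next
    j <- grid$first_marker[k]:grid$last_marker[k]
    L[, k] <- W[, j, drop = FALSE] %*% v_hat[j]
  }
  ids <- rownames(W)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(W)))
  rownames(L) <- ids
  structure(list(L = L, grid = grid, breed = sg$breed, ids = ids),
            class = "local_gebv")
}

#' Per-window local-GEBV variance, by breed
#'
#' Sample variance of the local GEBV across animals, per window and breed
#' group (plus a pooled `"all"` group), and the variance ratio to the
#' genome-wide mean over windows containing at least one marker. Breed groups
#' with fewer than two animals are excluded with a warning.
#'
#' @param lg a [local_gebv()] result.
#' @param by_breed also report per-breed groups (default TRUE).
#' @return tibble `window`, `chrom`, `midpoint`, `n_markers`, `breed`,
#'   `variance`, `mean_variance` (per breed, marker-bearing windows only),
#'   `ratio`.
#' @export
window_variance <- function(lg, by_breed = TRUE) {
  groups <- list(all = seq_len(nrow(lg$L)))
  if (by_breed) {
    for (b in unique(lg$breed)) {
      sel <- which(lg$breed == b)
      if (length(sel) < 2) {
        warning("breed group '", b, "' has fewer than 2 animals; excluded",
                call. = FALSE)
        next
      }
      groups[[b]] <- sel
    }
  }
  purrr::imap_dfr(groups, function(sel, label) {
    vr <- apply(lg$L[sel, , drop = FALSE], 2, var)
    mv <- mean(vr[lg$grid$n_markers > 0])
    tibble(window = lg$grid$window, chrom = lg$grid$chrom,
           midpoint = lg$grid$midpoint, n_markers = lg$grid$n_markers,
           breed = label, variance = vr, mean_variance = mv,
           ratio = if (mv > 0) vr / mv else NA_real_)
  })
}

#' Flag QTL-bearing windows
#'
#' A window contains a QTL when its local-GEBV variance is strictly greater
#' than `threshold` times the mean variance of marker-bearing windows, per
#' breed group. Windows flagged in exactly one breed (among the non-pooled
#' groups) are annotated breed-specific.
#'
#' @param variances tibble from [window_variance()].
#' @param threshold variance-ratio threshold (default 50).
#' @return the flagged subset with columns `qtl` (TRUE) and `breed_specific`.
#' @export
call_qtl_windows <- function(variances, threshold = 50) {
  flagged <- variances |>
    dplyr::filter(.data$n_markers > 0, .data$ratio > threshold) |>
    dplyr::mutate(qtl = TRUE)
  breed_rows <- dplyr::filter(flagged, .data$breed != "all")
  spec_count <- breed_rows |>
    dplyr::count(.data$window, name = "n_breeds_flagged")
  n_groups <- length(setdiff(unique(variances$breed), "all"))
  flagged |>
    dplyr::left_join(spec_count, by = "window") |>
    dplyr::mutate(
      n_breeds_flagged = dplyr::coalesce(.data$n_breeds_flagged, 0L),
      breed_specific = n_groups > 1 & .data$n_breeds_flagged == 1L)
}

#' Per-window trait-pair local-GEBV correlations
#'
#' For each window in which *both* traits pass the variance filter (local
#' GEBV variance strictly greater than `threshold` times the trait's average
#' marker-bearing window), the Pearson correlation of the two traits' local
#' GEBV across animals. Windows failing the filter for a trait are reported
#' with `pass = FALSE` and no correlation ("no effect" for that trait).
#'
#' @param lg_list named list of [local_gebv()] results, one per trait, on the
#'   same animals and grid.
#' @param threshold variance-ratio filter (default 3).
#' @return tibble `window`, `chrom`, `midpoint`, `trait1`, `trait2`,
#'   `pass` (both traits above filter), `correlation` (NA when not `pass`).
#' @export
pleiotropy_correlations <- function(lg_list, threshold = 3) {
  stopifnot(length(lg_list) >= 2, !is.null(names(lg_list)))
  grid <- lg_list[[1]]$grid
  ratios <- purrr::map(lg_list, function(lg) {
    vr <- apply(lg$L, 2, var)
    vr / mean(vr[grid$n_markers > 0])
  })
  traits <- names(lg_list)
  pairs <- utils::combn(traits, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pp) {
    ok <- ratios[[pp[1]]] > threshold & ratios[[pp[2]]] > threshold &
      grid$n_markers > 0
    cc <- rep(NA_real_, nrow(grid))
    for (k in which(ok)) {
      cc[k] <- cor(lg_list[[pp[1]]]$L[, k], lg_list[[pp[2]]]$L[, k])
    }
    tibble(window = grid$window, chrom = grid$chrom,
           midpoint = grid$midpoint, trait1 = pp[1], trait2 = pp[2],
           pass = ok, correlation = cc)
  })
}

window_sign_pattern <- function(lg_list, threshold = 3) {
  # per window: each trait classified -, + or n against the window's top
  # variance-ratio trait; below-filter traits are n
  grid <- lg_list[[1]]$grid
  traits <- names(lg_list)
  ratios <- purrr::map(lg_list, function(lg) {
    vr <- apply(lg$L, 2, var)
    vr / mean(vr[grid$n_markers > 0])
  })
  rat <- do.call(cbind, ratios)
  pattern <- character(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    if (grid$n_markers[k] == 0 || all(rat[k, ] <= threshold)) {
      pattern[k] <- paste(rep("n", length(traits)), collapse = "")
      next
    }
    top <- which.max(rat[k, ])
    sig <- vapply(seq_along(traits), function(t) {
      if (rat[k, t] <= threshold) return("n")
      if (t == top) return("+")
      if (cor(lg_list[[t]]$L[, k], lg_list[[top]]$L[, k]) < 0) "-" else "+"
    }, "")
    pattern[k] <- paste(sig, collapse = "")
  }
  pattern
}

#' Merge flagged windows into QTL regions
#'
#' Windows whose successive midpoints along a chromosome differ by less than
#' `max_gap` *and* whose per-trait effect-sign patterns (-, + or n per trait,
#' from the window sign pattern) agree are chain-merged into one region;
#' region span runs from the smallest start to the largest stop.
#'
#' @param flagged flagged-window tibble from [call_qtl_windows()] (any breed
#'   group; windows are merged on their union).
#' @param lg_list named per-trait [local_gebv()] list (defines sign
#'   patterns).
#' @param max_gap midpoint separation below which windows merge (default
#'   5e5 bp).
#' @param threshold variance-ratio filter used inside the sign patterns
#'   (default 3).
#' @return tibble `region`, `chrom`, `start`, `stop`, `midpoint`,
#'   `windows` (list column of member window ids), `pattern`.
#' @export
merge_windows_to_regions <- function(flagged, lg_list, max_gap = 500000,
                                     threshold = 3) {
  grid <- lg_list[[1]]$grid
  win <- grid |>
    dplyr::filter(.data$window %in% unique(flagged$window)) |>
    dplyr::arrange(.data$chrom, .data$midpoint)
  if (!nrow(win)) {
    return(tibble(region = integer(0), chrom = character(0),
                  start = double(0), stop = double(0), midpoint = double(0),
                  windows = list(), pattern = character(0)))
  }
  pattern <- window_sign_pattern(lg_list, threshold)
  win$pattern <- pattern[win$window]
  newreg <- c(TRUE, diff(as.integer(factor(win$chrom,
                                           unique(win$chrom)))) != 0 |
                diff(win$midpoint) >= max_gap |
                win$pattern[-1] != win$pattern[-nrow(win)])
  win$region <- cumsum(newreg)
  win |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(chrom = dplyr::first(.data$chrom),
                     start = min(.data$start), stop = max(.data$stop),
                     midpoint = (min(.data$start) + max(.data$stop)) / 2,
                     windows = list(.data$window),
                     pattern = dplyr::first(.data$pattern),
                     .groups = "drop")
}

#' Classify a QTL region's pleiotropy pattern
#'
#' Nine-way label: the yield trait (among `yield_traits`) with the largest
#' region variance ratio gives the prefix; the suffix is `-` when the
#' region-level local GEBV of the top trait correlates negatively with either
#' remaining yield trait passing the variance filter, `+` when any passing
#' correlation is positive, `n` when no other yield trait passes. Regions in
#' which no yield trait passes but a composition trait (`pct_traits`) does
#' are grouped with `MYn` (composition is read as a sensitive milk-volume
#' signal); regions with nothing above the filter are `"unclassified"`.
#'
#' @param region one row of [merge_windows_to_regions()] output (or a list
#'   with `windows`).
#' @param lg_list named per-trait [local_gebv()] list.
#' @param threshold variance-ratio filter (default 3).
#' @param yield_traits names of the yield traits (default FY, MY, PY).
#' @param pct_traits names of the composition traits (default F%, P%).
#' @return the class label string.
#' @export
classify_pleiotropy <- function(region, lg_list, threshold = 3,
                                yield_traits = c("FY", "MY", "PY"),
                                pct_traits = c("F%", "P%")) {
  grid <- lg_list[[1]]$grid
  wins <- unlist(region$windows)
  traits <- names(lg_list)
  # region-level local GEBV: sum over member windows
  agg <- purrr::map(lg_list, function(lg) {
    rowSums(lg$L[, wins, drop = FALSE])
  })
  ratios <- purrr::map_dbl(lg_list, function(lg) {
    vr <- apply(lg$L, 2, var)
    mv <- mean(vr[grid$n_markers > 0])
    if (mv > 0) max(vr[wins] / mv) else NA_real_
  })
  yt <- intersect(yield_traits, traits)
  pt <- intersect(pct_traits, traits)
  ypass <- yt[ratios[yt] > threshold]
  if (!length(ypass)) {
    if (length(pt) && any(ratios[pt] > threshold)) return("MYn")
    return("unclassified")
  }
  top <- yt[which.max(ratios[yt])]
  others <- setdiff(yt, top)
  others <- others[ratios[others] > threshold]
  if (!length(others)) return(paste0(top, "n"))
  cors <- vapply(others, function(tr) cor(agg[[top]], agg[[tr]]), 0)
  if (any(cors < 0)) paste0(top, "-")
  else if (any(cors > 0)) paste0(top, "+")
  else paste0(top, "n")
}

#' Map QTL from fitted SNP effects
#'
#' The full local-GEBV pipeline: window grid, per-trait local GEBV on the
#' reference animals, per-breed window variances, QTL calling at the 50x
#' threshold, region merging (< 0.5 Mbp midpoint gaps, matching sign
#' patterns) and nine-class pleiotropy labels.
#'
#' @param sg standardized reference genotypes.
#' @param effects named list (by trait) of per-marker effect vectors aligned
#'   to `sg` columns.
#' @param span,step window geometry in bp (defaults 250 kb / 50 kb).
#' @param qtl_threshold variance-ratio threshold for calling (default 50).
#' @param pleiotropy_threshold variance-ratio filter for correlations
#'   (default 3).
#' @param max_gap merge gap in bp (default 5e5).
#' @param yield_traits,pct_traits trait roles for classification.
#' @return object of class `qtl_map`: list with `regions` (tibble including
#'   per-trait variance ratios and `class`), `windows` (per-breed variance
#'   table of the trait with regions), `flagged`, `correlations`, `grid`.
#' @export
map_qtl <- function(sg, effects, span = 250000, step = 50000,
                    qtl_threshold = 50, pleiotropy_threshold = 3,
                    max_gap = 500000, yield_traits = c("FY", "MY", "PY"),
                    pct_traits = c("F%", "P%")) {
  stopifnot(is.list(effects), !is.null(names(effects)))
  grid <- make_windows(sg$map, span = span, step = step)
  lg_list <- purrr::map(effects, ~ local_gebv(sg, .x, grid))
  variances <- purrr::imap_dfr(lg_list, function(lg, tr) {
    dplyr::bind_cols(tibble(trait = tr),
                     window_variance(lg, by_breed = TRUE))
  })
  flagged <- call_qtl_windows(variances, threshold = qtl_threshold)
  correlations <- if (length(lg_list) >= 2) {
    pleiotropy_correlations(lg_list, threshold = pleiotropy_threshold)
  } else NULL
  regions <- merge_windows_to_regions(flagged, lg_list, max_gap = max_gap,
                                      threshold = pleiotropy_threshold)
  if (nrow(regions)) {
    regions$class <- vapply(seq_len(nrow(regions)), function(i) {
      classify_pleiotropy(regions[i, ], lg_list,
                          threshold = pleiotropy_threshold,
                          yield_traits = yield_traits,
                          pct_traits = pct_traits)
    }, "")
    # per-trait region-max variance ratios
    for (tr in names(lg_list)) {
      vr <- apply(lg_list[[tr]]$L, 2, var)
      mv <- mean(vr[grid$n_markers > 0])
      regions[[paste0("ratio_", tr)]] <- vapply(regions$windows, function(w) {
        if (mv > 0) max(vr[w] / mv) else NA_real_
      }, 0)
    }
  } else {
    regions$class <- character(0)
  }
  structure(list(regions = regions, windows = variances, flagged = flagged,
                 correlations = correlations, grid = grid,
                 thresholds = c(qtl = qtl_threshold,
                                pleiotropy = pleiotropy_threshold),
                 span = span, step = step, max_gap = max_gap),
            class = "qtl_map")
}

#' @export
print.qtl_map <- function(x, ...) {
  cat("<qtl_map>", nrow(x$grid), "windows,",
      length(unique(x$flagged$window)), "flagged,",
      nrow(x$regions), "region(s)\n")
  if (nrow(x$regions)) print(x$regions[c("region", "chrom", "start", "stop",
                                         "class")])
  invisible(x)
}

#' @rdname map_qtl
#' @param x a `qtl_map`.
#' @param ... unused.
#' @export
tidy.qtl_map <- function(x, ...) x$regions

#' @rdname map_qtl
#' @param object a `qtl_map`.
#' @param trait trait whose window variances to draw (default: first).
#' @export
autoplot.qtl_map <- function(object, trait = NULL, ...) {
  df <- dplyr::filter(object$windows, .data$breed == "all",
                      .data$n_markers > 0)
  if (is.null(trait)) trait <- df$trait[1]
  df <- dplyr::filter(df, .data$trait == !!trait)
  df$cum <- cumulative_bp(df, "midpoint")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cum / 1e6, y = .data$ratio,
                                   colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.7, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = object$thresholds["qtl"],
                        linetype = "dashed") +
    ggplot2::labs(x = "window midpoint, cumulative (Mb)",
                  y = "local GEBV variance ratio",
                  title = paste("Local-GEBV window variance -", trait)) +
    ggplot2::theme_minimal()
}
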