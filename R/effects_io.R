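#' Write per-marker SNP effects as TSV
#'
#' Columns: `marker_id`, `chrom`, `pos` (1-based bp), `effect`, plus any
#' posterior class-probability columns present (named `p_class*`). Numbers
#' round-trip losslessly at 12 significant digits.
#'
#' @param effects numeric vector aligned to `map`, or a tibble with
#'   `marker_id` and `effect` (and optional `p_class*` columns) as produced
#'   by `tidy()` on a fit.
#' @param map marker map tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_snp_effects <- function(effects, map, path) {
  map <- validate_marker_map(map)
  if (is.data.frame(effects)) {
    if (nrow(effects) != nrow(map)) {
      stop("effect table length (", nrow(effects),
           ") does not match map (", nrow(map), ")", call. = FALSE)
    }
    extra <- effects[grep("^p_class", names(effects))]
    eff <- effects$effect
  } else {
    if (length(effects) != nrow(map)) {
      stop("effect vector length (", length(effects),
           ") does not match map (", nrow(map), ")", call. = FALSE)
    }
    extra <- NULL
    eff <- as.numeric(effects)
  }
  out <- tibble(marker_id = map$marker_id, chrom = map$chrom, pos = map$pos,
                effect = eff)
  if (!is.null(extra) && ncol(extra)) out <- dplyr::bind_cols(out, extra)
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], signif, digits = 12)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a SNP-effect TSV written by [write_snp_effects()]
#' @param path TSV path.
#' @return tibble in file order.
#' @export
read_snp_effects <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  readr::read_tsv(path, col_types = readr::cols(
    marker_id = readr::col_character(), chrom = readr::col_character(),
    .default = readr::col_double()), progress = FALSE)
}

#' Write QTL regions as a BED-like TSV
#'
#' One row per region: `chrom`, `start`, `stop` (0-based half-open), `class`,
#' `midpoint_mb` (3 decimals), `n_windows`, plus any per-trait variance-ratio
#' columns (`ratio_*`). An empty region set writes a header-only file.
#'
#' @param regions region tibble from [map_qtl()] / `tidy(qtl_map)`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_qtl_regions <- function(regions, path) {
  ratio_cols <- grep("^ratio_", names(regions), value = TRUE)
  out <- tibble(chrom = as.character(regions$chrom),
                start = regions$start, stop = regions$stop,
                class = if (nrow(regions)) regions$class else character(0),
                midpoint_mb = round(regions$midpoint / 1e6, 3),
                n_windows = vapply(regions$windows, length, 0L))
  for (cc in ratio_cols) out[[cc]] <- signif(regions[[cc]], 12)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a QTL-region TSV written by [write_qtl_regions()]
#' @param path TSV path.
#' @return tibble in file order.
#' @export
read_qtl_regions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), class = readr::col_character(),
    .default = readr::col_double()), progress = FALSE)
}
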