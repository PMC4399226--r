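#' Trait parameter presets
#'
#' Heritability (`h2`) of a single record and repeatability (`t`) for the
#' dairy traits the package targets. The milk production traits (FY, MY, PY,
#' F%, P%) share h2 = 0.33, t = 0.56; stature (STAT) h2 = 0.45 (single
#' record, t set equal to h2); fertility (FERT) h2 = 0.03, t = 0.05; survival
#' (SURV) h2 = 0.025, t = 0.035.
#'
#' @param trait optional character vector; return only these traits.
#' @return tibble `trait`, `h2`, `t`.
#' @export
trait_params <- function(trait = NULL) {
  preset <- tibble(
    trait = c("FY", "MY", "PY", "F%", "P%", "STAT", "FERT", "SURV"),
    h2 = c(0.33, 0.33, 0.33, 0.33, 0.33, 0.45, 0.03, 0.025),
    t  = c(0.56, 0.56, 0.56, 0.56, 0.56, 0.45, 0.05, 0.035)
  )
  if (!is.null(trait)) {
    miss <- setdiff(trait, preset$trait)
    if (length(miss)) {
      stop("no preset parameters for trait(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    preset <- preset[match(trait, preset$trait), ]
  }
  preset
}

check_h2_t <- function(h2, t = NULL) {
  # h2 = 0 is admitted as the degenerate boundary (formulas reduce cleanly)
  if (any(h2 < 0 | h2 > 1)) {
    stop("heritability h2 must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(t) && any(t < h2 | t > 1)) {
    stop("repeatability t must lie in [h2, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Record weight for a bull with d effective daughters
#'
#' Daughter trait deviations carry an error variance of `sigma2_e / w` with
#' `w = d (1 - h2) / (4 - h2)`: the more effective daughters, the smaller the
#' error of the deviation. `d = 0` yields `w = 0` (an uninformative record).
#'
#' @param d effective daughter count (vectorised), `d >= 0`.
#' @param h2 heritability of a single record, in (0, 1].
#' @return numeric weight(s) `w >= 0`.
#' @export
bull_weight <- function(d, h2) {
  check_h2_t(h2)
  if (any(d < 0)) stop("effective daughter count d must be >= 0",
                       call. = FALSE)
  d * (1 - h2) / (4 - h2)
}

#' Record weight for a cow with r own records
#'
#' `w = r (1 - h2) / (1 + (r - 1) t - r h2)`, scaled so that a cow with a
#' single record has `w = 1` exactly, i.e. error variance `sigma2_e`.
#'
#' @param r own-record count (vectorised), at least 1.
#' @param h2 heritability of a single record, in (0, 1].
#' @param t repeatability, in `[h2, 1]`.
#' @return numeric weight(s) `w > 0`.
#' @export
cow_weight <- function(r, h2, t) {
  check_h2_t(h2, t)
  if (any(r < 1)) stop("cow record count r must be >= 1", call. = FALSE)
  den <- 1 + (r - 1) * t - r * h2
  if (any(den <= 0)) {
    stop("invalid parameter combination: 1 + (r-1)t - r*h2 <= 0",
         call. = FALSE)
  }
  r * (1 - h2) / den
}

#' Residual weight diagonal for a phenotype table
#'
#' Builds the per-record weights `w_i` (bulls via [bull_weight()], cows via
#' [cow_weight()]) and the diagonal of the residual weight matrix
#' `E = diag(1 / w_i)`. Records with `w = 0` (bulls with no effective
#' daughters) carry no information and are dropped with a warning.
#'
#' @param phenos phenotype tibble (see [read_phenotypes()]).
#' @param params trait parameters, tibble `trait`, `h2`, `t`; defaults to the
#'   [trait_params()] presets for the traits present.
#' @return the phenotype tibble with columns `w` and `e_diag` (`= 1/w`)
#'   appended, zero-weight records removed, input order preserved.
#' @export
residual_weights <- function(phenos, params = NULL) {
  phenos <- validate_phenotypes(phenos)
  if (is.null(params)) params <- trait_params(unique(phenos$trait))
  params <- as_tibble(params)
  miss <- setdiff(unique(phenos$trait), params$trait)
  if (length(miss)) {
    stop("no (h2, t) parameters supplied for trait(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::left_join(phenos, params[c("trait", "h2", "t")], by = "trait")
  out$w <- NA_real_
  bulls <- out$record_type == "bull"
  if (any(bulls)) {
    db <- ifelse(is.na(out$d[bulls]), 0, out$d[bulls])
    out$w[bulls] <- bull_weight(db, out$h2[bulls])
  }
  if (any(!bulls)) {
    out$w[!bulls] <- cow_weight(out$r[!bulls], out$h2[!bulls], out$t[!bulls])
  }
  drop <- out$w <= 0
  if (all(drop)) {
    stop("all records have zero weight; nothing to analyse", call. = FALSE)
  }
  if (any(drop)) {
    warning(sum(drop), " record(s) with zero weight dropped (no information)",
            call. = FALSE)
    out <- out[!drop, ]
  }
  out$e_diag <- 1 / out$w
  out$h2 <- NULL; out$t <- NULL
  out
}

#' Composition-trait deviation by linear approximation
#'
#' Converts a solid-yield deviation (fat or protein, kg) and a milk-yield
#' deviation (L) into a composition deviation (fat or protein fraction of
#' milk) by linearising the yield ratio at the population means:
#' `(yield_mean / milk_mean) * (yield_dev / yield_mean - milk_dev /
#' milk_mean)`. Returned on the fraction scale; multiply by 100 for percent.
#'
#' @param yield_dev solid-yield deviation (kg/lactation).
#' @param milk_dev milk-yield deviation (L/lactation).
#' @param yield_mean population mean solid yield (> 0), e.g. Holstein fat
#'   yield 284 kg/lactation.
#' @param milk_mean population mean milk yield (> 0), e.g. Holstein
#'   7417 L/lactation.
#' @return composition deviation, fraction scale (vectorised).
#' @export
composition_deviation <- function(yield_dev, milk_dev, yield_mean, milk_mean) {
  if (any(yield_mean <= 0) || any(milk_mean <= 0)) {
    stop("population means must be positive", call. = FALSE)
  }
  (yield_mean / milk_mean) * (yield_dev / yield_mean - milk_dev / milk_mean)
}
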