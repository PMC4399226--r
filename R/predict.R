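#' Predict genomic breeding values for new animals
#'
#' Standardises the validation genotypes with the *training* allele
#' frequencies and forms the SNP-only prediction `y_hat_v = W v_hat` and,
#' when polygenic solutions are supplied, the total genetic merit
#' `y_hat = a_hat + W v_hat`.
#'
#' @param genotypes a [genotype_set()] holding the validation animals.
#' @param fit a `gblup_fit` or `bayesr_fit` (anything with `v`
#'   (`marker_id`, `effect`), `freq` and `kept`), or a named effect vector
#'   plus explicit `freq`/`kept`.
#' @param a_hat optional named vector (or tibble `animal_id`, `estimate`) of
#'   polygenic solutions; animals without one get 0.
#' @return tibble `animal_id`, `breed`, `y_hat_v`, `y_hat`.
#' @export
predict_gebv <- function(genotypes, fit, a_hat = NULL) {
  freq_full <- rep(NA_real_, ncol(genotypes$dosages))
  freq_full[fit$kept] <- fit$freq
  if (length(fit$kept) != ncol(genotypes$dosages)) {
    stop("marker mismatch: fit was trained on ", length(fit$kept),
         " markers, genotypes have ", ncol(genotypes$dosages), call. = FALSE)
  }
  freq_full[!fit$kept] <- 0.5  # dropped markers never receive an effect
  sg <- standardize_genotypes(genotypes, freq = freq_full)
  v <- fit$v
  if (nrow(v) != sum(fit$kept)) {
    stop("marker mismatch between fitted effects and validation genotypes",
         call. = FALSE)
  }
  eff <- setNames(v$effect, v$marker_id)
  if (!all(names(eff) %in% colnames(sg$W))) {
    stop("marker mismatch between fitted effects and validation genotypes",
         call. = FALSE)
  }
  yv <- as.numeric(sg$W[, names(eff), drop = FALSE] %*% eff)
  av <- rep(0, nrow(sg$W))
  if (!is.null(a_hat)) {
    if (is.data.frame(a_hat)) a_hat <- setNames(a_hat$estimate,
                                                a_hat$animal_id)
    hit <- match(rownames(sg$W), names(a_hat))
    av <- ifelse(is.na(hit), 0, a_hat[hit])
  }
  tibble(animal_id = rownames(sg$W), breed = sg$breed,
         y_hat_v = yv, y_hat = av + yv)
}

#' Prediction accuracy: Pearson correlation of phenotype and prediction
#'
#' @param y observed phenotypes (n >= 3).
#' @param y_hat predictions.
#' @return the correlation `r(y, y_hat)`; `NA` with a warning when either
#'   vector has zero variance.
#' @export
accuracy <- function(y, y_hat) {
  if (length(y) < 3) stop("need at least 3 validation records", call. = FALSE)
  if (sd(y) == 0 || sd(y_hat) == 0) {
    warning("zero variance; accuracy undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(y, y_hat)
}

#' Prediction bias: regression of phenotype on prediction
#'
#' The OLS slope `cov(y, y_hat) / var(y_hat)`; 1 indicates no over- or
#' under-dispersion of the predictions.
#'
#' @inheritParams accuracy
#' @return the slope; `NA` with a warning when the predictions are constant.
#' @export
bias <- function(y, y_hat) {
  if (sd(y_hat) == 0) {
    warning("zero predictor variance; bias undefined", call. = FALSE)
    return(NA_real_)
  }
  as.numeric(cov(y, y_hat) / var(y_hat))
}

#' Approximate standard error of a validation accuracy
#'
#' `1 / sqrt(n)`, rounded to 3 decimals for reporting (0.062 at n = 262,
#' 0.098 at n = 105).
#'
#' @param n number of validation animals (n >= 2).
#' @return rounded approximate SE.
#' @export
accuracy_se <- function(n) {
  if (any(n < 2)) stop("need n >= 2", call. = FALSE)
  round(1 / sqrt(n), 3)
}

#' Score predictions against phenotypes, by breed
#'
#' Joins predictions to validation phenotypes and reports accuracy, bias and
#' the approximate SE per breed and prediction flavour (SNP-only `y_hat_v`
#' vs. total `y_hat`), plus a pooled `"all"` row.
#'
#' @param predictions tibble from [predict_gebv()].
#' @param phenotypes validation phenotype tibble (same trait).
#' @param method label recorded in the report (e.g. "bayesr").
#' @param reference label for the reference set used.
#' @return tibble `trait`, `reference`, `method`, `flavour`, `breed`, `n`,
#'   `accuracy`, `bias`, `approx_se`.
#' @export
validate_predictions <- function(predictions, phenotypes, method = "gblup",
                                 reference = "ref") {
  trait <- unique(phenotypes$trait)
  if (length(trait) != 1) {
    stop("validation phenotypes must contain exactly one trait",
         call. = FALSE)
  }
  joined <- dplyr::inner_join(predictions,
                              phenotypes[c("animal_id", "value")],
                              by = "animal_id")
  if (nrow(joined) < 3) stop("fewer than 3 scored animals", call. = FALSE)
  score_group <- function(df, breed_label) {
    if (nrow(df) < 3) return(NULL)  # too few animals to score this group
    purrr::map_dfr(c(snp_only = "y_hat_v", total = "y_hat"), function(col) {
      tibble(breed = breed_label, n = nrow(df),
             accuracy = accuracy(df$value, df[[col]]),
             bias = bias(df$value, df[[col]]),
             approx_se = accuracy_se(nrow(df)))
    }, .id = "flavour")
  }
  per_breed <- joined |>
    dplyr::group_by(.data$breed) |>
    dplyr::group_map(~ score_group(.x, .y$breed)) |>
    dplyr::bind_rows()
  pooled <- score_group(joined, "all")
  out <- dplyr::bind_rows(per_breed, pooled)
  dplyr::bind_cols(tibble(trait = trait, reference = reference,
                          method = method)[rep(1, nrow(out)), ], out)
}

#' Write a validation report TSV
#' @param report tibble from [validate_predictions()] (rows may be bound
#'   across traits/methods).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  readr::write_tsv(report, path, progress = FALSE)
  invisible(path)
}
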