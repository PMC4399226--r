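#' Construct a genotype set
#'
#' A genotype set bundles an animals x markers dosage matrix (allele counts in
#' `[0, 2]`, real-valued so imputed dosages are admitted), per-animal breed
#' labels and a marker map. It is the in-memory form of the raw genotypes that
#' underlie the design matrix of SNP covariates.
#'
#' @param dosages numeric matrix, animals x markers, entries in `[0, 2]`.
#'   Row names are taken as animal ids when `animal_ids` is missing.
#' @param map marker map: a data frame with columns `marker_id`, `chrom`,
#'   `pos` (1-based bp, strictly increasing within chromosome).
#' @param breed character vector of per-animal breed labels (recycled if
#'   length 1).
#' @param animal_ids optional character vector of unique animal ids.
#' @return an object of class `genotype_set`: a list with elements `dosages`,
#'   `map` (tibble) and `breed`.
#' @export
genotype_set <- function(dosages, map, breed = "A", animal_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(animal_ids)) animal_ids <- rownames(dosages)
  if (is.null(animal_ids)) animal_ids <- paste0("id", seq_len(nrow(dosages)))
  animal_ids <- as.character(animal_ids)
  if (anyDuplicated(animal_ids)) {
    stop("animal ids must be unique", call. = FALSE)
  }
  if (length(animal_ids) != nrow(dosages)) {
    stop("length(animal_ids) must equal nrow(dosages)", call. = FALSE)
  }
  map <- validate_marker_map(map)
  if (nrow(map) != ncol(dosages)) {
    stop("marker map length (", nrow(map), ") does not match genotype columns (",
         ncol(dosages), ")", call. = FALSE)
  }
  if (anyNA(dosages)) {
    stop("genotype set may not contain missing dosages; impute first",
         call. = FALSE)
  }
  rng <- range(dosages)
  if (rng[1] < 0 || rng[2] > 2) {
    bad <- which(dosages < 0 | dosages > 2, arr.ind = TRUE)[1, ]
    stop(sprintf("dosage outside [0, 2] at animal '%s', marker '%s'",
                 animal_ids[bad[1]], map$marker_id[bad[2]]), call. = FALSE)
  }
  rownames(dosages) <- animal_ids
  colnames(dosages) <- map$marker_id
  breed <- rep_len(as.character(breed), nrow(dosages))
  structure(list(dosages = dosages, map = map, breed = breed),
            class = "genotype_set")
}

validate_marker_map <- function(map) {
  map <- as_tibble(map)
  need <- c("marker_id", "chrom", "pos")
  miss <- setdiff(need, names(map))
  if (length(miss)) {
    stop("marker map is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  map$marker_id <- as.character(map$marker_id)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.double(map$pos)
  if (anyDuplicated(map$marker_id)) {
    stop("marker ids must be unique", call. = FALSE)
  }
  ok <- unlist(lapply(split(map$pos, factor(map$chrom, unique(map$chrom))),
                      function(p) c(TRUE, diff(p) > 0)), use.names = FALSE)
  if (!all(ok)) {
    stop("marker positions must be strictly increasing within chromosome (",
         "first violation at marker '",
         map$marker_id[order(match(map$chrom, unique(map$chrom)))[!ok][1]],
         "')", call. = FALSE)
  }
  map[need]
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("<genotype_set> ", nrow(x$dosages), " animals x ", ncol(x$dosages),
      " markers; breeds: ",
      paste(names(table(x$breed)), table(x$breed), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Read genotypes from disk
#'
#' Two dialects are supported: a dosage TSV (first column `animal_id`, one
#' column per marker named by marker id, entries in `[0, 2]`, blank/NA =
#' missing) accompanied by a marker map, and a PLINK .bed/.bim/.fam triple
#' (SNP-major .bed). Missing genotypes are mean-imputed per marker; load order
#' is preserved.
#'
#' @param path for `format = "tsv"` the dosage TSV; for `format = "plink"` the
#'   fileset prefix or the .bed path.
#' @param format `"auto"` (default; decided by extension), `"tsv"` or
#'   `"plink"`.
#' @param map for TSV input, the marker map (data frame or a TSV path with
#'   columns marker_id, chrom, pos). Ignored for PLINK input (the .bim is the
#'   map).
#' @param breed per-animal breed labels; for TSV input may also be a column
#'   `breed` in the file.
#' @return a [genotype_set()].
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "plink"),
                           map = NULL, breed = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path) ||
                  file.exists(paste0(path, ".bed"))) "plink" else "tsv"
  }
  if (format == "plink") read_plink(path, breed = breed)
  else read_dosage_tsv(path, map = map, breed = breed)
}

read_dosage_tsv <- function(path, map = NULL, breed = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  hdr <- names(readr::read_tsv(path, n_max = 0, col_types = readr::cols(),
                               progress = FALSE))
  if (!"animal_id" %in% hdr) {
    stop("dosage TSV must have an 'animal_id' first column: ", path,
         call. = FALSE)
  }
  spec <- readr::cols(animal_id = readr::col_character(),
                      .default = readr::col_double())
  if ("breed" %in% hdr) spec$cols$breed <- readr::col_character()
  tab <- readr::read_tsv(path, col_types = spec, progress = FALSE)
  breed_col <- NULL
  if ("breed" %in% names(tab)) {
    breed_col <- tab$breed
    tab$breed <- NULL
  }
  ids <- tab$animal_id
  dos <- as.matrix(tab[setdiff(names(tab), "animal_id")])
  if (is.null(map)) {
    # fall back to a synthetic single-chromosome map in column order
    map <- tibble(marker_id = colnames(dos), chrom = "1",
                  pos = seq_len(ncol(dos)))
  } else {
    if (is.character(map) && length(map) == 1) {
      map <- readr::read_tsv(map, col_types = readr::cols(
        marker_id = readr::col_character(), chrom = readr::col_character(),
        pos = readr::col_double()), progress = FALSE)
    }
    map <- validate_marker_map(map)
    if (!identical(map$marker_id, colnames(dos))) {
      if (!setequal(map$marker_id, colnames(dos))) {
        stop("marker map and dosage columns disagree", call. = FALSE)
      }
      dos <- dos[, map$marker_id, drop = FALSE]
    }
  }
  rng <- suppressWarnings(range(dos, na.rm = TRUE))
  if (rng[1] < 0 || rng[2] > 2) {
    bad <- which(dos < 0 | dos > 2, arr.ind = TRUE)[1, ]
    stop(sprintf("dosage outside [0, 2] at line %d, marker '%s' in %s",
                 bad[1] + 1L, colnames(dos)[bad[2]], path), call. = FALSE)
  }
  dos <- impute_marker_means(dos)
  if (is.null(breed)) breed <- if (is.null(breed_col)) "A" else breed_col
  genotype_set(dos, map, breed = breed, animal_ids = ids)
}

impute_marker_means <- function(dos) {
  nas <- which(colSums(is.na(dos)) > 0)
  for (j in nas) {
    x <- dos[, j]
    mu <- mean(x, na.rm = TRUE)
    if (is.nan(mu)) mu <- 0
    x[is.na(x)] <- mu
    dos[, j] <- x
  }
  dos
}

#' Write a genotype set as a dosage TSV (plus marker-map TSV)
#'
#' @param g a [genotype_set()]
#' @param path output TSV path; the marker map is written next to it as
#'   `<path>.map` unless `map_path` is given.
#' @param map_path optional explicit map path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(g, path, map_path = paste0(path, ".map")) {
  tab <- tibble(animal_id = rownames(g$dosages), breed = g$breed)
  tab <- dplyr::bind_cols(tab, as_tibble(g$dosages))
  readr::write_tsv(tab, path, progress = FALSE)
  readr::write_tsv(g$map, map_path, progress = FALSE)
  invisible(path)
}

# ---- PLINK bed/bim/fam ------------------------------------------------------
# SNP-major .bed: magic bytes 0x6c 0x1b 0x01 then ceil(n/4) bytes per marker,
# two bits per animal: 00 = 2 copies of allele A1, 10 = 1 copy, 11 = 0 copies,
# 01 = missing. Dosage = A1 allele count.

plink_paths <- function(prefix) {
  prefix <- sub("\\.bed$", "", prefix)
  list(bed = paste0(prefix, ".bed"), bim = paste0(prefix, ".bim"),
       fam = paste0(prefix, ".fam"))
}

read_plink <- function(prefix, breed = NULL) {
  p <- plink_paths(prefix)
  for (f in unlist(p)) {
    if (!file.exists(f)) stop("no such file: ", f, call. = FALSE)
  }
  bim <- readr::read_tsv(p$bim, col_names = c("chrom", "marker_id", "cm",
                                              "pos", "a1", "a2"),
                         col_types = "ccddcc", progress = FALSE)
  fam <- readr::read_table(p$fam,
                           col_names = c("fid", "iid", "pat", "mat", "sex",
                                         "phe"),
                           col_types = "cccccc", progress = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(p$bed, "raw", n = file.size(p$bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("malformed .bed (bad magic number): ", p$bed, call. = FALSE)
  }
  if (raw[3] != as.raw(0x01)) {
    stop("only SNP-major .bed files are supported: ", p$bed, call. = FALSE)
  }
  bpm <- ceiling(n / 4)
  if (length(raw) - 3L != bpm * m) {
    stop(sprintf("malformed .bed: expected %d data bytes, found %d",
                 bpm * m, length(raw) - 3L), call. = FALSE)
  }
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bpm, ncol = m)
  # decode the four 2-bit fields of every byte at once
  codes <- c(2, NA, 1, 0)  # 00, 01, 10, 11 -> A1 dosage
  dos <- matrix(NA_real_, n, m)
  for (k in 0:3) {
    bits <- (body %/% (4L^k)) %% 4L
    rows <- seq(k + 1L, by = 4L, length.out = bpm)
    rows <- rows[rows <= n]
    dos[rows, ] <- codes[bits[seq_along(rows), , drop = FALSE] + 1L]
  }
  dos <- impute_marker_means(dos)
  map <- bim[, c("marker_id", "chrom", "pos")]
  if (is.null(breed)) breed <- fam$fid
  genotype_set(dos, map, breed = breed, animal_ids = fam$iid)
}

#' Write a genotype set as a PLINK .bed/.bim/.fam triple
#'
#' Dosages are rounded to the nearest integer allele count (the .bed format
#' stores hard calls only); the breed label is written as the family id.
#'
#' @param g a [genotype_set()]
#' @param prefix fileset prefix (no extension).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  p <- plink_paths(prefix)
  n <- nrow(g$dosages); m <- ncol(g$dosages)
  dos <- round(g$dosages)
  code <- matrix(0L, n, m)
  code[dos == 2] <- 0L
  code[dos == 1] <- 2L
  code[dos == 0] <- 3L
  bpm <- ceiling(n / 4)
  pad <- bpm * 4L - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, m))
  w <- 4L^(0:3)
  bytes <- code[seq(1, bpm * 4L, 4L), , drop = FALSE] * w[1] +
    code[seq(2, bpm * 4L, 4L), , drop = FALSE] * w[2] +
    code[seq(3, bpm * 4L, 4L), , drop = FALSE] * w[3] +
    code[seq(4, bpm * 4L, 4L), , drop = FALSE] * w[4]
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), as.raw(as.integer(bytes))), p$bed)
  bim <- data.frame(chrom = g$map$chrom, marker_id = g$map$marker_id, cm = 0,
                    pos = g$map$pos, a1 = "A", a2 = "B")
  readr::write_tsv(bim, p$bim, col_names = FALSE, progress = FALSE)
  fam <- data.frame(fid = g$breed, iid = rownames(g$dosages), pat = 0, mat = 0,
                    sex = 0, phe = -9)
  readr::write_delim(fam, p$fam, delim = " ", col_names = FALSE,
                     progress = FALSE)
  invisible(prefix)
}

#' Subset a genotype set by animal ids
#' @param g a [genotype_set()]
#' @param ids animal ids to keep, in the order given.
#' @return a [genotype_set()] with the same marker map.
#' @export
subset_genotypes <- function(g, ids) {
  i <- match(ids, rownames(g$dosages))
  if (anyNA(i)) {
    stop("animal(s) not in genotype set: ",
         paste(head(ids[is.na(i)], 3), collapse = ", "), call. = FALSE)
  }
  genotype_set(g$dosages[i, , drop = FALSE], g$map, breed = g$breed[i],
               animal_ids = ids)
}
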