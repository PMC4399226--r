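#' Read a phenotype table
#'
#' Phenotypes are trait deviations for cows (own records, precision grows with
#' the record count `r`) and daughter trait deviations for bulls (precision
#' grows with the effective daughter count `d`). The TSV must carry columns
#' `animal_id`, `trait`, `value`, `record_type` (`bull`/`cow`), `d`, `r`,
#' `breed` and `sex`; bulls may have `r` empty and cows may have `d` empty.
#'
#' @param path TSV path.
#' @return tibble with typed columns, one row per record, file order
#'   preserved.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  hdr <- names(readr::read_tsv(path, n_max = 0, col_types = readr::cols(),
                               progress = FALSE))
  need <- c("animal_id", "trait", "value", "record_type", "d", "r", "breed",
            "sex")
  miss <- setdiff(need, hdr)
  if (length(miss)) {
    stop("phenotype file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(
    animal_id = readr::col_character(), trait = readr::col_character(),
    value = readr::col_double(), record_type = readr::col_character(),
    d = readr::col_double(), r = readr::col_double(),
    breed = readr::col_character(), sex = readr::col_character()
  ), progress = FALSE)[need]
  validate_phenotypes(tab)
}

validate_phenotypes <- function(tab) {
  tab <- as_tibble(tab)
  bad_type <- setdiff(unique(tab$record_type), c("bull", "cow"))
  if (length(bad_type)) {
    stop("unknown record_type: ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  dup <- tab |>
    dplyr::count(.data$animal_id, .data$trait) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop("duplicate record for animal '", dup$animal_id[1], "', trait '",
         dup$trait[1], "'", call. = FALSE)
  }
  cows <- tab$record_type == "cow"
  if (any(cows & (is.na(tab$r) | tab$r < 1))) {
    stop("cows must have record count r >= 1", call. = FALSE)
  }
  if (any(!cows & !is.na(tab$d) & tab$d < 0)) {
    stop("bulls must have effective daughter count d >= 0", call. = FALSE)
  }
  tab
}

#' Write a phenotype table
#' @param tab phenotype tibble (see [read_phenotypes()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(tab, path) {
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read a pedigree
#'
#' TSV with columns `animal_id`, `sire_id`, `dam_id`; `"0"`, empty or NA
#' denotes an unknown parent. The returned pedigree is topologically sorted so
#' parents precede offspring; unknown parents are preserved as founders.
#' Parents that appear only in the sire/dam columns are added as founder rows.
#'
#' @param path TSV path.
#' @return tibble `animal_id`, `sire_id`, `dam_id` (NA = unknown),
#'   topologically sorted.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, col_types = readr::cols(
    animal_id = readr::col_character(), sire_id = readr::col_character(),
    dam_id = readr::col_character()), progress = FALSE)
  miss <- setdiff(c("animal_id", "sire_id", "dam_id"), names(tab))
  if (length(miss)) {
    stop("pedigree file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  sort_pedigree(tab)
}

#' Topologically sort a pedigree
#'
#' @param ped data frame `animal_id`, `sire_id`, `dam_id` ("0"/""/NA =
#'   unknown).
#' @return sorted tibble; errors on duplicate ids, self-parents or ancestry
#'   cycles (the cycle is listed).
#' @export
sort_pedigree <- function(ped) {
  ped <- as_tibble(ped)[c("animal_id", "sire_id", "dam_id")]
  ped$animal_id <- as.character(ped$animal_id)
  for (col in c("sire_id", "dam_id")) {
    v <- as.character(ped[[col]])
    v[!is.na(v) & (v == "0" | v == "")] <- NA_character_
    ped[[col]] <- v
  }
  if (anyDuplicated(ped$animal_id)) {
    stop("duplicate animal id in pedigree: ",
         ped$animal_id[duplicated(ped$animal_id)][1], call. = FALSE)
  }
  self <- ped$animal_id == ped$sire_id | ped$animal_id == ped$dam_id
  if (any(self, na.rm = TRUE)) {
    stop("animal is its own parent (cycle): ",
         ped$animal_id[which(self)[1]], call. = FALSE)
  }
  # add parents that have no row of their own, as founders
  parents <- setdiff(stats::na.omit(c(ped$sire_id, ped$dam_id)),
                     ped$animal_id)
  if (length(parents)) {
    ped <- dplyr::bind_rows(
      tibble(animal_id = parents, sire_id = NA_character_,
             dam_id = NA_character_), ped)
  }
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$animal_id)
  si <- unname(idx[ped$sire_id]); di <- unname(idx[ped$dam_id])
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)  # FIFO: whole generations emit before their
  order <- integer(0)          # offspring, founders first
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    order <- c(order, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(order) < n) {
    cyc <- ped$animal_id[setdiff(seq_len(n), order)]
    stop("pedigree contains a cycle involving: ",
         paste(cyc, collapse = " -> "), call. = FALSE)
  }
  ped[order, ]
}

#' Write a pedigree table
#' @param ped pedigree tibble; unknown parents written as "0".
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped
  out$sire_id <- ifelse(is.na(out$sire_id), "0", out$sire_id)
  out$dam_id <- ifelse(is.na(out$dam_id), "0", out$dam_id)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
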