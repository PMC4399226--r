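# shared in-code fixtures; everything is generated, nothing is stored

tiny_map <- function(m = 4, chrom = "1", spacing = 1000) {
  tibble::tibble(marker_id = paste0("m", seq_len(m)), chrom = chrom,
                 pos = spacing * seq_len(m))
}

tiny_genotypes <- function() {
  dos <- matrix(c(0, 1, 2,
                  1, 1, 1,
                  2, 0, 1,
                  2, 2, 2), nrow = 3,
                dimnames = list(c("a1", "a2", "a3"), NULL))
  genotype_set(dos, tiny_map(4), breed = c("A", "A", "B"))
}

tiny_phenotypes <- function() {
  tibble::tibble(
    animal_id = c("a1", "a2", "a3"),
    trait = "FY",
    value = c(0.5, -0.2, 0.1),
    record_type = c("bull", "cow", "cow"),
    d = c(50, NA, NA),
    r = c(NA, 1, 3),
    breed = c("A", "A", "B"),
    sex = c("M", "F", "F"))
}

trio_pedigree <- function() {
  tibble::tibble(animal_id = c("s", "d", "o"),
                 sire_id = c(NA, NA, "s"),
                 dam_id = c(NA, NA, "d"))
}

# small random pedigree: founders then offspring of random earlier animals
random_pedigree <- function(n, n_founders = max(4, n %/% 5), seed = 1) {
  set.seed(seed)
  ids <- paste0("p", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1):n) {
    sire[i] <- ids[sample.int(i - 1, 1)]
    dam_pool <- setdiff(seq_len(i - 1), match(sire[i], ids))
    if (length(dam_pool)) dam[i] <- ids[sample(dam_pool, 1)]
  }
  tibble::tibble(animal_id = ids, sire_id = sire, dam_id = dam)
}

# small simulated bundle shared across tests (memoised per session)
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        n_ref = c(A_bull = 60, A_cow = 40, B_bull = 30, B_cow = 20),
        n_val = c(A_bull = 15, B_bull = 10, C_bull = 10, C_cow = 10),
        m = 400, n_chrom = 2, chrom_length_bp = 2e6,
        n_per_class = c(10, 4, 2), divergence_generations = 10,
        poly_frac = 0.5, recomb_rate = 2e-6, n_founder_hap = 900,
        bottleneck_hap = 700,  # enough haplotype diversity for a full-rank GRM
        seed = 424242)
      cache <<- suppressMessages(simulate_dataset(cfg))
    }
    cache
  }
})

ref_phenos <- function(bundle) {
  dplyr::filter(bundle$phenotypes, animal_id %in% bundle$reference_ids)
}
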