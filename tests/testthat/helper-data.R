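# small builders shared across tests

# occurrence table from a named list: site -> list(sample -> species chr vec)
occ_from_sets <- function(regions) {
  rows <- list()
  for (rg in names(regions)) {
    for (st in names(regions[[rg]])) {
      for (sm in names(regions[[rg]][[st]])) {
        sp <- regions[[rg]][[st]][[sm]]
        rows[[length(rows) + 1]] <- if (length(sp) == 0) {
          tibble::tibble(species = NA_character_, sample = sm, site = st,
                         region = rg, count = 0L)
        } else {
          tibble::tibble(species = sp, sample = sm, site = st, region = rg,
                         count = 1L)
        }
      }
    }
  }
  occurrence(dplyr::bind_rows(rows))
}

# random 0/1 species x unit matrix with at least one presence
random_incidence <- function(n_species, n_units, p = 0.4) {
  repeat {
    m <- matrix(rbinom(n_species * n_units, 1, p), n_species, n_units,
                dimnames = list(paste0("sp", seq_len(n_species)),
                                paste0("u", seq_len(n_units))))
    if (sum(m) > 0) return(m)
  }
}

# incidence matrix whose columns all hold at least one species
random_incidence_nonempty <- function(n_species, n_units, p = 0.4) {
  repeat {
    m <- random_incidence(n_species, n_units, p)
    if (all(colSums(m) > 0)) return(m)
  }
}
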