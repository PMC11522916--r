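# Small in-code fixtures shared across the suite.

# One segment row of a transect table.
seg <- function(site, year, protected, tid, len, category, taxon, icpt) {
  tibble::tibble(
    site = site, year = as.integer(year), protected = protected,
    transect_id = tid, transect_length_m = len, category = category,
    taxon = taxon, intercept_length_m = icpt
  )
}

# A fully classified single transect: coral taxa plus bare reef filler.
toy_transect <- function(site = "A", year = 2006, protected = TRUE,
                         tid = "T1", len = 10,
                         coral = c("Acropora sp01" = 2.5),
                         filler = "bare reef") {
  coral_rows <- purrr::imap_dfr(as.list(coral), function(l, tx) {
    seg(site, year, protected, tid, len, "reef-building coral", tx, l)
  })
  rest <- len - sum(coral)
  dplyr::bind_rows(
    coral_rows,
    seg(site, year, protected, tid, len, filler, NA_character_, rest)
  )
}

# A minimal complete trait table (no gaps) with enough spread for binning.
toy_traits <- function() {
  tibble::tibble(
    taxon = c("Acropora sp01", "Acropora sp02", "Porites sp01",
              "Porites sp02", "Montipora sp01", "Pavona sp01"),
    genus = c("Acropora", "Acropora", "Porites", "Porites", "Montipora",
              "Pavona"),
    growth_form = c("corymbose", "corymbose", "massive", "massive",
                    "encrusting", "foliose"),
    growth_rate = c(110, 90, 3, 4, 12, 30),
    skeletal_density = c(1.0, 1.1, 2.2, 2.1, 1.7, 1.3),
    colony_size = c(60, 80, 250, 400, 25, 70),
    colony_height = c(45, 60, 60, 80, 2, 12),
    corallite_width = c(0.8, 0.9, 6, 7, 1.5, 2.2),
    intra_colony_space = c(25, 30, 0.5, 0.6, 0.4, 4),
    sa_vol_ratio = c(30, 25, 0.8, 0.7, 2.5, 6)
  )
}

# A hand-made trait space on explicit coordinates (for geometry tests).
manual_space <- function(coords, taxa = NULL) {
  taxa <- taxa %||% sprintf("t%02d", seq_len(nrow(coords)))
  rownames(coords) <- taxa
  colnames(coords) <- paste0("PCoA", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = rep(1, ncol(coords)),
                 explained = rep(1 / ncol(coords), ncol(coords)), taxa = taxa),
            class = "trait_space")
}

`%||%` <- rlang::`%||%`
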