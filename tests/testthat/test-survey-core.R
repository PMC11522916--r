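test_that("transect files round-trip canonically and dialects normalise labels", {
  tr <- dplyr::bind_rows(
    toy_transect(coral = c("Acropora sp01" = 2.5, "Porites sp01" = 1.0)),
    toy_transect(site = "B", coral = c("Porites sp01" = 4))
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_transects(tr, path)
  back <- read_transects(path)
  expect_equal(as.data.frame(back), as.data.frame(tr))

  raw <- toy_transect()
  raw$category[raw$category == "reef-building coral"] <- "Coral"
  norm <- validate_transects(raw)
  expect_true("reef-building coral" %in% norm$category)
})

test_that("invalid transects are rejected with context", {
  bad <- toy_transect()
  bad$category[1] <- "volcano"
  expect_error(validate_transects(bad), class = "reefsucc_unknown_category")

  over <- seg("A", 2006, TRUE, "T1", 5, "reef-building coral", "Acropora sp01", 6)
  expect_error(validate_transects(over), class = "reefsucc_intercept_overflow")

  no_taxon <- seg("A", 2006, TRUE, "T1", 5, "reef-building coral", NA, 1)
  expect_error(validate_transects(no_taxon), "without taxon")
})

test_that("LIT cover is the intercepted-length ratio and rows close to 100", {
  tr <- toy_transect(coral = c("Acropora sp01" = 2.5))
  cov <- compute_cover(tr)
  expect_equal(cov[["reef-building coral"]], 25)
  expect_equal(cov[["bare reef"]], 75)
  expect_equal(rowSums(cov[c(benthic_categories(), "unclassified")]), 100)

  # six 10-m transects with coral intercepts totalling 13.662 m -> 22.77%
  six <- purrr::map_dfr(1:6, function(i) {
    toy_transect(tid = paste0("T", i), coral = c("Acropora sp01" = 13.662 / 6))
  })
  expect_equal(compute_cover(six)[["reef-building coral"]],
               100 * 13.662 / 60, tolerance = 1e-12)

  none <- toy_transect(coral = c("Acropora sp01" = 0))
  none <- none[none$category != "reef-building coral", ]
  expect_equal(compute_cover(none)[["reef-building coral"]], 0)
})

test_that("unclassified tape is reported, not renormalised", {
  short <- dplyr::bind_rows(
    seg("A", 2006, TRUE, "T1", 10, "reef-building coral", "Acropora sp01", 2),
    seg("A", 2006, TRUE, "T1", 10, "sand", NA, 3)
  )
  cov <- compute_cover(short)
  expect_equal(cov$unclassified, 50)
  expect_equal(rowSums(cov[c(benthic_categories(), "unclassified")]), 100)
})

test_that("pooled-year covers are the length-weighted mean of site covers", {
  tr <- dplyr::bind_rows(
    toy_transect(site = "A", len = 50, coral = c("Acropora sp01" = 5)),
    toy_transect(site = "B", len = 10, coral = c("Acropora sp01" = 3))
  )
  site_cov <- compute_cover(tr)
  pooled <- compute_cover(tr, by = "year")
  manual <- sum(site_cov[["reef-building coral"]] * site_cov$tape_m) /
    sum(site_cov$tape_m)
  expect_equal(pooled[["reef-building coral"]], manual, tolerance = 1e-12)

  # equal lengths: simple mean of 10% and 30% is 20%
  eq <- dplyr::bind_rows(
    toy_transect(site = "A", coral = c("Acropora sp01" = 1)),
    toy_transect(site = "B", coral = c("Acropora sp01" = 3))
  )
  am <- coral_abundance_matrix(eq, "pooled-year")
  expect_equal(am[["Acropora sp01"]], 20)
})

test_that("abundance matrix row sums agree with the coral category cover", {
  sc <- simulate_scenario(seed = 11)
  am <- coral_abundance_matrix(sc$transects, "pooled-year")
  cov <- compute_cover(sc$transects, by = "year")
  taxa <- setdiff(names(am), c("unit", "year"))
  expect_equal(rowSums(am[taxa]),
               cov[["reef-building coral"]][match(am$year, cov$year)],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("growth-form cover resolves genus records by the genus mode with ties alphabetical", {
  tr <- dplyr::bind_rows(
    toy_transect(coral = c("Acropora sp01" = 0.5, "Acropora sp02" = 0.5,
                           "Porites sp01" = 1)),
    toy_transect(site = "B", coral = c("Acropora spp." = 2))
  )
  gf <- growth_form_cover(coral_abundance_matrix(tr), toy_traits())
  # genus-level record takes the corymbose mode of Acropora
  b_row <- gf[gf$site == "B" & gf$cover > 0, ]
  expect_equal(b_row$growth_form, "corymbose")
  expect_equal(b_row$cover, 20)
  # per-unit totals conserved
  tot <- gf |> dplyr::group_by(site) |> dplyr::summarise(c = sum(cover))
  cov <- compute_cover(tr)
  expect_equal(tot$c, cov[["reef-building coral"]][match(tot$site, cov$site)],
               tolerance = 1e-9)

  # tie in the genus mode broken alphabetically
  tie_traits <- tibble::tibble(
    taxon = c("Genusa sp01", "Genusa sp02"), genus = "Genusa",
    growth_form = c("massive", "encrusting")
  )
  expect_equal(resolve_growth_form("Genusa spp.", tie_traits), "encrusting")

  expect_error(resolve_growth_form("Unknownus spp.", tie_traits),
               class = "reefsucc_unresolved_taxon")
})
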