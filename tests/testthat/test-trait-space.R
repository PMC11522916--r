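test_that("imputation fills gaps by hierarchical geometric means with provenance", {
  tr <- toy_traits()
  tr$growth_rate[1] <- NA           # congeners: 90 -> genus geometric mean
  tr$skeletal_density[5] <- NA      # no congener -> growth-form level fails too
  out <- impute_traits(tr)
  expect_equal(out$growth_rate[1], exp(mean(log(90))), tolerance = 1e-12)
  expect_equal(out$growth_rate_imputed[1], "genus")
  # Montipora has one member: genus mean unavailable; its growth form
  # (encrusting) has no other member either, so the global mean is used
  expect_equal(out$skeletal_density[5],
               exp(mean(log(toy_traits()$skeletal_density[-5]))),
               tolerance = 1e-12)
  expect_equal(out$skeletal_density_imputed[5], "global")

  # two measured congeners 4 and 6 -> geometric mean
  tr2 <- toy_traits()[1:3, ]
  tr2$taxon[3] <- "Acropora sp03"; tr2$genus[3] <- "Acropora"
  tr2$growth_form[3] <- "corymbose"
  tr2$colony_size <- c(4, 6, NA)
  out2 <- impute_traits(tr2)
  expect_equal(out2$colony_size[3], exp(mean(log(c(4, 6)))), tolerance = 1e-12)

  # complete tables come back unchanged
  full <- impute_traits(toy_traits())
  expect_equal(full[names(toy_traits())], toy_traits())
  expect_true(all(is.na(unlist(full[paste0(trait_names(), "_imputed")]))))

  all_gone <- toy_traits()
  all_gone$corallite_width <- NA_real_
  expect_error(impute_traits(all_gone), class = "reefsucc_all_missing_trait")
})

test_that("ordinal binning counts strict cut points and preserves order", {
  br <- default_trait_breaks()
  br[br$trait == "growth_rate", c("b1", "b2", "b3", "b4")] <-
    as.list(c(2, 4, 6, 8))
  tr <- toy_traits()[1:3, ]
  tr$growth_rate <- c(5, 4, 9)
  out <- bin_traits(tr, br)
  expect_equal(out$growth_rate, c(3L, 2L, 5L))  # 4 sits on a cut: lower bin

  # monotonicity on a grid of raw values
  vals <- seq(0.5, 9.5, by = 0.5)
  tr_m <- tr[rep(1, length(vals)), ]
  tr_m$taxon <- sprintf("t%02d", seq_along(vals))
  tr_m$growth_rate <- vals
  cats <- bin_traits(tr_m, br)$growth_rate
  expect_true(all(diff(cats[order(vals)]) >= 0))

  # clamping warns
  tr_c <- tr
  tr_c$growth_rate[1] <- 1e6
  expect_warning(bin_traits(tr_c, br), "clamped")
})

test_that("Gower distance averages range-normalised trait differences", {
  base <- tibble::tibble(
    taxon = c("a", "b", "c"), genus = "g", growth_form = "massive"
  )
  m <- rbind(c(3, 1, 1, 1, 1, 1, 1), c(1, 1, 1, 1, 1, 1, 1),
             c(5, 5, 5, 5, 5, 5, 5))
  for (j in seq_along(trait_names())) base[[trait_names()[j]]] <- m[, j]
  d <- as.matrix(gower_distance(base))
  expect_equal(d["a", "b"], (2 / 4) / 7, tolerance = 1e-12)
  expect_equal(d["b", "c"], 1, tolerance = 1e-12)
  expect_equal(d["a", "a"], 0)

  # zero-range trait dropped with a warning
  m2 <- m; m2[, 2] <- 3
  base2 <- base
  for (j in seq_along(trait_names())) base2[[trait_names()[j]]] <- m2[, j]
  expect_warning(d2 <- gower_distance(base2), "zero-range")
  expect_equal(as.matrix(d2)["a", "b"], (2 / 4) / 6, tolerance = 1e-12)
})

test_that("trait space construction preserves simplex geometry", {
  # 5 taxa at the corners of a 4-simplex: equal pairwise distances preserved
  coords <- rbind(diag(4) * 2, rep(0, 4)) + 1
  d_pts <- stats::dist(rbind(coords, colMeans(coords)))
  space <- build_trait_space(d_pts, n_axes = 4)
  rec <- stats::dist(space$coordinates)
  expect_equal(as.numeric(rec), as.numeric(d_pts), tolerance = 1e-9)
  expect_true(all(diff(space$eigenvalues) <= 1e-12))
  expect_error(build_trait_space(stats::dist(diag(3))), "at least 6")
})

test_that("occupied volume fraction behaves like a hull ratio", {
  # 2-D analogue: unit square reference, 3 corners occupy half of it
  sqr <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.4), c(0.3, 0.6))
  space <- manual_space(sqr, taxa = c("c1", "c2", "c3", "c4", "mid1", "mid2"))
  expect_equal(as.numeric(trait_volume_fraction(space, space$taxa)), 1)
  expect_equal(as.numeric(trait_volume_fraction(space, c("c1", "c2", "c3"))),
               0.5, tolerance = 1e-12)
  # interior taxa do not change the fraction
  expect_equal(
    as.numeric(trait_volume_fraction(space, c("c1", "c2", "c3", "mid1"))),
    0.5, tolerance = 1e-12)
  # monotone under supersets
  expect_lte(as.numeric(trait_volume_fraction(space, c("c1", "c2", "c3"))),
             as.numeric(trait_volume_fraction(space, c("c1", "c2", "c3", "c4"))))
  # degenerate subset: 0 with a flag
  expect_warning(vf <- trait_volume_fraction(space, c("c1", "c2")),
                 "degenerate")
  expect_equal(as.numeric(vf), 0)
  expect_true(attr(vf, "degenerate"))
})

test_that("5-NN redundancy equals a brute-force all-pairs oracle", {
  set.seed(14)
  coords <- matrix(rnorm(20 * 4), 20, 4)
  space <- manual_space(coords)
  got <- functional_redundancy_5nn(space, space$taxa)
  dm <- as.matrix(stats::dist(coords))
  oracle <- mean(vapply(1:20, function(i) {
    sum(sort(dm[i, -i])[1:5])
  }, 0))
  expect_equal(got, oracle, tolerance = 1e-9)

  # six coincident taxa: zero
  space0 <- manual_space(matrix(1, 6, 4))
  expect_equal(functional_redundancy_5nn(space0, space0$taxa), 0)

  # appending near-coincident copies strictly lowers the mean
  copies <- coords[rep(1, 5), ] + matrix(rnorm(20, 0, 1e-9), 5, 4)
  space2 <- manual_space(rbind(coords, copies))
  expect_lt(functional_redundancy_5nn(space2, space2$taxa), got)

  expect_error(functional_redundancy_5nn(space, space$taxa[1:5]), "at least 6")
})

test_that("functional dispersion is the weighted centroid distance mean", {
  two <- manual_space(rbind(c(0, 0, 0, 0), c(3, 4, 0, 0)))
  expect_equal(functional_dispersion(two, c(t01 = 2, t02 = 2)), 2.5,
               tolerance = 1e-12)
  expect_equal(functional_dispersion(two, c(t01 = 5, t02 = 0)), 0)

  set.seed(15)
  coords <- matrix(rnorm(3 * 4), 3, 4)
  space <- manual_space(coords)
  w <- c(t01 = 2, t02 = 1, t03 = 1)
  ctr <- colSums(coords * w) / sum(w)
  oracle <- sum(w * sqrt(rowSums((coords - rep(ctr, each = 3))^2))) / sum(w)
  expect_equal(functional_dispersion(space, w), oracle, tolerance = 1e-12)

  # invariant to weight rescaling
  expect_equal(functional_dispersion(space, w), functional_dispersion(space, w * 1e6),
               tolerance = 1e-12)
  expect_error(functional_dispersion(space, c(t01 = 0, t02 = 0, t03 = 0)),
               "zero")
})

test_that("KDE occupancy integrates to one and nests its contour masses", {
  set.seed(16)
  coords <- cbind(rnorm(200), rnorm(200), rnorm(200), rnorm(200))
  space <- manual_space(coords)
  k <- kde_occupancy(space, space$taxa, axes = c(1, 2))
  cell <- diff(k$x[1:2]) * diff(k$y[1:2])
  expect_equal(sum(k$z) * cell, 1, tolerance = 0.02)
  mass_in <- function(level) sum(k$z[k$z >= level]) * cell
  expect_equal(mass_in(k$levels[["0.50"]]), 0.5, tolerance = 0.03)
  expect_equal(mass_in(k$levels[["0.95"]]), 0.95, tolerance = 0.03)
  expect_gt(k$levels[["0.50"]], k$levels[["0.95"]])

  # symmetric 4-point cross gives a symmetric density
  cross <- manual_space(cbind(c(1, -1, 0, 0), c(0, 0, 1, -1), 0, 0) +
                          matrix(0, 4, 4))
  kc <- kde_occupancy(cross, cross$taxa, axes = c(1, 2), n_grid = 41)
  expect_equal(kc$z, t(kc$z), tolerance = 1e-9)                    # swap axes
  expect_equal(kc$z, kc$z[rev(seq_len(41)), rev(seq_len(41))],
               tolerance = 1e-9)                                   # point reflection

  flat <- manual_space(cbind(1, rnorm(5), rnorm(5), rnorm(5)))
  expect_error(kde_occupancy(flat, flat$taxa, axes = c(1, 2)), "zero-variance")
})
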