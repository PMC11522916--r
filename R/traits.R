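#' The seven coral functional traits
#'
#' Habitat-forming traits used to build the coral trait space: growth rate
#' (mm/yr), skeletal density (g/cm^3), colony size (cm), colony height (cm),
#' corallite width (mm), intra-colony space size (mm), and colony
#' surface-area:volume ratio (1/cm). Together they capture a coral's capacity
#' to produce carbonate, form three-dimensional framework, and capture
#' nutrients.
#'
#' @return Character vector of the 7 trait column names.
#' @export
trait_names <- function() {
  c("growth_rate", "skeletal_density", "colony_size", "colony_height",
    "corallite_width", "intra_colony_space", "sa_vol_ratio")
}

#' Fill missing trait values by hierarchical geometric means
#'
#' Gaps in the raw trait table are filled deterministically on the log scale
#' (all seven traits are positive): the geometric mean of measured congeners
#' first, then of the taxon's growth form, then the global geometric mean.
#' The level used is recorded per cell in `<trait>_imputed` columns
#' (`NA` = measured, else `"genus"`, `"growth_form"`, `"global"`).
#'
#' @param traits Tibble with `taxon`, `genus`, `growth_form` and the seven
#'   raw trait columns of [trait_names()], gaps as `NA`.
#' @return The completed tibble with imputation-provenance columns appended.
#' @export
impute_traits <- function(traits) {
  check_columns(traits, c("taxon", "genus", "growth_form", trait_names()),
                "trait table")
  out <- tibble::as_tibble(traits)
  for (tr in trait_names()) {
    v <- out[[tr]]
    if (any(v[!is.na(v)] <= 0)) {
      rs_abort(sprintf("trait %s has non-positive raw values", tr))
    }
    if (all(is.na(v))) {
      rs_abort(sprintf("trait %s is missing for every taxon", tr),
               class = "reefsucc_all_missing_trait")
    }
    lv <- log(v)
    flag <- rep(NA_character_, length(v))
    gap <- which(is.na(v))
    if (length(gap) > 0) {
      genus_mean <- tapply(lv, out$genus, mean, na.rm = TRUE)
      form_mean <- tapply(lv, out$growth_form, mean, na.rm = TRUE)
      global_mean <- mean(lv, na.rm = TRUE)
      for (i in gap) {
        gm <- genus_mean[[out$genus[i]]]
        fm <- form_mean[[out$growth_form[i]]]
        if (!is.na(gm) && is.finite(gm)) {
          lv[i] <- gm; flag[i] <- "genus"
        } else if (!is.na(fm) && is.finite(fm)) {
          lv[i] <- fm; flag[i] <- "growth_form"
        } else {
          lv[i] <- global_mean; flag[i] <- "global"
        }
      }
    }
    out[[tr]] <- exp(lv)
    out[[paste0(tr, "_imputed")]] <- flag
  }
  out
}

#' Default ordinal bin breaks per trait
#'
#' Four strictly increasing cut points per trait define the five ordinal
#' categories; `lo`/`hi` bound the plausible raw range, values outside are
#' clamped with a warning. These breaks span the raw scales used by the
#' synthetic trait generator.
#'
#' @return Tibble: `trait`, `b1`..`b4`, `lo`, `hi`.
#' @export
default_trait_breaks <- function() {
  tibble::tribble(
    ~trait,                ~b1,   ~b2,   ~b3,   ~b4,   ~lo,    ~hi,
    "growth_rate",          5,     20,    50,    100,   0.1,    250,
    "skeletal_density",     0.8,   1.2,   1.6,   2.0,   0.2,    3,
    "colony_size",          10,    30,    100,   300,   1,      1000,
    "colony_height",        5,     15,    40,    100,   0.5,    300,
    "corallite_width",      1,     2.5,   5,     10,    0.1,    40,
    "intra_colony_space",   1,     3,     8,     20,    0.1,    80,
    "sa_vol_ratio",         1,     3,     8,     20,    0.1,    80
  )
}

#' Bin raw trait values into ordinal 1-5 categories
#'
#' Category = 1 + number of cut points strictly below the value, so a value
#' exactly on a cut point takes the lower category, and binning preserves
#' order. Values outside each trait's declared `lo`/`hi` range are clamped
#' with a warning.
#'
#' @param traits Complete trait tibble (see [impute_traits()]).
#' @param breaks Per-trait breaks tibble; see [default_trait_breaks()].
#' @return Tibble `taxon`, `genus`, `growth_form` plus the seven trait
#'   columns as integers in 1..5.
#' @export
bin_traits <- function(traits, breaks = default_trait_breaks()) {
  check_columns(traits, c("taxon", "genus", "growth_form", trait_names()),
                "trait table")
  check_columns(breaks, c("trait", "b1", "b2", "b3", "b4", "lo", "hi"), "breaks")
  out <- traits[c("taxon", "genus", "growth_form")]
  for (tr in trait_names()) {
    b <- breaks[breaks$trait == tr, ]
    if (nrow(b) != 1) rs_abort(sprintf("no breaks declared for trait %s", tr))
    cuts <- as.numeric(b[c("b1", "b2", "b3", "b4")])
    if (any(diff(cuts) <= 0)) rs_abort(sprintf("breaks for %s not increasing", tr))
    v <- traits[[tr]]
    if (anyNA(v)) rs_abort(sprintf("trait %s still has gaps; impute first", tr))
    outside <- v < b$lo | v > b$hi
    if (any(outside)) {
      rlang::warn(sprintf("%d %s value(s) outside [%g, %g]; clamped",
                          sum(outside), tr, b$lo, b$hi))
      v <- pmin(pmax(v, b$lo), b$hi)
    }
    out[[tr]] <- 1L + vapply(v, function(x) sum(cuts < x), 0L)
  }
  out
}

#' Gower distance over ordinal trait categories
#'
#' Per-trait dissimilarity `|x - y| / range` with the range taken over the
#' whole table (4 when both extreme categories occur), averaged unweighted
#' over the seven traits. Traits with zero range carry no information and are
#' dropped from the mean with a warning.
#'
#' @param ordinal Tibble from [bin_traits()] (or any tibble with `taxon` and
#'   the trait columns as integers in 1..5).
#' @return A `dist` object labelled by taxon, entries in \[0, 1\].
#' @export
gower_distance <- function(ordinal) {
  check_columns(ordinal, c("taxon", trait_names()), "ordinal trait table")
  m <- as.matrix(ordinal[trait_names()])
  if (any(is.na(m)) || any(m < 1) || any(m > 5)) {
    rs_abort("ordinal categories must be complete and within 1..5")
  }
  rng <- apply(m, 2, function(col) diff(range(col)))
  if (any(rng == 0)) {
    rlang::warn(sprintf("zero-range trait(s) dropped from Gower mean: %s",
                        paste(colnames(m)[rng == 0], collapse = ", ")))
  }
  use <- rng > 0
  if (!any(use)) rs_abort("all traits have zero range")
  n <- nrow(m)
  dm <- matrix(0, n, n)
  for (j in which(use)) {
    dm <- dm + abs(outer(m[, j], m[, j], `-`)) / rng[j]
  }
  dm <- dm / sum(use)
  rownames(dm) <- colnames(dm) <- ordinal$taxon
  stats::as.dist(dm)
}

#' Build the pooled coral trait space
#'
#' PCoA of the Gower distance matrix over the pooled taxon set of all years
#' and sites; the first `n_axes` (default 4) principal coordinates form the
#' fixed reference frame in which every per-year assemblage subset is
#' measured, which is what makes per-year occupied-volume fractions
#' comparable.
#'
#' @param d Gower `dist` over taxa (see [gower_distance()]).
#' @param n_axes Number of retained axes (default 4).
#' @return Object of class `trait_space`: `coordinates` (taxa x axes),
#'   `eigenvalues`, `explained`, `taxa`.
#' @export
build_trait_space <- function(d, n_axes = 4) {
  d <- stats::as.dist(d)
  if (attr(d, "Size") < 6) rs_abort("trait space needs at least 6 taxa")
  ord <- pcoa(d, n_axes = n_axes)
  if (ncol(ord$coordinates) < n_axes) {
    rs_abort(sprintf(
      "only %d positive trait-space axes available, %d requested",
      ncol(ord$coordinates), n_axes
    ))
  }
  structure(list(
    coordinates = ord$coordinates,
    eigenvalues = ord$eigenvalues,
    explained = ord$explained,
    taxa = ord$labels
  ), class = "trait_space")
}

#' @export
print.trait_space <- function(x, ...) {
  cat(sprintf("trait space: %d taxa on %d axes; explained %s\n",
              length(x$taxa), ncol(x$coordinates),
              paste0(sprintf("%.1f%%", 100 * x$explained), collapse = " ")))
  invisible(x)
}

# Internal: coordinates of a taxon subset, validating membership.
space_subset <- function(space, taxa) {
  missing <- setdiff(taxa, space$taxa)
  if (length(missing) > 0) {
    rs_abort(sprintf("taxa not in the trait space: %s",
                     paste(utils::head(missing, 5), collapse = ", ")))
  }
  space$coordinates[match(taxa, space$taxa), , drop = FALSE]
}

#' Occupied trait-space volume fraction
#'
#' Convex-hull volume of an assemblage's taxa in the retained trait-space
#' axes, divided by the hull volume of the full pooled taxon set. Equals 1
#' for the full set, is monotone non-decreasing under supersets, and returns
#' 0 (with attribute `degenerate = TRUE` and a warning) when the subset has
#' too few affinely independent taxa to span the space.
#'
#' @param space A `trait_space`.
#' @param taxa Character vector of taxa present in the assemblage.
#' @return Fraction in \[0, 1\] with attribute `degenerate`.
#' @export
trait_volume_fraction <- function(space, taxa) {
  full <- convex_hull_volume(space$coordinates)
  if (attr(full, "degenerate") || full <= 0) {
    rs_abort("pooled trait space is degenerate; occupied volume undefined")
  }
  sub <- convex_hull_volume(space_subset(space, unique(taxa)))
  if (attr(sub, "degenerate")) {
    rlang::warn("degenerate assemblage subset; occupied volume reported as 0")
    return(structure(0, degenerate = TRUE))
  }
  structure(min(as.numeric(sub) / as.numeric(full), 1), degenerate = FALSE)
}

#' Five-nearest-neighbour functional redundancy
#'
#' For each taxon, the sum of Euclidean trait-space distances to its `k`
#' (default 5) nearest other taxa; the assemblage value is the mean over
#' taxa. Smaller values mean denser packing, i.e. higher functional
#' redundancy. Distance ties are broken by taxon-label order so the statistic
#' is deterministic.
#'
#' @param space A `trait_space`.
#' @param taxa Taxa present in the assemblage (at least `k + 1`).
#' @param k Number of neighbours (default 5).
#' @return Mean summed neighbour distance (scalar >= 0).
#' @export
functional_redundancy_5nn <- function(space, taxa, k = 5) {
  taxa <- unique(taxa)
  if (length(taxa) < k + 1) {
    rs_abort(sprintf("need at least %d taxa for %d-NN redundancy", k + 1, k))
  }
  z <- space_subset(space, taxa)
  dm <- as.matrix(stats::dist(z))
  per_taxon <- vapply(seq_along(taxa), function(i) {
    d_i <- dm[i, -i]
    lab <- taxa[-i]
    o <- order(d_i, lab)
    sum(d_i[o][seq_len(k)])
  }, 0)
  mean(per_taxon)
}

#' Abundance-weighted functional dispersion (FDis)
#'
#' Mean abundance-weighted Euclidean distance of taxa to the
#' abundance-weighted centroid of the assemblage in trait space:
#' `FDis = sum(w_i ||z_i - c||) / sum(w_i)` with
#' `c = sum(w_i z_i) / sum(w_i)`. Invariant to rescaling all weights; zero
#' iff all positive-weight taxa are coincident.
#'
#' @param space A `trait_space`.
#' @param weights Named non-negative vector of abundances (percent cover),
#'   names are taxa; at least one positive.
#' @return Dispersion (scalar >= 0).
#' @export
functional_dispersion <- function(space, weights) {
  if (is.null(names(weights))) rs_abort("weights must be named by taxon")
  w <- weights[weights > 0]
  if (length(w) == 0) rs_abort("all abundance weights are zero")
  z <- space_subset(space, names(w))
  ctr <- colSums(z * w) / sum(w)
  dists <- sqrt(rowSums((z - matrix(ctr, nrow(z), ncol(z), byrow = TRUE))^2))
  sum(w * dists) / sum(w)
}

#' Kernel-density occupancy of a trait-space plane
#'
#' Gaussian kernel density of an assemblage's taxa on a pair of trait-space
#' axes (normal-reference plug-in bandwidth per axis), with density contour
#' levels enclosing 50% and 95% of the estimated probability mass, as used
#' for trait-space occupancy heat maps.
#'
#' @param space A `trait_space`.
#' @param taxa Taxa present (at least 3).
#' @param axes Integer pair of axis indices, `c(1, 2)` or `c(3, 4)`.
#' @param n_grid Grid resolution per axis.
#' @param mass Probability masses for the contour levels.
#' @return Object of class `reef_kde`: `x`, `y`, `z` (density grid),
#'   `levels` (named by mass), `axes`, `points`.
#' @export
kde_occupancy <- function(space, taxa, axes = c(1, 2), n_grid = 101,
                          mass = c(0.5, 0.95)) {
  taxa <- unique(taxa)
  if (length(taxa) < 3) rs_abort("KDE occupancy needs at least 3 taxa")
  z <- space_subset(space, taxa)[, axes, drop = FALSE]
  if (any(apply(z, 2, stats::sd) < 1e-12)) {
    rs_abort("zero-variance axis; KDE bandwidth undefined")
  }
  h <- c(MASS::bandwidth.nrd(z[, 1]), MASS::bandwidth.nrd(z[, 2]))
  lims <- c(range(z[, 1]) + c(-3, 3) * h[1] / 4,
            range(z[, 2]) + c(-3, 3) * h[2] / 4)
  k <- MASS::kde2d(z[, 1], z[, 2], h = h, n = n_grid, lims = lims)
  cell <- diff(k$x[1:2]) * diff(k$y[1:2])
  dens <- sort(as.numeric(k$z), decreasing = TRUE)
  cum <- cumsum(dens) * cell
  levels <- vapply(mass, function(m) {
    i <- which(cum >= m * cum[length(cum)])[1]
    dens[i]
  }, 0)
  structure(list(
    x = k$x, y = k$y, z = k$z,
    levels = stats::setNames(levels, format(mass)),
    axes = axes, points = z
  ), class = "reef_kde")
}

#' Per-assemblage functional trait metrics
#'
#' Computes the three trait-space metrics (occupied-volume fraction, 5-NN
#' redundancy, abundance-weighted dispersion) for each row of a pooled
#' abundance matrix (typically the per-year meta-assemblages), all measured
#' in one fixed pooled trait space.
#'
#' @param space A `trait_space` built on the pooled taxon set.
#' @param abundance Wide abundance tibble, e.g.
#'   `coral_abundance_matrix(tr, "pooled-year")`.
#' @return Tibble: `unit`, `year` (if present), `n_taxa`, `volume_fraction`,
#'   `degenerate`, `redundancy_5nn`, `dispersion`.
#' @export
functional_metrics <- function(space, abundance) {
  parts <- abundance_parts(abundance)
  purrr::map_dfr(seq_len(nrow(parts$matrix)), function(i) {
    w <- parts$matrix[i, ]
    present <- names(w)[w > 0]
    vf <- trait_volume_fraction(space, present)
    tibble::tibble(
      unit = rownames(parts$matrix)[i],
      year = if ("year" %in% names(parts$meta)) parts$meta$year[i] else NA_integer_,
      n_taxa = length(present),
      volume_fraction = as.numeric(vf),
      degenerate = attr(vf, "degenerate"),
      redundancy_5nn = functional_redundancy_5nn(space, present),
      dispersion = functional_dispersion(space, w[present])
    )
  })
}
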