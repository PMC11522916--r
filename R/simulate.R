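# Synthetic survey scenario generator. The defaults emulate the design of a
# three-survey (2006/2010/2018) eight-site fringing-reef monitoring study:
# one 50-m line-intercept transect per site in the first year, six 10-m
# replicates thereafter; a coral assemblage that loses its corymbose and
# branching taxa after year 1 and gains many near-duplicate encrusting and
# massive taxa by year 3; and belt-transect fish counts positively coupled
# to coral cover for large fish and small coral dwellers.

# Internal: Dirichlet draw via gamma normalisation.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Scenario configuration for the synthetic survey generator
#'
#' Returns the default scenario: 8 sites (4 protected), surveys in 2006,
#' 2010 and 2018, a 90-taxon coral pool whose per-year richness is 48/50/78,
#' mean total coral cover 27.87/12.94/22.76 percent with faster year-3
#' recovery at protected sites, about 12 percent of raw trait cells masked
#' missing, and fish surveys at 5 sites with abundance positively coupled to
#' coral cover for large fish and 5-10 cm coral dwellers. Any field can be
#' overridden through `...`.
#'
#' @param ... Named overrides of default fields.
#' @return Object of class `scenario_config` (a named list).
#' @export
scenario_config <- function(...) {
  cfg <- list(
    n_sites = 8L,
    n_protected = 4L,
    years = c(2006L, 2010L, 2018L),
    transect_plan = list(c(n = 1, length_m = 50), c(n = 6, length_m = 10),
                         c(n = 6, length_m = 10)),
    n_taxa = 90L,          # 12 lost + 36 core + 14 year-2 + 28 year-3 additions
    n_lost = 12L,          # corymbose/branching taxa present only in year 1
    n_edge_y3 = 8L,        # year-3 additions that extend trait axes 1-2
    coral_cover_mean = c(27.87, 12.94, 22.76),
    protected_recovery_bonus = 10,  # percentage-point year-3 cover difference
    site_cover_sd = 0.8,   # lognormal sd of site multipliers (among-site CV ~0.9)
    cover_noise = 0.02,    # Dirichlet noise; 0 = transects hit targets exactly
    site_occupancy = 0.5,  # chance a pool taxon also occurs beyond its home site
    raw_jitter_sd = 0.4,   # lognormal spread of raw traits around archetypes
    duplicate_jitter_sd = 0.04,
    missing_trait_frac = 0.12,
    fish_sites = 5L,       # 3 protected + 2 unprotected of the 8
    belt_width_m = 2,
    fish_transect_length_m = c(150, 150, 60),
    fish_total = list(cd = c(21.70, 14.75, 11.10),
                      ncd = c(39.52, 12.64, 9.75)),
    fish_size_weights = list(
      cd = c(`<5` = 0.45, `5-10` = 0.35, `10-20` = 0.15, `>20` = 0.05),
      ncd = c(`<5` = 0.10, `5-10` = 0.25, `10-20` = 0.25, `>20` = 0.40)
    ),
    fish_cover_slopes = list(cd = c(`<5` = 0, `5-10` = 0.12, `10-20` = 0, `>20` = 0),
                             ncd = c(`<5` = 0, `5-10` = 0, `10-20` = 0, `>20` = 0.16)),
    species_per_fish_class = 4L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    rs_abort(sprintf("unknown scenario fields: %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  if (any(cfg$coral_cover_mean < 0) || any(cfg$coral_cover_mean > 100)) {
    rs_abort("coral cover targets must lie in [0, 100]")
  }
  structure(cfg, class = "scenario_config")
}

# Growth-form archetypes on the ordinal 1-5 scale for the seven traits.
# Corymbose and branching forms occupy an extreme region (fast growth, high
# intra-colony space and surface-area:volume) that no other form reaches, so
# they are hull vertices of the pooled trait space by construction; the
# "massive_edge"/"encrusting_edge" variants extend the size/density plane.
growth_form_archetypes <- function() {
  a <- rbind(
    corymbose       = c(5, 2, 3, 4, 1, 5, 5),
    branching       = c(5, 1, 4, 5, 1, 4, 4),
    digitate        = c(4, 2, 3, 3, 1, 3, 4),
    encrusting      = c(2, 4, 2, 1, 2, 1, 2),
    massive         = c(1, 5, 4, 3, 3, 1, 1),
    submassive      = c(2, 4, 3, 2, 3, 2, 2),
    laminar         = c(3, 3, 3, 2, 2, 2, 3),
    foliose         = c(3, 2, 3, 2, 2, 3, 3),
    massive_edge    = c(1, 5, 5, 5, 4, 1, 1),
    encrusting_edge = c(2, 3, 1, 1, 1, 1, 2)
  )
  colnames(a) <- trait_names()
  a
}

form_genera <- function() {
  list(
    corymbose = "Acropora", branching = c("Pocillopora", "Seriatopora"),
    digitate = c("Montipora", "Acropora"),
    encrusting = c("Montipora", "Leptastrea", "Psammocora"),
    massive = c("Porites", "Favia", "Platygyra", "Goniopora"),
    submassive = c("Porites", "Hydnophora"),
    laminar = c("Echinopora", "Turbinaria"),
    foliose = c("Merulina", "Pavona"),
    massive_edge = "Porites", encrusting_edge = "Montipora"
  )
}

# Internal: geometric midpoint of an ordinal bin on the raw scale.
bin_midpoints <- function(breaks) {
  mids <- matrix(0, nrow(breaks), 5)
  rownames(mids) <- breaks$trait
  for (i in seq_len(nrow(breaks))) {
    edges <- as.numeric(breaks[i, c("lo", "b1", "b2", "b3", "b4", "hi")])
    mids[i, ] <- sqrt(edges[-6] * edges[-1])
  }
  mids
}

#' Generate the synthetic coral trait pool
#'
#' Draws ~90 coral taxa from growth-form archetypes. Raw trait values are
#' lognormal around the archetype's bin midpoints; a configurable fraction of
#' raw cells is masked missing to exercise imputation; near-duplicate taxa
#' (the year-2/year-3 cohort additions) are jittered copies of parents in
#' their growth form. Deterministic for a given seed.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed.
#' @return List: `traits` (raw table with gaps), `cohorts` (taxon, cohort
#'   membership), `complete_traits` (no gaps, for ground truth).
#' @export
generate_trait_pool <- function(config = scenario_config(), seed) {
  set.seed(substream_seed(seed, "traits"))
  arch <- growth_form_archetypes()
  genera <- form_genera()
  breaks <- default_trait_breaks()
  mids <- bin_midpoints(breaks)

  plan <- list(
    lost = c(corymbose = 8L, branching = config$n_lost - 8L),
    core = c(massive = 12L, submassive = 8L, encrusting = 8L, laminar = 4L,
             foliose = 4L),
    y2_add = c(encrusting = 7L, massive = 7L),
    y3_add = c(encrusting = 10L, massive = 10L,
               massive_edge = ceiling(config$n_edge_y3 / 2),
               encrusting_edge = floor(config$n_edge_y3 / 2))
  )
  rows <- list()
  counter <- new.env()
  new_taxon <- function(form, cohort, parent_raw = NULL) {
    genus <- sample(rep(genera[[form]], 2), 1)
    key <- genus
    counter[[key]] <- (counter[[key]] %||% 0L) + 1L
    taxon <- sprintf("%s sp%02d", genus, counter[[key]])
    if (is.null(parent_raw)) {
      target <- arch[form, ]
      sd_j <- if (grepl("_edge$", form)) config$raw_jitter_sd / 2 else
        config$raw_jitter_sd
      raw <- vapply(seq_along(target), function(j) {
        mids[trait_names()[j], target[j]] * exp(stats::rnorm(1, 0, sd_j))
      }, 0)
    } else {
      raw <- parent_raw * exp(stats::rnorm(length(parent_raw), 0,
                                           config$duplicate_jitter_sd))
    }
    names(raw) <- trait_names()
    c(list(taxon = taxon, genus = genus,
           growth_form = sub("_edge$", "", form), cohort = cohort),
      as.list(raw))
  }
  for (cohort in names(plan)) {
    for (form in names(plan[[cohort]])) {
      n_f <- plan[[cohort]][[form]]
      duplicate <- cohort %in% c("y2_add", "y3_add") && !grepl("edge", form)
      parents <- Filter(function(r) r$growth_form == form &&
                          r$cohort %in% c("core"), rows)
      for (i in seq_len(n_f)) {
        parent_raw <- NULL
        if (duplicate && length(parents) > 0) {
          pr <- parents[[sample.int(length(parents), 1)]]
          parent_raw <- unlist(pr[trait_names()])
        }
        rows[[length(rows) + 1]] <- new_taxon(form, cohort, parent_raw)
      }
    }
  }
  pool <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  complete <- pool[c("taxon", "genus", "growth_form", trait_names())]

  traits <- complete
  n_cells <- nrow(traits) * length(trait_names())
  n_mask <- round(config$missing_trait_frac * n_cells)
  mask <- sample.int(n_cells, n_mask)
  for (idx in mask) {
    r <- ((idx - 1) %% nrow(traits)) + 1
    cl <- trait_names()[((idx - 1) %/% nrow(traits)) + 1]
    traits[[cl]][r] <- NA_real_
  }
  # never mask an entire taxon row or an entire trait column
  for (cl in trait_names()) {
    if (all(is.na(traits[[cl]]))) traits[[cl]][1] <- complete[[cl]][1]
  }
  list(
    traits = traits,
    cohorts = pool[c("taxon", "genus", "growth_form", "cohort")],
    complete_traits = complete
  )
}

# Internal: non-coral benthos composition of the free (non-coral) cover,
# shifting from rocky/bare substrate after disturbance to sandy substrate
# during recovery.
substrate_weights <- function(year_index) {
  w <- switch(year_index,
    c(rock = 0.28, `bare reef` = 0.16, CCA = 0.12, sand = 0.12,
      `soft coral` = 0.12, zoantharian = 0.03, corallimorpharian = 0.02,
      sponge = 0.04, `sea anemone` = 0.02, macroalgae = 0.07, other = 0.02),
    c(rock = 0.22, `bare reef` = 0.36, CCA = 0.08, sand = 0.12,
      `soft coral` = 0.06, zoantharian = 0.02, corallimorpharian = 0.02,
      sponge = 0.03, `sea anemone` = 0.02, macroalgae = 0.05, other = 0.02),
    c(rock = 0.18, `bare reef` = 0.10, CCA = 0.10, sand = 0.32,
      `soft coral` = 0.10, zoantharian = 0.02, corallimorpharian = 0.02,
      sponge = 0.03, `sea anemone` = 0.02, macroalgae = 0.09, other = 0.02)
  )
  w / sum(w)
}

# Internal: growth-form share of total coral cover per survey year.
form_cover_weights <- function(year_index) {
  switch(year_index,
    c(corymbose = 0.20, branching = 0.12, digitate = 0.00, massive = 0.30,
      submassive = 0.11, encrusting = 0.11, laminar = 0.09, foliose = 0.07),
    c(massive = 0.45, submassive = 0.16, encrusting = 0.24, laminar = 0.08,
      foliose = 0.07),
    c(massive = 0.42, submassive = 0.12, encrusting = 0.33, laminar = 0.07,
      foliose = 0.06)
  )
}

#' Generate synthetic line-intercept benthic surveys
#'
#' Realises per-transect intercept segments for every site and year of the
#' scenario. Per-transect category shares are Dirichlet noise around the
#' site-year targets (so tape lengths are always fully classified and never
#' exceeded), total coral cover follows the configured V-shaped trajectory
#' with extra year-3 recovery at protected sites, and the coral share is
#' split among the taxa of each year's cohort pool.
#'
#' @param config A [scenario_config()].
#' @param pool Trait pool from [generate_trait_pool()].
#' @param seed Integer seed.
#' @return List: `transects` (segment tibble), `truth` (tibble of site-year
#'   target total covers).
#' @export
generate_benthic_surveys <- function(config = scenario_config(), pool, seed) {
  set.seed(substream_seed(seed, "benthic"))
  sites <- sprintf("S%d", seq_len(config$n_sites))
  protected <- seq_len(config$n_sites) <= config$n_protected
  cohorts <- pool$cohorts
  year_pool <- list(
    cohorts$taxon[cohorts$cohort %in% c("lost", "core")],
    cohorts$taxon[cohorts$cohort %in% c("core", "y2_add")],
    cohorts$taxon[cohorts$cohort %in% c("core", "y2_add", "y3_add")]
  )
  site_mult <- exp(stats::rnorm(config$n_sites, 0, config$site_cover_sd))
  site_mult <- site_mult / mean(site_mult)

  conc <- if (config$cover_noise > 0) 1 / config$cover_noise else Inf
  draw_shares <- function(target) {
    target <- target / sum(target)
    if (!is.finite(conc)) return(target)
    rdirichlet1(pmax(target, 1e-6) * conc)
  }

  segments <- list()
  truth <- list()
  for (yi in seq_along(config$years)) {
    year <- config$years[yi]
    taxa_y <- year_pool[[yi]]
    # within-year taxon base weights: growth-form share split lognormally
    forms <- cohorts$growth_form[match(taxa_y, cohorts$taxon)]
    fw <- form_cover_weights(yi)
    wt <- stats::setNames(rep(0, length(taxa_y)), taxa_y)
    for (f in unique(forms)) {
      members <- taxa_y[forms == f]
      raw_w <- exp(stats::rnorm(length(members), 0, 0.6))
      share <- fw[[f]] %||% 0.02
      wt[members] <- share * raw_w / sum(raw_w)
    }
    wt <- wt / sum(wt)
    home <- stats::setNames(sites[1 + (seq_along(taxa_y) - 1) %% config$n_sites],
                            taxa_y)
    for (si in seq_along(sites)) {
      base <- config$coral_cover_mean[yi] * site_mult[si]
      if (yi == length(config$years)) {
        base <- base + ifelse(protected[si], 1, -1) *
          config$protected_recovery_bonus / 2
      }
      coral_target <- min(max(base, 0.5), 95)
      present <- taxa_y[home == sites[si] |
                          stats::runif(length(taxa_y)) < config$site_occupancy]
      if (length(present) == 0) present <- taxa_y[home == sites[si]]
      taxon_w <- wt[present] / sum(wt[present])
      sub_w <- substrate_weights(yi)
      target <- c(coral_target / 100, (1 - coral_target / 100) * sub_w)
      names(target)[1] <- "reef-building coral"
      plan <- config$transect_plan[[yi]]
      for (ti in seq_len(plan[["n"]])) {
        shares <- draw_shares(target)
        names(shares) <- names(target)
        taxon_shares <- if (!is.finite(conc)) taxon_w else
          rdirichlet1(pmax(taxon_w, 1e-6) * conc)
        len <- plan[["length_m"]]
        coral_len <- shares[["reef-building coral"]] * len
        seg <- tibble::tibble(
          site = sites[si], year = year, protected = protected[si],
          transect_id = sprintf("T%d", ti), transect_length_m = len,
          category = c(rep("reef-building coral", length(present)),
                       names(sub_w)),
          taxon = c(present, rep(NA_character_, length(sub_w))),
          intercept_length_m = c(coral_len * taxon_shares,
                                 shares[names(sub_w)] * len)
        )
        segments[[length(segments) + 1]] <- seg[seg$intercept_length_m > 0, ]
      }
      truth[[length(truth) + 1]] <- tibble::tibble(
        site = sites[si], year = year, protected = protected[si],
        coral_cover_target = coral_target
      )
    }
  }
  list(transects = dplyr::bind_rows(segments), truth = dplyr::bind_rows(truth))
}

#' Generate synthetic belt-transect fish surveys
#'
#' Poisson counts per (site, year, coral-dweller flag, size class) around a
#' linear predictor `intercept + slope * coral cover` on the
#' individuals-per-60-m2 scale, scaled to the year's transect area. Slope
#' defaults are positive only for >20 cm non-coral dwellers and 5-10 cm
#' coral dwellers; intercepts are per class and year so non-coral-dweller
#' abundance declines across surveys as observed in heavily fished reefs.
#' Class counts are split multinomially over a fixed species pool.
#'
#' @param config A [scenario_config()].
#' @param benthic_truth Tibble of site-year target coral covers (from
#'   [generate_benthic_surveys()]).
#' @param seed Integer seed.
#' @return List: `fish` (record tibble), `lookup` (taxon, cd_flag),
#'   `truth` (expected abundances per class).
#' @export
generate_fish_surveys <- function(config = scenario_config(), benthic_truth,
                                  seed) {
  set.seed(substream_seed(seed, "fish"))
  sites <- sprintf("S%d", seq_len(config$n_sites))
  protected <- seq_len(config$n_sites) <= config$n_protected
  n_prot_fish <- min(3L, config$fish_sites)
  fish_sites <- c(sites[protected][seq_len(n_prot_fish)],
                  sites[!protected][seq_len(config$fish_sites - n_prot_fish)])
  cd_genera <- c("Chromis", "Dascyllus", "Pomacentrus", "Gobiodon")
  ncd_genera <- c("Caesio", "Scarus", "Siganus", "Lutjanus")
  species <- list(); lookup <- list()
  for (cd in c(TRUE, FALSE)) {
    for (sc in fish_size_classes()) {
      gen <- if (cd) cd_genera else ncd_genera
      sp <- sprintf("%s sp%02d", sample(rep(gen, 3), config$species_per_fish_class),
                    seq_len(config$species_per_fish_class) +
                      10 * match(sc, fish_size_classes()))
      key <- paste(cd, sc)
      w <- exp(stats::rnorm(length(sp), 0, 0.5))
      species[[key]] <- list(taxa = sp, w = w / sum(w))
      lookup[[key]] <- tibble::tibble(taxon = sp, cd_flag = cd)
    }
  }
  lookup <- dplyr::bind_rows(lookup)

  records <- list(); truth <- list()
  for (yi in seq_along(config$years)) {
    year <- config$years[yi]
    mean_cover <- config$coral_cover_mean[yi]
    len <- config$fish_transect_length_m[yi]
    area <- len * config$belt_width_m
    for (cd in c(TRUE, FALSE)) {
      cls <- if (cd) "cd" else "ncd"
      totals <- config$fish_total[[cls]][yi]
      sw <- config$fish_size_weights[[cls]]
      slopes <- config$fish_cover_slopes[[cls]]
      for (sc in fish_size_classes()) {
        base <- totals * sw[[sc]]
        slope <- slopes[[sc]]
        intercept <- base - slope * mean_cover
        if (intercept < 0) {
          rs_abort(sprintf(
            "negative expected abundance for %s %s in year %d; reduce the cover slope",
            cls, sc, year
          ), class = "reefsucc_negative_expectation")
        }
        for (site in fish_sites) {
          cover <- benthic_truth$coral_cover_target[
            benthic_truth$site == site & benthic_truth$year == year]
          lambda60 <- intercept + slope * cover
          lambda <- lambda60 * area / 60
          total_count <- stats::rpois(1, lambda)
          pool <- species[[paste(cd, sc)]]
          split <- if (total_count > 0)
            as.integer(stats::rmultinom(1, total_count, pool$w)) else
            rep(0L, length(pool$taxa))
          records[[length(records) + 1]] <- tibble::tibble(
            site = site, year = year, taxon = pool$taxa, count = split,
            size_class = sc, transect_length_m = len,
            belt_width_m = config$belt_width_m
          )
          truth[[length(truth) + 1]] <- tibble::tibble(
            site = site, year = year, cd_flag = cd, size_class = sc,
            expected_60m2 = lambda60, slope = slope
          )
        }
      }
    }
  }
  fish <- dplyr::bind_rows(records)
  fish <- fish[fish$count > 0 | !duplicated(paste(fish$site, fish$year)), ]
  list(fish = fish, lookup = lookup, truth = dplyr::bind_rows(truth))
}

#' Simulate a complete survey scenario
#'
#' Runs the three generators (trait pool, benthic transects, fish surveys)
#' off one master seed with named substreams, returning every input table the
#' analysis pipeline needs plus the generating ground truth.
#'
#' @param config A [scenario_config()].
#' @param seed Integer master seed.
#' @return List of class `reef_scenario`: `transects`, `fish`, `traits`
#'   (raw, with gaps), `cd_lookup`, `ground_truth`, `config`, `seed`.
#' @export
simulate_scenario <- function(config = scenario_config(), seed) {
  if (missing(seed)) rs_abort("simulate_scenario() requires a seed")
  pool <- generate_trait_pool(config, seed)
  benthic <- generate_benthic_surveys(config, pool, seed)
  fish <- generate_fish_surveys(config, benthic$truth, seed)
  structure(list(
    transects = benthic$transects,
    fish = fish$fish,
    traits = pool$traits,
    cd_lookup = fish$lookup,
    ground_truth = list(
      cohorts = pool$cohorts,
      complete_traits = pool$complete_traits,
      site_cover = benthic$truth,
      fish_expectations = fish$truth,
      deleted_year2 = pool$cohorts$taxon[pool$cohorts$cohort == "lost"],
      added_year3 = pool$cohorts$taxon[pool$cohorts$cohort == "y3_add"]
    ),
    config = config,
    seed = seed
  ), class = "reef_scenario")
}

#' Write scenario input tables to a directory
#'
#' Writes the three input TSVs (benthic transects, fish records,
#' coral-dweller lookup), the raw trait table, and a ground-truth JSON.
#'
#' @param scenario A `reef_scenario` from [simulate_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(scenario$transects, file.path(dir, "transects.tsv"))
  readr::write_tsv(scenario$fish, file.path(dir, "fish.tsv"))
  readr::write_tsv(scenario$cd_lookup, file.path(dir, "cd_lookup.tsv"))
  readr::write_tsv(scenario$traits, file.path(dir, "traits.tsv"))
  jsonlite::write_json(
    list(seed = scenario$seed,
         deleted_year2 = scenario$ground_truth$deleted_year2,
         added_year3 = scenario$ground_truth$added_year3,
         site_cover = scenario$ground_truth$site_cover),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
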