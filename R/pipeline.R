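# One-call orchestration: survey ingestion -> cover -> diversity ->
# multivariate -> trait space -> fish -> mixed models, with every
# intermediate exposed as a table and an auditable JSON manifest.

# Internal: TSV with a one-line provenance header.
write_reef_tsv <- function(df, path, seed, config_hash) {
  writeLines(sprintf("#generated-by reefsucc %s; seed=%s; config=%s",
                     as.character(utils::packageVersion("reefsucc")),
                     seed, config_hash), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  path
}

#' Run the full succession analysis pipeline
#'
#' Executes the analysis stages on a simulated or field scenario and returns
#' (and optionally writes) all result tables: benthic composition, Hill
#' diversity with coverage and rarefaction, PCoA / PERMANOVA / db-RDA of
#' coral assemblages, per-year functional trait metrics with KDE occupancy
#' grids, fish abundance partitions and assemblage tests, and the linear
#' mixed models of cover and of coral-fish relationships. Any stage error
#' aborts with the stage name; when writing to disk, a failed run leaves no
#' partial output behind.
#'
#' @param scenario A `reef_scenario` from [simulate_scenario()], or a list
#'   with elements `transects`, `fish`, `traits`, `cd_lookup`.
#' @param seed Integer seed used for every permutation test.
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @param stages Stages to run (subset of the default vector). `cover` is
#'   always run; later stages that depend on a disabled stage are skipped.
#' @param n_perm Permutations for PERMANOVA (default 999).
#' @param pcoa_axes Retained trait-space axes (default 4).
#' @param alpha Significance level for ANOVA/LSD (default 0.05).
#' @param resolution_cm Pseudo-count resolution for cover-based rarefaction.
#' @return Named list of result tables and fitted objects, plus `manifest`.
#' @export
run_pipeline <- function(scenario, seed, out_dir = NULL,
                         stages = c("cover", "diversity", "multivariate",
                                    "traitspace", "fish", "lmm"),
                         n_perm = 999, pcoa_axes = 4, alpha = 0.05,
                         resolution_cm = 1) {
  if (missing(seed)) rs_abort("run_pipeline() requires a seed")
  stages <- match.arg(stages, several.ok = TRUE)
  warnings_log <- character(0)
  timings <- list()
  res <- list()
  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        rs_abort(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)),
                 class = "reefsucc_stage_error")
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  transects <- run_stage("ingest", validate_transects(scenario$transects))

  res$cover_site_year <- run_stage("cover", compute_cover(transects))
  res$cover_pooled_year <- run_stage("cover", compute_cover(transects, by = "year"))
  res$abundance_site_year <- run_stage("cover", coral_abundance_matrix(transects))
  res$abundance_pooled_year <- run_stage(
    "cover", coral_abundance_matrix(transects, "pooled-year"))
  res$growth_form_cover <- run_stage(
    "cover", growth_form_cover(res$abundance_pooled_year, scenario$traits))

  if ("diversity" %in% stages) {
    res$diversity <- run_stage("diversity", {
      parts <- abundance_parts(res$abundance_pooled_year)
      tape_by_year <- res$cover_pooled_year$tape_m[
        match(parts$meta$year, res$cover_pooled_year$year)]
      purrr::map_dfr(seq_len(nrow(parts$matrix)), function(i) {
        counts <- cover_to_counts(parts$matrix[i, ], tape_by_year[i],
                                  resolution_cm)
        counts <- counts[counts > 0]
        dplyr::mutate(rarefaction_curve(counts),
                      unit = rownames(parts$matrix)[i], .before = 1)
      })
    })
  }

  if ("multivariate" %in% stages) {
    res$permanova <- run_stage("multivariate", {
      d <- bray_curtis(res$abundance_site_year)
      design <- res$abundance_site_year[c("year", "protected")]
      permanova(d, design, n_perm = n_perm,
                seed = substream_seed(seed, "permanova"))
    })
    res$dbrda <- run_stage("multivariate", {
      d <- bray_curtis(res$abundance_site_year)
      cand <- res$cover_site_year[benthic_categories()]
      names(cand)[names(cand) == "reef-building coral"] <- "coral cover"
      dbrda_forward_select(d, cand)
    })
    res$pcoa <- run_stage("multivariate",
                          pcoa(bray_curtis(res$abundance_site_year)))
  }

  if ("traitspace" %in% stages) {
    res$traits_complete <- run_stage("traitspace", impute_traits(scenario$traits))
    res$traits_ordinal <- run_stage("traitspace", bin_traits(res$traits_complete))
    space <- run_stage("traitspace", {
      parts <- abundance_parts(res$abundance_pooled_year)
      observed <- res$traits_ordinal[res$traits_ordinal$taxon %in% parts$taxa, ]
      build_trait_space(gower_distance(observed), n_axes = pcoa_axes)
    })
    res$trait_space <- space
    res$functional_metrics <- run_stage(
      "traitspace", functional_metrics(space, res$abundance_pooled_year))
    res$kde <- run_stage("traitspace", {
      parts <- abundance_parts(res$abundance_pooled_year)
      grids <- list()
      for (i in seq_len(nrow(parts$matrix))) {
        present <- colnames(parts$matrix)[parts$matrix[i, ] > 0]
        yr <- rownames(parts$matrix)[i]
        grids[[paste0(yr, "_ax12")]] <- kde_occupancy(space, present, c(1, 2))
        grids[[paste0(yr, "_ax34")]] <- kde_occupancy(space, present, c(3, 4))
      }
      grids
    })
    res$richness_lsd <- run_stage("traitspace", {
      parts <- abundance_parts(res$abundance_site_year)
      site_rich <- tibble::tibble(
        year = parts$meta$year,
        richness = rowSums(parts$matrix > 0)
      )
      anova_lsd(site_rich, "richness", "year", alpha = alpha)
    })
  }

  if ("fish" %in% stages && !is.null(scenario$fish)) {
    res$fish_abundance <- run_stage("fish", {
      standardize_abundance(scenario$fish) |>
        partition_cd_ncd(scenario$cd_lookup)
    })
    res$fish_totals <- run_stage("fish", {
      res$fish_abundance |>
        dplyr::group_by(.data$site, .data$year, .data$cd_flag,
                        .data$size_class) |>
        dplyr::summarise(abundance_60m2 = sum(.data$abundance_60m2),
                         .groups = "drop")
    })
    res$fish_permanova <- run_stage("fish", {
      fm <- fish_matrix(res$fish_abundance)
      prot <- res$cover_site_year$protected[
        match(fm$site, res$cover_site_year$site)]
      permanova(bray_curtis(fm), tibble::tibble(year = fm$year, protected = prot),
                n_perm = n_perm, seed = substream_seed(seed, "fish-permanova"))
    })
    res$fish_anova <- run_stage("fish", {
      tot <- res$fish_totals |>
        dplyr::group_by(.data$site, .data$year) |>
        dplyr::summarise(abundance_60m2 = sum(.data$abundance_60m2),
                         .groups = "drop")
      anova_lsd(tot, "abundance_60m2", "year", alpha = alpha)
    })
  }

  if ("lmm" %in% stages) {
    res$cover_lmm <- run_stage("lmm", {
      df <- res$cover_site_year
      df$coral_cover <- df[["reef-building coral"]]
      df$year_f <- factor(df$year)
      fit_lmm(df, coral_cover ~ protected * year_f + (1 | site))
    })
    if (!is.null(res$fish_totals)) {
      res$fish_lmm <- run_stage("lmm", {
        cover <- res$cover_site_year[c("site", "year")]
        cover$coral_cover <- res$cover_site_year[["reef-building coral"]]
        models <- list(
          total_gt20 = list(filter = function(d) d$size_class == ">20",
                            predictor = "coral_cover"),
          ncd_gt20 = list(filter = function(d) d$size_class == ">20" & !d$cd_flag,
                          predictor = "coral_cover"),
          cd_5_10 = list(filter = function(d) d$size_class == "5-10" & d$cd_flag,
                         predictor = "coral_cover"),
          cd_lt5 = list(filter = function(d) d$size_class == "<5" & d$cd_flag,
                        predictor = "volume_fraction")
        )
        purrr::imap_dfr(models, function(m, nm) {
          resp <- res$fish_totals |>
            dplyr::filter(m$filter(res$fish_totals)) |>
            dplyr::group_by(.data$site, .data$year) |>
            dplyr::summarise(abundance = sum(.data$abundance_60m2),
                             .groups = "drop") |>
            dplyr::left_join(cover, by = c("site", "year"))
          if (m$predictor == "volume_fraction") {
            if (is.null(res$functional_metrics)) return(NULL)
            resp <- dplyr::left_join(
              resp, res$functional_metrics[c("year", "volume_fraction")],
              by = "year")
            fit <- fit_lmm(resp, abundance ~ volume_fraction + (1 | site))
          } else {
            fit <- fit_lmm(resp, abundance ~ coral_cover + (1 | site) + (1 | year))
          }
          dplyr::mutate(tidy(fit), model = nm, .before = 1)
        })
      })
    }
  }

  cfg_for_hash <- scenario$config %||% list()
  config_hash <- rlang::hash(list(cfg_for_hash, stages, n_perm, pcoa_axes,
                                  alpha, resolution_cm))
  manifest <- list(
    package_version = as.character(utils::packageVersion("reefsucc")),
    seed = seed,
    config_hash = config_hash,
    stages = stages,
    n_perm = n_perm,
    pcoa_axes = pcoa_axes,
    alpha = alpha,
    resolution_cm = resolution_cm,
    lsd_multiplicity_correction = "none (Fisher's LSD)",
    trait_imputation = "hierarchical geometric means (genus > growth form > global)",
    warnings = warnings_log
  )
  res$manifest <- manifest
  res$timings_s <- timings   # wall-clock; kept out of the manifest so that
                             # identical runs write byte-identical artifacts

  if (!is.null(out_dir)) {
    tmp <- file.path(out_dir, ".partial")
    dir.create(tmp, showWarnings = FALSE, recursive = TRUE)
    ok <- FALSE
    on.exit(if (!ok) unlink(tmp, recursive = TRUE), add = TRUE)
    wt <- function(df, name) write_reef_tsv(df, file.path(tmp, name), seed,
                                            config_hash)
    wt(res$cover_site_year, "cover_site_year.tsv")
    wt(res$cover_pooled_year, "cover_pooled_year.tsv")
    wt(res$growth_form_cover, "growth_form_cover.tsv")
    if (!is.null(res$diversity)) wt(res$diversity, "diversity.tsv")
    if (!is.null(res$permanova)) wt(tidy(res$permanova), "permanova.tsv")
    if (!is.null(res$dbrda)) wt(res$dbrda$steps, "dbrda_steps.tsv")
    if (!is.null(res$functional_metrics))
      wt(res$functional_metrics, "functional_metrics.tsv")
    if (!is.null(res$fish_totals)) wt(res$fish_totals, "fish_totals.tsv")
    if (!is.null(res$cover_lmm)) wt(tidy(res$cover_lmm), "cover_lmm.tsv")
    if (!is.null(res$fish_lmm)) wt(res$fish_lmm, "fish_lmm.tsv")
    jsonlite::write_json(manifest, file.path(tmp, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    for (f in list.files(tmp)) {
      file.rename(file.path(tmp, f), file.path(out_dir, f))
    }
    unlink(tmp, recursive = TRUE)
    ok <- TRUE
  }
  res
}

#' Tidy a PERMANOVA table
#'
#' @param x A `reef_permanova` object.
#' @param ... Unused.
#' @return Plain tibble of the term table.
#' @export
tidy.reef_permanova <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("term", "df", "ss", "r2", "f", "p")])
}

#' Tidy a PCoA ordination
#'
#' @param x A `reef_pcoa` object.
#' @param ... Unused.
#' @return Tibble of unit scores with one row per unit.
#' @export
tidy.reef_pcoa <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(unit = x$labels),
                   tibble::as_tibble(x$coordinates))
}

#' Tidy a db-RDA forward-selection model
#'
#' @param x A `reef_dbrda` object.
#' @param ... Unused.
#' @return The per-step AIC log tibble.
#' @export
tidy.reef_dbrda <- function(x, ...) x$steps

#' Glance at a db-RDA forward-selection model
#'
#' @param x A `reef_dbrda` object.
#' @param ... Unused.
#' @return One-row tibble of inertia partition and final AIC.
#' @export
glance.reef_dbrda <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$selected),
    total_inertia = x$total_inertia,
    constrained_inertia = x$constrained_inertia,
    unconstrained_inertia = x$unconstrained_inertia,
    aic = x$aic
  )
}
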