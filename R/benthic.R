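#' Benthos and substrate categories
#'
#' The twelve benthic/substrate categories recorded along a line-intercept
#' transect (LIT): live hard-coral cover plus the abiotic and non-scleractinian
#' biotic cover types commonly distinguished in tropical reef monitoring.
#' "bare reef" is dead coral framework covered by sediment or turf algae;
#' "CCA" is crustose coralline algae.
#'
#' @return Character vector of the 12 canonical category labels.
#' @export
benthic_categories <- function() {
  c(
    "rock", "bare reef", "reef-building coral", "CCA", "sand",
    "soft coral", "zoantharian", "corallimorpharian", "sponge",
    "sea anemone", "macroalgae", "other"
  )
}

#' Default category dialect map
#'
#' Field sheets name the same benthic categories in many ways. A dialect is a
#' named character vector mapping raw labels (lower-cased) to canonical labels
#' from [benthic_categories()]. Canonical labels always map to themselves.
#'
#' @return Named character vector (raw label -> canonical label).
#' @export
default_dialect <- function() {
  canon <- benthic_categories()
  extra <- c(
    "coral"                    = "reef-building coral",
    "hard coral"               = "reef-building coral",
    "reef building coral"      = "reef-building coral",
    "scleractinian"            = "reef-building coral",
    "dead coral"               = "bare reef",
    "crustose coralline algae" = "CCA",
    "crude coralline algae"    = "CCA",
    "coralline algae"          = "CCA",
    "soft corals"              = "soft coral",
    "sponges"                  = "sponge",
    "spores"                   = "sponge",
    "sea anemones"             = "sea anemone",
    "anemone"                  = "sea anemone",
    "ma"                       = "macroalgae",
    "macro algae"              = "macroalgae",
    "others"                   = "other",
    "unknown"                  = "other"
  )
  c(stats::setNames(canon, tolower(canon)), extra)
}

transect_columns <- c(
  "site", "year", "protected", "transect_id", "transect_length_m",
  "category", "taxon", "intercept_length_m"
)

#' Read line-intercept transect records
#'
#' Reads a delimited file with one row per intercept segment and validates it
#' into the canonical transect table used throughout the package. Required
#' columns: `site`, `year`, `protected`, `transect_id`, `transect_length_m`,
#' `category`, `taxon` (empty unless the category is reef-building coral) and
#' `intercept_length_m`.
#'
#' @param path Path to a TSV or CSV file.
#' @param dialect Named character vector mapping raw category labels to
#'   canonical ones; see [default_dialect()].
#' @return A validated tibble of intercept segments.
#' @export
read_transects <- function(path, dialect = default_dialect()) {
  if (!file.exists(path)) {
    rs_abort(sprintf("transect file does not exist: %s", path))
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(
    path, delim = delim, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      site = readr::col_character(),
      year = readr::col_integer(),
      protected = readr::col_logical(),
      transect_id = readr::col_character(),
      transect_length_m = readr::col_double(),
      category = readr::col_character(),
      taxon = readr::col_character(),
      intercept_length_m = readr::col_double()
    )
  )
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    rs_abort(sprintf(
      "malformed transect file %s: first problem at line %d (%s)",
      path, prob$row[1], prob$expected[1]
    ), class = "reefsucc_parse_error")
  }
  validate_transects(raw, dialect = dialect)
}

#' Validate and normalise a transect segment table
#'
#' Checks the line-intercept invariants: category labels must resolve through
#' the dialect map, a coral taxon is present if and only if the category is
#' "reef-building coral", intercept lengths are non-negative, and the summed
#' intercepts of a transect cannot exceed its tape length.
#'
#' @inheritParams read_transects
#' @param transects Data frame of intercept segments.
#' @return The normalised tibble (canonical category labels, ordered columns).
#' @export
validate_transects <- function(transects, dialect = default_dialect()) {
  check_columns(transects, transect_columns, "transect table")
  tr <- tibble::as_tibble(transects)[transect_columns]
  key <- tolower(trimws(tr$category))
  mapped <- unname(dialect[key])
  bad <- which(is.na(mapped))
  if (length(bad) > 0) {
    rs_abort(sprintf(
      "unknown benthic category '%s' at row %d (site %s, transect %s)",
      tr$category[bad[1]], bad[1], tr$site[bad[1]], tr$transect_id[bad[1]]
    ), class = "reefsucc_unknown_category")
  }
  tr$category <- mapped
  tr$taxon <- ifelse(is.na(tr$taxon) | trimws(tr$taxon) == "", NA_character_, tr$taxon)

  coral <- tr$category == "reef-building coral"
  if (any(coral & is.na(tr$taxon))) {
    i <- which(coral & is.na(tr$taxon))[1]
    rs_abort(sprintf("reef-building coral segment without taxon at row %d", i))
  }
  if (any(!coral & !is.na(tr$taxon))) {
    i <- which(!coral & !is.na(tr$taxon))[1]
    rs_abort(sprintf(
      "taxon '%s' given for non-coral category '%s' at row %d",
      tr$taxon[i], tr$category[i], i
    ))
  }
  if (any(tr$intercept_length_m < 0) || any(tr$transect_length_m <= 0)) {
    rs_abort("intercept lengths must be >= 0 and transect lengths > 0")
  }
  sums <- tr |>
    dplyr::group_by(.data$site, .data$year, .data$transect_id) |>
    dplyr::summarise(
      total = sum(.data$intercept_length_m),
      length = .data$transect_length_m[1],
      n_len = dplyr::n_distinct(.data$transect_length_m),
      .groups = "drop"
    )
  if (any(sums$n_len > 1)) {
    i <- which(sums$n_len > 1)[1]
    rs_abort(sprintf(
      "transect %s/%d/%s has inconsistent transect_length_m values",
      sums$site[i], sums$year[i], sums$transect_id[i]
    ))
  }
  over <- sums$total > sums$length + 1e-9
  if (any(over)) {
    i <- which(over)[1]
    rs_abort(sprintf(
      "intercepts sum to %.3f m on a %.3f m tape (site %s, year %d, transect %s)",
      sums$total[i], sums$length[i], sums$site[i], sums$year[i], sums$transect_id[i]
    ), class = "reefsucc_intercept_overflow")
  }
  tr
}

#' Write transect records to a canonical TSV
#'
#' @param transects Validated transect tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transects <- function(transects, path) {
  tr <- validate_transects(transects)
  readr::write_tsv(tr, path)
  invisible(path)
}

#' Percent cover from line-intercept transects
#'
#' Computes percent cover per benthic category for each survey unit. LIT cover
#' is a length ratio, so transects of unequal length are pooled by length:
#' cover = 100 * (summed intercepts of a category) / (summed tape lengths).
#' Tape not accounted for by any segment is reported in an explicit
#' `unclassified` column rather than renormalised away, so each row sums to
#' 100 exactly.
#'
#' @param transects Validated transect tibble (see [validate_transects()]).
#' @param by Grouping columns defining a survey unit; default site-by-year.
#' @return Wide tibble: grouping columns, `protected` (when grouping includes
#'   `site`), one column per canonical category, and `unclassified`.
#' @export
compute_cover <- function(transects, by = c("site", "year")) {
  tr <- validate_transects(transects)
  if (nrow(tr) == 0) rs_abort("no transect records")
  tapes <- tr |>
    dplyr::distinct(.data$site, .data$year, .data$transect_id,
                    .data$transect_length_m, .data$protected) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      tape_m = sum(.data$transect_length_m),
      protected = if ("site" %in% by) .data$protected[1] else NA,
      .groups = "drop"
    )
  long <- tr |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by)), .data$category) |>
    dplyr::summarise(intercept_m = sum(.data$intercept_length_m), .groups = "drop") |>
    dplyr::left_join(tapes, by = by) |>
    dplyr::mutate(cover = 100 * .data$intercept_m / .data$tape_m)
  wide <- long |>
    dplyr::select(dplyr::all_of(by), "protected", "tape_m", "category", "cover") |>
    tidyr::pivot_wider(
      names_from = "category", values_from = "cover", values_fill = 0
    )
  for (cat in benthic_categories()) {
    if (!cat %in% names(wide)) wide[[cat]] <- 0
  }
  cats <- benthic_categories()
  wide$unclassified <- pmax(0, 100 - rowSums(wide[cats]))
  meta <- c(by, if ("site" %in% by) "protected", "tape_m")
  wide[c(meta, cats, "unclassified")]
}

#' Coral taxon abundance matrix (percent cover)
#'
#' Builds the assemblage-by-taxon matrix of percent cover used by the
#' multivariate and trait-space analyses. At `level = "site-year"` each row is
#' one site in one year; at `level = "pooled-year"` all sites surveyed in a
#' year are pooled into a single meta-assemblage, equivalent to the
#' length-weighted mean of the site rows.
#'
#' @param transects Validated transect tibble.
#' @param level `"site-year"` or `"pooled-year"`.
#' @return Wide tibble with metadata columns (`unit`, `site`, `year`,
#'   `protected` as applicable) followed by one numeric column per coral taxon.
#' @export
coral_abundance_matrix <- function(transects,
                                   level = c("site-year", "pooled-year")) {
  level <- match.arg(level)
  tr <- validate_transects(transects)
  by <- if (level == "site-year") c("site", "year") else "year"
  tapes <- tr |>
    dplyr::distinct(.data$site, .data$year, .data$transect_id,
                    .data$transect_length_m, .data$protected) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      tape_m = sum(.data$transect_length_m),
      protected = if (identical(by, c("site", "year"))) .data$protected[1] else NA,
      .groups = "drop"
    )
  coral <- tr |>
    dplyr::filter(.data$category == "reef-building coral") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by)), .data$taxon) |>
    dplyr::summarise(intercept_m = sum(.data$intercept_length_m), .groups = "drop")
  taxa <- sort(unique(coral$taxon))
  wide <- coral |>
    dplyr::left_join(tapes, by = by) |>
    dplyr::mutate(cover = 100 * .data$intercept_m / .data$tape_m) |>
    dplyr::select(dplyr::all_of(by), "protected", "cover", "taxon") |>
    tidyr::pivot_wider(names_from = "taxon", values_from = "cover",
                       values_fill = 0) |>
    dplyr::left_join(dplyr::select(tapes, dplyr::all_of(by)), by = by)
  units_meta <- tapes |> dplyr::select(dplyr::all_of(by), "protected")
  wide <- dplyr::left_join(units_meta, wide[c(by, taxa)], by = by)
  wide[taxa] <- lapply(wide[taxa], function(x) ifelse(is.na(x), 0, x))
  unit <- if (level == "site-year") paste(wide$site, wide$year, sep = ":") else
    as.character(wide$year)
  out <- dplyr::bind_cols(tibble::tibble(unit = unit), wide)
  if (level == "pooled-year") out$protected <- NULL
  out
}

# Internal: split a wide assemblage tibble into metadata and numeric matrix.
abundance_parts <- function(df) {
  meta_cols <- intersect(c("unit", "site", "year", "protected", "tape_m"), names(df))
  taxa <- setdiff(names(df), meta_cols)
  m <- as.matrix(df[taxa])
  if (!is.numeric(m)) rs_abort("abundance columns must be numeric")
  rownames(m) <- if ("unit" %in% names(df)) df$unit else seq_len(nrow(df))
  list(meta = df[meta_cols], matrix = m, taxa = taxa)
}

#' Resolve growth forms for coral taxa
#'
#' Taxa identified only to genus (e.g. "Acropora spp.") take the growth form
#' occurring most frequently within the genus in the trait table; frequency
#' ties are broken alphabetically by growth-form label so the assignment is
#' deterministic.
#'
#' @param taxa Character vector of coral taxon labels.
#' @param traits Trait table with columns `taxon`, `genus`, `growth_form`.
#' @return Character vector of growth forms, same length as `taxa`.
#' @export
resolve_growth_form <- function(taxa, traits) {
  check_columns(traits, c("taxon", "genus", "growth_form"), "trait table")
  direct <- traits$growth_form[match(taxa, traits$taxon)]
  need <- is.na(direct)
  if (any(need)) {
    genus_mode <- traits |>
      dplyr::filter(!is.na(.data$growth_form)) |>
      dplyr::count(.data$genus, .data$growth_form) |>
      dplyr::arrange(.data$genus, dplyr::desc(.data$n), .data$growth_form) |>
      dplyr::distinct(.data$genus, .keep_all = TRUE)
    genus <- vapply(strsplit(taxa[need], "\\s+"), `[`, "", 1)
    direct[need] <- genus_mode$growth_form[match(genus, genus_mode$genus)]
  }
  if (any(is.na(direct))) {
    rs_abort(sprintf(
      "cannot resolve growth form for taxa: %s",
      paste(unique(taxa[is.na(direct)]), collapse = ", ")
    ), class = "reefsucc_unresolved_taxon")
  }
  direct
}

#' Coral cover by growth form
#'
#' Aggregates a coral abundance matrix to cover per growth form per unit,
#' using [resolve_growth_form()] for taxa recorded at genus level. Growth-form
#' covers sum to the unit's total coral cover.
#'
#' @param abundance Output of [coral_abundance_matrix()].
#' @param traits Trait table with `taxon`, `genus`, `growth_form`.
#' @return Long tibble: unit metadata, `growth_form`, `cover`.
#' @export
growth_form_cover <- function(abundance, traits) {
  parts <- abundance_parts(abundance)
  gf <- resolve_growth_form(parts$taxa, traits)
  long <- tidyr::pivot_longer(abundance, dplyr::all_of(parts$taxa),
                              names_to = "taxon", values_to = "cover")
  long$growth_form <- gf[match(long$taxon, parts$taxa)]
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(names(parts$meta))), .data$growth_form) |>
    dplyr::summarise(cover = sum(.data$cover), .groups = "drop")
}
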