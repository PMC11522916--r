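#' Fish size classes
#'
#' The four body-length classes used in belt-transect visual censuses, kept
#' as an ordered categorical axis (never converted to midpoint lengths).
#'
#' @return Character vector of size-class labels.
#' @export
fish_size_classes <- function() {
  c("<5", "5-10", "10-20", ">20")
}

fish_columns <- c(
  "site", "year", "taxon", "count", "size_class",
  "transect_length_m", "belt_width_m"
)

#' Read belt-transect fish records
#'
#' One row per (transect, taxon, size class) observation with the transect
#' dimensions needed for standardisation.
#'
#' @param path TSV/CSV path with columns `site`, `year`, `taxon`, `count`,
#'   `size_class`, `transect_length_m`, `belt_width_m`.
#' @return Validated tibble.
#' @export
read_fish <- function(path) {
  if (!file.exists(path)) rs_abort(sprintf("fish file does not exist: %s", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE)
  validate_fish(raw)
}

#' Validate fish survey records
#'
#' @param records Data frame of fish observations.
#' @return Validated tibble with canonical column order.
#' @export
validate_fish <- function(records) {
  check_columns(records, fish_columns, "fish table")
  f <- tibble::as_tibble(records)[union(fish_columns, names(records))]
  if (any(!f$size_class %in% fish_size_classes())) {
    bad <- unique(f$size_class[!f$size_class %in% fish_size_classes()])
    rs_abort(sprintf("unknown size class(es): %s", paste(bad, collapse = ", ")))
  }
  if (any(f$count < 0) || any(abs(f$count - round(f$count)) > 1e-9)) {
    rs_abort("fish counts must be non-negative integers")
  }
  if (any(f$transect_length_m <= 0) || any(f$belt_width_m <= 0)) {
    rs_abort("transect dimensions must be positive", class = "reefsucc_zero_area")
  }
  f$count <- as.integer(round(f$count))
  f
}

#' Standardise fish abundance to individuals per 60 m^2
#'
#' Belt-transect survey areas differ between years, so counts are expressed
#' on a common area: `abundance = count / (length x width) * 60`. Grouped
#' totals are conserved and standardisation is linear in the counts.
#'
#' @param records Validated fish tibble (see [validate_fish()]).
#' @param by Grouping columns for the output (default site-by-year, keeping
#'   taxon and size class).
#' @return Long tibble: grouping columns, `taxon`, `size_class`,
#'   `abundance_60m2`.
#' @export
standardize_abundance <- function(records, by = c("site", "year")) {
  f <- validate_fish(records)
  f$abundance_60m2 <- f$count / (f$transect_length_m * f$belt_width_m) * 60
  f |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by)), .data$taxon,
                    .data$size_class) |>
    dplyr::summarise(abundance_60m2 = sum(.data$abundance_60m2),
                     .groups = "drop")
}

#' Partition fish abundance into coral dwellers and non-coral dwellers
#'
#' Splits a standardised abundance table by a literature-based coral-dweller
#' (CD) classification. Every taxon must be matched directly or, failing
#' that, at genus level (first word of the label). In strict mode an
#' unmatched taxon is an error; in lenient mode it defaults to non-coral
#' dweller (NCD) with a warning. The partition is exhaustive and disjoint so
#' CD + NCD totals equal the overall totals.
#'
#' @param abundance Long tibble from [standardize_abundance()].
#' @param lookup Tibble with columns `taxon`, `cd_flag` (logical).
#' @param mode `"strict"` or `"lenient"`.
#' @return The input tibble with a logical `cd_flag` column appended.
#' @export
partition_cd_ncd <- function(abundance, lookup, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  check_columns(lookup, c("taxon", "cd_flag"), "coral-dweller lookup")
  flag <- lookup$cd_flag[match(abundance$taxon, lookup$taxon)]
  need <- is.na(flag)
  if (any(need)) {
    genus <- vapply(strsplit(abundance$taxon[need], "\\s+"), `[`, "", 1)
    genus_lookup <- lookup |>
      dplyr::mutate(genus = vapply(strsplit(.data$taxon, "\\s+"), `[`, "", 1)) |>
      dplyr::group_by(.data$genus) |>
      dplyr::summarise(cd_flag = .data$cd_flag[1], .groups = "drop")
    flag[need] <- genus_lookup$cd_flag[match(genus, genus_lookup$genus)]
  }
  if (any(is.na(flag))) {
    unmatched <- unique(abundance$taxon[is.na(flag)])
    if (mode == "strict") {
      rs_abort(sprintf("taxa missing from coral-dweller lookup: %s",
                       paste(unmatched, collapse = ", ")),
               class = "reefsucc_unmatched_taxon")
    }
    rlang::warn(sprintf("%d unmatched taxa defaulted to NCD: %s",
                        length(unmatched), paste(unmatched, collapse = ", ")))
    flag[is.na(flag)] <- FALSE
  }
  dplyr::mutate(abundance, cd_flag = flag)
}

#' Fish assemblage matrix for multivariate analysis
#'
#' Site-year by taxon matrix of standardised abundances, in the same wide
#' layout as [coral_abundance_matrix()], ready for [bray_curtis()],
#' [permanova()] and [dbrda_forward_select()].
#'
#' @param abundance Long tibble from [standardize_abundance()].
#' @return Wide tibble with `unit`, `site`, `year` then one column per taxon.
#' @export
fish_matrix <- function(abundance) {
  check_columns(abundance, c("site", "year", "taxon", "abundance_60m2"),
                "fish abundance")
  wide <- abundance |>
    dplyr::group_by(.data$site, .data$year, .data$taxon) |>
    dplyr::summarise(abundance_60m2 = sum(.data$abundance_60m2),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "taxon", values_from = "abundance_60m2",
                       values_fill = 0)
  dplyr::bind_cols(
    tibble::tibble(unit = paste(wide$site, wide$year, sep = ":")), wide
  )
}
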