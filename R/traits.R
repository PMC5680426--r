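#' Read a species-trait CSV
#'
#' Expects the compilation format used throughout the package: columns
#' `species, study, lc50_mg_l, duration_h, phylum, class, group` (header
#' required, UTF-8).  `group` is a coarse ecological label (e.g.
#' `macroinvertebrate`) used to define pruned subanalyses.
#'
#' @param path Path to the CSV file.
#' @return A tibble of raw trait records.
#' @export
read_trait_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("Trait CSV not found: %s", path))
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_trait_records(tbl)
}

validate_trait_records <- function(records) {
  records <- tibble::as_tibble(records)
  needed <- c("species", "study", "lc50_mg_l", "duration_h")
  miss <- setdiff(needed, names(records))
  if (length(miss)) {
    abort(sprintf("Trait table is missing columns: %s.", paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(records$lc50_mg_l)) || any(records$lc50_mg_l <= 0)) {
    abort("All LC50 values must be finite and > 0 (mg/L).")
  }
  records
}

#' Aggregate trait records to one LC50 per species
#'
#' Applies the two-stage averaging rule used for literature compilations:
#' multiple estimates for a species *within* one study are first averaged to a
#' study-level mean, then the study-level means are averaged to a single
#' species value.  A species with one record keeps that value.
#'
#' @param records Tibble of raw trait records (see [read_trait_csv()]).
#' @return A tibble with one row per species: `species`, `lc50` (mg/L),
#'   `n_records`, `n_studies`, and the first observed taxonomic labels among
#'   `phylum`, `class`, `group` when those columns are present.
#' @examples
#' recs <- tibble::tibble(
#'   species = "Daphnia pulex", study = c("s1", "s1", "s2"),
#'   lc50_mg_l = c(1000, 2000, 3000), duration_h = 48
#' )
#' aggregate_species(recs) # study means 1500 and 3000 -> 2250
#' @export
aggregate_species <- function(records) {
  records <- validate_trait_records(records)
  taxa_cols <- intersect(c("phylum", "class", "group"), names(records))
  study_means <- records |>
    dplyr::group_by(.data$species, .data$study) |>
    dplyr::summarise(
      study_mean = mean(.data$lc50_mg_l),
      n_records = dplyr::n(),
      .groups = "drop"
    )
  out <- study_means |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      lc50 = mean(.data$study_mean),
      n_records = sum(.data$n_records),
      n_studies = dplyr::n(),
      .groups = "drop"
    )
  if (length(taxa_cols)) {
    taxa <- records |>
      dplyr::distinct(.data$species, dplyr::pick(dplyr::all_of(taxa_cols)))
    taxa <- taxa[!duplicated(taxa$species), , drop = FALSE]
    out <- dplyr::left_join(out, taxa, by = "species")
  }
  out
}

#' One-way F test of LC50 on exposure duration
#'
#' Ordinary least-squares one-way test of whether mean LC50 differs among
#' exposure-duration categories (24/48/72/96 h as present in the data).  A
#' non-significant result is the usual justification for pooling durations
#' before per-species aggregation.
#'
#' @param records Tibble of raw trait records.
#' @param trait_scale `"raw"` (mg/L) or `"log10"`.
#' @return A one-row tibble: `statistic` (F), `df1`, `df2`, `p_value`,
#'   `n_groups`, `n_obs`.  Degrees of freedom are whatever the data imply.
#' @export
duration_effect_test <- function(records, trait_scale = c("raw", "log10")) {
  records <- validate_trait_records(records)
  trait_scale <- match.arg(trait_scale)
  y <- if (trait_scale == "log10") log10(records$lc50_mg_l) else records$lc50_mg_l
  grp <- factor(records$duration_h)
  if (nlevels(grp) < 2) abort("Need at least 2 duration groups for the F test.")
  if (length(y) <= nlevels(grp)) abort("Too few observations for the F test.")
  fit <- lm(y ~ grp)
  a <- anova(fit)
  tibble::tibble(
    statistic = a[["F value"]][1],
    df1 = a[["Df"]][1],
    df2 = a[["Df"]][2],
    p_value = a[["Pr(>F)"]][1],
    n_groups = nlevels(grp),
    n_obs = length(y)
  )
}
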