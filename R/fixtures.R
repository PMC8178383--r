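#' Packaged reference tables
#'
#' Transcriptions of the summary tables of the published durum wheat
#' meta-QTL study these methods re-implement (see the package vignette).
#' All are plain TSV under `inst/extdata`.
#'
#' * `trait_dictionary()` — 36 trait codes with categories
#'   (quality / abiotic / biotic).
#' * `reference_mqtl()` — the 85-MQTL catalogue: peak, member count,
#'   traits, 95% CI bounds and flanking markers with bp; a derived
#'   `ci_width` column is added.
#' * `reference_selected_mqtl()` — the 10 promising MQTL with CI width,
#'   flanking-marker distance (Mb) and mean PVE.
#' * `reference_gene_counts()` — TE-excluded gene-model counts per selected
#'   MQTL for the durum and bread wheat annotations.
#' * `reference_populations()` — the mapping populations behind the QTL
#'   database, one row per (cross, trait), with population type and size.
#'
#' @return A tibble.
#' @name reference_tables
NULL

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "metaqtl")
  if (p == "") abort(paste0("packaged file not found: ", file))
  p
}

#' @rdname reference_tables
#' @export
trait_dictionary <- function() {
  readr::read_tsv(extdata_path("trait_dictionary.tsv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname reference_tables
#' @export
reference_mqtl <- function() {
  readr::read_tsv(extdata_path("mqtl_catalogue.tsv"),
                  show_col_types = FALSE, progress = FALSE) |>
    mutate(ci_width = round(.data$ci_right - .data$ci_left, 6),
           span_bp = abs(.data$right_bp - .data$left_bp))
}

#' @rdname reference_tables
#' @export
reference_selected_mqtl <- function() {
  readr::read_tsv(extdata_path("selected_mqtl.tsv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname reference_tables
#' @export
reference_gene_counts <- function() {
  readr::read_tsv(extdata_path("mqtl_gene_counts.tsv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname reference_tables
#' @export
reference_populations <- function() {
  readr::read_tsv(extdata_path("study_populations.tsv"),
                  show_col_types = FALSE, progress = FALSE)
}
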