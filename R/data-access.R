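# Accessors for the small plain-text reference tables shipped with the
# package: the published healthy-gut baseline species list and the cohort
# participant statistics.

#' Baseline healthy-gut species list
#'
#' The packaged transcription of the published 109-species healthy human
#' gut baseline (GutFeelingKB species level): scientific name, a coarse
#' phylum/group tag, the `(presence;abundance)` cohort cell, and the
#' comma-joined GenBank accessions. Presence is the percentage of cohort
#' samples the organism was observed in; abundance is its average percent
#' relative abundance where present.
#'
#' @param parse Parse the `(p;a)` cells into numeric columns
#'   (default TRUE).
#' @return Tibble with `scientific_name`, `group`, `genbank_accessions`
#'   and (when `parse = TRUE`) `presence_percent`,
#'   `mean_abundance_percent`.
#' @export
baseline_species <- function(parse = TRUE) {
  path <- system.file("extdata", "gutfeelingkb_species.tsv",
                      package = "gutbaseline", mustWork = TRUE)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (parse) {
    tbl <- dplyr::bind_cols(tbl, parse_presence_cell(tbl$presence_abundance))
    tbl$presence_abundance <- NULL
  }
  tbl
}

#' Baseline species list as a knowledgebase
#'
#' Wraps [baseline_species()] into a `kb_table` so knowledgebase
#' operations (versioned additions, serialization, expansion) can be
#' exercised against the published baseline.
#'
#' @return A `kb_table` with one record per baseline species.
#' @export
baseline_kb <- function() {
  sp <- baseline_species()
  records <- purrr::pmap_dfr(sp, function(scientific_name, group,
                                          genbank_accessions,
                                          presence_percent,
                                          mean_abundance_percent) {
    organism_record(
      scientific_name = scientific_name,
      genbank_accessions = strsplit(genbank_accessions, ",")[[1]],
      lineage = c(group = group),
      presence_percent = presence_percent,
      mean_abundance_percent = mean_abundance_percent
    )
  })
  new_kb(records)
}

#' Cohort participant statistics
#'
#' The packaged participant-count table for the two healthy cohorts
#' (HMP and GW): samples per ethnicity and per gender. Each cohort's
#' ethnicity counts and gender counts both sum to its sample total.
#'
#' @return Tibble with a `cohort` column and count columns.
#' @export
participant_counts <- function() {
  path <- system.file("extdata", "cohort_participants.tsv",
                      package = "gutbaseline", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
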