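# broom-style tidiers for the package's result objects.

#' Tidy a census hitlist
#'
#' @param x A `census_hitlist`.
#' @param ... Unused.
#' @return Plain tibble of per-organism census rows.
#' @export
tidy.census_hitlist <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a census run
#'
#' @param x A `census_hitlist`.
#' @param ... Unused.
#' @return Tibble with `n_organisms`, `total_sampled`, `aligned`,
#'   `unaligned`, `aligned_fraction`.
#' @export
glance.census_hitlist <- function(x, ...) {
  total <- attr(x, "total_sampled")
  unaligned <- attr(x, "unaligned_count")
  tibble::tibble(
    n_organisms = nrow(x),
    total_sampled = total,
    aligned = total - unaligned,
    unaligned = unaligned,
    aligned_fraction = if (total > 0) (total - unaligned) / total else NA_real_
  )
}

#' Tidy a curation report
#'
#' @param x A `curation_report`.
#' @param ... Unused.
#' @return Long tibble of all organisms with `status`
#'   (`accepted`/`rejected`) and `reason` (`NA` for accepted).
#' @export
tidy.curation_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$accepted, status = "accepted", reason = NA_character_),
    dplyr::mutate(x$rejected, status = "rejected")
  )
}

#' Tidy a correlation matrix into long form
#'
#' @param x A `correlation_matrix`.
#' @param ... Unused.
#' @return Tibble `organism_id`, `feature`, `correlation`.
#' @export
tidy.correlation_matrix <- function(x, ...) {
  tibble::as_tibble(x) %>%
    tidyr::pivot_longer(-"organism_id", names_to = "feature",
                        values_to = "correlation")
}

#' One-row summary of a correlation matrix
#'
#' @param x A `correlation_matrix`.
#' @param ... Unused.
#' @return Tibble with dimensions, the evidence threshold, and the number
#'   of entries at or above it in absolute value.
#' @export
glance.correlation_matrix <- function(x, ...) {
  long <- tidy.correlation_matrix(x)
  thr <- attr(x, "threshold")
  tibble::tibble(
    n_organisms = dplyr::n_distinct(long$organism_id),
    n_features = dplyr::n_distinct(long$feature),
    threshold = thr,
    n_hits = sum(abs(long$correlation) >= thr),
    normalized = attr(x, "normalized")
  )
}

#' Tidy an abundance profile
#'
#' @param x An `abundance_profile`.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `organism_id`, `abundance`.
#' @export
tidy.abundance_profile <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x),
                sample_id = attr(x, "sample_id") %||% NA_character_,
                .before = 1)
}

#' One-row summary of a knowledgebase
#'
#' @param x A `kb_table`.
#' @param ... Unused.
#' @return Tibble with `version`, `n_organisms`, `n_with_proteome`.
#' @export
glance.kb_table <- function(x, ...) {
  tibble::tibble(
    version = x$version,
    n_organisms = nrow(x$records),
    n_with_proteome = sum(!is.na(x$records$proteome_id) &
                            nzchar(x$records$proteome_id))
  )
}
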