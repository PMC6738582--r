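# Relative-abundance profiles, sample-by-organism matrices, taxonomy rank
# roll-ups, and cohort summary statistics with zero-exclusion.

#' Relative abundance profile of one sample
#'
#' Organism percentages are computed over *aligned* reads and sum to 100;
#' the unaligned fraction of all reads is carried alongside, never mixed
#' into the 100%.
#'
#' @param assignments Per-read assignment tibble (`read_id`,
#'   `organism_id`) covering every read, with unmapped reads as
#'   `"UNALIGNED"`.
#' @param total_reads Total read count; defaults to `nrow(assignments)`.
#' @param sample_id Sample identifier.
#' @return An `abundance_profile` tibble (`organism_id`, `abundance` in
#'   percent) with attributes `sample_id` and `unaligned_fraction`.
#' @export
profile_sample <- function(assignments, total_reads = nrow(assignments),
                           sample_id = "sample") {
  assignments <- tibble::as_tibble(assignments)
  unaligned <- sum(assignments$organism_id == UNALIGNED)
  aligned <- assignments %>% dplyr::filter(.data$organism_id != UNALIGNED)
  n_aligned <- nrow(aligned)
  out <- if (n_aligned == 0) {
    tibble::tibble(organism_id = character(0), abundance = numeric(0))
  } else {
    aligned %>%
      dplyr::count(.data$organism_id) %>%
      dplyr::mutate(abundance = .data$n / n_aligned * 100) %>%
      dplyr::select("organism_id", "abundance") %>%
      dplyr::arrange(dplyr::desc(.data$abundance), .data$organism_id)
  }
  structure(out, sample_id = sample_id,
            unaligned_fraction = if (total_reads > 0)
              unaligned / total_reads * 100 else 0,
            class = c("abundance_profile", class(out)))
}

#' Assemble per-sample profiles into an abundance matrix
#'
#' @param profiles Named list of `abundance_profile` objects (names are
#'   sample ids; unnamed lists fall back to each profile's own id).
#' @param organisms Optional tibble (`organism_id`, `taxid`) used later
#'   for taxonomy roll-ups.
#' @param rank Taxonomic rank label of the columns (default `"species"`).
#' @return An `abundance_matrix` tibble: `sample_id` column plus one
#'   percentage column per organism; rows sum to 100 over organisms.
#' @export
abundance_matrix <- function(profiles, organisms = NULL, rank = "species") {
  ids <- names(profiles)
  if (is.null(ids)) {
    ids <- vapply(profiles, function(p) attr(p, "sample_id"), "")
  }
  long <- purrr::map2_dfr(profiles, ids, function(p, id) {
    dplyr::mutate(tibble::as_tibble(p), sample_id = id)
  })
  wide <- long %>%
    tidyr::pivot_wider(id_cols = "sample_id", names_from = "organism_id",
                       values_from = "abundance", values_fill = 0)
  structure(wide, rank = rank, organisms = organisms,
            class = c("abundance_matrix", class(wide)))
}

abundance_values <- function(matrix) {
  as.matrix(matrix[, setdiff(names(matrix), "sample_id"), drop = FALSE])
}

#' Roll an abundance matrix up to a higher taxonomic rank
#'
#' Column taxa are replaced by their ancestor at `target_rank` (looked up
#' in `tree` via each column's taxid) and descendant columns are summed.
#' Columns whose lineage has no node at the target rank are grouped under
#' `"unranked"`. Row sums are preserved exactly.
#'
#' @param matrix An `abundance_matrix` whose `organisms` attribute maps
#'   `organism_id` to `taxid`.
#' @param tree A `taxonomy_tree`.
#' @param target_rank Rank label, e.g. `"genus"`, `"family"`, `"phylum"`.
#' @return An `abundance_matrix` at `target_rank`.
#' @export
rollup <- function(matrix, tree, target_rank) {
  if (!target_rank %in% c(tree$nodes$rank, "unranked")) {
    abort(sprintf("unknown rank label: %s", target_rank))
  }
  if (identical(attr(matrix, "rank"), target_rank)) return(matrix)
  organisms <- attr(matrix, "organisms")
  if (is.null(organisms)) {
    abort("matrix carries no organism->taxid map; cannot roll up")
  }
  cols <- setdiff(names(matrix), "sample_id")
  group_of <- vapply(cols, function(org) {
    taxid <- organisms$taxid[match(org, organisms$organism_id)]
    if (is.na(taxid) || !taxid %in% tree$nodes$taxid) return("unranked")
    lin <- lineage(tree, taxid)
    hit <- lin$name[lin$rank == target_rank]
    if (length(hit) == 0) "unranked" else hit[1]
  }, "")
  vals <- abundance_values(matrix)
  rolled <- t(rowsum(t(vals), group = group_of))
  out <- dplyr::bind_cols(matrix["sample_id"],
                          tibble::as_tibble(rolled))
  # taxid map for the rolled-up columns (e.g. for a further roll-up)
  new_orgs <- tibble::tibble(
    organism_id = colnames(rolled),
    taxid = tree$nodes$taxid[match(colnames(rolled), tree$nodes$name)]
  )
  structure(out, rank = target_rank, organisms = new_orgs,
            class = c("abundance_matrix", class(out)))
}

#' Cohort summary statistics of an abundance matrix
#'
#' Presence is the percentage of samples with nonzero abundance, computed
#' over all samples; mean, sd, min, max and median are computed excluding
#' zero-abundance samples (so they describe the organism where it occurs).
#' `sd` is the sample standard deviation (n-1 denominator). Organisms
#' absent everywhere get `NA` statistics and presence 0.
#'
#' @param matrix An `abundance_matrix`.
#' @return A `cohort_stats` tibble: `organism_id`, `presence_percent`,
#'   `mean`, `sd`, `min`, `max`, `median`, `n_present`.
#' @export
cohort_stats <- function(matrix) {
  vals <- abundance_values(matrix)
  if (nrow(vals) == 0) abort("abundance matrix has no samples")
  out <- purrr::map_dfr(colnames(vals), function(org) {
    x <- vals[, org]
    nz <- x[x > 0]
    tibble::tibble(
      organism_id = org,
      presence_percent = length(nz) / length(x) * 100,
      mean = if (length(nz)) mean(nz) else NA_real_,
      sd = if (length(nz) > 1) stats::sd(nz) else NA_real_,
      min = if (length(nz)) min(nz) else NA_real_,
      max = if (length(nz)) max(nz) else NA_real_,
      median = if (length(nz)) stats::median(nz) else NA_real_,
      n_present = length(nz)
    )
  })
  out <- dplyr::arrange(out, dplyr::desc(.data$mean))
  class(out) <- c("cohort_stats", class(out))
  out
}

#' Write an abundance matrix as TSV
#'
#' Samples in rows, organisms in columns; percentages rounded to 2
#' decimals at serialization only (in-memory values keep full precision).
#'
#' @param matrix An `abundance_matrix`.
#' @param path Output path.
#' @param digits Decimal places at serialization (default 2).
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(matrix, path, digits = 2) {
  out <- dplyr::mutate(tibble::as_tibble(matrix),
                       dplyr::across(dplyr::where(is.numeric),
                                     ~ round(.x, digits)))
  readr::write_tsv(out, path)
  invisible(path)
}
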