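# Iterative subsampling taxonomic census and automated curation rules:
# the match-count floor, lineage verification and the pathogen 1% rule.

#' Census configuration
#'
#' Defaults follow the subsampling design used for taxonomic profiling:
#' 2,500 reads per iteration over up to 5 iterations, a total alignment
#' budget of 12,500 reads.
#'
#' @param reads_per_iteration Reads sampled per iteration (default 2500).
#' @param max_iterations Number of iterations (default 5).
#' @param seed Integer seed; iteration `i` draws with `seed + i - 1`.
#' @return A `census_config` list with the derived `total_budget`.
#' @export
census_config <- function(reads_per_iteration = 2500L, max_iterations = 5L,
                          seed = 1L) {
  if (reads_per_iteration <= 0 || max_iterations <= 0) {
    abort("reads_per_iteration and max_iterations must be positive")
  }
  structure(list(
    reads_per_iteration = as.integer(reads_per_iteration),
    max_iterations = as.integer(max_iterations),
    total_budget = as.integer(reads_per_iteration) * as.integer(max_iterations),
    seed = as.integer(seed)
  ), class = "census_config")
}

#' Randomly subsample reads without replacement
#'
#' Draws exactly `n` distinct reads uniformly at random, reproducibly for
#' a given seed, preserving original record order. When `n` exceeds the
#' number of reads, all reads are returned with a warning.
#'
#' @param reads Read tibble or FASTQ path.
#' @param n Number of reads to draw.
#' @param seed Integer seed.
#' @return Read tibble of `n` rows.
#' @export
subsample_reads <- function(reads, n, seed = 1L) {
  if (n <= 0) abort("subsample size must be positive")
  reads <- as_reads_input(reads)
  if (n >= nrow(reads)) {
    if (n > nrow(reads)) {
      warn(sprintf("requested %d reads but file has %d; taking all",
                   n, nrow(reads)))
    }
    return(reads)
  }
  idx <- with_seed(seed, sample.int(nrow(reads), n))
  reads[sort(idx), ]
}

#' Run a subsampling taxonomic census
#'
#' Each iteration draws `reads_per_iteration` reads (without replacement
#' within the iteration, independently across iterations), maps them with
#' best-match assignment, and accumulates per-organism match counts over
#' all iterations.
#'
#' @param reads Read tibble or FASTQ path.
#' @param db A `reference_db` from [build_index()].
#' @param cfg A [census_config()].
#' @param min_seeds Seed-count floor passed to the aligner.
#' @return A `census_hitlist`: tibble (`organism_id`, `taxid`,
#'   `match_count`, `fraction`) with attributes `total_sampled` and
#'   `unaligned_count`. Fractions are of all sampled reads, so they sum
#'   to at most 1.
#' @export
run_census <- function(reads, db, cfg = census_config(), min_seeds = 2L) {
  reads <- as_reads_input(reads)
  if (nrow(reads) == 0) {
    out <- tibble::tibble(organism_id = character(0), taxid = integer(0),
                          match_count = integer(0), fraction = numeric(0))
    return(structure(out, total_sampled = 0L, unaligned_count = 0L,
                     class = c("census_hitlist", class(out))))
  }
  tallies <- vector("list", cfg$max_iterations)
  total_sampled <- 0L
  for (i in seq_len(cfg$max_iterations)) {
    sub <- suppressWarnings(
      subsample_reads(reads, cfg$reads_per_iteration, seed = cfg$seed + i - 1L))
    total_sampled <- total_sampled + nrow(sub)
    tallies[[i]] <- assign_reads(sub, db, min_seeds = min_seeds)
  }
  assignments <- dplyr::bind_rows(tallies)
  unaligned <- sum(assignments$organism_id == UNALIGNED)
  taxids <- db$organisms %>%
    dplyr::distinct(.data$organism_id, .data$taxid)
  out <- assignments %>%
    dplyr::filter(.data$organism_id != UNALIGNED) %>%
    dplyr::count(.data$organism_id, name = "match_count") %>%
    dplyr::left_join(taxids, by = "organism_id") %>%
    dplyr::mutate(fraction = .data$match_count / total_sampled) %>%
    dplyr::select("organism_id", "taxid", "match_count", "fraction") %>%
    dplyr::arrange(dplyr::desc(.data$match_count), .data$organism_id)
  structure(out, total_sampled = total_sampled,
            unaligned_count = as.integer(unaligned),
            class = c("census_hitlist", class(out)))
}

#' @export
print.census_hitlist <- function(x, ...) {
  cat(sprintf("<census_hitlist> %d organisms; %d reads sampled, %d unaligned\n",
              nrow(x), attr(x, "total_sampled"), attr(x, "unaligned_count")))
  NextMethod()
}

#' Curation criteria for census hits
#'
#' Encodes the organism-acceptance rules applied to a census hitlist:
#' a minimum match count over the whole census (default 5 of the 12,500
#' alignment budget), a resolvable taxonomic lineage, and — for organisms
#' on a user-supplied pathogen watch list — a minimum abundance of 1% of
#' sampled reads.
#'
#' @param min_match_count Minimum summed match count (default 5).
#' @param pathogen_min_abundance Minimum fraction for pathogens
#'   (default 0.01).
#' @param pathogen_list Character vector of organism ids and/or taxids on
#'   the pathogen watch list.
#' @param require_lineage Reject organisms whose taxid does not resolve in
#'   the taxonomy (default TRUE).
#' @return A `curation_criteria` list.
#' @export
curation_criteria <- function(min_match_count = 5L,
                              pathogen_min_abundance = 0.01,
                              pathogen_list = character(0),
                              require_lineage = TRUE) {
  if (pathogen_min_abundance < 0 || pathogen_min_abundance > 1) {
    abort("pathogen_min_abundance must be in [0, 1]")
  }
  structure(list(min_match_count = as.integer(min_match_count),
                 pathogen_min_abundance = pathogen_min_abundance,
                 pathogen_list = as.character(pathogen_list),
                 require_lineage = require_lineage),
            class = "curation_criteria")
}

#' Curate a census hitlist
#'
#' Applies [curation_criteria()] to every organism in the hitlist. An
#' organism is accepted iff its match count reaches the floor, its lineage
#' resolves in `tree` (when required), and — if it is on the pathogen
#' list — its sampled-read fraction reaches the pathogen abundance floor.
#' Every rejection carries a reason: `LOW_COUNT`, `NO_LINEAGE` or
#' `PATHOGEN_BELOW_THRESHOLD`.
#'
#' @param hitlist A `census_hitlist` from [run_census()].
#' @param tree A `taxonomy_tree` (may be `NULL` when
#'   `require_lineage = FALSE`).
#' @param criteria A [curation_criteria()].
#' @return A `curation_report`: list with `accepted` and `rejected`
#'   tibbles (rejected rows carry `reason`).
#' @export
curate <- function(hitlist, tree = NULL, criteria = curation_criteria()) {
  h <- tibble::as_tibble(hitlist)
  low <- h$match_count < criteria$min_match_count
  no_lineage <- if (criteria$require_lineage) {
    if (is.null(tree)) rep(TRUE, nrow(h))
    else !(h$taxid %in% tree$nodes$taxid) | is.na(h$taxid)
  } else rep(FALSE, nrow(h))
  is_pathogen <- h$organism_id %in% criteria$pathogen_list |
    as.character(h$taxid) %in% criteria$pathogen_list
  pathogen_low <- is_pathogen & h$fraction < criteria$pathogen_min_abundance
  reason <- dplyr::case_when(
    low ~ "LOW_COUNT",
    no_lineage ~ "NO_LINEAGE",
    pathogen_low ~ "PATHOGEN_BELOW_THRESHOLD",
    TRUE ~ NA_character_
  )
  structure(list(
    accepted = h[is.na(reason), ],
    rejected = dplyr::mutate(h[!is.na(reason), ],
                             reason = reason[!is.na(reason)])
  ), class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf("<curation_report> %d accepted, %d rejected\n",
              nrow(x$accepted), nrow(x$rejected)))
  if (nrow(x$rejected) > 0) {
    tab <- table(x$rejected$reason)
    cat("  rejections:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = ", "), "\n")
  }
  invisible(x)
}
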