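# The versioned organism knowledgebase (GutFeelingKB-style): organism
# records with accessions, lineage, cohort statistics and annotations;
# TSV serialization; idempotent versioned additions; representative-
# proteome-group (RPG) expansion.

KB_COLUMNS <- c("organism_id", "scientific_name", "taxid", "lineage",
                "genbank_accessions", "refseq_accession", "assembly_id",
                "proteome_id", "rpg_cluster_id", "presence_percent",
                "mean_abundance_percent", "annotations")

#' Parse a presence/abundance cell
#'
#' Cells of the form `"(p;a)"` pair the percentage of cohort samples an
#' organism is present in with its average percent relative abundance.
#'
#' @param text Character vector of cells like `"(100;17.44)"`.
#' @return Tibble with `presence_percent` and `mean_abundance_percent`.
#' @examples
#' parse_presence_cell("(100;17.44)")
#' @export
parse_presence_cell <- function(text) {
  m <- stringr::str_match(stringr::str_trim(text),
                          "^\\(\\s*([0-9.]+)\\s*;\\s*([0-9.]+)\\s*\\)$")
  if (anyNA(m[, 1])) {
    abort(sprintf("malformed presence/abundance cell: %s",
                  text[which(is.na(m[, 1]))[1]]))
  }
  out <- tibble::tibble(presence_percent = as.numeric(m[, 2]),
                        mean_abundance_percent = as.numeric(m[, 3]))
  if (any(out$presence_percent > 100 | out$mean_abundance_percent > 100)) {
    abort("presence and abundance must be percentages in [0, 100]")
  }
  out
}

#' Construct an organism record
#'
#' @param organism_id Unique identifier (defaults to the scientific name).
#' @param scientific_name Organism scientific name.
#' @param taxid NCBI-style taxid (positive integer, `NA` when unknown).
#' @param genbank_accessions Character vector of GenBank accessions (at
#'   least one).
#' @param lineage Named character vector or single `rank=name;...` string.
#' @param refseq_accession,assembly_id,proteome_id,rpg_cluster_id Optional
#'   database cross-references.
#' @param presence_percent,mean_abundance_percent Cohort statistics in
#'   `[0, 100]`.
#' @param annotations Free-text annotation (description, antibiotic
#'   resistance/susceptibility, physical characteristics, citations).
#' @return One-row `organism_record` tibble.
#' @export
organism_record <- function(scientific_name, genbank_accessions,
                            organism_id = scientific_name,
                            taxid = NA_integer_, lineage = "",
                            refseq_accession = NA_character_,
                            assembly_id = NA_character_,
                            proteome_id = NA_character_,
                            rpg_cluster_id = NA_character_,
                            presence_percent = NA_real_,
                            mean_abundance_percent = NA_real_,
                            annotations = "") {
  if (length(genbank_accessions) == 0 || all(!nzchar(genbank_accessions))) {
    abort("an organism record needs at least one GenBank accession")
  }
  if (!is.na(taxid) && taxid <= 0) abort("taxid must be positive when given")
  for (v in c(presence_percent, mean_abundance_percent)) {
    if (!is.na(v) && (v < 0 || v > 100)) {
      abort("presence and abundance must be in [0, 100]")
    }
  }
  if (!is.null(names(lineage))) {
    lineage <- paste(names(lineage), lineage, sep = "=", collapse = ";")
  }
  tibble::tibble(
    organism_id = organism_id,
    scientific_name = scientific_name,
    taxid = as.integer(taxid),
    lineage = lineage,
    genbank_accessions = paste(genbank_accessions, collapse = ","),
    refseq_accession = refseq_accession,
    assembly_id = assembly_id,
    proteome_id = proteome_id,
    rpg_cluster_id = rpg_cluster_id,
    presence_percent = presence_percent,
    mean_abundance_percent = mean_abundance_percent,
    annotations = annotations
  )
}

new_kb <- function(records, version = 1L, provenance = NULL) {
  if (anyDuplicated(records$organism_id)) {
    abort("duplicate organism_id in knowledgebase")
  }
  if (is.null(provenance)) {
    provenance <- tibble::tibble(version = integer(0), action = character(0),
                                 organism_id = character(0),
                                 timestamp = character(0))
  }
  structure(list(records = tibble::as_tibble(records),
                 version = as.integer(version),
                 provenance = provenance),
            class = "kb_table")
}

#' Create an empty knowledgebase
#'
#' @return A `kb_table` at version 1 with no records.
#' @export
empty_kb <- function() {
  records <- tibble::as_tibble(
    stats::setNames(rep(list(character(0)), length(KB_COLUMNS)), KB_COLUMNS))
  records$taxid <- integer(0)
  records$presence_percent <- numeric(0)
  records$mean_abundance_percent <- numeric(0)
  new_kb(records)
}

#' @export
print.kb_table <- function(x, ...) {
  cat(sprintf("<kb_table> version %d, %d organisms\n",
              x$version, nrow(x$records)))
  invisible(x)
}

#' Load a knowledgebase from TSV
#'
#' The serialization is a single TSV, one row per organism, multi-valued
#' cells comma-joined, with the version carried in a `# kb_version=N`
#' comment line.
#'
#' @param path TSV path (or a data frame already in KB layout).
#' @return A `kb_table`.
#' @export
load_kb <- function(path) {
  version <- 1L
  if (is.character(path) && length(path) == 1) {
    first <- readLines(path, n = 1)
    if (grepl("^# kb_version=", first)) {
      version <- as.integer(sub("^# kb_version=", "", first))
    }
    records <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                               progress = FALSE, na = "NA",
                               col_types = readr::cols(
                                 taxid = readr::col_integer(),
                                 presence_percent = readr::col_double(),
                                 mean_abundance_percent = readr::col_double(),
                                 .default = readr::col_character()))
  } else {
    records <- tibble::as_tibble(path)
  }
  missing <- setdiff(KB_COLUMNS, names(records))
  if (length(missing) > 0) {
    abort(sprintf("knowledgebase table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  new_kb(records[, KB_COLUMNS], version = version)
}

#' Save a knowledgebase to TSV
#'
#' @param kb A `kb_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_kb <- function(kb, path) {
  body <- readr::format_tsv(kb$records)
  writeLines(c(sprintf("# kb_version=%d", kb$version),
               strsplit(body, "\n", fixed = TRUE)[[1]]), path)
  invisible(path)
}

#' Add an organism to the knowledgebase
#'
#' Appending a new organism increments the version and logs a provenance
#' entry. Re-adding an identical record is a no-op (version unchanged);
#' re-adding the same `organism_id` with different fields is an error.
#'
#' @param kb A `kb_table`.
#' @param record A one-row [organism_record()].
#' @return The updated `kb_table`.
#' @export
add_organism <- function(kb, record) {
  record <- tibble::as_tibble(record)[, KB_COLUMNS]
  existing <- kb$records[kb$records$organism_id == record$organism_id, ]
  if (nrow(existing) > 0) {
    if (isTRUE(all.equal(as.data.frame(existing), as.data.frame(record),
                         check.attributes = FALSE))) {
      return(kb)
    }
    abort(sprintf("organism %s already present with conflicting fields",
                  record$organism_id))
  }
  version <- kb$version + 1L
  provenance <- dplyr::bind_rows(kb$provenance, tibble::tibble(
    version = version, action = "add", organism_id = record$organism_id,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  new_kb(dplyr::bind_rows(kb$records, record), version = version,
         provenance = provenance)
}

#' Expand a knowledgebase through representative proteome groups
#'
#' Every RPG cluster containing a knowledgebase proteome contributes all
#' of its member proteomes; members without any cluster contribute only
#' themselves. The result is deduplicated and is always a superset of the
#' knowledgebase's mapped proteomes.
#'
#' @param kb A `kb_table` whose records may carry `proteome_id`.
#' @param clusters Tibble (or TSV path) with columns `cluster_id`,
#'   `proteome_id` and optionally `is_representative`.
#' @return Tibble of expanded entries: `proteome_id`, `cluster_id` (`NA`
#'   for unclustered knowledgebase members).
#' @export
expand_rpg <- function(kb, clusters) {
  clusters <- as_table_input(clusters)
  if (anyDuplicated(clusters[, c("cluster_id", "proteome_id")])) {
    clusters <- dplyr::distinct(clusters, .data$cluster_id, .data$proteome_id,
                                .keep_all = TRUE)
  }
  if (anyDuplicated(clusters$proteome_id)) {
    abort("a proteome belongs to more than one cluster")
  }
  kb_prot <- kb$records$proteome_id
  kb_prot <- kb_prot[!is.na(kb_prot) & nzchar(kb_prot)]
  hit_clusters <- unique(
    clusters$cluster_id[clusters$proteome_id %in% kb_prot])
  members <- clusters[clusters$cluster_id %in% hit_clusters,
                      c("proteome_id", "cluster_id")]
  unclustered <- setdiff(kb_prot, clusters$proteome_id)
  out <- dplyr::bind_rows(
    tibble::as_tibble(members),
    tibble::tibble(proteome_id = unclustered, cluster_id = NA_character_))
  dplyr::distinct(out, .data$proteome_id, .keep_all = TRUE)
}

#' Rank-level summary of a knowledgebase
#'
#' Counts distinct names at each lineage rank (computed from the records'
#' lineage strings, never hard-coded).
#'
#' @param kb A `kb_table`.
#' @return Tibble `rank`, `n_distinct`.
#' @export
kb_rank_counts <- function(kb) {
  lin <- kb$records$lineage
  lin <- lin[nzchar(lin)]
  pairs <- purrr::map_dfr(lin, function(s) {
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, "=", fixed = TRUE)
    tibble::tibble(rank = vapply(kv, `[[`, "", 1),
                   name = vapply(kv, function(x) x[2], ""))
  })
  if (nrow(pairs) == 0) return(tibble::tibble(rank = character(0),
                                              n_distinct = integer(0)))
  pairs %>%
    dplyr::distinct(.data$rank, .data$name) %>%
    dplyr::count(.data$rank, name = "n_distinct")
}
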