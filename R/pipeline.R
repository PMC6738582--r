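# End-to-end orchestration of the baseline workflow: QC -> census ->
# curation -> knowledgebase update -> full best-match mapping ->
# abundance profiles and roll-ups -> dark-matter contigs -> cohort
# statistics -> optional feature correlation -> per-sample report.
# Stages communicate through files in a structured run directory so any
# stage's outputs can be inspected and reproduced.

#' Pipeline configuration
#'
#' @param reads Named character vector/list of FASTQ paths, one per
#'   sample (names are sample ids).
#' @param reference Reference FASTA path.
#' @param organism_map Organism map TSV path or tibble (`accession`,
#'   `organism_id`, `taxid`).
#' @param taxonomy Optional list with `nodes` and `names` dump paths, or
#'   a `taxonomy_tree`.
#' @param kb Optional knowledgebase TSV path (created when absent).
#' @param features Optional feature-table TSV path or tibble.
#' @param pathogens Optional character vector (or single-column file) of
#'   pathogen organism ids/taxids.
#' @param outdir Output directory for all stage files.
#' @param census A [census_config()].
#' @param thresholds A [qc_thresholds()].
#' @param darkmatter A [darkmatter_config()].
#' @param report_threshold Cumulative-coverage reporting threshold.
#' @param k,min_seeds Aligner parameters.
#' @param assemble_first Assemble *all* reads before the contig length
#'   filter instead of only the unaligned ones (default FALSE; the
#'   post-alignment route preserves dark-matter contigs that partially
#'   overlap known organisms).
#' @param seed Master seed propagated to every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(reads, reference, organism_map, taxonomy = NULL,
                            kb = NULL, features = NULL, pathogens = character(0),
                            outdir = tempfile("gutbaseline_run"),
                            census = census_config(),
                            thresholds = qc_thresholds(),
                            darkmatter = darkmatter_config(),
                            report_threshold = 0.5, k = 15L, min_seeds = 2L,
                            assemble_first = FALSE, seed = 1L) {
  if (is.null(names(reads)) || any(!nzchar(names(reads)))) {
    names(reads) <- paste0("sample", seq_along(reads))
  }
  for (f in unlist(reads)) {
    if (!file.exists(f)) abort(sprintf("reads file not found: %s", f))
  }
  if (is.character(reference) && !file.exists(reference)) {
    abort(sprintf("reference file not found: %s", reference))
  }
  structure(list(reads = reads, reference = reference,
                 organism_map = organism_map, taxonomy = taxonomy, kb = kb,
                 features = features, pathogens = pathogens, outdir = outdir,
                 census = census, thresholds = thresholds,
                 darkmatter = darkmatter,
                 report_threshold = report_threshold,
                 k = as.integer(k), min_seeds = as.integer(min_seeds),
                 assemble_first = assemble_first, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_log <- function(manifest, stage, sample, status, detail = "") {
  message(sprintf("[%s] %s %s %s", stage, sample, status, detail))
  dplyr::bind_rows(manifest, tibble::tibble(
    stage = stage, sample = sample, status = status, detail = detail))
}

#' Run the full baseline workflow
#'
#' Executes every stage for every sample, writing per-stage files under
#' `cfg$outdir` (QC JSON, census hitlist and curation report, versioned
#' knowledgebase TSV, per-sample assignments, abundance matrix and
#' roll-ups, tagged dark-matter FASTA, cohort statistics, correlation
#' matrix when features are given, and a report JSON per sample) and
#' returning a manifest of stage outcomes. All outputs are pure functions
#' of (inputs, config, seed).
#'
#' @param cfg A [pipeline_config()].
#' @return Manifest tibble (`stage`, `sample`, `status`, `detail`),
#'   invisibly-attached `outdir` attribute.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- tibble::tibble(stage = character(0), sample = character(0),
                             status = character(0), detail = character(0))
  tree <- if (inherits(cfg$taxonomy, "taxonomy_tree")) cfg$taxonomy
          else if (!is.null(cfg$taxonomy)) {
            parse_taxdump(cfg$taxonomy$nodes, cfg$taxonomy$names)
          }
  db <- build_index(cfg$reference, cfg$organism_map, k = cfg$k)
  kb <- if (!is.null(cfg$kb) && file.exists(cfg$kb)) load_kb(cfg$kb)
        else empty_kb()
  criteria <- curation_criteria(pathogen_list = cfg$pathogens,
                                require_lineage = !is.null(tree))
  profiles <- list()
  for (sample in names(cfg$reads)) {
    reads <- read_fastq(cfg$reads[[sample]])
    stats <- read_stats(reads)
    write_qc_json(stats, file.path(cfg$outdir, paste0(sample, "_qc.json")))
    flags <- flag_file(stats, cfg$thresholds)
    kept <- filter_reads(reads, cfg$thresholds)
    manifest <- stage_log(manifest, "qc", sample, "ok",
                          sprintf("reads=%d kept=%d pass=%s", nrow(reads),
                                  nrow(kept$kept), flags$pass))
    reads <- kept$kept

    census_cfg <- cfg$census
    census_cfg$seed <- cfg$seed + match(sample, names(cfg$reads)) * 100L
    hits <- run_census(reads, db, census_cfg, min_seeds = cfg$min_seeds)
    readr::write_tsv(tibble::as_tibble(hits),
                     file.path(cfg$outdir, paste0(sample, "_census.tsv")))
    report <- curate(hits, tree, criteria)
    readr::write_tsv(tidy.curation_report(report),
                     file.path(cfg$outdir, paste0(sample, "_curation.tsv")))
    manifest <- stage_log(manifest, "census", sample, "ok",
                          sprintf("organisms=%d accepted=%d", nrow(hits),
                                  nrow(report$accepted)))

    for (i in seq_len(nrow(report$accepted))) {
      org <- report$accepted[i, ]
      if (!org$organism_id %in% kb$records$organism_id) {
        accs <- db$organisms$accession[
          db$organisms$organism_id == org$organism_id]
        kb <- add_organism(kb, organism_record(
          scientific_name = org$organism_id, genbank_accessions = accs,
          organism_id = org$organism_id, taxid = org$taxid))
      }
    }
    manifest <- stage_log(manifest, "kb", sample, "ok",
                          sprintf("version=%d organisms=%d", kb$version,
                                  nrow(kb$records)))

    assignments <- assign_reads(reads, db, min_seeds = cfg$min_seeds)
    readr::write_tsv(assignments,
                     file.path(cfg$outdir, paste0(sample, "_assignments.tsv")))
    profile <- profile_sample(assignments, sample_id = sample)
    profiles[[sample]] <- profile
    manifest <- stage_log(manifest, "profile", sample, "ok",
                          sprintf("organisms=%d unaligned=%.1f%%",
                                  nrow(profile),
                                  attr(profile, "unaligned_fraction")))

    unaligned <- collect_unaligned(reads, assignments)
    assembly_input <- if (isTRUE(cfg$assemble_first)) reads else unaligned
    contigs <- assemble_greedy(assembly_input, min_overlap = 30L)
    tagged <- filter_and_tag(contigs, cfg$darkmatter, sample_id = sample)
    if (nrow(tagged) > 0) {
      write_tagged_fasta(tagged, file.path(cfg$outdir,
                                           paste0(sample, "_darkmatter.fasta")))
    }
    manifest <- stage_log(manifest, "darkmatter", sample, "ok",
                          sprintf("unaligned=%d contigs=%d retained=%d",
                                  nrow(unaligned), nrow(contigs),
                                  nrow(tagged)))
  }

  organisms <- dplyr::distinct(db$organisms, .data$organism_id, .data$taxid)
  mat <- abundance_matrix(profiles, organisms = organisms, rank = "species")
  write_abundance_tsv(mat, file.path(cfg$outdir, "abundance_species.tsv"))
  if (!is.null(tree)) {
    for (rank in intersect(c("genus", "family", "phylum"),
                           unique(tree$nodes$rank))) {
      write_abundance_tsv(rollup(mat, tree, rank),
                          file.path(cfg$outdir,
                                    sprintf("abundance_%s.tsv", rank)))
    }
  }
  stats_tbl <- cohort_stats(mat)
  readr::write_tsv(stats_tbl, file.path(cfg$outdir, "cohort_stats.tsv"))
  manifest <- stage_log(manifest, "cohort", "all", "ok",
                        sprintf("samples=%d organisms=%d", nrow(mat),
                                nrow(stats_tbl)))

  if (!is.null(cfg$features)) {
    feats <- encode_categorical(as_table_input(cfg$features))
    corr <- cosine_correlation(standardize(mat), standardize(feats))
    readr::write_tsv(tibble::as_tibble(corr),
                     file.path(cfg$outdir, "correlation.tsv"))
    jsonlite::write_json(correlation_hits(corr),
                         file.path(cfg$outdir, "correlation_hits.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- stage_log(manifest, "correlate", "all", "ok",
                          sprintf("hits=%d", nrow(correlation_hits(corr))))
  }

  ranges <- reference_ranges(stats_tbl)
  for (sample in names(profiles)) {
    rep_doc <- render_report(profiles[[sample]], kb = kb, ranges = ranges,
                             threshold = cfg$report_threshold)
    write_report_json(rep_doc,
                      file.path(cfg$outdir, paste0(sample, "_report.json")))
  }
  manifest <- stage_log(manifest, "report", "all", "ok",
                        sprintf("reports=%d", length(profiles)))

  save_kb(kb, file.path(cfg$outdir, "kb.tsv"))
  readr::write_tsv(manifest, file.path(cfg$outdir, "manifest.tsv"))
  attr(manifest, "outdir") <- cfg$outdir
  manifest
}
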