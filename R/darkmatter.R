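# Metagenomic dark matter: unaligned-read collection, contig length
# filtering with header tagging, and the genome-coverage-fraction
# rationale behind the 10 kb contig threshold.

#' Dark-matter configuration
#'
#' @param min_contig_length Minimum retained contig length in nucleotides,
#'   inclusive (default 10,000).
#' @param coding_density Average protein-coding fraction of a bacterial
#'   genome, used by [coverage_fraction()] (default 0.87).
#' @return A `darkmatter_config` list.
#' @export
darkmatter_config <- function(min_contig_length = 10000L,
                              coding_density = 0.87) {
  if (min_contig_length <= 0) abort("min_contig_length must be positive")
  if (coding_density <= 0 || coding_density > 1) {
    abort("coding_density must be in (0, 1]")
  }
  structure(list(min_contig_length = as.integer(min_contig_length),
                 coding_density = coding_density),
            class = "darkmatter_config")
}

#' Collect the unaligned reads of a sample
#'
#' Returns exactly the reads assigned `"UNALIGNED"`, preserving original
#' record order and content; these are the assembler's input for
#' dark-matter contig construction.
#'
#' @param reads Read tibble or FASTQ path.
#' @param assignments Per-read assignment tibble covering all reads.
#' @return Read tibble of unaligned reads.
#' @export
collect_unaligned <- function(reads, assignments) {
  reads <- as_reads_input(reads)
  missing <- setdiff(assignments$read_id, reads$read_id)
  if (length(missing) > 0) {
    abort(sprintf("assignment refers to read absent from file: %s",
                  missing[1]))
  }
  unaligned_ids <- assignments$read_id[assignments$organism_id == UNALIGNED]
  reads[reads$read_id %in% unaligned_ids, ]
}

#' Filter contigs at the length threshold and tag their headers
#'
#' Retains contigs at or above the length threshold, sorts them long to
#' short, and rewrites each header as
#' `sampleID|rank|length|gender|age|ethnicity` (rank 1 = longest; missing
#' metadata fields become `"NA"`).
#'
#' @param contigs FASTA path, `DNAStringSet`, or tibble (`contig_id`,
#'   `sequence`).
#' @param cfg A [darkmatter_config()].
#' @param sample_id Sample identifier for the header.
#' @param sample_meta Named list/vector with `gender`, `age`, `ethnicity`.
#' @return Tibble of tagged contigs: `header`, `rank_by_length`, `length`,
#'   `sequence`.
#' @export
filter_and_tag <- function(contigs, cfg = darkmatter_config(),
                           sample_id = "sample", sample_meta = list()) {
  if (is.data.frame(contigs)) {
    tbl <- tibble::as_tibble(contigs)
  } else {
    seqs <- as_fasta_input(contigs)
    tbl <- tibble::tibble(contig_id = names(seqs),
                          sequence = as.character(seqs))
  }
  meta <- function(field) {
    v <- sample_meta[[field]]
    if (is.null(v) || is.na(v) || !nzchar(as.character(v))) "NA"
    else as.character(v)
  }
  out <- tbl %>%
    dplyr::mutate(length = nchar(.data$sequence)) %>%
    dplyr::filter(.data$length >= cfg$min_contig_length) %>%
    dplyr::arrange(dplyr::desc(.data$length)) %>%
    dplyr::mutate(
      rank_by_length = dplyr::row_number(),
      header = sprintf("%s|%d|%d|%s|%s|%s", sample_id, .data$rank_by_length,
                       .data$length, meta("gender"), meta("age"),
                       meta("ethnicity"))
    ) %>%
    dplyr::select("header", "rank_by_length", "length", "sequence")
  out
}

#' Write tagged contigs as FASTA
#'
#' @param tagged Tibble from [filter_and_tag()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tagged_fasta <- function(tagged, path) {
  seqs <- Biostrings::DNAStringSet(tagged$sequence)
  names(seqs) <- tagged$header
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Genome and coding-region coverage of a single contig
#'
#' Rationale for the contig length threshold: a retained contig of
#' `contig_len` nucleotides covers at least
#' `100 * contig_len / genome_len` percent of a genome of `genome_len`
#' nucleotides, and `100 * contig_len / (genome_len * coding_density)`
#' percent of its protein-coding region.
#'
#' @param contig_len Contig length (nt), at most `genome_len`.
#' @param genome_len Genome length (nt).
#' @param coding_density Protein-coding fraction of the genome
#'   (default 0.87).
#' @return Tibble with `genome_percent` and `coding_percent` (full
#'   precision; round at presentation).
#' @export
coverage_fraction <- function(contig_len, genome_len, coding_density = 0.87) {
  if (any(contig_len <= 0) || any(genome_len <= 0) || coding_density <= 0) {
    abort("lengths and coding density must be positive")
  }
  if (any(contig_len > genome_len)) {
    abort("contig length exceeds genome length")
  }
  tibble::tibble(
    genome_percent = 100 * contig_len / genome_len,
    coding_percent = 100 * contig_len / (genome_len * coding_density)
  )
}

#' Naive greedy exact-overlap joiner (test assembler)
#'
#' A deliberately simple stand-in satisfying the assembler contract
#' (reads in, contigs out) for tests and demos: repeatedly merges the
#' pair of sequences with the longest exact suffix-prefix overlap at or
#' above `min_overlap`. Quadratic; suitable only for toy inputs.
#'
#' @param reads Read tibble or character vector of sequences.
#' @param min_overlap Minimum exact overlap to merge (default 20).
#' @return Tibble (`contig_id`, `sequence`).
#' @export
assemble_greedy <- function(reads, min_overlap = 20L) {
  seqs <- if (is.data.frame(reads)) reads$sequence else as.character(reads)
  seqs <- unique(seqs)
  overlap_len <- function(a, b) {
    max_try <- min(nchar(a), nchar(b))
    for (len in rev(seq_len(max_try))) {
      if (len < min_overlap) return(0L)
      if (substring(a, nchar(a) - len + 1, nchar(a)) ==
          substring(b, 1, len)) return(len)
    }
    0L
  }
  repeat {
    n <- length(seqs)
    if (n < 2) break
    best <- c(0L, 0L, 0L)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      ov <- overlap_len(seqs[i], seqs[j])
      if (ov > best[3]) best <- c(i, j, ov)
    }
    if (best[3] < min_overlap) break
    merged <- paste0(seqs[best[1]],
                     substring(seqs[best[2]], best[3] + 1))
    seqs <- c(seqs[-c(best[1], best[2])], merged)
  }
  tibble::tibble(contig_id = paste0("contig", seq_along(seqs)),
                 sequence = seqs)
}

#' Pass-through assembler
#'
#' Satisfies the assembler contract when contigs have already been built
#' externally: input sequences are returned unchanged as contigs.
#'
#' @param reads Read tibble or character vector of sequences.
#' @return Tibble (`contig_id`, `sequence`).
#' @export
assemble_passthrough <- function(reads) {
  seqs <- if (is.data.frame(reads)) reads$sequence else as.character(reads)
  ids <- if (is.data.frame(reads) && "read_id" %in% names(reads)) {
    reads$read_id
  } else if (is.data.frame(reads) && "contig_id" %in% names(reads)) {
    reads$contig_id
  } else {
    paste0("contig", seq_along(seqs))
  }
  tibble::tibble(contig_id = ids, sequence = seqs)
}
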