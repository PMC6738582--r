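# Read-to-organism mapping: a pluggable aligner contract with a built-in
# k-mer seed-count aligner and deterministic best-match assignment.
#
# The built-in aligner indexes every k-mer of every reference sequence on
# both strands. A read's score against an organism is the total number of
# (read k-mer, reference posting) matches summed over the organism's
# accessions — so multi-replicon genomes are not penalized, and the score
# is invariant to read orientation.

UNALIGNED <- "UNALIGNED"

#' Build a k-mer index over a reference database
#'
#' @param reference FASTA path or `DNAStringSet` of reference sequences.
#' @param organism_map Table (or TSV path) with columns `accession`,
#'   `organism_id`, `taxid` assigning every reference accession to an
#'   organism.
#' @param k Seed length, between 4 and 31 (default 15).
#' @return A `reference_db`: list with `organisms` (tibble), `sequences`
#'   (`DNAStringSet`), `postings` (tibble `kmer`, `accession`, `offset`,
#'   `strand`), `counts` (tibble `kmer`, `organism_id`, `n`) and `k`.
#' @export
build_index <- function(reference, organism_map, k = 15L) {
  if (k < 4 || k > 31) abort("k must be between 4 and 31")
  seqs <- as_fasta_input(reference)
  names(seqs) <- first_token(names(seqs))
  map <- as_table_input(organism_map)
  missing <- setdiff(names(seqs), map$accession)
  if (length(missing) > 0) {
    abort(sprintf("accession absent from organism map: %s", missing[1]))
  }
  postings <- purrr::map_dfr(seq_along(seqs), function(i) {
    s <- as.character(seqs[[i]])
    if (nchar(s) < k) return(NULL)
    fwd <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    rev <- substring(rc, 1:(nchar(rc) - k + 1), k:nchar(rc))
    tibble::tibble(
      kmer = c(fwd, rev),
      accession = names(seqs)[i],
      offset = c(seq_along(fwd), seq_along(rev)),
      strand = rep(c("+", "-"), c(length(fwd), length(rev)))
    )
  })
  counts <- postings %>%
    dplyr::left_join(map[, c("accession", "organism_id")], by = "accession") %>%
    dplyr::count(.data$kmer, .data$organism_id)
  structure(list(
    organisms = tibble::as_tibble(map),
    sequences = seqs,
    postings = postings,
    counts = counts,
    k = as.integer(k)
  ), class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db> %d organisms, %d accessions, k=%d, %d postings\n",
              length(unique(x$organisms$organism_id)), length(x$sequences),
              x$k, nrow(x$postings)))
  invisible(x)
}

read_kmers <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) return(character(0))
  substring(sequence, 1:(n - k + 1), k:n)
}

#' Align reads against a k-mer reference index
#'
#' Scores every read against every organism as the total count of matching
#' seeds (read k-mers found in the organism's indexed sequences, either
#' strand). Organisms with fewer than `min_seeds` matching seeds are not
#' reported. Reads shorter than `k` are skipped with a warning.
#'
#' @param reads Read tibble (from [read_fastq()]), FASTQ path, or a
#'   character vector of sequences.
#' @param db A `reference_db` from [build_index()].
#' @param min_seeds Minimum seed count for a reported alignment (default 2).
#' @return Tibble of alignments: `read_id`, `organism_id`, `match_score`.
#' @export
align_reads <- function(reads, db, min_seeds = 2L) {
  if (is.character(reads) && (length(reads) > 1 || !file.exists(reads))) {
    reads <- tibble::tibble(
      read_id = if (is.null(names(reads))) paste0("read", seq_along(reads))
                else names(reads),
      sequence = unname(reads))
  } else {
    reads <- as_reads_input(reads)
  }
  short <- nchar(reads$sequence) < db$k
  if (any(short)) {
    warn(sprintf("%d read(s) shorter than k=%d skipped", sum(short), db$k))
    reads <- reads[!short, ]
  }
  if (nrow(reads) == 0) {
    return(tibble::tibble(read_id = character(0), organism_id = character(0),
                          match_score = integer(0)))
  }
  kmer_list <- lapply(reads$sequence, read_kmers, k = db$k)
  query <- tibble::tibble(
    read_id = rep(reads$read_id, lengths(kmer_list)),
    kmer = unlist(kmer_list, use.names = FALSE)
  )
  query %>%
    dplyr::inner_join(db$counts, by = "kmer",
                      relationship = "many-to-many") %>%
    dplyr::group_by(.data$read_id, .data$organism_id) %>%
    dplyr::summarise(match_score = sum(.data$n), .groups = "drop") %>%
    dplyr::filter(.data$match_score >= min_seeds)
}

#' Align a single read
#'
#' @param read A single nucleotide sequence string.
#' @inheritParams align_reads
#' @return Tibble of alignments for the read.
#' @export
align_read <- function(read, db, min_seeds = 2L) {
  align_reads(stats::setNames(read, "read1"), db, min_seeds = min_seeds)
}

#' Best-match assignment of reads to organisms
#'
#' Each read is assigned to the organism with the greatest match score.
#' Ties are broken deterministically by the lexicographically smallest
#' `organism_id`; reads with no reported alignment are assigned
#' `"UNALIGNED"`.
#'
#' @param alignments Alignment tibble from [align_reads()].
#' @param read_ids Optional character vector of all read ids; reads absent
#'   from `alignments` are then included as `UNALIGNED`.
#' @return Tibble `read_id`, `organism_id`.
#' @export
best_match_assign <- function(alignments, read_ids = NULL) {
  assigned <- alignments %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::arrange(dplyr::desc(.data$match_score), .data$organism_id,
                   .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup() %>%
    dplyr::select("read_id", "organism_id")
  if (!is.null(read_ids)) {
    assigned <- tibble::tibble(read_id = read_ids) %>%
      dplyr::left_join(assigned, by = "read_id") %>%
      dplyr::mutate(organism_id = dplyr::coalesce(.data$organism_id, UNALIGNED))
  }
  assigned
}

#' Map reads end-to-end: align then best-match assign
#'
#' @inheritParams align_reads
#' @return Tibble `read_id`, `organism_id` covering every input read
#'   (unmappable reads as `"UNALIGNED"`).
#' @export
assign_reads <- function(reads, db, min_seeds = 2L) {
  reads <- as_reads_input(reads)
  aln <- suppressWarnings(align_reads(reads, db, min_seeds = min_seeds))
  best_match_assign(aln, read_ids = reads$read_id)
}
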