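# FASTQ read quality control: per-file statistics, the mean-Phred read
# filter, and file-level pass/warn flags.

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ path (plain or gzip).
#' @return Tibble with `read_id`, `sequence`, `quality` (Phred string).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble::tibble(
    read_id = first_token(names(x)),
    sequence = unname(as.character(x)),
    quality = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' Write a read tibble back to FASTQ
#'
#' @param reads Tibble as returned by [read_fastq()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- character(4L * nrow(reads))
  lines[seq(1, length(lines), 4)] <- paste0("@", reads$read_id)
  lines[seq(2, length(lines), 4)] <- reads$sequence
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <- reads$quality
  writeLines(lines, path)
  invisible(path)
}

#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom S4Vectors mcols
NULL

as_reads_input <- function(reads) {
  if (is.character(reads) && length(reads) == 1) read_fastq(reads)
  else tibble::as_tibble(reads)
}

# list of integer Phred vectors, one per read (offset 33 by default)
quality_ints <- function(quality, offset = 33L) {
  lapply(quality, function(q) utf8ToInt(q) - offset)
}

validate_reads <- function(reads) {
  mismatch <- which(nchar(reads$sequence) != nchar(reads$quality))
  if (length(mismatch) > 0) {
    abort(sprintf("sequence/quality length mismatch at record %d",
                  mismatch[1]))
  }
  reads
}

#' Per-file read QC statistics
#'
#' Computes the base composition, per-cycle mean Phred quality, read length
#' histogram and per-read mean-quality histogram that underpin file-level
#' quality review of shotgun metagenomic runs.
#'
#' @param reads FASTQ path or a tibble from [read_fastq()].
#' @param phred_offset Quality encoding offset (33 for Phred+33).
#' @return A `qc_stats` list: `base_counts` (named A/C/G/T/N counts),
#'   `per_position_mean_quality`, `length_histogram` tibble,
#'   `mean_read_quality_histogram` tibble (integer-binned), `n_reads`.
#' @export
read_stats <- function(reads, phred_offset = 33L) {
  reads <- validate_reads(as_reads_input(reads))
  bases <- c("A", "C", "G", "T", "N")
  if (nrow(reads) == 0) {
    return(structure(list(
      base_counts = stats::setNames(rep(0, 5), bases),
      per_position_mean_quality = numeric(0),
      length_histogram = tibble::tibble(length = integer(0), n = integer(0)),
      mean_read_quality_histogram = tibble::tibble(mean_quality = integer(0),
                                                   n = integer(0)),
      n_reads = 0L
    ), class = "qc_stats"))
  }
  seq_set <- Biostrings::DNAStringSet(reads$sequence)
  freq <- colSums(Biostrings::letterFrequency(seq_set, letters = bases))
  quals <- quality_ints(reads$quality, phred_offset)
  lens <- lengths(quals)
  pos <- sequence(lens)
  qv <- unlist(quals, use.names = FALSE)
  per_pos <- as.numeric(tapply(qv, pos, mean))
  mean_q <- vapply(quals, mean, 0)
  structure(list(
    base_counts = stats::setNames(as.numeric(freq), bases),
    per_position_mean_quality = per_pos,
    length_histogram = dplyr::count(tibble::tibble(length = nchar(reads$sequence)),
                                    .data$length),
    mean_read_quality_histogram = dplyr::count(
      tibble::tibble(mean_quality = as.integer(floor(mean_q))),
      .data$mean_quality),
    n_reads = nrow(reads)
  ), class = "qc_stats")
}

#' @export
print.qc_stats <- function(x, ...) {
  cat(sprintf("<qc_stats> %d reads, %.0f bases\n", x$n_reads,
              sum(x$base_counts)))
  if (x$n_reads > 0) {
    cat(sprintf("  mean per-cycle quality: %.1f (min %.1f)\n",
                mean(x$per_position_mean_quality),
                min(x$per_position_mean_quality)))
  }
  invisible(x)
}

#' Quality-filter thresholds
#'
#' Reads with a mean Phred quality of `min_mean_read_quality` *or less* are
#' discarded (the threshold is inclusive). `positional_quality_floor` and
#' `base_skew_tolerance` drive file-level warning flags only.
#'
#' @param min_mean_read_quality Mean-Phred discard threshold (default 20).
#' @param positional_quality_floor Per-cycle mean quality warning floor
#'   (default 20).
#' @param base_skew_tolerance Maximum absolute deviation of any A/C/G/T
#'   frequency from 0.25 before a base-composition warning (default 0.15).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_mean_read_quality = 20,
                          positional_quality_floor = 20,
                          base_skew_tolerance = 0.15) {
  if (min_mean_read_quality < 0 || positional_quality_floor < 0) {
    abort("quality thresholds must be non-negative")
  }
  structure(list(min_mean_read_quality = min_mean_read_quality,
                 positional_quality_floor = positional_quality_floor,
                 base_skew_tolerance = base_skew_tolerance),
            class = "qc_thresholds")
}

#' Discard low-quality reads
#'
#' Keeps exactly the reads whose mean Phred quality is strictly greater
#' than the threshold; a read at the threshold is discarded.
#'
#' @param reads FASTQ path or read tibble.
#' @param thresholds A [qc_thresholds()] object.
#' @param phred_offset Quality encoding offset.
#' @return List with `kept` (read tibble) and `discarded` (count).
#' @export
filter_reads <- function(reads, thresholds = qc_thresholds(),
                         phred_offset = 33L) {
  reads <- validate_reads(as_reads_input(reads))
  if (nrow(reads) == 0) return(list(kept = reads, discarded = 0L))
  mean_q <- vapply(quality_ints(reads$quality, phred_offset), mean, 0)
  keep <- mean_q > thresholds$min_mean_read_quality
  list(kept = reads[keep, ], discarded = sum(!keep))
}

#' Quality-filter paired reads
#'
#' Mates are judged independently by the same inclusive mean-Phred rule
#' as [filter_reads()]; with `drop_pair_on_either = TRUE` (default) a
#' pair is discarded when either mate fails, keeping the two files
#' synchronized.
#'
#' @param reads1,reads2 Mate FASTQ paths or read tibbles, in matching
#'   record order.
#' @param thresholds A [qc_thresholds()] object.
#' @param drop_pair_on_either Drop both mates when either fails
#'   (default TRUE); otherwise each file is filtered independently.
#' @param phred_offset Quality encoding offset.
#' @return List with `kept1`, `kept2` (read tibbles) and `discarded`
#'   (pairs dropped, or total single-end discards when filtering
#'   independently).
#' @export
filter_read_pairs <- function(reads1, reads2, thresholds = qc_thresholds(),
                              drop_pair_on_either = TRUE,
                              phred_offset = 33L) {
  r1 <- validate_reads(as_reads_input(reads1))
  r2 <- validate_reads(as_reads_input(reads2))
  if (nrow(r1) != nrow(r2)) {
    abort(sprintf("mate files differ in read count: %d vs %d",
                  nrow(r1), nrow(r2)))
  }
  if (!drop_pair_on_either) {
    f1 <- filter_reads(r1, thresholds, phred_offset)
    f2 <- filter_reads(r2, thresholds, phred_offset)
    return(list(kept1 = f1$kept, kept2 = f2$kept,
                discarded = f1$discarded + f2$discarded))
  }
  pass <- function(r) {
    if (nrow(r) == 0) return(logical(0))
    vapply(quality_ints(r$quality, phred_offset), mean, 0) >
      thresholds$min_mean_read_quality
  }
  keep <- pass(r1) & pass(r2)
  list(kept1 = r1[keep, ], kept2 = r2[keep, ], discarded = sum(!keep))
}

#' File-level QC flags
#'
#' @param stats A `qc_stats` object from [read_stats()].
#' @param thresholds A [qc_thresholds()] object.
#' @return One-row tibble: `pass`, `positional_warn` (some cycle's mean
#'   quality below the floor) and `base_skew_warn` (an A/C/G/T frequency
#'   deviating from 0.25 beyond tolerance).
#' @export
flag_file <- function(stats, thresholds = qc_thresholds()) {
  positional_warn <- length(stats$per_position_mean_quality) > 0 &&
    any(stats$per_position_mean_quality < thresholds$positional_quality_floor)
  acgt <- stats$base_counts[c("A", "C", "G", "T")]
  base_skew_warn <- sum(acgt) > 0 &&
    any(abs(acgt / sum(acgt) - 0.25) > thresholds$base_skew_tolerance)
  tibble::tibble(pass = !positional_warn && !base_skew_warn,
                 positional_warn = positional_warn,
                 base_skew_warn = base_skew_warn)
}

#' Serialize QC statistics as JSON
#'
#' @param stats A `qc_stats` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_json <- function(stats, path) {
  jsonlite::write_json(list(
    n_reads = stats$n_reads,
    base_counts = as.list(stats$base_counts),
    per_position_mean_quality = stats$per_position_mean_quality,
    length_histogram = stats$length_histogram,
    mean_read_quality_histogram = stats$mean_read_quality_histogram
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
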