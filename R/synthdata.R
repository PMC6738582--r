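# Seed-deterministic synthetic fixtures: toy taxonomies, reference
# genomes, shotgun reads drawn from a known abundance profile with a
# substitution error model and planted dark matter, and feature tables
# with planted correlations. These generators define the study conditions
# every stage of the package is tested under.

#' Simulation specification
#'
#' @param n_organisms Number of reference organisms.
#' @param genome_lengths Genome lengths (nt), recycled to `n_organisms`.
#' @param true_profile Organism fractions, summing to 1.
#' @param n_reads Number of reads to simulate.
#' @param read_length Read length (nt).
#' @param error_rate Per-base substitution probability.
#' @param darkmatter_fraction Fraction of reads drawn from an extra genome
#'   excluded from the reference (taken from the total before profile
#'   allocation).
#' @param taxonomy_shape Named counts per rank for [make_taxonomy()].
#' @param seed Integer seed; all generators are deterministic given it.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_organisms = 3, genome_lengths = 5000,
                     true_profile = rep(1 / n_organisms, n_organisms),
                     n_reads = 1000, read_length = 100, error_rate = 0,
                     darkmatter_fraction = 0,
                     taxonomy_shape = NULL, seed = 1L) {
  if (abs(sum(true_profile) - 1) > 1e-8) {
    abort("true_profile fractions must sum to 1")
  }
  if (length(true_profile) != n_organisms) {
    abort("true_profile length must equal n_organisms")
  }
  if (darkmatter_fraction < 0 || darkmatter_fraction >= 1) {
    abort("darkmatter_fraction must be in [0, 1)")
  }
  genome_lengths <- rep_len(genome_lengths, n_organisms)
  if (any(genome_lengths < read_length)) {
    abort("genome lengths must be at least the read length")
  }
  structure(list(
    n_organisms = as.integer(n_organisms),
    genome_lengths = as.integer(genome_lengths),
    true_profile = true_profile,
    n_reads = as.integer(n_reads),
    read_length = as.integer(read_length),
    error_rate = error_rate,
    darkmatter_fraction = darkmatter_fraction,
    taxonomy_shape = taxonomy_shape,
    seed = as.integer(seed)
  ), class = "sim_spec")
}

#' Generate a toy taxonomy
#'
#' Builds a rooted tree with the requested number of nodes at each rank
#' (ranks in canonical order, children distributed round-robin over the
#' previous rank), parseable by [parse_taxdump()] after [write_taxdump()].
#'
#' @param shape Named integer vector of counts per rank, e.g.
#'   `c(phylum = 2, genus = 4, species = 8)`; each count must be >= 1.
#' @param seed Unused randomness hook kept for interface symmetry; the
#'   generated tree is fully determined by `shape`.
#' @return A `taxonomy_tree`. Leaf taxa (deepest rank) are named
#'   `"<rank> <i>"`.
#' @export
make_taxonomy <- function(shape = c(phylum = 2, genus = 4, species = 8),
                          seed = NULL) {
  if (any(shape < 1)) abort("every rank count must be >= 1")
  rank_order <- c("superkingdom", "kingdom", "phylum", "class", "order",
                  "family", "genus", "species", "strain")
  ranks <- intersect(rank_order, names(shape))
  if (length(ranks) != length(shape)) {
    abort("taxonomy_shape names must be canonical rank labels")
  }
  nodes <- tibble::tibble(taxid = 1L, parent_taxid = 1L, rank = "no rank",
                          name = "root")
  next_id <- 2L
  parents <- 1L
  for (r in ranks) {
    n <- shape[[r]]
    ids <- seq.int(next_id, length.out = n)
    nodes <- dplyr::bind_rows(nodes, tibble::tibble(
      taxid = ids,
      parent_taxid = rep_len(parents, n),
      rank = r,
      name = sprintf("%s %d", r, seq_len(n))
    ))
    parents <- ids
    next_id <- next_id + n
  }
  new_taxonomy_tree(nodes)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

all_kmers <- function(seqs, k) {
  unique(unlist(lapply(seqs, function(s) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    c(read_kmers(s, k), read_kmers(rc, k))
  }), use.names = FALSE))
}

#' Generate reference genomes and an organism map
#'
#' Genomes are i.i.d. uniform-base sequences of the specified lengths.
#' In `disjoint_kmers` mode, genomes are resampled until no two organisms
#' share any k-mer on either strand, so error-free reads are attributable
#' to exactly one organism (used for 100%-accuracy alignment tests).
#'
#' @param spec A [sim_spec()].
#' @param disjoint_kmers Enforce pairwise-disjoint k-mer sets (default
#'   FALSE).
#' @param k k-mer size used for the disjointness guarantee (default 15).
#' @param taxids Optional taxids per organism (defaults to `1000 + i`).
#' @return List with `fasta` (`DNAStringSet`, one accession per organism,
#'   named `orgN_acc1`) and `organism_map` tibble (`accession`,
#'   `organism_id`, `taxid`).
#' @export
make_genomes <- function(spec, disjoint_kmers = FALSE, k = 15L,
                         taxids = NULL) {
  with_seed(spec$seed, {
    seqs <- character(spec$n_organisms)
    seen <- character(0)
    for (i in seq_len(spec$n_organisms)) {
      repeat {
        s <- random_dna(spec$genome_lengths[i])
        if (!disjoint_kmers) break
        km <- all_kmers(s, k)
        if (!any(km %in% seen)) {
          seen <- c(seen, km)
          break
        }
      }
      seqs[i] <- s
    }
    organism_id <- sprintf("org%02d", seq_len(spec$n_organisms))
    fasta <- Biostrings::DNAStringSet(seqs)
    names(fasta) <- paste0(organism_id, "_acc1")
    list(
      fasta = fasta,
      organism_map = tibble::tibble(
        accession = names(fasta),
        organism_id = organism_id,
        taxid = taxids %||% (1000L + seq_len(spec$n_organisms))
      )
    )
  })
}

sample_reads_from <- function(genome, n, read_length) {
  if (n == 0) {
    return(character(0))
  }
  starts <- sample.int(nchar(genome) - read_length + 1, n, replace = TRUE)
  reads <- substring(genome, starts, starts + read_length - 1)
  flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
  if (any(flip)) {
    reads[flip] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[flip])))
  }
  reads
}

# substitution-only error model: each base independently replaced by one
# of the three other bases with probability error_rate
apply_substitutions <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0) {
    return(reads)
  }
  mat <- matrix(unlist(strsplit(reads, "", fixed = TRUE)),
                nrow = length(reads), byrow = TRUE)
  hit <- matrix(stats::runif(length(mat)) < error_rate,
                nrow = length(reads))
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    old <- mat[hit]
    mat[hit] <- vapply(old, function(b) sample(setdiff(bases, b), 1), "")
  }
  apply(mat, 1, paste, collapse = "")
}

#' Simulate shotgun reads from a known abundance profile
#'
#' Each read's source organism is drawn from `true_profile` (multinomial);
#' its position is uniform over the genome, its strand uniform, and
#' substitutions occur independently per base at `error_rate`. A
#' `darkmatter_fraction` of reads is first set aside and drawn from an
#' extra genome generated with the same base composition but excluded
#' from the reference, so its unalignability stems from sequence
#' identity, not composition.
#'
#' @param spec A [sim_spec()].
#' @param genomes Output of [make_genomes()] for the same spec.
#' @return List with `reads` (tibble `read_id`, `sequence`, `quality`),
#'   `truth` (tibble `read_id`, `source`, with `"darkmatter"` for planted
#'   dark-matter reads) and `darkmatter_genome` (character or `NULL`).
#' @export
make_reads <- function(spec, genomes) {
  with_seed(spec$seed + 1L, {
    n_dark <- stats::rbinom(1, spec$n_reads, spec$darkmatter_fraction)
    n_ref <- spec$n_reads - n_dark
    source_idx <- sample.int(spec$n_organisms, n_ref, replace = TRUE,
                             prob = spec$true_profile)
    org_ids <- genomes$organism_map$organism_id
    ref_seqs <- as.character(genomes$fasta)
    reads <- character(0)
    sources <- character(0)
    for (i in seq_len(spec$n_organisms)) {
      n_i <- sum(source_idx == i)
      reads <- c(reads, sample_reads_from(ref_seqs[i], n_i,
                                          spec$read_length))
      sources <- c(sources, rep(org_ids[i], n_i))
    }
    dark_genome <- NULL
    if (n_dark > 0 || spec$darkmatter_fraction > 0) {
      dark_genome <- random_dna(max(spec$genome_lengths))
    }
    if (n_dark > 0) {
      reads <- c(reads, sample_reads_from(dark_genome, n_dark,
                                          spec$read_length))
      sources <- c(sources, rep("darkmatter", n_dark))
    }
    ord <- sample.int(length(reads))
    tibble_out <- tibble::tibble(
      read_id = sprintf("read%06d", seq_along(reads)),
      sequence = apply_substitutions(reads[ord], spec$error_rate),
      quality = strrep("I", spec$read_length)
    )
    list(
      reads = tibble_out,
      truth = tibble::tibble(read_id = tibble_out$read_id,
                             source = sources[ord]),
      darkmatter_genome = dark_genome
    )
  })
}

#' Simulate a per-sample nutrient/anthropometric feature table
#'
#' Planted features are linear in an organism's abundance plus Gaussian
#' noise; unplanted features are pure noise. One categorical column
#' (`gender`) is always included for encoding tests.
#'
#' @param profiles Tibble or matrix of per-sample organism abundances
#'   (samples in rows; a `sample_id` column is honoured).
#' @param planted Tibble with columns `organism_id`, `feature`, `slope`,
#'   `noise_sd` describing the planted correlations.
#' @param n_noise_features Number of additional pure-noise features.
#' @param seed Integer seed.
#' @return Feature tibble with `sample_id`, planted and noise features,
#'   and a categorical `gender` column.
#' @export
make_features <- function(profiles,
                          planted = tibble::tibble(
                            organism_id = character(0), feature = character(0),
                            slope = numeric(0), noise_sd = numeric(0)),
                          n_noise_features = 3, seed = 1L) {
  profiles <- tibble::as_tibble(profiles)
  id <- profiles[["sample_id"]] %||% paste0("s", seq_len(nrow(profiles)))
  ab <- profiles[, setdiff(names(profiles), "sample_id"), drop = FALSE]
  n <- nrow(ab)
  if (n < 2) abort("need at least 2 samples to build a feature table")
  with_seed(seed, {
    out <- tibble::tibble(sample_id = id)
    for (i in seq_len(nrow(planted))) {
      org <- planted$organism_id[i]
      if (!org %in% names(ab)) {
        abort(sprintf("planted organism not in profiles: %s", org))
      }
      out[[planted$feature[i]]] <- planted$slope[i] * ab[[org]] +
        stats::rnorm(n, sd = planted$noise_sd[i])
    }
    for (j in seq_len(n_noise_features)) {
      out[[sprintf("noise%02d", j)]] <- stats::rnorm(n)
    }
    out$gender <- sample(c("F", "M"), n, replace = TRUE)
    out
  })
}
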