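# Shared fixture builders: tiny taxonomies, FASTQ files and random trees,
# all constructed in code at test time.

# a 3-node chain: root(1) <- phylum(2) <- species(3)
tiny_tree <- function() {
  gutbaseline:::new_taxonomy_tree(tibble::tibble(
    taxid = c(1L, 2L, 3L),
    parent_taxid = c(1L, 1L, 2L),
    rank = c("no rank", "phylum", "species"),
    name = c("root", "Phylum A", "Species a")
  ))
}

# random rooted tree: each node's parent drawn among earlier nodes
random_tree <- function(n, seed, term_nodes = integer(0),
                        term = "uncultured") {
  withr::with_seed(seed, {
    parent <- c(1L, vapply(2:n, function(i) sample.int(i - 1L, 1), 1L))
    name <- sprintf("taxon %03d", 1:n)
    name[term_nodes] <- paste(name[term_nodes], term)
    gutbaseline:::new_taxonomy_tree(tibble::tibble(
      taxid = 1:n,
      parent_taxid = parent,
      rank = c("no rank", sample(c("phylum", "class", "order", "family",
                                   "genus", "species"), n - 1, replace = TRUE)),
      name = name
    ))
  })
}

# brute-force lineage by walking parent pointers on the raw table
walk_lineage <- function(tree, taxid) {
  nodes <- tree$nodes
  out <- integer(0)
  repeat {
    out <- c(out, taxid)
    parent <- nodes$parent_taxid[nodes$taxid == taxid]
    if (parent == taxid) break
    taxid <- parent
  }
  out
}

write_fastq_file <- function(reads, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "reads.fastq")
  write_fastq(reads, path)
  path
}

# reads tibble from parallel vectors
reads_tbl <- function(sequences, qualities = NULL, ids = NULL) {
  tibble::tibble(
    read_id = ids %||% paste0("r", seq_along(sequences)),
    sequence = sequences,
    quality = qualities %||% strrep("I", nchar(sequences))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
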