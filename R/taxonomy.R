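# Taxonomy-dump parsing, lineage queries, term blacklists and reference
# database filtering ("Filtered-nt"-style construction).

TAXDUMP_RANKS <- c("superkingdom", "kingdom", "phylum", "class", "order",
                   "family", "genus", "species", "strain", "no rank")

#' Default reference-database blacklist terms
#'
#' Lineage terms marking sequences without a clear biological taxonomic
#' placement (unclassified, uncultured, synthetic constructs, vectors and
#' the like). A taxon whose scientific name — or any ancestor's name —
#' contains one of these terms (case-insensitive substring) is removed,
#' together with all of its descendants, when building a filtered
#' nucleotide reference database.
#'
#' @return Character vector of lowercase terms.
#' @export
default_blacklist_terms <- function() {
  c("unclassified", "unidentified", "uncultured", "unspecified",
    "unknown", "vector", "environmental sample", "artificial sequence",
    "other sequence")
}

split_taxdump_lines <- function(lines, what) {
  lines <- lines[nzchar(lines)]
  bad <- which(!grepl("\t\\|$", lines))
  if (length(bad) > 0) {
    abort(sprintf("malformed %s record at line %d: missing '\\t|' terminator",
                  what, bad[1]))
  }
  body <- sub("\t\\|$", "", lines)
  strsplit(body, "\t\\|\t")
}

#' Parse NCBI-taxonomy-dump-style node and name tables
#'
#' Reads the taxonomy-dump dialect (fields separated by `"\t|\t"`, records
#' terminated by `"\t|"`). The nodes table must carry taxid, parent taxid
#' and rank in its first three fields; the names table taxid, name and
#' (fourth field) name class. Each node is named by its `scientific name`
#' class entry.
#'
#' @param nodes_file Path to a nodes table (`nodes.dmp` dialect).
#' @param names_file Path to a names table (`names.dmp` dialect).
#' @return A `taxonomy_tree` object: a list with a `nodes` tibble
#'   (`taxid`, `parent_taxid`, `rank`, `name`) and the `root_taxid`.
#' @examples
#' tax <- make_taxonomy(c(phylum = 2, genus = 2, species = 4), seed = 1)
#' lineage(tax, max(tax$nodes$taxid))
#' @export
parse_taxdump <- function(nodes_file, names_file) {
  node_fields <- split_taxdump_lines(readLines(nodes_file), "nodes")
  name_fields <- split_taxdump_lines(readLines(names_file), "names")
  bad <- which(lengths(node_fields) < 3)
  if (length(bad) > 0) {
    abort(sprintf("malformed nodes record at line %d: fewer than 3 fields",
                  bad[1]))
  }
  nodes <- tibble::tibble(
    taxid = as.integer(vapply(node_fields, `[[`, "", 1)),
    parent_taxid = as.integer(vapply(node_fields, `[[`, "", 2)),
    rank = vapply(node_fields, `[[`, "", 3)
  )
  bad <- which(lengths(name_fields) < 4)
  if (length(bad) > 0) {
    abort(sprintf("malformed names record at line %d: fewer than 4 fields",
                  bad[1]))
  }
  names_tbl <- tibble::tibble(
    taxid = as.integer(vapply(name_fields, `[[`, "", 1)),
    name = vapply(name_fields, `[[`, "", 2),
    name_class = vapply(name_fields, `[[`, "", 4)
  )
  sci <- dplyr::filter(names_tbl, .data$name_class == "scientific name")
  nodes <- dplyr::left_join(nodes, dplyr::select(sci, "taxid", "name"),
                            by = "taxid")
  if (anyNA(nodes$name)) {
    abort(sprintf("taxid %d has no scientific name",
                  nodes$taxid[which(is.na(nodes$name))[1]]))
  }
  new_taxonomy_tree(nodes)
}

new_taxonomy_tree <- function(nodes) {
  if (anyDuplicated(nodes$taxid)) {
    abort("duplicate taxid in nodes table")
  }
  root <- nodes$taxid[nodes$taxid == nodes$parent_taxid]
  if (length(root) != 1) {
    abort("tree must have exactly one root (a node that is its own parent)")
  }
  dangling <- setdiff(nodes$parent_taxid, nodes$taxid)
  if (length(dangling) > 0) {
    abort(sprintf("dangling parent taxid: %d", dangling[1]))
  }
  tree <- structure(
    list(nodes = tibble::as_tibble(nodes), root_taxid = root),
    class = "taxonomy_tree"
  )
  # cycle check: every node must reach root
  depth <- node_depths(tree)
  if (anyNA(depth)) {
    abort("taxonomy contains a cycle: some lineages never reach the root")
  }
  tree
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("<taxonomy_tree> %d nodes, root taxid %d\n",
              nrow(x$nodes), x$root_taxid))
  ranks <- table(x$nodes$rank)
  cat("  ranks:", paste(sprintf("%s=%d", names(ranks), ranks),
                        collapse = ", "), "\n")
  invisible(x)
}

# depth of each node (root = 0), NA when a node sits on a cycle
node_depths <- function(tree) {
  nodes <- tree$nodes
  parent_idx <- match(nodes$parent_taxid, nodes$taxid)
  n <- nrow(nodes)
  depth <- rep(NA_integer_, n)
  depth[nodes$taxid == tree$root_taxid] <- 0L
  frontier <- which(depth == 0L)
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    children <- which(parent_idx %in% frontier & is.na(depth))
    children <- setdiff(children, which(depth == 0L))
    depth[children] <- d
    frontier <- children
  }
  depth
}

#' Serialize a taxonomy tree to dump-dialect tables
#'
#' Inverse of [parse_taxdump()]; useful for round-trip tests and for
#' materializing synthetic taxonomies on disk.
#'
#' @param tree A `taxonomy_tree`.
#' @param nodes_file,names_file Output paths.
#' @return The tree, invisibly.
#' @export
write_taxdump <- function(tree, nodes_file, names_file) {
  n <- tree$nodes
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|", n$taxid, n$parent_taxid, n$rank),
             nodes_file)
  writeLines(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", n$taxid, n$name),
             names_file)
  invisible(tree)
}

#' Lineage of a taxon, from the node up to the root
#'
#' @param tree A `taxonomy_tree`.
#' @param taxid Taxid present in the tree.
#' @return Tibble with one row per lineage node (`taxid`, `rank`, `name`),
#'   first row the query node, last row the root.
#' @export
lineage <- function(tree, taxid) {
  nodes <- tree$nodes
  idx <- match(taxid, nodes$taxid)
  if (is.na(idx)) abort(sprintf("unknown taxid: %s", taxid))
  parent_idx <- match(nodes$parent_taxid, nodes$taxid)
  path <- integer(0)
  while (TRUE) {
    path <- c(path, idx)
    if (nodes$taxid[idx] == tree$root_taxid) break
    idx <- parent_idx[idx]
  }
  nodes[path, c("taxid", "rank", "name")]
}

#' Build a taxid blacklist from lineage terms
#'
#' A taxid is blacklisted when its own scientific name, or the name of any
#' ancestor, contains at least one term (case-insensitive substring match).
#' The result is closed under descendants: every child of a blacklisted
#' node is blacklisted.
#'
#' @param tree A `taxonomy_tree`.
#' @param terms Character vector of terms; defaults to
#'   [default_blacklist_terms()].
#' @return A `taxon_blacklist`: list with `terms` and the integer set
#'   `taxids`.
#' @export
build_blacklist <- function(tree, terms = default_blacklist_terms()) {
  if (length(terms) == 0 || any(!nzchar(terms))) {
    abort("blacklist terms must be non-empty strings")
  }
  terms <- tolower(terms)
  nodes <- tree$nodes
  name_lc <- tolower(nodes$name)
  self_hit <- Reduce(`|`, lapply(terms, function(t) {
    stringr::str_detect(name_lc, stringr::fixed(t))
  }))
  # propagate down the tree in depth order: node is blacklisted iff its own
  # name matches or its parent is blacklisted
  depth <- node_depths(tree)
  parent_idx <- match(nodes$parent_taxid, nodes$taxid)
  black <- self_hit
  for (i in order(depth)) {
    if (depth[i] > 0 && black[parent_idx[i]]) black[i] <- TRUE
  }
  structure(list(terms = terms, taxids = nodes$taxid[black]),
            class = "taxon_blacklist")
}

#' @export
print.taxon_blacklist <- function(x, ...) {
  cat(sprintf("<taxon_blacklist> %d terms, %d blacklisted taxids\n",
              length(x$terms), length(x$taxids)))
  invisible(x)
}

#' Bookkeeping record for a reference-filtering run
#'
#' Counts are conserved: `initial_sequences` always equals
#' `removed_sequences + retained_sequences + unmapped_sequences`.
#'
#' @param initial_sequences,removed_sequences,unmapped_sequences Counts.
#' @param removed_taxids Number of distinct blacklisted taxids hit.
#' @return A one-row `filter_stats` tibble with the retained count derived
#'   from the other three.
#' @export
filter_stats <- function(initial_sequences, removed_sequences,
                         unmapped_sequences = 0, removed_taxids = NA_integer_) {
  counts <- c(initial_sequences, removed_sequences, unmapped_sequences)
  if (any(counts < 0)) abort("filter_stats counts must be non-negative")
  out <- tibble::tibble(
    initial_sequences = initial_sequences,
    removed_sequences = removed_sequences,
    retained_sequences = initial_sequences - removed_sequences -
      unmapped_sequences,
    removed_taxids = removed_taxids,
    unmapped_sequences = unmapped_sequences
  )
  if (out$retained_sequences < 0) {
    abort("removed + unmapped exceeds the initial sequence count")
  }
  class(out) <- c("filter_stats", class(out))
  out
}

#' Filter a reference FASTA against a taxid blacklist
#'
#' Keeps exactly the sequences whose accession (FASTA identifier up to the
#' first whitespace) maps to a taxid that exists and is not blacklisted.
#' Sequences without a taxid mapping are removed and counted separately,
#' mirroring the exclusion of hits lacking a clear taxonomic lineage.
#' Input order and header text are preserved.
#'
#' @param reference FASTA path or `DNAStringSet`.
#' @param acc2taxid Two-column table (`accession`, `taxid`) or TSV path.
#' @param blacklist A `taxon_blacklist` from [build_blacklist()].
#' @param out_fasta Optional path; when given, the retained sequences are
#'   also written there.
#' @return List with `fasta` (retained `DNAStringSet`) and `stats`
#'   (a [filter_stats()] row).
#' @export
filter_reference <- function(reference, acc2taxid, blacklist,
                             out_fasta = NULL) {
  seqs <- as_fasta_input(reference)
  map <- as_table_input(acc2taxid)
  names(map)[1:2] <- c("accession", "taxid")
  if (anyDuplicated(map$accession)) {
    abort("duplicate accession in acc2taxid mapping")
  }
  acc <- first_token(names(seqs))
  taxid <- map$taxid[match(acc, map$accession)]
  unmapped <- is.na(taxid)
  removed <- !unmapped & taxid %in% blacklist$taxids
  keep <- !unmapped & !removed
  stats <- filter_stats(
    initial_sequences = length(seqs),
    removed_sequences = sum(removed),
    unmapped_sequences = sum(unmapped),
    removed_taxids = length(unique(taxid[removed]))
  )
  out <- seqs[keep]
  if (!is.null(out_fasta)) Biostrings::writeXStringSet(out, out_fasta)
  list(fasta = out, stats = stats)
}
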