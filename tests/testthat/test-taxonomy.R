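test_that("taxdump parsing builds a minimal tree with correct lineage", {
  dir <- withr::local_tempdir()
  nodes <- file.path(dir, "nodes.dmp")
  names_f <- file.path(dir, "names.dmp")
  writeLines(c("1\t|\t1\t|\tno rank\t|",
               "2\t|\t1\t|\tphylum\t|",
               "3\t|\t2\t|\tspecies\t|"), nodes)
  writeLines(c("1\t|\troot\t|\t\t|\tscientific name\t|",
               "2\t|\tBacteroidetes junk\t|\t\t|\tsynonym\t|",
               "2\t|\tBacteroidetes\t|\t\t|\tscientific name\t|",
               "3\t|\tBacteroides dorei\t|\t\t|\tscientific name\t|"), names_f)
  tree <- parse_taxdump(nodes, names_f)
  expect_equal(nrow(tree$nodes), 3)
  # scientific-name class wins over the synonym
  expect_equal(tree$nodes$name[tree$nodes$taxid == 2], "Bacteroidetes")
  lin <- lineage(tree, 3)
  expect_equal(lin$taxid, c(3, 2, 1))
  expect_equal(lineage(tree, 1)$taxid, 1)
})

test_that("parsing errors name the offending record", {
  dir <- withr::local_tempdir()
  nodes <- file.path(dir, "nodes.dmp")
  names_f <- file.path(dir, "names.dmp")
  writeLines(c("1\t|\t1\t|\tno rank\t|", "2\t|\t1\t|\tphylum"), nodes)
  writeLines("1\t|\troot\t|\t\t|\tscientific name\t|", names_f)
  expect_error(parse_taxdump(nodes, names_f), "line 2")
  # dangling parent
  writeLines(c("1\t|\t1\t|\tno rank\t|", "2\t|\t9\t|\tphylum\t|"), nodes)
  writeLines(c("1\t|\troot\t|\t\t|\tscientific name\t|",
               "2\t|\tx\t|\t\t|\tscientific name\t|"), names_f)
  expect_error(parse_taxdump(nodes, names_f), "dangling")
  # missing scientific name
  writeLines(c("1\t|\t1\t|\tno rank\t|", "2\t|\t1\t|\tphylum\t|"), nodes)
  writeLines(c("1\t|\troot\t|\t\t|\tscientific name\t|",
               "2\t|\tx\t|\t\t|\tsynonym\t|"), names_f)
  expect_error(parse_taxdump(nodes, names_f), "no scientific name")
})

test_that("a 50-node random tree round-trips through the dump dialect", {
  tree <- random_tree(50, seed = 11)
  dir <- withr::local_tempdir()
  nodes <- file.path(dir, "n.dmp")
  names_f <- file.path(dir, "m.dmp")
  write_taxdump(tree, nodes, names_f)
  back <- parse_taxdump(nodes, names_f)
  expect_equal(back$nodes, tree$nodes)
  expect_equal(back$root_taxid, tree$root_taxid)
})

test_that("lineage equals a brute-force parent-pointer walk on random trees", {
  tree <- random_tree(50, seed = 3)
  for (t in tree$nodes$taxid) {
    expect_equal(lineage(tree, t)$taxid, walk_lineage(tree, t))
  }
  expect_error(lineage(tree, 999L), "unknown taxid")
})

test_that("blacklist matches terms and is closed under descendants", {
  # node 2 named with the term; its whole subtree must be blacklisted
  tree <- gutbaseline:::new_taxonomy_tree(tibble::tibble(
    taxid = 1:5,
    parent_taxid = c(1L, 1L, 2L, 2L, 3L),
    rank = c("no rank", "family", "genus", "genus", "species"),
    name = c("root", "environmental samples", "g1", "g2", "s1")
  ))
  bl <- build_blacklist(tree, "environmental sample")
  expect_setequal(bl$taxids, 2:5)
  # no matching names -> empty
  expect_length(build_blacklist(tree, "unclassified")$taxids, 0)
  expect_error(build_blacklist(tree, ""), "non-empty")
})

test_that("blacklist equals per-node brute-force lineage scan on random trees", {
  for (seed in c(5, 6, 7)) {
    tree <- random_tree(60, seed = seed,
                        term_nodes = sample(2:60, 6), term = "uncultured")
    bl <- build_blacklist(tree, "uncultured")
    brute <- tree$nodes$taxid[vapply(tree$nodes$taxid, function(t) {
      any(grepl("uncultured", lineage(tree, t)$name, ignore.case = TRUE))
    }, TRUE)]
    expect_setequal(bl$taxids, brute)
    # descendant closure
    for (t in bl$taxids) {
      kids <- tree$nodes$taxid[tree$nodes$parent_taxid == t &
                                 tree$nodes$taxid != t]
      expect_true(all(kids %in% bl$taxids))
    }
  }
})

test_that("reference filtering removes blacklisted and unmapped sequences", {
  tree <- random_tree(10, seed = 1, term_nodes = 4L)
  bl <- build_blacklist(tree, "uncultured")
  black_taxid <- bl$taxids[1]
  ok_taxid <- setdiff(tree$nodes$taxid, c(bl$taxids, 1L))[1]
  seqs <- Biostrings::DNAStringSet(
    setNames(rep(strrep("ACGT", 5), 10),
             sprintf("seq%02d extra header text", 1:10)))
  acc <- sprintf("seq%02d", 1:10)
  # 3 blacklisted, 1 unmapped, 6 clean
  map <- tibble::tibble(accession = acc[1:9],
                        taxid = c(rep(black_taxid, 3), rep(ok_taxid, 6)))
  res <- filter_reference(seqs, map, bl)
  expect_equal(res$stats$initial_sequences, 10)
  expect_equal(res$stats$removed_sequences, 3)
  expect_equal(res$stats$unmapped_sequences, 1)
  expect_equal(res$stats$retained_sequences, 6)
  # order and header text preserved
  expect_equal(names(res$fasta), sprintf("seq%02d extra header text", 4:9))
  # idempotence: filtering the filtered set removes nothing
  res2 <- filter_reference(res$fasta, map, bl)
  expect_equal(res2$stats$removed_sequences, 0)
  expect_equal(res2$stats$unmapped_sequences, 0)
  expect_equal(length(res2$fasta), length(res$fasta))
  # duplicate accession is an error
  expect_error(filter_reference(seqs, map[c(1, 1, 2:9), ], bl), "duplicate")
})

test_that("filtering equals brute-force per-sequence lineage scan", {
  tree <- random_tree(40, seed = 9, term_nodes = sample(2:40, 4))
  bl <- build_blacklist(tree, "uncultured")
  n <- 200
  withr::with_seed(2, {
    taxid <- sample(tree$nodes$taxid, n, replace = TRUE)
  })
  seqs <- Biostrings::DNAStringSet(setNames(rep("ACGTACGT", n),
                                            sprintf("s%03d", 1:n)))
  map <- tibble::tibble(accession = sprintf("s%03d", 1:n), taxid = taxid)
  res <- filter_reference(seqs, map, bl)
  brute_keep <- !vapply(taxid, function(t) {
    any(grepl("uncultured", lineage(tree, t)$name, ignore.case = TRUE))
  }, TRUE)
  expect_equal(names(res$fasta), sprintf("s%03d", which(brute_keep)))
  expect_equal(res$stats$retained_sequences +
                 res$stats$removed_sequences +
                 res$stats$unmapped_sequences,
               res$stats$initial_sequences)
})
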