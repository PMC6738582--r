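sample_record <- function(id = "Testus examplus", taxid = 42L) {
  organism_record(scientific_name = id, genbank_accessions = c("AC1", "AC2"),
                  taxid = taxid, lineage = c(phylum = "P", species = id),
                  presence_percent = 50, mean_abundance_percent = 1.5)
}

test_that("presence/abundance cells parse and reject malformed input", {
  expect_equal(parse_presence_cell("(100;17.44)"),
               tibble::tibble(presence_percent = 100,
                              mean_abundance_percent = 17.44))
  expect_equal(parse_presence_cell("(1.02;2.10)")$presence_percent, 1.02)
  expect_equal(parse_presence_cell("(0;0)")$mean_abundance_percent, 0)
  expect_equal(parse_presence_cell("(100; 0.003)")$mean_abundance_percent,
               0.003)
  expect_error(parse_presence_cell("100;17.44"), "malformed")
  expect_error(parse_presence_cell("(droP;tables)"), "malformed")
})

test_that("knowledgebase round-trips through TSV including version", {
  kb <- empty_kb()
  expect_equal(kb$version, 1L)
  kb <- add_organism(kb, sample_record("Org one"))
  kb <- add_organism(kb, sample_record("Org two"))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "kb.tsv")
  save_kb(kb, path)
  back <- load_kb(path)
  expect_equal(back$records, kb$records)
  expect_equal(back$version, kb$version)
})

test_that("random 30-record knowledgebase round-trips bit-identically", {
  withr::with_seed(5, {
    kb <- empty_kb()
    for (i in 1:30) {
      kb <- add_organism(kb, organism_record(
        scientific_name = sprintf("Species %02d", i),
        genbank_accessions = replicate(sample(1:3, 1),
                                       paste0("AC", sample(1e5, 1))),
        taxid = i,
        lineage = c(phylum = sample(LETTERS, 1), species = paste("sp", i)),
        presence_percent = round(stats::runif(1, 0, 100), 2),
        mean_abundance_percent = round(stats::runif(1, 0, 20), 3)))
    }
  })
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.tsv")
  p2 <- file.path(dir, "b.tsv")
  save_kb(kb, p1)
  save_kb(load_kb(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("adds are versioned, idempotent, and conflict-checked", {
  kb <- empty_kb()
  kb <- add_organism(kb, sample_record("A"))
  expect_equal(kb$version, 2L)
  expect_equal(nrow(kb$records), 1)
  # identical re-add: no-op
  kb2 <- add_organism(kb, sample_record("A"))
  expect_equal(kb2$version, 2L)
  expect_equal(kb2$records, kb$records)
  # conflicting re-add: error
  expect_error(add_organism(kb, sample_record("A", taxid = 43L)),
               "conflicting")
  # version = 1 + number of distinct organisms added
  withr::with_seed(9, ids <- sample(sprintf("O%02d", 1:6), 10, replace = TRUE))
  kb3 <- empty_kb()
  for (id in ids) kb3 <- add_organism(kb3, sample_record(id))
  expect_equal(kb3$version, 1L + length(unique(ids)))
  # provenance recorded one entry per new organism
  expect_equal(nrow(kb3$provenance), length(unique(ids)))
})

test_that("rpg expansion takes the union of hit clusters", {
  kb <- empty_kb()
  kb <- add_organism(kb, organism_record("A", "AC1", proteome_id = "UP1"))
  kb <- add_organism(kb, organism_record("B", "AC2", proteome_id = "UP2"))
  clusters <- tibble::tibble(
    cluster_id = c("c1", "c1", "c1", "c2", "c2", "c2", "c2", "c3"),
    proteome_id = c("UP1", "UPx", "UPy", "UP2", "UPa", "UPb", "UPc", "UPz"))
  ex <- expand_rpg(kb, clusters)
  expect_equal(nrow(ex), 7)  # 3 + 4, cluster c3 untouched
  expect_true(all(c("UP1", "UP2") %in% ex$proteome_id))
  # member not in any cluster contributes only itself
  kb <- add_organism(kb, organism_record("C", "AC3", proteome_id = "UPsolo"))
  ex2 <- expand_rpg(kb, clusters)
  expect_equal(nrow(ex2), 8)
  expect_true("UPsolo" %in% ex2$proteome_id)
  # expansion is a superset of the KB's mapped proteomes and monotone
  expect_true(all(c("UP1", "UP2", "UPsolo") %in% ex2$proteome_id))
  more <- dplyr::bind_rows(clusters,
                           tibble::tibble(cluster_id = "c4",
                                          proteome_id = "UPsolo"))
  expect_true(all(ex2$proteome_id %in% expand_rpg(kb, more)$proteome_id))
  # a proteome in two clusters is rejected
  bad <- dplyr::bind_rows(clusters,
                          tibble::tibble(cluster_id = "c9",
                                         proteome_id = "UP1"))
  expect_error(expand_rpg(kb, bad), "more than one cluster")
})

test_that("expansion equals a brute-force set-union oracle on random clusters", {
  withr::with_seed(14, {
    prot <- sprintf("UP%03d", 1:60)
    cluster_of <- sample(sprintf("c%02d", 1:12), 60, replace = TRUE)
    kb_prots <- sample(prot, 8)
  })
  clusters <- tibble::tibble(cluster_id = cluster_of, proteome_id = prot)
  kb <- empty_kb()
  for (i in seq_along(kb_prots)) {
    kb <- add_organism(kb, organism_record(paste("Org", i), "AC",
                                           organism_id = paste("Org", i),
                                           proteome_id = kb_prots[i]))
  }
  ex <- expand_rpg(kb, clusters)
  hit <- unique(cluster_of[prot %in% kb_prots])
  brute <- unique(c(prot[cluster_of %in% hit],
                    setdiff(kb_prots, prot)))
  expect_setequal(ex$proteome_id, brute)
})

test_that("rank counts are computed from lineages", {
  kb <- empty_kb()
  kb <- add_organism(kb, organism_record(
    "A", "AC1", lineage = c(phylum = "P1", genus = "G1", species = "A")))
  kb <- add_organism(kb, organism_record(
    "B", "AC2", lineage = c(phylum = "P1", genus = "G2", species = "B")))
  rc <- kb_rank_counts(kb)
  expect_equal(rc$n_distinct[rc$rank == "phylum"], 1L)
  expect_equal(rc$n_distinct[rc$rank == "genus"], 2L)
  expect_equal(rc$n_distinct[rc$rank == "species"], 2L)
})
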