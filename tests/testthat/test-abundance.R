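assignments_tbl <- function(counts, unaligned = 0) {
  orgs <- rep(names(counts), counts)
  ids <- paste0("r", seq_len(length(orgs) + unaligned))
  tibble::tibble(read_id = ids,
                 organism_id = c(orgs, rep("UNALIGNED", unaligned)))
}

test_that("profiles are percentages over aligned reads", {
  p <- profile_sample(assignments_tbl(c(A = 80, B = 20)), sample_id = "s1")
  expect_equal(p$abundance[p$organism_id == "A"], 80)
  expect_equal(p$abundance[p$organism_id == "B"], 20)
  expect_equal(sum(p$abundance), 100)
  expect_equal(attr(p, "unaligned_fraction"), 0)

  all_un <- profile_sample(assignments_tbl(c(), unaligned = 50))
  expect_equal(nrow(all_un), 0)
  expect_equal(attr(all_un, "unaligned_fraction"), 100)

  mixed <- profile_sample(assignments_tbl(c(A = 30), unaligned = 70))
  expect_equal(mixed$abundance, 100)  # aligned-only normalization
  expect_equal(attr(mixed, "unaligned_fraction"), 70)
})

test_that("error-free synthetic mixtures are recovered within multinomial noise", {
  spec <- sim_spec(n_organisms = 3, genome_lengths = 1500,
                   true_profile = c(0.6, 0.3, 0.1), n_reads = 3000,
                   read_length = 80, seed = 37)
  g <- make_genomes(spec, disjoint_kmers = TRUE)
  rr <- make_reads(spec, g)
  db <- build_index(g$fasta, g$organism_map, k = 15)
  p <- profile_sample(assign_reads(rr$reads, db))
  for (i in 1:3) {
    truth <- c(60, 30, 10)[i]
    est <- p$abundance[p$organism_id == sprintf("org%02d", i)]
    se <- 100 * sqrt(truth / 100 * (1 - truth / 100) / spec$n_reads)
    expect_lt(abs(est - truth), 3 * se)
  }
})

make_matrix_fixture <- function() {
  tree <- gutbaseline:::new_taxonomy_tree(tibble::tibble(
    taxid = 1:7,
    parent_taxid = c(1L, 1L, 1L, 2L, 2L, 3L, 3L),
    rank = c("no rank", "genus", "genus", "species", "species", "species",
             "species"),
    name = c("root", "Genus1", "Genus2", "sp1", "sp2", "sp3", "sp4")
  ))
  profiles <- list(
    s1 = profile_sample(assignments_tbl(c(sp1 = 10, sp2 = 5, sp3 = 60,
                                          sp4 = 25)), sample_id = "s1"),
    s2 = profile_sample(assignments_tbl(c(sp1 = 40, sp3 = 60)),
                        sample_id = "s2")
  )
  orgs <- tibble::tibble(organism_id = paste0("sp", 1:4), taxid = 4:7)
  list(tree = tree,
       mat = abundance_matrix(profiles, organisms = orgs, rank = "species"))
}

test_that("rollup sums descendants and preserves row sums", {
  fx <- make_matrix_fixture()
  genus <- rollup(fx$mat, fx$tree, "genus")
  expect_equal(genus$Genus1[genus$sample_id == "s1"], 15)
  expect_equal(genus$Genus2[genus$sample_id == "s1"], 85)
  expect_equal(rowSums(gutbaseline:::abundance_values(genus)),
               rowSums(gutbaseline:::abundance_values(fx$mat)),
               tolerance = 1e-12)
  # rollup to current rank is the identity
  expect_equal(rollup(fx$mat, fx$tree, "species"), fx$mat)
  expect_error(rollup(fx$mat, fx$tree, "kingdom"), "unknown rank")
})

test_that("row sums survive rollup of a random 20-organism matrix to 1e-9", {
  shape <- c(phylum = 3, genus = 6, species = 20)
  tree <- make_taxonomy(shape)
  species <- tree$nodes[tree$nodes$rank == "species", ]
  withr::with_seed(8, {
    vals <- matrix(stats::runif(5 * 20), nrow = 5)
  })
  vals <- vals / rowSums(vals) * 100
  profiles <- lapply(1:5, function(i) {
    p <- tibble::tibble(organism_id = species$name, abundance = vals[i, ])
    structure(p, sample_id = paste0("s", i), unaligned_fraction = 0,
              class = c("abundance_profile", class(p)))
  })
  names(profiles) <- paste0("s", 1:5)
  mat <- abundance_matrix(profiles,
                          organisms = tibble::tibble(
                            organism_id = species$name,
                            taxid = species$taxid),
                          rank = "species")
  for (rank in c("genus", "phylum")) {
    rolled <- rollup(mat, tree, rank)
    expect_equal(rowSums(gutbaseline:::abundance_values(rolled)),
                 rowSums(gutbaseline:::abundance_values(mat)),
                 tolerance = 1e-9)
  }
})

test_that("cohort stats exclude zeros from moments but not from presence", {
  profiles <- list(
    s1 = structure(tibble::tibble(organism_id = "A", abundance = 100),
                   sample_id = "s1", unaligned_fraction = 0,
                   class = c("abundance_profile", "tbl_df", "tbl", "data.frame")),
    s2 = structure(tibble::tibble(organism_id = c("A", "B"),
                                  abundance = c(90, 10)),
                   sample_id = "s2", unaligned_fraction = 0,
                   class = c("abundance_profile", "tbl_df", "tbl", "data.frame")),
    s3 = structure(tibble::tibble(organism_id = c("A", "B"),
                                  abundance = c(80, 20)),
                   sample_id = "s3", unaligned_fraction = 0,
                   class = c("abundance_profile", "tbl_df", "tbl", "data.frame"))
  )
  st <- cohort_stats(abundance_matrix(profiles))
  b <- st[st$organism_id == "B", ]
  expect_equal(b$presence_percent, 2 / 3 * 100)
  expect_equal(b$mean, 15)
  expect_equal(b$min, 10)
  expect_equal(b$max, 20)
  expect_equal(b$median, 15)
  expect_equal(b$sd, stats::sd(c(10, 20)))
})

test_that("cohort stats equal brute-force zero-filtered recomputation", {
  withr::with_seed(12, {
    vals <- matrix(stats::rbinom(8 * 6, 1, 0.7) * stats::runif(48, 1, 30),
                   nrow = 8)
  })
  colnames(vals) <- paste0("o", 1:6)
  mat <- dplyr::bind_cols(tibble::tibble(sample_id = paste0("s", 1:8)),
                          tibble::as_tibble(vals))
  class(mat) <- c("abundance_matrix", class(mat))
  st <- cohort_stats(mat)
  for (org in paste0("o", 1:6)) {
    x <- vals[, org]
    nz <- x[x > 0]
    row <- st[st$organism_id == org, ]
    expect_equal(row$presence_percent, 100 * length(nz) / length(x))
    if (length(nz) > 0) {
      expect_equal(row$mean, mean(nz))
      expect_equal(row$median, stats::median(nz))
    } else {
      expect_true(is.na(row$mean))
    }
  }
  # presence is invariant to column scaling (compare matched by organism)
  mat2 <- mat
  mat2$o1 <- mat2$o1 * 7
  st2 <- cohort_stats(mat2)
  expect_equal(st2$presence_percent[match(st$organism_id, st2$organism_id)],
               st$presence_percent)
})

test_that("the packaged baseline species table reproduces printed cohort facts", {
  kb <- baseline_kb()
  expect_equal(nrow(kb$records), 109)
  top <- kb$records[which.max(kb$records$mean_abundance_percent), ]
  expect_equal(top$scientific_name, "Bacteroides dorei")
  expect_equal(top$mean_abundance_percent, 17.44)
})
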