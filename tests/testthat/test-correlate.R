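test_that("standardization centers and scales columns, flagging constants", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 20, 60))
  z <- standardize(m)
  expect_equal(colMeans(z), c(a = 0, b = 0))
  expect_equal(apply(z, 2, stats::sd), c(a = 1, b = 1))
  expect_warning(z2 <- standardize(cbind(c = c(5, 5, 5))), "zero-variance")
  expect_equal(unname(z2[, 1]), c(0, 0, 0))
  expect_error(standardize(matrix(1, nrow = 1)), "at least 2 rows")
  # random matrix: tight numerical check
  withr::with_seed(3, m2 <- matrix(stats::rnorm(40), 10, 4))
  z3 <- standardize(m2)
  expect_true(all(abs(colMeans(z3)) < 1e-12))
  expect_true(all(abs(apply(z3, 2, stats::var) - 1) < 1e-12))
})

test_that("categorical encoding is lexicographic and order-invariant", {
  f <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                      gender = c("F", "M", "F"), kcal = c(1, 2, 3))
  enc <- encode_categorical(f)
  expect_equal(enc$gender, c(0, 1, 0))
  expect_equal(attr(enc, "encoding_map")$gender, c(F = 0, M = 1))
  expect_equal(enc$kcal, f$kcal)  # numeric untouched
  # shuffled rows give the same mapping
  enc2 <- encode_categorical(f[c(3, 1, 2), ])
  expect_equal(attr(enc2, "encoding_map"), attr(enc, "encoding_map"))
  # mixed numeric/text column is rejected by name
  bad <- tibble::tibble(x = c("1", "2", "oops"))
  expect_error(encode_categorical(bad), "'x'")
})

test_that("cosine correlation matches hand-computed cases", {
  B <- standardize(cbind(org = c(1, 2, 3)))
  expect_equal(unname(as.matrix(
    cosine_correlation(B, standardize(cbind(f = c(2, 4, 6))))[, "f"])[1, 1]), 1)
  expect_equal(unname(as.matrix(
    cosine_correlation(B, standardize(cbind(f = c(3, 2, 1))))[, "f"])[1, 1]), -1)
  # orthogonal columns after centering
  expect_equal(unname(as.matrix(
    cosine_correlation(cbind(b = c(1, -1, 0)),
                       cbind(f = c(0, 0, 1)) - 1 / 3)[, "f"])[1, 1]),
    0, tolerance = 1e-12)
  # raw (unnormalized) mode reproduces the literal sum product
  raw <- cosine_correlation(cbind(b = c(1, 2)), cbind(f = c(3, 4)),
                            normalize = FALSE)
  expect_equal(unname(as.matrix(raw[, "f"])[1, 1]), 11)
  expect_error(cosine_correlation(cbind(1:3), cbind(1:4)), "mismatch")
})

test_that("normalized correlation is bounded with unit self-similarity", {
  withr::with_seed(6, {
    B <- standardize(matrix(stats::rnorm(60), 10, 6,
                            dimnames = list(NULL, paste0("o", 1:6))))
  })
  cc <- cosine_correlation(B, B)
  vals <- as.matrix(cc[, -1])
  expect_true(all(vals >= -1 - 1e-12 & vals <= 1 + 1e-12))
  expect_equal(unname(diag(vals)), rep(1, 6))
  # symmetry under swapping the two matrices
  cc2 <- cosine_correlation(B[, 1:3], B[, 4:6])
  cc3 <- cosine_correlation(B[, 4:6], B[, 1:3])
  expect_equal(as.matrix(cc2[, -1]), t(as.matrix(cc3[, -1])),
               ignore_attr = TRUE)
})

test_that("planted correlations clear the 0.7 threshold and decay with noise", {
  withr::with_seed(40, {
    ab <- tibble::tibble(sample_id = paste0("s", 1:50),
                         orgA = stats::runif(50, 0, 30),
                         orgB = stats::runif(50, 0, 30))
  })
  cors <- vapply(c(0.1, 1, 10), function(noise) {
    feats <- make_features(ab, planted = tibble::tibble(
      organism_id = "orgA", feature = "nutrient1", slope = 2,
      noise_sd = noise), n_noise_features = 2, seed = 41)
    feats$gender <- NULL
    cc <- cosine_correlation(standardize(ab), standardize(feats))
    as.matrix(cc[cc$organism_id == "orgA", "nutrient1"])[1, 1]
  }, 0)
  expect_gt(cors[1], 0.7)
  expect_true(all(diff(abs(cors)) < 0))
  # an unplanted feature stays below threshold
  feats <- make_features(ab, n_noise_features = 3, seed = 43)
  feats$gender <- NULL
  cc <- cosine_correlation(standardize(ab), standardize(feats))
  expect_true(all(abs(as.matrix(cc[, -1])) < 0.7))
  expect_equal(nrow(correlation_hits(cc)), 0)
})

test_that("variability ratio matches its definitions", {
  # identical replicates within hosts -> intra 0
  tbl <- tidyr::expand_grid(host = c("h1", "h2"), replicate = 1:3) %>%
    dplyr::mutate(organism_id = "A",
                  abundance = dplyr::if_else(host == "h1", 10, 20))
  v <- variability_ratio(tbl)
  expect_equal(v$intra_host, 0)
  expect_equal(v$inter_host, stats::sd(c(10, 20)))
  expect_equal(v$ratio, 0)
  expect_error(variability_ratio(dplyr::filter(tbl, host == "h1")),
               "2 hosts")
})

test_that("variability ratio equals brute-force recomputation on a random fixture", {
  withr::with_seed(44, {
    tbl <- tidyr::expand_grid(host = paste0("h", 1:5), replicate = 1:3,
                              organism_id = c("A", "B")) %>%
      dplyr::mutate(abundance = stats::runif(dplyr::n(), 0, 50))
  })
  v <- variability_ratio(tbl)
  for (org in c("A", "B")) {
    sub <- tbl[tbl$organism_id == org, ]
    host_sd <- tapply(sub$abundance, sub$host, stats::sd)
    host_mean <- tapply(sub$abundance, sub$host, mean)
    row <- v[v$organism_id == org, ]
    expect_equal(row$intra_host, mean(host_sd))
    expect_equal(row$inter_host, stats::sd(host_mean))
    expect_equal(row$ratio, mean(host_sd) / stats::sd(host_mean))
  }
})
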