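# Nutrient-abundance correlation: column standardization, categorical
# encoding, the cosine-similarity correlation between abundance and
# feature matrices, and the intra-/inter-host variability ratio.

#' Standardize matrix columns (zero center, unit variance)
#'
#' Each column is centered to mean 0 and scaled to variance 1. Columns
#' with zero variance become all-zero, with a warning, rather than NaN.
#'
#' @param x Numeric matrix or data frame (a `sample_id` column, if
#'   present, is passed through untouched).
#' @return Object of the same shape with standardized numeric columns.
#' @export
standardize <- function(x) {
  is_df <- is.data.frame(x)
  id <- NULL
  if (is_df && "sample_id" %in% names(x)) {
    id <- x["sample_id"]
    x <- x[, setdiff(names(x), "sample_id"), drop = FALSE]
  }
  m <- as.matrix(x)
  if (nrow(m) < 2) abort("standardization needs at least 2 rows")
  centered <- scale(m, center = TRUE, scale = FALSE)
  sds <- apply(m, 2, stats::sd)
  zero_var <- sds == 0
  if (any(zero_var)) {
    warn(sprintf("zero-variance column(s) set to 0: %s",
                 paste(colnames(m)[zero_var], collapse = ", ")))
    sds[zero_var] <- 1
  }
  out <- sweep(centered, 2, sds, `/`)
  attr(out, "scaled:center") <- NULL
  if (is_df) {
    out <- tibble::as_tibble(as.data.frame(out))
    if (!is.null(id)) out <- dplyr::bind_cols(id, out)
  }
  out
}

#' Encode categorical feature columns as numbers
#'
#' Non-numeric columns (or those named in `columns`) are mapped to
#' `0..L-1` with levels taken in lexicographic order, so the encoding is
#' invariant to row order. The mapping is recorded in the result's
#' `encoding_map` attribute.
#'
#' @param features Feature tibble (samples in rows).
#' @param columns Optional character vector naming the categorical
#'   columns; by default every non-numeric column is encoded.
#' @return The feature tibble with encoded columns and an `encoding_map`
#'   attribute (named list of level->code vectors).
#' @export
encode_categorical <- function(features, columns = NULL) {
  features <- tibble::as_tibble(features)
  if (is.null(columns)) {
    columns <- names(features)[!vapply(features, is.numeric, TRUE)]
    columns <- setdiff(columns, "sample_id")
  }
  maps <- list()
  for (col in columns) {
    v <- features[[col]]
    if (is.numeric(v)) next
    suppressWarnings(numeric_like <- !is.na(as.numeric(v[!is.na(v)])))
    if (any(numeric_like) && !all(numeric_like)) {
      abort(sprintf("column '%s' mixes numeric and text values", col))
    }
    levels <- sort(unique(as.character(v)))
    code <- stats::setNames(seq_along(levels) - 1, levels)
    features[[col]] <- unname(code[as.character(v)])
    maps[[col]] <- code
  }
  attr(features, "encoding_map") <- maps
  features
}

#' Cosine-similarity correlation of organisms against features
#'
#' For standardized abundance matrix `B` (samples x organisms) and feature
#' matrix `F` (samples x features), the raw statistic for organism `j` and
#' feature `k` is the sum product `sum_i B[i,j] * F[i,k]`. With
#' `normalize = TRUE` (default) each entry is divided by the product of
#' the two column norms, giving a true cosine similarity bounded in
#' `[-1, 1]` with unit self-similarity; `normalize = FALSE` reproduces
#' the literal unnormalized sum.
#'
#' @param B Abundance matrix/tibble (samples x organisms), standardized.
#' @param F_mat Feature matrix/tibble (samples x features), standardized
#'   and categorical-encoded.
#' @param normalize Divide by column-norm products (default TRUE).
#' @param threshold Marginal evidence threshold recorded on the result
#'   (default 0.7).
#' @return A `correlation_matrix`: tibble with `organism_id` column and
#'   one column per feature, plus `threshold` and `normalized` attributes.
#' @export
cosine_correlation <- function(B, F_mat, normalize = TRUE, threshold = 0.7) {
  drop_id <- function(x) {
    if (is.data.frame(x) && "sample_id" %in% names(x)) {
      x <- x[, setdiff(names(x), "sample_id"), drop = FALSE]
    }
    as.matrix(x)
  }
  bm <- drop_id(B)
  fm <- drop_id(F_mat)
  if (nrow(bm) != nrow(fm)) {
    abort(sprintf("sample count mismatch: %d abundance rows vs %d feature rows",
                  nrow(bm), nrow(fm)))
  }
  cc <- crossprod(bm, fm)
  if (normalize) {
    nb <- sqrt(colSums(bm^2))
    nf <- sqrt(colSums(fm^2))
    denom <- outer(nb, nf)
    cc <- ifelse(denom > 0, cc / denom, 0)
  }
  out <- dplyr::bind_cols(
    tibble::tibble(organism_id = colnames(bm) %||% paste0("V", seq_len(ncol(bm)))),
    tibble::as_tibble(as.data.frame(cc)))
  structure(out, threshold = threshold, normalized = normalize,
            class = c("correlation_matrix", class(out)))
}

#' @importFrom rlang %||%
NULL

#' Entries exceeding the evidence threshold
#'
#' @param correlation A `correlation_matrix`.
#' @param threshold Absolute-value cutoff; defaults to the matrix's own
#'   threshold attribute.
#' @return Long tibble (`organism_id`, `feature`, `correlation`) of
#'   entries with `|correlation| >= threshold`.
#' @export
correlation_hits <- function(correlation,
                             threshold = attr(correlation, "threshold")) {
  tidy.correlation_matrix(correlation) %>%
    dplyr::filter(abs(.data$correlation) >= threshold)
}

#' Intra- versus inter-host variability of organism abundances
#'
#' Intra-host variability is the standard deviation of a host's repeated
#' measurements, averaged over hosts (hosts with a single replicate
#' contribute sd 0 by default). Inter-host variability is the standard
#' deviation of per-host mean abundances. Their ratio estimates the
#' stability of an organism's abundance within a host relative to the
#' cohort spread; it is `NA` when the inter-host sd is 0.
#'
#' @param long_table Tibble with columns `host`, `replicate`,
#'   `organism_id`, `abundance`.
#' @param single_replicate_sd Value contributed by single-replicate hosts
#'   (default 0; set `NA` to drop them from the average).
#' @return Tibble `organism_id`, `intra_host`, `inter_host`, `ratio`.
#' @export
variability_ratio <- function(long_table, single_replicate_sd = 0) {
  long_table <- tibble::as_tibble(long_table)
  if (dplyr::n_distinct(long_table$host) < 2) {
    abort("variability analysis needs at least 2 hosts")
  }
  per_host <- long_table %>%
    dplyr::group_by(.data$organism_id, .data$host) %>%
    dplyr::summarise(
      host_sd = if (dplyr::n() > 1) stats::sd(.data$abundance)
                else single_replicate_sd,
      host_mean = mean(.data$abundance),
      .groups = "drop")
  per_host %>%
    dplyr::group_by(.data$organism_id) %>%
    dplyr::summarise(
      intra_host = mean(.data$host_sd, na.rm = TRUE),
      inter_host = stats::sd(.data$host_mean),
      .groups = "drop") %>%
    dplyr::mutate(ratio = dplyr::if_else(.data$inter_host > 0,
                                         .data$intra_host / .data$inter_host,
                                         NA_real_))
}
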