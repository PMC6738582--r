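# The standardized fecal biome report: Sample/Patient/Result domains,
# top-coverage organism selection, reference-range flags against cohort
# statistics, and a family-collapsed overview.

#' Organisms covering the top fraction of a sample's abundance
#'
#' Takes organisms in descending abundance until their cumulative percent
#' reaches `threshold * 100`, including the organism that crosses it; the
#' result is always a prefix of the abundance-sorted organism list.
#'
#' @param profile An `abundance_profile` (or tibble `organism_id`,
#'   `abundance`).
#' @param threshold Cumulative-abundance coverage in `[0, 1]`
#'   (default 0.5, i.e. the top 50% of inhabitants).
#' @return Tibble `organism_id`, `abundance`, `cumulative` of selected
#'   organisms, in descending abundance.
#' @export
top_fraction <- function(profile, threshold = 0.5) {
  p <- tibble::as_tibble(profile)
  if (nrow(p) == 0 || !"abundance" %in% names(p)) {
    return(tibble::tibble(organism_id = character(0),
                          abundance = numeric(0), cumulative = numeric(0)))
  }
  p <- p %>%
    dplyr::arrange(dplyr::desc(.data$abundance), .data$organism_id) %>%
    dplyr::mutate(cumulative = cumsum(.data$abundance))
  if (nrow(p) == 0) return(p)
  crossing <- which(p$cumulative >= threshold * 100)
  keep <- if (length(crossing) == 0) nrow(p) else crossing[1]
  p[seq_len(keep), ]
}

#' Reference ranges from cohort statistics
#'
#' @param stats A `cohort_stats` tibble (see [cohort_stats()]).
#' @return Tibble `taxon`, `relative_min`, `relative_max`, `mean`,
#'   `median`, `sd`.
#' @export
reference_ranges <- function(stats) {
  tibble::tibble(
    taxon = stats$organism_id,
    relative_min = stats$min,
    relative_max = stats$max,
    mean = stats$mean,
    median = stats$median,
    sd = stats$sd
  )
}

#' Flag a value against a reference range
#'
#' Boundaries are inclusive: a value equal to the observed cohort minimum
#' or maximum is `WITHIN` (it was, by definition, observed in healthy
#' samples).
#'
#' @param value Numeric vector of sample abundances (percent).
#' @param relative_min,relative_max Range bounds (recycled).
#' @return Character vector of `"WITHIN"`, `"ABOVE"`, `"BELOW"` (`NA`
#'   bounds give `NA`).
#' @export
range_flag <- function(value, relative_min, relative_max) {
  dplyr::case_when(
    is.na(relative_min) | is.na(relative_max) ~ NA_character_,
    value < relative_min ~ "BELOW",
    value > relative_max ~ "ABOVE",
    TRUE ~ "WITHIN"
  )
}

#' Family-collapsed reference overview
#'
#' Rolls a species/strain-level abundance matrix up to family rank and
#' computes cohort reference ranges there, with the same zero-exclusion
#' rule as [cohort_stats()].
#'
#' @param matrix An `abundance_matrix` at species or strain rank.
#' @param tree A `taxonomy_tree`.
#' @return Reference-range tibble at family level.
#' @export
family_overview <- function(matrix, tree) {
  reference_ranges(cohort_stats(rollup(matrix, tree, "family")))
}

#' Render the three-domain fecal biome report
#'
#' The Sample domain carries sample and pipeline identifiers, the Patient
#' domain demographic and requester fields, and the Result domain one row
#' per reported organism: its abundance in this sample, the healthy-cohort
#' reference range, a WITHIN/ABOVE/BELOW flag, and an organismal comment
#' drawn verbatim from the knowledgebase (`"not in KB"` when absent). No
#' phenotype interpretation is generated.
#'
#' @param profile An `abundance_profile` for the sample.
#' @param patient_meta Named list of patient fields (missing fields render
#'   as `"NA"`).
#' @param kb A `kb_table` supplying organismal comments.
#' @param ranges Reference-range tibble from [reference_ranges()] or
#'   [family_overview()].
#' @param threshold Cumulative-coverage reporting threshold (default 0.5).
#' @param sample_meta Named list of sample-domain fields (ids, dates,
#'   pipeline identifier).
#' @return A `fecalbiome_report` list with `sample_domain`,
#'   `patient_domain` and `result_domain`.
#' @export
render_report <- function(profile, patient_meta = list(), kb = empty_kb(),
                          ranges = NULL, threshold = 0.5,
                          sample_meta = list()) {
  top <- top_fraction(profile, threshold = threshold)
  comments <- if (nrow(kb$records) > 0) {
    stats::setNames(kb$records$annotations, kb$records$organism_id)
  } else c()
  result <- top %>%
    dplyr::mutate(taxon = .data$organism_id) %>%
    dplyr::left_join(ranges %||%
                       tibble::tibble(taxon = character(0),
                                      relative_min = numeric(0),
                                      relative_max = numeric(0),
                                      mean = numeric(0), median = numeric(0),
                                      sd = numeric(0)),
                     by = "taxon") %>%
    dplyr::mutate(
      flag = range_flag(.data$abundance, .data$relative_min,
                        .data$relative_max),
      comment = dplyr::coalesce(unname(comments[.data$organism_id]),
                                "not in KB")) %>%
    dplyr::select("taxon", "abundance", "relative_min", "relative_max",
                  "mean", "median", "sd", "flag", "comment") %>%
    dplyr::arrange(dplyr::desc(.data$abundance))
  as_chr_domain <- function(meta, defaults) {
    fields <- utils::modifyList(defaults, lapply(meta, as.character))
    lapply(fields, function(v) if (is.null(v) || !nzchar(v)) "NA" else v)
  }
  structure(list(
    sample_domain = as_chr_domain(sample_meta, list(
      sample_id = attr(profile, "sample_id") %||% "NA",
      pipeline = "gutbaseline", report_date = "NA")),
    patient_domain = as_chr_domain(patient_meta, list(
      requester = "NA", gender = "NA", age = "NA", ethnicity = "NA")),
    result_domain = result,
    threshold = threshold
  ), class = "fecalbiome_report")
}

#' @export
print.fecalbiome_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.fecalbiome_report <- function(x, ...) {
  fmt_domain <- function(d) {
    paste0("  ", names(d), ": ", unlist(d))
  }
  num <- function(v) ifelse(is.na(v), "NA", sprintf("%.2f", v))
  rows <- x$result_domain
  c("== FECAL BIOME REPORT ==",
    "-- Sample --", fmt_domain(x$sample_domain),
    "-- Patient --", fmt_domain(x$patient_domain),
    sprintf("-- Result (top %.0f%% of inhabitants) --", 100 * x$threshold),
    sprintf("  %-40s %8s %17s %7s  %s", "Taxon", "Abund%", "Range[min-max]",
            "Flag", "Comment"),
    sprintf("  %-40s %8s %8s-%8s %7s  %s",
            rows$taxon, num(rows$abundance), num(rows$relative_min),
            num(rows$relative_max),
            ifelse(is.na(rows$flag), "NA", rows$flag),
            substr(rows$comment, 1, 40)))
}

#' Serialize a report as JSON
#'
#' @param report A `fecalbiome_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(list(
    sample_domain = report$sample_domain,
    patient_domain = report$patient_domain,
    result_domain = report$result_domain,
    threshold = report$threshold
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path JSON path written by [write_report_json()].
#' @return A `fecalbiome_report`.
#' @export
read_report_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    sample_domain = as.list(x$sample_domain),
    patient_domain = as.list(x$patient_domain),
    result_domain = tibble::as_tibble(x$result_domain),
    threshold = x$threshold
  ), class = "fecalbiome_report")
}
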