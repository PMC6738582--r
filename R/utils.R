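# Internal helpers shared across modules.

#' @importFrom rlang .data abort warn .env
#' @importFrom dplyr %>%
NULL

# Run an expression with a temporarily-seeded RNG, restoring the caller's
# RNG state afterwards so library code never perturbs user simulations.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Coerce a path or data frame to a tibble, reading TSV when given a path.
as_table_input <- function(x, col_types = NULL) {
  if (is.character(x) && length(x) == 1) {
    readr::read_tsv(x, col_types = col_types, show_col_types = FALSE,
                    progress = FALSE)
  } else {
    tibble::as_tibble(x)
  }
}

# Coerce FASTA input (path or DNAStringSet) to a DNAStringSet.
as_fasta_input <- function(x) {
  if (is.character(x) && length(x) == 1) {
    Biostrings::readDNAStringSet(x)
  } else if (methods::is(x, "DNAStringSet")) {
    x
  } else {
    abort("expected a FASTA path or a DNAStringSet")
  }
}

#' @importFrom methods is
NULL

first_token <- function(x) sub("\\s.*$", "", x)

#' Re-exported pipe and tidier generics
#'
#' See \code{dplyr::\link[dplyr]{\%>\%}}, \code{generics::\link[generics]{tidy}}
#' and \code{generics::\link[generics]{glance}}.
#'
#' @name reexports
#' @aliases %>% tidy glance
#' @importFrom generics tidy glance
#' @export %>%
#' @export tidy
#' @export glance
NULL
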