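#' Bundled reference tabulations from the national NT program evaluation
#'
#' Small published summary tables shipped as plain-text data under
#' `inst/extdata/`, used in worked examples and consistency checks:
#'
#' * `reference_adherence_cases()` expands the published NT-direction by
#'   injunction-direction cell counts (with authorship split) into a
#'   case-level `data.frame` suitable for [crosstab_agreement()]. The
#'   marginal cells and per-author agreement counts are published; the
#'   joint authorship-by-cell allocation is not, so one allocation
#'   consistent with all published margins is used (every agreement and
#'   citation statistic depends only on the margins). Claim values on these
#'   rows are placeholders — the table carries no monetary information.
#' * `reference_program_counts()` returns the yearly NT counts for the
#'   2020-2022 triennium (all authors and HIAE) and HIAE direct program
#'   costs in BRL, as published.
#' * `reference_per_case_estimates()` returns the published per-case
#'   saving point estimate and interval bounds (BRL per case per year).
#'
#' @return See each function's description.
#' @name reference-data
NULL

ref_path <- function(f) system.file("extdata", f, package = "judimpact",
                                    mustWork = TRUE)

#' @rdname reference-data
#' @export
reference_adherence_cases <- function() {
  tab <- utils::read.csv(ref_path("reference_adherence.csv"),
                         stringsAsFactors = FALSE)
  idx <- rep(seq_len(nrow(tab)), tab$n)
  n <- length(idx)
  as_case_df(data.frame(
    case_id = sprintf("ref_%03d", seq_len(n)),
    filing_year = 2021L,
    court = "reference",
    claim_type = "medication",
    value_brl = 1,
    has_nt = TRUE,
    nt_direction = tab$nt_direction[idx],
    nt_author = tab$nt_author[idx],
    nt_cited = TRUE,
    injunction_direction = tab$injunction_direction[idx],
    excluded_reason = NA_character_,
    stringsAsFactors = FALSE
  ))
}

#' @rdname reference-data
#' @export
reference_program_counts <- function() {
  utils::read.csv(ref_path("reference_program.csv"), stringsAsFactors = FALSE)
}

#' @rdname reference-data
#' @export
reference_per_case_estimates <- function() {
  tab <- utils::read.csv(ref_path("reference_estimates.csv"),
                         stringsAsFactors = FALSE)
  stats::setNames(tab$value_brl, tab$quantity)
}
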