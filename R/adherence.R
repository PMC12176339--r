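#' Cross-tabulate NT directions against injunction outcomes
#'
#' Builds the 2x2 table of technical-note direction versus judicial
#' decision and the agreement percentage (concordant cells over all
#' cells). Optionally restricted to one authorship stratum. Percentages
#' are kept at full precision; reports round half-up to one decimal.
#'
#' @param cases NT-bearing case `data.frame`; every case used must have
#'   both `nt_direction` and `injunction_direction` recorded.
#' @param stratum optional `"HIAE"` or `"other"` to filter by `nt_author`.
#' @return object of class `adherence_table`: `counts` (2x2 integer matrix,
#'   NT direction in rows, injunction direction in columns),
#'   `agreement_pct`, `n`, `stratum`.
#' @export
crosstab_agreement <- function(cases, stratum = NULL) {
  use <- cases$has_nt & !is.na(cases$nt_direction) &
    !is.na(cases$injunction_direction)
  if (!is.null(stratum)) {
    stratum <- match.arg(stratum, author_levels)
    use <- use & !is.na(cases$nt_author) & cases$nt_author == stratum
  }
  sub <- cases[use, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop_ji("agreement undefined: no cases with both directions%s",
            if (is.null(stratum)) "" else sprintf(" in stratum '%s'", stratum),
            class = "undefined_statistic_error")
  counts <- table(nt = factor(sub$nt_direction, direction_levels),
                  injunction = factor(sub$injunction_direction, direction_levels))
  counts <- matrix(as.integer(counts), 2, 2, dimnames = dimnames(counts))
  agreement <- 100 * sum(diag(counts)) / sum(counts)
  structure(list(counts = counts, agreement_pct = agreement,
                 n = sum(counts), stratum = stratum),
            class = "adherence_table")
}

#' @export
print.adherence_table <- function(x, ...) {
  cat(sprintf("NT/injunction agreement%s: %.1f%% of %d cases\n",
              if (is.null(x$stratum)) "" else paste0(" (", x$stratum, ")"),
              round_half_up(x$agreement_pct, 1), x$n))
  print(x$counts)
  invisible(x)
}

#' Citation rate of technical notes in rulings
#'
#' Percentage of NT-bearing cases whose decision report references the NT,
#' pooled or within an authorship stratum. Cases with an unrecorded
#' `nt_cited` flag are excluded from the denominator.
#'
#' @param cases NT-bearing case `data.frame` with `nt_cited` flags.
#' @param stratum optional `"HIAE"` or `"other"`.
#' @return list with `pct`, `cited`, `n`, `stratum`.
#' @export
citation_rate <- function(cases, stratum = NULL) {
  use <- cases$has_nt & !is.na(cases$nt_cited)
  if (!is.null(stratum)) {
    stratum <- match.arg(stratum, author_levels)
    use <- use & !is.na(cases$nt_author) & cases$nt_author == stratum
  }
  sub <- cases[use, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop_ji("citation rate undefined: empty stratum",
            class = "undefined_statistic_error")
  list(pct = 100 * mean(sub$nt_cited), cited = sum(sub$nt_cited),
       n = nrow(sub), stratum = stratum)
}

#' Full adherence report (pooled and per-author)
#'
#' @param cases NT-bearing case `data.frame`.
#' @return list with `pooled`, `by_author` (per-stratum tables where the
#'   stratum is non-empty) and `citation` (pooled + per-author rates).
#' @export
adherence_report <- function(cases) {
  by_author <- list()
  citation <- list()
  ok <- function(expr) tryCatch(expr, judimpact_error = function(e) NULL)
  for (a in author_levels) {
    tab <- ok(crosstab_agreement(cases, stratum = a))
    if (!is.null(tab)) by_author[[a]] <- tab
    citation[[a]] <- ok(citation_rate(cases, stratum = a))
  }
  list(pooled = crosstab_agreement(cases), by_author = by_author,
       citation = c(list(pooled = ok(citation_rate(cases))), citation))
}

#' Serialize an adherence report to JSON
#'
#' @param report an [adherence_report()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_adherence <- function(report, path) {
  tab_json <- function(t) if (is.null(t)) NULL else
    list(counts = as.data.frame(as.table(t$counts)),
         agreement_pct = t$agreement_pct,
         agreement_pct_reported = round_half_up(t$agreement_pct, 1), n = t$n)
  cite_json <- function(r) if (is.null(r)) NULL else
    list(pct = r$pct, pct_reported = round_half_up(r$pct, 1),
         cited = r$cited, n = r$n)
  jsonlite::write_json(list(
    schema = "judimpact/adherence/1",
    pooled = tab_json(report$pooled),
    by_author = lapply(report$by_author, tab_json),
    citation = lapply(report$citation, cite_json)
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
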