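#' Aggregate per-case savings to program level
#'
#' Scales a per-case estimate (point and interval bounds, BRL per case per
#' year) by the number of technical notes issued each year, then totals.
#' Arithmetic is exact at full precision; rounding happens only at the
#' reporting layer.
#'
#' @param per_case_point per-case point estimate (BRL/case/year).
#' @param counts named integer vector, NT count per year.
#' @param per_case_low,per_case_high optional per-case interval bounds.
#' @return object of class `program_savings`: `per_year` `data.frame`
#'   (`year`, `nt_count`, `low_brl`, `point_brl`, `high_brl`), `totals`
#'   (one-row `data.frame`), `per_case_point_brl`.
#' @export
#' @examples
#' aggregate_program_savings(1312.74, c(`2020` = 11441, `2021` = 38427,
#'                                      `2022` = 35010))
aggregate_program_savings <- function(per_case_point, counts,
                                      per_case_low = NA_real_,
                                      per_case_high = NA_real_) {
  counts <- unlist(counts)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop_ji("NT counts must be non-negative integers", class = "config_error")
  if (!is.finite(per_case_point))
    stop_ji("per-case point estimate must be finite", class = "config_error")
  yrs <- names(counts) %||% as.character(seq_along(counts))
  per_year <- data.frame(
    year = yrs, nt_count = as.integer(counts),
    low_brl = counts * per_case_low,
    point_brl = counts * per_case_point,
    high_brl = counts * per_case_high,
    stringsAsFactors = FALSE, row.names = NULL
  )
  totals <- data.frame(nt_count = sum(per_year$nt_count),
                       low_brl = sum(per_year$low_brl),
                       point_brl = sum(per_year$point_brl),
                       high_brl = sum(per_year$high_brl))
  structure(list(per_year = per_year, totals = totals,
                 per_case_point_brl = per_case_point),
            class = "program_savings")
}

#' @export
print.program_savings <- function(x, ...) {
  cat("Program-level savings (BRL, per-case point",
      sprintf("%.2f)\n", x$per_case_point_brl))
  tab <- rbind(x$per_year[, -1], cbind(x$totals))
  rownames(tab) <- c(x$per_year$year, "total")
  print(round_half_up(as.matrix(tab), 2))
  invisible(x)
}

#' Define a price-index series for reference-year adjustment
#'
#' @param values named positive numeric vector: index value per year.
#' @param reference_year year monetary amounts are expressed in after
#'   adjustment; must be covered by `values`.
#' @return object of class `price_index_series`.
#' @export
price_index_series <- function(values, reference_year) {
  values <- unlist(values)
  if (is.null(names(values)) || any(!is.finite(values)) || any(values <= 0))
    stop_ji("index values must be a named vector of positive numbers",
            class = "config_error")
  if (!as.character(reference_year) %in% names(values))
    stop_ji("reference year %s is not covered by the index", reference_year,
            class = "coverage_error")
  structure(list(values = values, reference_year = as.integer(reference_year)),
            class = "price_index_series")
}

#' Adjust yearly amounts to the reference year
#'
#' Inflates (or deflates) nominal yearly BRL amounts to reference-year
#' values: `amount[y] * index[reference] / index[y]`. Reference-year
#' amounts pass through unchanged. No index is hard-coded; users supply the
#' series appropriate to their setting (for Brazilian health spending the
#' national consumer price index, IPCA, is the usual choice).
#'
#' @param amounts named numeric vector of BRL amounts by year.
#' @param index a [price_index_series()] covering every amount year.
#' @return named numeric vector of adjusted amounts.
#' @export
adjust_to_reference <- function(amounts, index) {
  stopifnot(inherits(index, "price_index_series"))
  amounts <- unlist(amounts)
  yrs <- names(amounts)
  if (is.null(yrs)) stop_ji("amounts must be named by year", class = "config_error")
  missing_years <- setdiff(yrs, names(index$values))
  if (length(missing_years))
    stop_ji("price index does not cover year(s): %s",
            paste(missing_years, collapse = ", "), class = "coverage_error")
  ref <- index$values[[as.character(index$reference_year)]]
  amounts * ref / index$values[yrs]
}

#' Return on investment
#'
#' `ROI = (benefit - cost) / cost`, dimensionless; multiply by 100 for the
#' percentage form used in reporting. Both arguments must be expressed in
#' the same reference-year currency.
#'
#' @param benefit_brl total benefit (BRL).
#' @param cost_brl total cost (BRL); must be positive.
#' @return object of class `cost_benefit`: `benefit_brl`, `cost_brl`,
#'   `roi`, `roi_pct`.
#' @export
#' @examples
#' compute_roi(27205223.76, 10227301.59)  # roi ~ 1.66
compute_roi <- function(benefit_brl, cost_brl) {
  if (!is.finite(cost_brl) || cost_brl <= 0)
    stop_ji("cost must be positive to compute an ROI", class = "domain_error")
  roi <- (benefit_brl - cost_brl) / cost_brl
  structure(list(benefit_brl = benefit_brl, cost_brl = cost_brl,
                 roi = roi, roi_pct = 100 * roi),
            class = "cost_benefit")
}

#' @export
print.cost_benefit <- function(x, ...) {
  cat(sprintf("Benefit BRL %.2f against cost BRL %.2f: ROI %.2f (%s%%)\n",
              x$benefit_brl, x$cost_brl, round_half_up(x$roi, 2),
              format(round_half_up(x$roi_pct, 1), nsmall = 1)))
  invisible(x)
}
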