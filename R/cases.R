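#' @name case-schema
#' @title Litigation case records
#'
#' @description
#' The unit of analysis is one lawsuit claiming a health service (a
#' medication, a treatment or a medical procedure) from the public payer,
#' possibly informed by a technical note (NT) from a judicial
#' health-technology-assessment unit. A case collection is a plain
#' `data.frame` with one row per lawsuit and the columns:
#'
#' \describe{
#'   \item{case_id}{character, opaque identifier.}
#'   \item{filing_year}{integer year.}
#'   \item{court}{factor, court label.}
#'   \item{claim_type}{factor: `medication`, `treatment`, `procedure`.}
#'   \item{value_brl}{positive numeric, annualized monetary value of the
#'     claim in BRL per year. Values are stored annualized once; no
#'     multi-year expansion is ever performed.}
#'   \item{has_nt}{logical, whether a technical note exists for the case.}
#'   \item{nt_direction}{factor `favorable`/`unfavorable` (to the patient);
#'     `NA` iff `has_nt` is `FALSE`.}
#'   \item{nt_author}{factor `HIAE`/`other`; `NA` iff no NT.}
#'   \item{nt_cited}{logical, whether the ruling cites the NT; `NA` iff no NT.}
#'   \item{injunction_direction}{factor `favorable`/`unfavorable`, the
#'     preliminary-injunction outcome; may be `NA` (no injunction recorded).}
#'   \item{excluded_reason}{factor `confidential`, `missing_info`,
#'     `non_health_claim`, or `NA`; a non-`NA` value removes the case from
#'     every downstream computation.}
#' }
#'
#' CSV serialization is UTF-8, comma-separated, with a mandatory header and
#' a decimal *point* in `value_brl` regardless of locale (BRL amounts in
#' Brazilian sources use a decimal comma; files must be converted before
#' reading). Missing optional fields are empty strings.
NULL

claim_levels <- c("medication", "treatment", "procedure")
direction_levels <- c("favorable", "unfavorable")
author_levels <- c("HIAE", "other")
exclusion_levels <- c("confidential", "missing_info", "non_health_claim")

case_columns <- c(
  "case_id", "filing_year", "court", "claim_type", "value_brl", "has_nt",
  "nt_direction", "nt_author", "nt_cited", "injunction_direction",
  "excluded_reason"
)

# canonicalize categorical spellings; returns NA for unknown labels
canon_label <- function(x, levels, map = NULL) {
  x <- trimws(x)
  x[x == ""] <- NA_character_
  lx <- tolower(x)
  if (!is.null(map)) {
    hit <- match(lx, names(map))
    x[!is.na(hit)] <- map[hit[!is.na(hit)]]
    lx <- tolower(x)
  }
  out <- levels[match(lx, tolower(levels))]
  out[is.na(x)] <- NA_character_
  out
}

canon_logical <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Validate a case collection against the schema invariants
#'
#' Checks each row of a case `data.frame` (see [case-schema]) and returns a
#' character vector of per-row problems (`NA` where the row is valid).
#' Rows flagged with an `excluded_reason` are exempt from the value and
#' injunction requirements: they were annotated only far enough to be
#' classified out.
#'
#' @param cases case `data.frame`.
#' @return character vector, one element per row; `NA` means valid.
#' @export
validate_cases <- function(cases) {
  n <- nrow(cases)
  problem <- rep(NA_character_, n)
  note <- function(bad, msg) {
    bad <- which(bad & is.na(problem))
    problem[bad] <<- msg
  }
  excl <- !is.na(cases$excluded_reason)
  note(is.na(cases$case_id) | cases$case_id == "", "missing case_id")
  note(is.na(cases$filing_year), "missing or non-integer filing_year")
  note(!excl & (is.na(cases$value_brl) | cases$value_brl <= 0),
       "value_brl missing or non-positive on a non-excluded row")
  note(is.na(cases$has_nt), "missing has_nt")
  nt <- !is.na(cases$has_nt) & cases$has_nt
  note(nt & is.na(cases$nt_direction),
       "has_nt is true but nt_direction is absent")
  note(nt & is.na(cases$nt_author), "has_nt is true but nt_author is absent")
  note(nt & is.na(cases$nt_cited), "has_nt is true but nt_cited is absent")
  no_nt <- !is.na(cases$has_nt) & !cases$has_nt
  note(no_nt & (!is.na(cases$nt_direction) | !is.na(cases$nt_author) |
                  !is.na(cases$nt_cited)),
       "has_nt is false but NT fields are present")
  problem
}

#' Read litigation cases from CSV
#'
#' Parses a case CSV (see [case-schema] for the column contract), normalizes
#' categorical spellings to their canonical form (case-insensitive;
#' `"others"` maps to `"other"`), and validates every row. Valid rows are
#' returned in file order; invalid rows are dropped and reported in the
#' `"rejected"` attribute, a `data.frame` with the offending file row number
#' and the reason.
#'
#' @param path path to a CSV file.
#' @param schema_version schema tag the file must carry no marker for;
#'   currently only `"1"` is understood.
#' @return case `data.frame` with attribute `rejected`.
#' @seealso [write_cases()], [apply_exclusions()]
#' @export
read_cases <- function(path, schema_version = "1") {
  if (!file.exists(path)) stop_ji("file not found: %s", path, class = "io_error")
  if (!identical(schema_version, "1"))
    stop_ji("unknown schema version '%s'", schema_version, class = "schema_error")
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(case_columns, names(raw))
  if (length(missing_cols))
    stop_ji("missing mandatory column(s): %s",
            paste(missing_cols, collapse = ", "), class = "schema_error")

  yr <- suppressWarnings(as.integer(trimws(raw$filing_year)))
  val <- suppressWarnings(as.numeric(trimws(raw$value_brl)))
  val[trimws(raw$value_brl) == ""] <- NA_real_
  court <- trimws(raw$court)
  court[court == ""] <- NA_character_
  cases <- data.frame(
    case_id = trimws(raw$case_id),
    filing_year = yr,
    court = court,
    claim_type = canon_label(raw$claim_type, claim_levels),
    value_brl = val,
    has_nt = canon_logical(raw$has_nt),
    nt_direction = canon_label(raw$nt_direction, direction_levels),
    nt_author = canon_label(raw$nt_author, author_levels,
                            map = c(hiae = "HIAE", others = "other")),
    nt_cited = canon_logical(raw$nt_cited),
    injunction_direction = canon_label(raw$injunction_direction, direction_levels),
    excluded_reason = canon_label(raw$excluded_reason, exclusion_levels),
    stringsAsFactors = FALSE
  )
  # unknown (non-empty, non-canonical) labels are row errors, not silent NAs
  bad_label <- rep(NA_character_, nrow(raw))
  flag <- function(col, parsed, what) {
    bad <- trimws(raw[[col]]) != "" & is.na(parsed) & is.na(bad_label)
    bad_label[bad] <<- sprintf("unrecognized %s '%s'", what,
                               trimws(raw[[col]][bad]))
  }
  flag("claim_type", cases$claim_type, "claim_type")
  flag("nt_direction", cases$nt_direction, "nt_direction")
  flag("nt_author", cases$nt_author, "nt_author")
  flag("injunction_direction", cases$injunction_direction, "injunction_direction")
  flag("excluded_reason", cases$excluded_reason, "excluded_reason")
  flag("has_nt", cases$has_nt, "has_nt")
  flag("nt_cited", cases$nt_cited, "nt_cited")
  flag("value_brl", cases$value_brl, "value_brl")
  flag("filing_year", cases$filing_year, "filing_year")

  problem <- validate_cases(cases)
  problem[is.na(problem) & !is.na(bad_label)] <- bad_label[is.na(problem) & !is.na(bad_label)]
  keep <- is.na(problem)
  rejected <- data.frame(row = which(!keep), reason = problem[!keep],
                         stringsAsFactors = FALSE)
  out <- as_case_df(cases[keep, , drop = FALSE])
  attr(out, "rejected") <- rejected
  out
}

# coerce canonical character columns to the schema's factor/logical types
as_case_df <- function(cases) {
  cases$court <- factor(cases$court)
  cases$claim_type <- factor(cases$claim_type, levels = claim_levels)
  cases$nt_direction <- factor(cases$nt_direction, levels = direction_levels)
  cases$nt_author <- factor(cases$nt_author, levels = author_levels)
  cases$injunction_direction <- factor(cases$injunction_direction,
                                       levels = direction_levels)
  cases$excluded_reason <- factor(cases$excluded_reason, levels = exclusion_levels)
  rownames(cases) <- NULL
  cases
}

#' Write litigation cases to CSV
#'
#' Inverse of [read_cases()]: writes the standard case CSV (UTF-8, comma
#' separator, decimal point, header row, empty string for `NA`).
#' `read_cases(write_cases(x))` is the identity on valid collections.
#'
#' @param cases case `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cases <- function(cases, path) {
  out <- cases[, case_columns]
  for (nm in names(out)) {
    if (is.factor(out[[nm]])) out[[nm]] <- as.character(out[[nm]])
    if (is.logical(out[[nm]])) out[[nm]] <- ifelse(is.na(out[[nm]]), NA_character_,
                                                   ifelse(out[[nm]], "true", "false"))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8",
                   quote = TRUE)
  invisible(path)
}

#' Apply exclusion and cleaning rules
#'
#' Splits a case collection into the retained analysis set and an audit of
#' exclusions, mirroring the annotation-stage cleaning of litigation
#' databases: cases are removed for legal confidentiality, missing
#' information, or because the claim is not a health claim. Exclusion is
#' classification, not failure — no error is ever raised for an excluded row.
#'
#' Beyond pre-flagged `excluded_reason` values, any case missing one of the
#' `required_fields` is classified `missing_info`. The default field list is
#' the minimal covariate/outcome set every downstream model needs.
#'
#' @param cases case `data.frame`.
#' @param required_fields character, columns that must be non-`NA` for a
#'   case to be analyzable.
#' @return list with `retained` (case `data.frame`, all invariants holding)
#'   and `audit` (named integer vector of counts per exclusion reason;
#'   reasons with zero count are dropped). `length(cases) = nrow(retained) +
#'   sum(audit)` always.
#' @export
apply_exclusions <- function(cases,
                             required_fields = c("filing_year", "court",
                                                 "claim_type", "value_brl")) {
  stopifnot(all(required_fields %in% names(cases)))
  reason <- as.character(cases$excluded_reason)
  miss <- Reduce(`|`, lapply(required_fields, function(f) is.na(cases[[f]])))
  reason[is.na(reason) & miss] <- "missing_info"
  retained <- cases[is.na(reason), , drop = FALSE]
  rownames(retained) <- NULL
  audit_tab <- table(factor(reason, levels = exclusion_levels))
  audit <- stats::setNames(as.integer(audit_tab), names(audit_tab))
  audit <- audit[audit > 0]
  list(retained = retained, audit = audit)
}

#' Write an exclusion audit as JSON
#'
#' @param audit named integer vector from [apply_exclusions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_audit <- function(audit, path) {
  jsonlite::write_json(list(schema = "judimpact/audit/1",
                            excluded = as.list(audit),
                            total_excluded = sum(audit)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
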