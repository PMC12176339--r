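#' Build a run configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]: the
#' generator settings, the model backend, bootstrap size, the yearly NT
#' counts used for program aggregation, optional yearly direct costs (for
#' ROI) and an optional price index for reference-year adjustment.
#' `run_config_from_yaml()` reads the same structure from a YAML file.
#'
#' @param generator a [generator_config()] or a plain list of its arguments.
#' @param backend model backend tag.
#' @param n_bootstrap bootstrap replicates for the savings estimate.
#' @param seed integer master seed (overrides the generator's seed).
#' @param counts_by_year named vector, NT count per year.
#' @param costs_by_year optional named vector, direct program cost per year
#'   (BRL); enables the ROI stage.
#' @param price_index optional [price_index_series()] (or list with
#'   `values` and `reference_year`) applied to per-year savings and costs.
#' @return object of class `run_config`.
#' @export
run_config <- function(generator = list(), backend = "forest",
                       n_bootstrap = 200, seed = 1L,
                       counts_by_year = c(`2020` = 11441, `2021` = 38427,
                                          `2022` = 35010),
                       costs_by_year = NULL, price_index = NULL) {
  if (!inherits(generator, "generator_config"))
    generator <- do.call(generator_config, generator)
  generator$seed <- as.integer(seed)
  if (!is.null(price_index) && !inherits(price_index, "price_index_series"))
    price_index <- price_index_series(price_index$values, price_index$reference_year)
  structure(list(generator = generator,
                 backend = match.arg(backend, backend_tags),
                 n_bootstrap = n_bootstrap, seed = as.integer(seed),
                 counts_by_year = counts_by_year,
                 costs_by_year = costs_by_year, price_index = price_index),
            class = "run_config")
}

#' @rdname run_config
#' @param path path to a YAML file whose top-level keys are the
#'   `run_config()` arguments.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop_ji("pipeline stage '%s' failed: %s", name, conditionMessage(e),
            class = "pipeline_error")
  })
  message(sprintf("[judimpact] %-10s %6.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full impact-evaluation pipeline on synthetic data
#'
#' One-shot end-to-end runner: generates a synthetic case collection,
#' applies exclusions, fits the counterfactual model, estimates per-case
#' savings with bootstrap intervals, computes adherence statistics,
#' aggregates program-level savings from the configured yearly NT counts
#' (price-adjusted if an index is supplied), and — when direct costs are
#' configured — the program ROI. All artifacts are written to `out_dir`:
#' `cases.csv`, `audit.json`, `model_meta.json`, `estimate.json`,
#' `adherence.json`, `program.json` and a human-readable `summary.txt`.
#' Every number in the summary is recomputable from the written artifacts.
#'
#' @param config a [run_config()] (or YAML path).
#' @param out_dir output directory, created if absent.
#' @return invisibly, a list with all in-memory results (`cases`,
#'   `retained`, `audit`, `estimate`, `adherence`, `program`, `roi`,
#'   `paths`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- run_config_from_yaml(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  cases <- stage("simulate", {
    x <- generate_cases(config$generator)
    write_cases(x, p("cases.csv"))
    x
  })
  cleaned <- stage("exclude", {
    x <- apply_exclusions(cases)
    write_audit(x$audit, p("audit.json"))
    x
  })
  estimate <- stage("estimate", {
    e <- estimate_savings(cleaned$retained, backend = config$backend,
                          n_bootstrap = config$n_bootstrap, seed = config$seed)
    write_estimate(e, p("estimate.json"))
    jsonlite::write_json(c(list(schema = "judimpact/model_meta/1",
                                backend = e$backend, seed = e$seed),
                           e$train_meta),
                         p("model_meta.json"), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    e
  })
  adherence <- stage("adherence", {
    a <- adherence_report(cleaned$retained)
    write_adherence(a, p("adherence.json"))
    a
  })
  program_roi <- stage("aggregate", {
    prog <- aggregate_program_savings(estimate$point_median_brl,
                                      config$counts_by_year,
                                      per_case_low = estimate$ci_low_brl,
                                      per_case_high = estimate$ci_high_brl)
    benefit_by_year <- stats::setNames(prog$per_year$point_brl, prog$per_year$year)
    roi <- NULL
    if (!is.null(config$price_index)) {
      benefit_by_year <- adjust_to_reference(benefit_by_year, config$price_index)
    }
    if (!is.null(config$costs_by_year)) {
      costs <- unlist(config$costs_by_year)
      if (!is.null(config$price_index)) costs <- adjust_to_reference(costs, config$price_index)
      roi <- compute_roi(sum(benefit_by_year), sum(costs))
    }
    out <- list(schema = "judimpact/program/1",
                per_case_point_brl = prog$per_case_point_brl,
                per_year = prog$per_year, totals = prog$totals)
    if (!is.null(roi)) out$roi <- unclass(roi)
    jsonlite::write_json(out, p("program.json"), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    list(program = prog, roi = roi)
  })

  stage("summary", {
    con <- file(p("summary.txt"), "w"); on.exit(close(con))
    w <- function(...) writeLines(sprintf(...), con)
    w("judimpact pipeline summary")
    w("backend: %s  seed: %d  bootstrap: %d", config$backend, config$seed,
      config$n_bootstrap)
    w("cases generated: %d  retained: %d  excluded: %d", nrow(cases),
      nrow(cleaned$retained), sum(cleaned$audit))
    w("median saving per case/year: BRL %.2f (CI %.2f to %.2f)",
      estimate$point_median_brl, estimate$ci_low_brl, estimate$ci_high_brl)
    w("mean saving per case/year:   BRL %.2f", estimate$point_mean_brl)
    w("pooled NT/decision agreement: %.1f%% (n = %d)",
      round_half_up(adherence$pooled$agreement_pct, 1), adherence$pooled$n)
    w("program savings point total: BRL %.2f over %d NTs",
      program_roi$program$totals$point_brl, program_roi$program$totals$nt_count)
    if (!is.null(program_roi$roi))
      w("ROI: %.2f (%.1f%%)", program_roi$roi$roi, program_roi$roi$roi_pct)
    NULL
  })

  invisible(list(cases = cases, retained = cleaned$retained,
                 audit = cleaned$audit, estimate = estimate,
                 adherence = adherence, program = program_roi$program,
                 roi = program_roi$roi,
                 paths = vapply(c("cases.csv", "audit.json", "model_meta.json",
                                  "estimate.json", "adherence.json",
                                  "program.json", "summary.txt"), p, "")))
}
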