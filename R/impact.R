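#' Counterfactual probability of a favorable injunction
#'
#' For a case that was decided *without* a technical note, answers: had an
#' NT been available, what is the probability the injunction would have
#' been favorable to the patient? Model 1 supplies the chance the NT would
#' have been favorable; Model 2 supplies the injunction probability under
#' each NT direction; the counterfactual mixes the two:
#'
#' \deqn{p_{cf}(x) = p_1(x)\,m_2(x, fav) + (1 - p_1(x))\,m_2(x, unfav)}
#'
#' @param model an [fit_impact_model()] result.
#' @param cases case `data.frame`; every row must have `has_nt = FALSE`
#'   (the counterfactual is only defined for NT-less cases).
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
counterfactual_probability <- function(model, cases) {
  if (any(cases$has_nt))
    stop_ji("counterfactual probability is only defined for cases without an NT",
            class = "domain_error")
  X <- design_matrix(model$prep, cases)
  p1 <- predict_p1(model, X)
  n <- nrow(X)
  # both NT states in one stacked Model-2 query
  p2 <- predict_p2(model, X[rep(seq_len(n), 2), , drop = FALSE],
                   rep(c(1, 0), each = n))
  p1 * p2[seq_len(n)] + (1 - p1) * p2[n + seq_len(n)]
}

#' Per-case expected saving from a decision change
#'
#' The economic quantity of the analysis: when an injunction that was
#' favorable to the patient would have been reversed by an NT-informed
#' decision, the public payer saves the annualized claim value; the
#' opposite reversal is a loss; no reversal is zero. Taking the expectation
#' over the counterfactual decision gives the signed expected saving:
#'
#' * observed favorable: `value_brl * (1 - p_cf)`
#' * observed unfavorable: `-value_brl * p_cf`
#'
#' so `|saving| <= value_brl` always, and the sign nets savings against
#' losses.
#'
#' @param cases case `data.frame` with `has_nt = FALSE` and observed
#'   `injunction_direction`.
#' @param p_cf counterfactual probabilities from
#'   [counterfactual_probability()], one per case.
#' @return numeric vector of signed expected savings (BRL per case per year).
#' @export
per_case_saving <- function(cases, p_cf) {
  if (any(cases$has_nt))
    stop_ji("savings are only defined for cases decided without an NT",
            class = "domain_error")
  if (anyNA(cases$injunction_direction))
    stop_ji("savings require an observed injunction_direction", class = "domain_error")
  stopifnot(length(p_cf) == nrow(cases), all(p_cf >= 0 & p_cf <= 1))
  ifelse(cases$injunction_direction == "favorable",
         cases$value_brl * (1 - p_cf),
         -cases$value_brl * p_cf)
}

# fit on the NT subset, score the NT-less subset; the one step every
# bootstrap replicate repeats
savings_once <- function(train, eval_cases, backend, seed, num_trees,
                         min_node_size, min_train, compute_meta = TRUE) {
  model <- fit_impact_model(train, backend = backend, seed = seed,
                            num_trees = num_trees,
                            min_node_size = min_node_size,
                            min_train = min_train, compute_meta = compute_meta)
  p_cf <- counterfactual_probability(model, eval_cases)
  list(model = model, p_cf = p_cf,
       saving = per_case_saving(eval_cases, p_cf))
}

#' Point estimate of the per-case saving (no interval)
#'
#' Fits the chosen backend once on the NT-bearing cases and returns the
#' median and mean of the signed per-case expected savings over the NT-less
#' cases. [estimate_savings()] wraps this with bootstrap intervals.
#'
#' @inheritParams estimate_savings
#' @return list with `median_brl`, `mean_brl`, `n_train`, `n_eval`.
#' @export
savings_point_estimate <- function(cases, backend = "forest", seed = 1L,
                                   num_trees = 500, min_node_size = NULL,
                                   min_train = 50) {
  sp <- split_analysis_sets(cases)
  fit <- savings_once(sp$train, sp$eval, backend, seed, num_trees,
                      min_node_size, min_train)
  list(median_brl = stats::median(fit$saving), mean_brl = mean(fit$saving),
       n_train = nrow(sp$train), n_eval = nrow(sp$eval))
}

split_analysis_sets <- function(cases) {
  if (any(!is.na(cases$excluded_reason)))
    stop_ji("excluded cases must be removed (apply_exclusions) before estimation",
            class = "domain_error")
  train <- cases[cases$has_nt & !is.na(cases$nt_direction) &
                   !is.na(cases$injunction_direction), , drop = FALSE]
  eval_cases <- cases[!cases$has_nt & !is.na(cases$injunction_direction), ,
                      drop = FALSE]
  if (nrow(eval_cases) == 0L)
    stop_ji("no NT-less cases with observed injunctions: nothing to estimate",
            class = "estimation_error")
  list(train = train, eval = eval_cases)
}

#' Estimate per-case savings with bootstrap intervals
#'
#' The full counterfactual savings estimator. The NT-bearing cases are the
#' training set; the NT-less cases with observed injunctions are the
#' evaluation set. The point estimates (median and mean of signed per-case
#' savings) come from the full-data fit. Uncertainty stems from model
#' estimation, so the bootstrap resamples the *training* cases with
#' replacement, refits, and re-scores the fixed evaluation set; the
#' interval is the percentile interval of the bootstrap medians. A
#' resample in which either training outcome is single-class cannot be fit
#' and is redrawn (up to `max_redraws` extra draws, counted in
#' `n_degenerate_redrawn`).
#'
#' @param cases case `data.frame` containing both NT and NT-less cases
#'   (exclusions already applied).
#' @param backend `"forest"`, `"sequential_logit"` or `"two_stage_linear"`.
#' @param n_bootstrap number of bootstrap replicates (>= 100).
#' @param seed integer seed governing every random draw.
#' @param ci_level nominal coverage of the percentile interval.
#' @param num_trees trees per forest (forest backend).
#' @param min_node_size forest terminal-node size (`NULL` = ranger default).
#' @param min_train minimum training-set size.
#' @return object of class `savings_estimate`: `point_median_brl`,
#'   `point_mean_brl`, `ci_low_brl`, `ci_high_brl`, `ci_level`,
#'   `boot_medians`, `boot_means`, `n_bootstrap`, `n_degenerate_redrawn`,
#'   `seed`, `backend`, `train_meta`, and `per_case` (a `data.frame` with
#'   `case_id`, `p_nt_fav`, `p_cf_inj_fav`, `expected_saving_brl`).
#' @export
estimate_savings <- function(cases, backend = "forest", n_bootstrap = 500,
                             seed = 1L, ci_level = 0.95, num_trees = 500,
                             min_node_size = NULL, min_train = 50) {
  backend <- match.arg(backend, backend_tags)
  if (n_bootstrap < 100)
    stop_ji("n_bootstrap must be at least 100 (got %d)", n_bootstrap,
            class = "config_error")
  sp <- split_analysis_sets(cases)
  train <- sp$train
  eval_cases <- sp$eval

  full <- savings_once(train, eval_cases, backend, seed, num_trees,
                       min_node_size, min_train)
  per_case <- data.frame(
    case_id = eval_cases$case_id,
    p_nt_fav = predict_nt_favorable(full$model, eval_cases),
    p_cf_inj_fav = full$p_cf,
    expected_saving_brl = full$saving,
    stringsAsFactors = FALSE
  )

  n_tr <- nrow(train)
  boot_medians <- numeric(n_bootstrap)
  boot_means <- numeric(n_bootstrap)
  redraws <- 0L
  with_seed(seed, {
    for (b in seq_len(n_bootstrap)) {
      repeat {
        idx <- sample.int(n_tr, n_tr, replace = TRUE)
        tb <- train[idx, , drop = FALSE]
        ok <- length(unique(tb$nt_direction)) == 2L &&
          length(unique(tb$injunction_direction)) == 2L
        if (ok) break
        redraws <- redraws + 1L
        if (redraws > 100L)
          stop_ji("too many degenerate bootstrap resamples; training set too small or too unbalanced",
                  class = "estimation_error")
      }
      fb <- savings_once(tb, eval_cases, backend, seed + b, num_trees,
                         min_node_size, min_train = min(min_train, n_tr),
                         compute_meta = FALSE)
      boot_medians[b] <- stats::median(fb$saving)
      boot_means[b] <- mean(fb$saving)
    }
  })
  if (redraws > 0L)
    warning(sprintf("%d degenerate bootstrap resample(s) redrawn", redraws))
  alpha <- (1 - ci_level) / 2
  # canonical percentile-bootstrap convention: (B+1)*alpha order statistics
  # (quantile type 6); R's default type 7 is anti-conservative at small B
  ci <- unname(stats::quantile(boot_medians, c(alpha, 1 - alpha), type = 6))
  structure(list(
    point_median_brl = stats::median(per_case$expected_saving_brl),
    point_mean_brl = mean(per_case$expected_saving_brl),
    ci_low_brl = ci[1], ci_high_brl = ci[2], ci_level = ci_level,
    boot_medians = boot_medians, boot_means = boot_means,
    n_bootstrap = as.integer(n_bootstrap), n_degenerate_redrawn = redraws,
    seed = as.integer(seed), backend = backend,
    train_meta = full$model$train_meta, per_case = per_case,
    n_train = n_tr, n_eval = nrow(eval_cases)
  ), class = "savings_estimate")
}

#' @export
print.savings_estimate <- function(x, ...) {
  cat(sprintf("Counterfactual savings estimate (%s backend)\n", x$backend))
  cat(sprintf("  training cases (with NT):    %d\n", x$n_train))
  cat(sprintf("  evaluated cases (no NT):     %d\n", x$n_eval))
  cat(sprintf("  median saving per case/year: BRL %s\n",
              format(round_half_up(x$point_median_brl, 2), big.mark = ",", nsmall = 2)))
  cat(sprintf("  mean saving per case/year:   BRL %s\n",
              format(round_half_up(x$point_mean_brl, 2), big.mark = ",", nsmall = 2)))
  cat(sprintf("  %d%% bootstrap CI (median):  BRL %s to %s  (%d replicates)\n",
              round(100 * x$ci_level),
              format(round_half_up(x$ci_low_brl, 2), big.mark = ","),
              format(round_half_up(x$ci_high_brl, 2), big.mark = ","),
              x$n_bootstrap))
  invisible(x)
}

#' Serialize a savings estimate to JSON
#'
#' @param estimate a `savings_estimate`.
#' @param path output path.
#' @param include_per_case write the per-case table too (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_estimate <- function(estimate, path, include_per_case = TRUE) {
  x <- estimate
  out <- list(schema = "judimpact/estimate/1", backend = x$backend,
              seed = x$seed, n_bootstrap = x$n_bootstrap,
              ci_level = x$ci_level,
              point_median_brl = x$point_median_brl,
              point_mean_brl = x$point_mean_brl,
              ci_low_brl = x$ci_low_brl, ci_high_brl = x$ci_high_brl,
              n_train = x$n_train, n_eval = x$n_eval,
              n_degenerate_redrawn = x$n_degenerate_redrawn,
              train_meta = x$train_meta)
  if (include_per_case) out$per_case <- x$per_case
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
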