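no_nt_cases <- function(n = 5, value_brl = 10000, injunction = "favorable") {
  make_cases(n, has_nt = FALSE, injunction_direction = injunction,
             value_brl = value_brl)
}

test_that("counterfactual probability is the Model-1 mixture of Model-2 maps", {
  # model2 constant at 0.7 regardless of NT state -> p_cf = 0.7 for any p1
  m <- mock_logit_model(coef1 = c(1.3, 0.5, 0, 0),
                        coef2 = c(qlogis(0.7), 0, 0, 0, 0))
  cases <- no_nt_cases(4, value_brl = c(100, 1000, 10000, 1e6))
  expect_equal(counterfactual_probability(m, cases), rep(0.7, 4), tolerance = 1e-12)

  # mixture endpoint: m2(fav) = 1, m2(unfav) = 0, p1 = 0.5 -> p_cf = 0.5
  ml <- mock_linear_model(coef1 = c(0.5, 0, 0, 0), coef2 = c(0, 0, 0, 0, 1))
  expect_equal(counterfactual_probability(ml, cases), rep(0.5, 4), tolerance = 1e-12)

  expect_error(counterfactual_probability(m, make_cases(2, has_nt = TRUE)),
               class = "domain_error")
})

test_that("counterfactual equals exhaustive NT-state enumeration on a grid", {
  cases <- generate_cases(test_config(n_cases = 2000, seed = 23, p_has_nt = 1))
  m <- fit_impact_model(cases, backend = "sequential_logit", seed = 1)
  grid <- expand.grid(value_brl = c(500, 10120, 250000),
                      claim_type = c("medication", "treatment", "procedure"),
                      court = c("court_02", "court_07", "court_10"),
                      stringsAsFactors = FALSE)
  gcases <- judimpact:::as_case_df(data.frame(
    case_id = sprintf("g%02d", seq_len(nrow(grid))), filing_year = 2020L,
    court = grid$court, claim_type = grid$claim_type, value_brl = grid$value_brl,
    has_nt = FALSE, nt_direction = NA_character_, nt_author = NA_character_,
    nt_cited = NA, injunction_direction = NA_character_,
    excluded_reason = NA_character_, stringsAsFactors = FALSE))
  # oracle: enumerate both NT states explicitly and weight by Model 1
  p1 <- predict_nt_favorable(m, gcases)
  enum <- vapply(seq_len(nrow(gcases)), function(i) {
    row <- gcases[i, , drop = FALSE]
    states <- c(favorable = predict_injunction(m, row, "favorable"),
                unfavorable = predict_injunction(m, row, "unfavorable"))
    sum(c(p1[i], 1 - p1[i]) * states)
  }, numeric(1))
  expect_equal(counterfactual_probability(m, gcases), enum, tolerance = 1e-12)
})

test_that("the signed saving rule follows the decision-change logic", {
  expect_equal(per_case_saving(no_nt_cases(1), p_cf = 1), 0)               # no reversal expected
  expect_equal(per_case_saving(no_nt_cases(1, injunction = "unfavorable"), 0), 0)
  expect_equal(per_case_saving(no_nt_cases(1, value_brl = 10000), 0.25), 7500)
  expect_equal(per_case_saving(no_nt_cases(1, value_brl = 10000,
                                           injunction = "unfavorable"), 0.25),
               -2500)
  expect_error(per_case_saving(make_cases(1, has_nt = TRUE), 0.5),
               class = "domain_error")
  noinj <- no_nt_cases(1)
  noinj$injunction_direction <- factor(NA, levels = c("favorable", "unfavorable"))
  expect_error(per_case_saving(noinj, 0.5), class = "domain_error")
})

test_that("the saving formula agrees with Monte-Carlo simulated reversals", {
  v <- 10000; p_cf <- 0.3
  set.seed(101)
  draws <- runif(2e5) < p_cf       # counterfactual favorable?
  mc_fav <- mean(v * !draws)       # observed favorable: saving iff reversal to unfavorable
  mc_unf <- mean(-v * draws)       # observed unfavorable: loss iff reversal to favorable
  expect_equal(per_case_saving(no_nt_cases(1, v), p_cf), mc_fav, tolerance = 0.01)
  expect_equal(per_case_saving(no_nt_cases(1, v, "unfavorable"), p_cf), mc_unf,
               tolerance = 0.01)
})

test_that("estimate_savings satisfies its structural invariants", {
  cases <- generate_cases(test_config(n_cases = 1200, seed = 31))
  est <- estimate_savings(cases, backend = "sequential_logit",
                          n_bootstrap = 100, seed = 5)
  pc <- est$per_case
  expect_true(all(pc$p_nt_fav >= 0 & pc$p_nt_fav <= 1))
  expect_true(all(pc$p_cf_inj_fav >= 0 & pc$p_cf_inj_fav <= 1))
  vals <- cases$value_brl[match(pc$case_id, cases$case_id)]
  expect_true(all(abs(pc$expected_saving_brl) <= vals + 1e-9))
  expect_equal(est$point_median_brl, median(pc$expected_saving_brl))
  expect_equal(est$point_mean_brl, mean(pc$expected_saving_brl))
  expect_lte(est$ci_low_brl, est$point_median_brl)
  expect_gte(est$ci_high_brl, est$point_median_brl)
  expect_error(estimate_savings(cases, n_bootstrap = 50), class = "config_error")
  all_nt <- generate_cases(test_config(n_cases = 300, seed = 1, p_has_nt = 1))
  expect_error(estimate_savings(all_nt, n_bootstrap = 100,
                                backend = "sequential_logit"),
               class = "estimation_error")
})

test_that("the median estimate is invariant to case order", {
  cases <- generate_cases(test_config(n_cases = 1000, seed = 37))
  shuffled <- cases[rev(seq_len(nrow(cases))), ]
  a <- savings_point_estimate(cases, backend = "sequential_logit", seed = 1)
  b <- savings_point_estimate(shuffled, backend = "sequential_logit", seed = 1)
  expect_equal(a$median_brl, b$median_brl, tolerance = 1e-9)
  expect_equal(a$mean_brl, b$mean_brl, tolerance = 1e-9)
})

test_that("strongly unfavorable NT worlds drive savings toward full case value", {
  # NTs nearly always unfavorable; informed decisions nearly always deny;
  # uninformed observed decisions nearly always grant
  cfg <- test_config(
    n_cases = 4000, seed = 41,
    beta_nt = list(intercept = -3, log_value = 0, claim = NULL, court = NULL),
    beta_inj = list(intercept = -3, log_value = 0, claim = NULL, court = NULL),
    nt_effect = 3, no_nt_shift = 6)
  cases <- generate_cases(cfg)
  sub <- cases[!cases$has_nt & cases$injunction_direction == "favorable", ]
  m <- fit_impact_model(cases[cases$has_nt, ], backend = "sequential_logit", seed = 1)
  saving <- per_case_saving(sub, counterfactual_probability(m, sub))
  expect_gt(median(saving) / median(sub$value_brl), 0.85)
})

test_that("degenerate bootstrap resamples are redrawn and counted", {
  cases <- generate_cases(test_config(n_cases = 400, seed = 43))
  train <- cases[cases$has_nt, ][1:60, ]
  train$nt_direction[] <- "unfavorable"
  train$nt_direction[1:2] <- "favorable"   # rare class: resamples often miss it
  evalc <- cases[!cases$has_nt, ][1:50, ]
  small <- rbind(train, evalc)
  expect_warning(
    est <- estimate_savings(small, backend = "sequential_logit",
                            n_bootstrap = 100, seed = 7, min_train = 10),
    "degenerate bootstrap"
  )
  expect_gt(est$n_degenerate_redrawn, 0)
})
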