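test_that("rank-based AUC matches the brute-force pairwise count and pROC", {
  set.seed(42)
  scores <- round(runif(30), 1)   # rounding forces ties
  labels <- runif(30) < plogis(4 * scores - 2)
  if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
  pos <- scores[labels]; neg <- scores[!labels]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(auc_rank(scores, labels), mean(pairs), tolerance = 1e-12)
  expect_equal(auc_rank(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
  expect_equal(auc_rank(c(0, 0, 1, 1), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auc_rank(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(auc_rank(1:4, rep(TRUE, 4)), class = "metric_error")
})

test_that("a separable world is fit almost perfectly", {
  cfg <- test_config(n_cases = 2000, seed = 2, p_has_nt = 1,
                     beta_nt = list(intercept = 0, log_value = 8,
                                    claim = NULL, court = NULL),
                     nt_effect = 10)
  cases <- generate_cases(cfg)
  m <- fit_impact_model(cases, backend = "forest", seed = 1, num_trees = 200)
  expect_gte(m$train_meta$auc_model1, 0.99)
  ev <- evaluate_model(m, cases)
  expect_gte(ev$auc_model1, 0.99)
})

test_that("sequential-logit predictions match the closed-form logit", {
  # two courts keep every covariate cell well populated at n = 5000, so the
  # +-0.05 band is several prediction SEs wide everywhere on the grid
  cfg <- test_config(n_cases = 5000, seed = 6, p_has_nt = 1,
                     court_labels = c("court_01", "court_02"),
                     beta_nt = list(intercept = 0.35, log_value = -0.8,
                                    claim = c(treatment = 0.2, procedure = -0.2),
                                    court = c(court_02 = 0.3)),
                     beta_inj = list(intercept = -0.36, log_value = -0.25,
                                     claim = c(treatment = 0.15, procedure = -0.15),
                                     court = c(court_02 = -0.3)))
  cases <- generate_cases(cfg)
  m <- fit_impact_model(cases, backend = "sequential_logit", seed = 1)
  # held-out grid spanning the central bulk of the value distribution
  grid <- expand.grid(value_brl = c(2000, 10120, 60000),
                      claim_type = c("medication", "treatment", "procedure"),
                      court = c("court_01", "court_02"),
                      stringsAsFactors = FALSE)
  gc_ <- judimpact:::as_case_df(data.frame(
    case_id = sprintf("g%02d", seq_len(nrow(grid))), filing_year = 2021L,
    court = grid$court, claim_type = grid$claim_type,
    value_brl = grid$value_brl, has_nt = FALSE,
    nt_direction = NA_character_, nt_author = NA_character_, nt_cited = NA,
    injunction_direction = NA_character_, excluded_reason = NA_character_,
    stringsAsFactors = FALSE))
  truth <- generator_probabilities(cfg, gc_)
  expect_lt(max(abs(predict_nt_favorable(m, gc_) - truth$p_nt_favorable)), 0.05)
  expect_lt(max(abs(predict_injunction(m, gc_, "favorable") -
                      truth$p_inj_nt_favorable)), 0.05)
  expect_lt(max(abs(predict_injunction(m, gc_, "unfavorable") -
                      truth$p_inj_nt_unfavorable)), 0.05)
})

test_that("sequential logit recovers the generating coefficients within 2 SE", {
  cfg <- test_config(n_cases = 5000, seed = 9, p_has_nt = 1)
  cases <- generate_cases(cfg)
  m <- fit_impact_model(cases, backend = "sequential_logit", seed = 1)
  # reference fit with SEs on the identical design (the oracle route)
  X <- judimpact:::design_matrix(m$prep, cases)
  y <- cases$nt_direction == "favorable"
  ref <- glm(y ~ X, family = binomial())
  expect_equal(unname(m$model1$coef), unname(coef(ref)), tolerance = 1e-6)
  # true coefficients on the model's z scale: z_model = (log v - c)/s, so
  # slope_model = beta_logv * s_train / sigma_true etc.
  s <- m$prep$scale; ctr <- m$prep$center
  slope_true <- cfg$beta_nt$log_value * s / cfg$value_log_sigma
  int_true <- cfg$beta_nt$intercept +
    cfg$beta_nt$log_value * (ctr - cfg$value_log_mu) / cfg$value_log_sigma
  se <- summary(ref)$coefficients[, "Std. Error"]
  est <- coef(ref)
  expect_lt(abs(est["(Intercept)"] - int_true), 2 * se["(Intercept)"])
  expect_lt(abs(est["Xz"] - slope_true), 2 * se["Xz"])
  expect_lt(abs(est["Xclaim_treatment"] - cfg$beta_nt$claim[["treatment"]]),
            2 * se["Xclaim_treatment"])
})

test_that("degenerate and undersized training sets are refused by name", {
  cases <- generate_cases(test_config(n_cases = 300, seed = 1, p_has_nt = 1))
  small <- cases[1:30, ]
  expect_error(fit_impact_model(small, "sequential_logit"), "at least 50",
               class = "sample_size_error")
  const <- cases
  const$nt_direction[] <- "favorable"
  expect_error(fit_impact_model(const, "sequential_logit"),
               "nt_direction is constant", class = "degenerate_fit_error")
  mixed <- cases
  mixed$has_nt[1] <- FALSE
  mixed$nt_direction[1] <- NA
  expect_error(fit_impact_model(mixed, "sequential_logit"), class = "domain_error")
})

test_that("every backend returns probabilities in [0,1] under both NT directions", {
  cases <- generate_cases(test_config(n_cases = 800, seed = 13, p_has_nt = 1))
  for (bk in c("forest", "sequential_logit", "two_stage_linear")) {
    m <- fit_impact_model(cases, backend = bk, seed = 2, num_trees = 100)
    for (dir in c("favorable", "unfavorable")) {
      p <- predict_injunction(m, cases, dir)
      expect_true(all(p >= 0 & p <= 1), info = paste(bk, dir))
    }
    p1 <- predict_nt_favorable(m, cases)
    expect_true(all(p1 >= 0 & p1 <= 1), info = bk)
    expect_true(all(c("auc_model1", "auc_model2", "acc_model1", "acc_model2",
                      "n_train") %in% names(m$train_meta)))
  }
})

test_that("a null NT effect yields matching Model-2 maps at scale", {
  cfg <- test_config(n_cases = 20000, seed = 17, p_has_nt = 1, nt_effect = 0)
  cases <- generate_cases(cfg)
  m <- fit_impact_model(cases, backend = "forest", seed = 3, num_trees = 200)
  gap <- mean(abs(predict_injunction(m, cases, "favorable") -
                    predict_injunction(m, cases, "unfavorable")))
  expect_lt(gap, 0.03)
})

test_that("evaluation metrics behave at the trivial limits", {
  cases <- generate_cases(test_config(n_cases = 400, seed = 19, p_has_nt = 1))
  m <- fit_impact_model(cases, backend = "sequential_logit", seed = 1)
  ev <- evaluate_model(m, cases)
  expect_true(ev$auc_model1 >= 0 && ev$auc_model1 <= 1)
  expect_true(ev$acc_model2 >= 0 && ev$acc_model2 <= 1)
  oneclass <- cases
  oneclass$injunction_direction[] <- "favorable"
  expect_error(evaluate_model(m, oneclass), class = "metric_error")
})
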