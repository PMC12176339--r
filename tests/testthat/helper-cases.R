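# small in-code case builders shared across test files

make_cases <- function(n = 10,
                       has_nt = TRUE,
                       nt_direction = "favorable",
                       nt_author = "HIAE",
                       nt_cited = TRUE,
                       injunction_direction = "favorable",
                       value_brl = 10000,
                       court = "court_01",
                       claim_type = "medication",
                       excluded_reason = NA_character_) {
  df <- data.frame(
    case_id = sprintf("t_%04d", seq_len(n)),
    filing_year = 2021L,
    court = rep_len(court, n),
    claim_type = rep_len(claim_type, n),
    value_brl = rep_len(value_brl, n),
    has_nt = rep_len(has_nt, n),
    nt_direction = rep_len(ifelse(rep_len(has_nt, n), nt_direction, NA_character_), n),
    nt_author = rep_len(ifelse(rep_len(has_nt, n), nt_author, NA_character_), n),
    nt_cited = ifelse(rep_len(has_nt, n), rep_len(nt_cited, n), NA),
    injunction_direction = rep_len(injunction_direction, n),
    excluded_reason = rep_len(excluded_reason, n),
    stringsAsFactors = FALSE
  )
  judimpact:::as_case_df(df)
}

# a hand-built sequential-logit model whose probability maps are fully
# controlled by the supplied coefficients (design: intercept, z,
# claim_treatment, claim_procedure, court dummies..., [nt_favorable])
mock_logit_model <- function(coef1, coef2, court_levels = "court_01") {
  structure(list(
    backend = "sequential_logit",
    model1 = list(coef = coef1), model2 = list(coef = coef2),
    prep = list(center = 0, scale = 1,
                claim_levels = c("medication", "treatment", "procedure"),
                court_levels = court_levels),
    seed = 1L, train_meta = list()), class = "impact_model")
}

mock_linear_model <- function(coef1, coef2, court_levels = "court_01") {
  m <- mock_logit_model(coef1, coef2, court_levels)
  m$backend <- "two_stage_linear"
  m
}

# generator tuned so that each downstream stage has signal but no extreme
# class imbalance; used wherever a test just needs "a reasonable world"
test_config <- function(n_cases = 2000, seed = 1, ...) {
  generator_config(n_cases = n_cases, seed = seed, ...)
}
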