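#' @name impact-models
#' @title Two-stage counterfactual model of NT direction and injunction outcome
#'
#' @description
#' The impact analysis rests on two fitted probability maps, estimated on
#' the cases that carry a technical note (NT):
#'
#' * **Model 1** predicts the NT direction (favorable/unfavorable to the
#'   patient) from the case covariates: standardized log claim value,
#'   claim type, court.
#' * **Model 2** predicts the preliminary-injunction outcome from the same
#'   covariates plus the NT direction as a binary feature, so it can be
#'   queried under *either* NT direction for any case — the property the
#'   counterfactual step depends on.
#'
#' Three exchangeable backends are provided: `"forest"` (probability random
#' forests), `"sequential_logit"` (two logistic regressions), and
#' `"two_stage_linear"` (a two-stage linear-probability estimator: stage 1
#' regresses the NT indicator on the covariates, stage 2 regresses the
#' injunction on covariates plus the stage-1 fitted value; predictions are
#' clipped to \[0, 1\]).
NULL

backend_tags <- c("forest", "sequential_logit", "two_stage_linear")

# --- design matrices --------------------------------------------------------

# Fix the covariate encoding from the training data: standardized log value,
# one-hot claim and court dummies (first level as reference).
make_prep <- function(cases) {
  lv <- log(cases$value_brl)
  list(center = mean(lv), scale = stats::sd(lv),
       claim_levels = levels(cases$claim_type),
       court_levels = levels(cases$court))
}

design_matrix <- function(prep, cases) {
  sc <- if (prep$scale > 0) prep$scale else 1
  z <- (log(cases$value_brl) - prep$center) / sc
  claim <- factor(as.character(cases$claim_type), levels = prep$claim_levels)
  court <- factor(as.character(cases$court), levels = prep$court_levels)
  if (anyNA(claim) || anyNA(court))
    stop_ji("cases contain claim/court labels unseen at training time",
            class = "predict_error")
  one_hot <- function(f, pre) {
    lv <- levels(f)[-1]                      # first level is the reference
    if (!length(lv)) return(matrix(0, length(f), 0))
    m <- matrix(0, length(f), length(lv),
                dimnames = list(NULL, paste0(pre, lv)))
    for (j in seq_along(lv)) m[, j] <- as.numeric(f == lv[j])
    m
  }
  cbind(z = z, one_hot(claim, "claim_"), one_hot(court, "court_"))
}

clip01 <- function(p) pmin(1, pmax(0, p))

# --- AUC / accuracy ---------------------------------------------------------

#' Rank-based AUC
#'
#' Area under the ROC curve computed from midranks (the Wilcoxon statistic),
#' which gives tied score pairs the standard half credit.
#'
#' @param scores numeric predicted scores.
#' @param labels logical (or 0/1) outcomes; must contain both classes.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L)
    stop_ji("AUC undefined: outcome has a single class", class = "metric_error")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# --- fitting ----------------------------------------------------------------

#' Fit the two-stage impact model
#'
#' Fits Model 1 (NT direction) and Model 2 (injunction outcome given NT
#' direction) on NT-bearing cases with observed outcomes, under the chosen
#' backend. Training metadata records per-model training AUC, an
#' out-of-sample accuracy (out-of-bag for the forest, 5-fold
#' cross-validation for the regression backends), and the training size.
#'
#' @param cases_with_nt case `data.frame`; every row must have
#'   `has_nt = TRUE` with non-missing `nt_direction` and
#'   `injunction_direction`.
#' @param backend `"forest"`, `"sequential_logit"` or `"two_stage_linear"`.
#' @param seed integer seed for the stochastic backends and CV folds.
#' @param num_trees trees per forest (forest backend only).
#' @param min_node_size minimum terminal-node size for the probability
#'   forests (forest backend only); `NULL` uses ranger's default.
#' @param min_train minimum admissible training size.
#' @param compute_meta whether to evaluate training AUC/accuracy metadata;
#'   bootstrap refits skip it for speed.
#' @return object of class `impact_model`: list with `backend`, fitted
#'   `model1`/`model2` states, the covariate `prep`, `train_meta`
#'   (`auc_model1`, `auc_model2`, `acc_model1`, `acc_model2`, `n_train`)
#'   and `seed`.
#' @seealso [predict_nt_favorable()], [predict_injunction()],
#'   [evaluate_model()]
#' @export
fit_impact_model <- function(cases_with_nt, backend = "forest", seed = 1L,
                             num_trees = 500, min_node_size = NULL,
                             min_train = 50, compute_meta = TRUE) {
  backend <- match.arg(backend, backend_tags)
  cases <- cases_with_nt
  if (nrow(cases) < min_train)
    stop_ji("training set has %d cases; at least %d required", nrow(cases),
            min_train, class = "sample_size_error")
  if (any(!cases$has_nt) || anyNA(cases$nt_direction) ||
      anyNA(cases$injunction_direction))
    stop_ji("training cases must all carry an NT with observed nt_direction and injunction_direction",
            class = "domain_error")
  y1 <- cases$nt_direction == "favorable"
  y2 <- cases$injunction_direction == "favorable"
  outcomes <- list(nt_direction = y1, injunction_direction = y2)
  for (nm in names(outcomes)) {
    y <- outcomes[[nm]]
    if (length(unique(y)) < 2L)
      stop_ji("degenerate fit: %s is constant ('%s') in the training data",
              nm, if (y[1]) "favorable" else "unfavorable",
              class = "degenerate_fit_error")
  }
  prep <- make_prep(cases)
  X1 <- design_matrix(prep, cases)
  X2 <- cbind(X1, nt_favorable = as.numeric(y1))

  fitted <- switch(backend,
    forest = fit_forest(X1, y1, X2, y2, seed, num_trees, min_node_size),
    sequential_logit = fit_seq_logit(X1, y1, X2, y2, seed),
    two_stage_linear = fit_two_stage(X1, y1, X2, y2, seed)
  )
  model <- structure(list(backend = backend, model1 = fitted$model1,
                          model2 = fitted$model2, prep = prep, seed = seed),
                     class = "impact_model")
  if (compute_meta) {
    p1 <- predict_p1(model, X1)
    p2 <- predict_p2(model, X1, as.numeric(y1))
    model$train_meta <- list(
      auc_model1 = auc_rank(p1, y1), auc_model2 = auc_rank(p2, y2),
      acc_model1 = fitted$oob_acc1, acc_model2 = fitted$oob_acc2,
      accuracy_kind = fitted$acc_kind, n_train = nrow(cases)
    )
  }
  model
}

fit_forest <- function(X1, y1, X2, y2, seed, num_trees, min_node_size = NULL) {
  rf <- function(X, y, s) {
    ranger::ranger(y = factor(y, levels = c(FALSE, TRUE)),
                   x = X, probability = TRUE,
                   num.trees = num_trees, min.node.size = min_node_size,
                   seed = s, num.threads = 1)
  }
  m1 <- rf(X1, y1, seed)
  m2 <- rf(X2, y2, seed + 1L)
  oob_acc <- function(m, y) {
    p <- m$predictions[, "TRUE"]
    ok <- !is.na(p)              # a row can be in-bag for every tree
    mean((p[ok] > 0.5) == y[ok])
  }
  list(model1 = m1, model2 = m2,
       oob_acc1 = oob_acc(m1, y1), oob_acc2 = oob_acc(m2, y2),
       acc_kind = "out_of_bag")
}

fit_seq_logit <- function(X1, y1, X2, y2, seed) {
  g <- function(X, y) {
    suppressWarnings(stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                                    family = stats::binomial()))$coefficients
  }
  list(model1 = list(coef = g(X1, y1)), model2 = list(coef = g(X2, y2)),
       oob_acc1 = cv_accuracy(X1, y1, seed, link = "logit"),
       oob_acc2 = cv_accuracy(X2, y2, seed + 1L, link = "logit"),
       acc_kind = "cv5")
}

fit_two_stage <- function(X1, y1, X2, y2, seed) {
  l <- function(X, y) stats::lm.fit(cbind(`(Intercept)` = 1, X), y)$coefficients
  c1 <- l(X1, y1)
  # stage 2: injunction on covariates and the stage-1 fitted NT propensity
  nt_hat <- clip01(drop(cbind(1, X1) %*% c1))
  X2h <- X2
  X2h[, "nt_favorable"] <- nt_hat
  c2 <- l(X2h, y2)
  list(model1 = list(coef = c1), model2 = list(coef = c2),
       oob_acc1 = cv_accuracy(X1, y1, seed, link = "identity"),
       oob_acc2 = cv_accuracy(X2h, y2, seed + 1L, link = "identity"),
       acc_kind = "cv5")
}

cv_accuracy <- function(X, y, seed, link, k = 5) {
  with_seed(seed, {
    fold <- sample(rep(seq_len(k), length.out = length(y)))
    pred <- numeric(length(y))
    for (f in seq_len(k)) {
      tr <- fold != f
      co <- if (link == "logit")
        suppressWarnings(stats::glm.fit(cbind(1, X[tr, , drop = FALSE]), y[tr],
                                        family = stats::binomial()))$coefficients
      else stats::lm.fit(cbind(1, X[tr, , drop = FALSE]), y[tr])$coefficients
      co[is.na(co)] <- 0
      eta <- drop(cbind(1, X[!tr, , drop = FALSE]) %*% co)
      pred[!tr] <- if (link == "logit") stats::plogis(eta) else clip01(eta)
    }
    mean((pred > 0.5) == y)
  })
}

# --- prediction -------------------------------------------------------------

predict_p1 <- function(model, X) {
  p <- switch(model$backend,
    forest = stats::predict(model$model1, X, num.threads = 1)$predictions[, "TRUE"],
    sequential_logit = stats::plogis(drop(cbind(1, X) %*% na_zero(model$model1$coef))),
    two_stage_linear = clip01(drop(cbind(1, X) %*% na_zero(model$model1$coef)))
  )
  unname(p)
}

predict_p2 <- function(model, X, nt_favorable) {
  X2 <- cbind(X, nt_favorable = nt_favorable)
  p <- switch(model$backend,
    forest = stats::predict(model$model2, X2, num.threads = 1)$predictions[, "TRUE"],
    sequential_logit = stats::plogis(drop(cbind(1, X2) %*% na_zero(model$model2$coef))),
    two_stage_linear = clip01(drop(cbind(1, X2) %*% na_zero(model$model2$coef)))
  )
  unname(p)
}

#' Predict the probability of a favorable NT (Model 1)
#'
#' @param model an `impact_model`.
#' @param cases case `data.frame`.
#' @return numeric vector in \[0, 1\].
#' @export
predict_nt_favorable <- function(model, cases) {
  predict_p1(model, design_matrix(model$prep, cases))
}

#' Predict the probability of a favorable injunction (Model 2)
#'
#' Queries Model 2 for given cases under a stated NT direction; both
#' directions are accepted for every case, which is what makes
#' counterfactual queries possible.
#'
#' @param model an `impact_model`.
#' @param cases case `data.frame`.
#' @param nt_direction `"favorable"`/`"unfavorable"`, length 1 or `nrow(cases)`.
#' @return numeric vector in \[0, 1\].
#' @export
predict_injunction <- function(model, cases, nt_direction) {
  nt <- as.character(nt_direction)
  if (!all(nt %in% direction_levels))
    stop_ji("nt_direction must be 'favorable' or 'unfavorable'",
            class = "domain_error")
  ntf <- as.numeric(rep_len(nt == "favorable", nrow(cases)))
  predict_p2(model, design_matrix(model$prep, cases), ntf)
}

na_zero <- function(co) { co[is.na(co)] <- 0; co }

#' Evaluate a fitted impact model on labeled cases
#'
#' Computes rank-based AUC and 0.5-threshold accuracy for each sub-model on
#' cases with observed outcomes (Model 2 is evaluated at the observed NT
#' direction).
#'
#' @param model an `impact_model`.
#' @param cases NT-bearing case `data.frame` with observed `nt_direction`
#'   and `injunction_direction`.
#' @return list with `auc_model1`, `auc_model2`, `acc_model1`, `acc_model2`, `n`.
#' @export
evaluate_model <- function(model, cases) {
  if (anyNA(cases$nt_direction) || anyNA(cases$injunction_direction))
    stop_ji("evaluation cases must have observed NT and injunction directions",
            class = "domain_error")
  y1 <- cases$nt_direction == "favorable"
  y2 <- cases$injunction_direction == "favorable"
  p1 <- predict_nt_favorable(model, cases)
  p2 <- predict_injunction(model, cases, cases$nt_direction)
  list(auc_model1 = auc_rank(p1, y1), auc_model2 = auc_rank(p2, y2),
       acc_model1 = mean((p1 > 0.5) == y1), acc_model2 = mean((p2 > 0.5) == y2),
       n = nrow(cases))
}

#' @export
print.impact_model <- function(x, ...) {
  m <- x$train_meta
  cat(sprintf("Two-stage impact model (backend: %s, n_train = %d)\n",
              x$backend, m$n_train))
  cat(sprintf("  Model 1 (NT direction):        train AUC %.3f, %s accuracy %.1f%%\n",
              m$auc_model1, m$accuracy_kind, 100 * m$acc_model1))
  cat(sprintf("  Model 2 (injunction outcome):  train AUC %.3f, %s accuracy %.1f%%\n",
              m$auc_model2, m$accuracy_kind, 100 * m$acc_model2))
  invisible(x)
}
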