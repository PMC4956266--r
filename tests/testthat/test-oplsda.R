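test_that("with no orthogonal components the model matches textbook PLS1", {
  for (seed in c(3, 17)) {
    fx <- two_class_fixture(seed)
    fit <- fit_oplsda(fx$X, fx$labels, positive_class = "case", n_orth = 0)
    y <- ifelse(fx$labels == "case", 1, -1)
    Xs <- scale(fx$X)[, ]
    t_oracle <- pls1_score_oracle(Xs, y)
    cosine <- abs(sum(fit$t_pred * t_oracle)) /
      sqrt(sum(fit$t_pred^2) * sum(t_oracle^2))
    expect_gt(cosine, 1 - 1e-8)
  }
})

test_that("orthogonal scores are orthogonal to the response and predictive score", {
  for (n_orth in 1:3) {
    fx <- two_class_fixture(7 + n_orth)
    fit <- fit_oplsda(fx$X, fx$labels, positive_class = "case", n_orth = n_orth)
    y <- ifelse(fx$labels == "case", 1, -1)
    for (a in seq_len(n_orth)) {
      expect_lt(abs(sum(fit$T_o[, a] * y)) / sqrt(sum(fit$T_o[, a]^2) * sum(y^2)),
                1e-8)
      expect_lt(abs(sum(fit$T_o[, a] * fit$t_pred)) /
                  sqrt(sum(fit$T_o[, a]^2) * sum(fit$t_pred^2)), 1e-8)
    }
    expect_true(all(fit$pcorr >= -1 & fit$pcorr <= 1))
  }
})

test_that("a feature identical to the response coding tops the pcorr profile", {
  fx <- two_class_fixture(5)
  y <- ifelse(fx$labels == "case", 1, -1)
  X <- cbind(fx$X, canary = y)
  fit <- fit_oplsda(X, fx$labels, positive_class = "case", n_orth = 0)
  # pcorr correlates features with the predictive score, not with y itself,
  # so the canary is bounded by cor(t_pred, y) < 1; it must still dominate
  expect_equal(names(which.max(fit$pcorr)), "canary")
  expect_gt(unname(fit$pcorr["canary"]), 0.9)
  expect_equal(unname(fit$pcorr["canary"]),
               cor(fit$t_pred, y), tolerance = 1e-10)
})

test_that("prediction uses the zero threshold and filters orthogonal variation", {
  fx <- two_class_fixture(9)
  fit <- fit_oplsda(fx$X, fx$labels, positive_class = "case", n_orth = 1)
  # class means land on opposite sides of zero
  mu_case <- matrix(colMeans(fx$X[fx$labels == "case", ]), 1)
  mu_ctrl <- matrix(colMeans(fx$X[fx$labels == "control", ]), 1)
  expect_gt(predict(fit, mu_case)$yhat, 0)
  expect_lt(predict(fit, mu_ctrl)$yhat, 0)
  # training mean row scores exactly zero -> positive class by the tie rule
  mu <- matrix(colMeans(fx$X), 1)
  pm <- predict(fit, mu)
  expect_equal(pm$yhat, 0, tolerance = 1e-10)
  expect_equal(pm$labels, "case")
  # adding any multiple of the orthogonal loading leaves yhat unchanged
  bump <- mu + 5 * matrix(fit$P_o[, 1] / fit$weights, 1)
  expect_equal(predict(fit, bump)$yhat, pm$yhat, tolerance = 1e-8)
  expect_error(predict(fit, mu[, 1:3, drop = FALSE]), "columns")
  expect_error(fit_oplsda(fx$X, rep("case", nrow(fx$X))), "exactly 2")
})

test_that("variance bookkeeping decomposes the scaled sum of squares", {
  fx <- two_class_fixture(13)
  fit <- fit_oplsda(fx$X, fx$labels, positive_class = "case", n_orth = 2)
  Xs <- scale(fx$X)[, ]
  ss_total <- sum(Xs^2)
  # reconstruct: orthogonal parts + predictive part + residual
  Xrem <- Xs
  for (a in 1:2) Xrem <- Xrem - tcrossprod(Xrem %*% fit$W_o[, a], fit$P_o[, a])
  resid <- Xrem - tcrossprod(fit$t_pred, fit$p_pred)
  captured <- sum(tcrossprod(fit$t_pred, fit$p_pred)^2) +
    sum((Xs - Xrem)^2)
  expect_equal(captured + sum(resid^2) +
                 2 * sum((Xs - Xrem) * tcrossprod(fit$t_pred, fit$p_pred)),
               ss_total, tolerance = 1e-8 * ss_total)
})

test_that("cross-validation is stratified, complete and deterministic", {
  fx <- two_class_fixture(19, n_per = 14)
  cv <- cross_validate_oplsda(fx$X, fx$labels, positive_class = "case",
                              n_orth = 1, folds = 7)
  expect_equal(length(cv$yhat_cv), 28)
  # every fold contains both classes
  expect_true(all(table(cv$fold, cv$labels) > 0))
  cv2 <- cross_validate_oplsda(fx$X, fx$labels, positive_class = "case",
                               n_orth = 1, folds = 7)
  expect_identical(cv$yhat_cv, cv2$yhat_cv)
  # leave-one-out (folds = class size) is supported
  cv_loo <- cross_validate_oplsda(fx$X, fx$labels, positive_class = "case",
                                  n_orth = 1, folds = 14)
  expect_equal(length(unique(cv_loo$fold)), 14)
  expect_gt(cv_loo$q2, 0.5)
})

test_that("Q2 is high on separated classes and near zero on null data", {
  q2s <- vapply(1:20, function(seed) {
    coh <- small_cohort(seed)
    tab <- normalized_identified(coh)
    md <- coh$metadata
    rows <- md$pooled_group %in% c("SLE", "HV")
    cv <- cross_validate_oplsda(tab$values[rows, ], md$pooled_group[rows],
                                positive_class = "SLE", n_orth = 1, folds = 7)
    cv$q2
  }, numeric(1))
  expect_gt(median(q2s), 0.5)
  q2_null <- vapply(1:20, function(seed) {
    coh <- generate_cohort(generator_config(seed = seed + 400), effects = NULL)
    tab <- normalized_identified(coh)
    md <- coh$metadata
    rows <- md$pooled_group %in% c("SLE", "HV")
    cross_validate_oplsda(tab$values[rows, ], md$pooled_group[rows],
                          positive_class = "SLE", n_orth = 1, folds = 7)$q2
  }, numeric(1))
  expect_lte(median(q2_null), 0.05)
})

test_that("CV-ANOVA follows the F construction and its limits", {
  fx <- two_class_fixture(23)
  cv <- cross_validate_oplsda(fx$X, fx$labels, positive_class = "case",
                              n_orth = 1, folds = 5)
  an <- cv_anova(cv)
  N <- length(cv$y)
  expect_equal(an$df_model, 2)
  expect_equal(an$df_error, N - 3)
  expect_equal(an$F, ((an$ss_total - an$press) / 2) / (an$press / (N - 3)),
               tolerance = 1e-12)
  expect_lt(an$p, 1e-6)  # separated classes cross-validate strongly
  # cross-validated prediction no better than the mean -> F = 0, p = 1
  null_cv <- cv
  null_cv$yhat_cv <- rep(mean(cv$y), N)
  an0 <- cv_anova(null_cv)
  expect_equal(an0$F, 0)
  expect_equal(an0$p, 1)
  # perfect prediction -> p -> 0
  perf <- cv; perf$yhat_cv <- cv$y
  expect_equal(cv_anova(perf)$p, 0)
})

test_that("CV-ANOVA is valid (conservative) under the null", {
  # small null two-class problems, many seeds; exchangeable groups. On null
  # data cross-validated predictions are typically worse than the response
  # mean (PRESS >= SS), so the F statistic truncates at zero and the test
  # rejects well below its nominal level: valid, conservative
  ps <- vapply(1:200, function(seed) {
    set.seed(seed)
    X <- matrix(rnorm(24 * 8), 24, 8)
    labs <- rep(c("a", "b"), each = 12)
    cv <- cross_validate_oplsda(X, labs, positive_class = "a", n_orth = 1,
                                folds = 6)
    cv_anova(cv)$p
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.09)
  expect_gt(mean(ps == 1), 0.5)
})

test_that("confusion summaries obey the stated identities", {
  cs <- confusion_summary(tp = 59, fn = 41, tn = 86, fp = 14)
  expect_equal(cs$sensitivity, 0.59)
  expect_equal(cs$specificity, 0.86)
  fx <- two_class_fixture(29)
  cv <- cross_validate_oplsda(fx$X, fx$labels, positive_class = "case",
                              n_orth = 1, folds = 5)
  cf <- confusion_from_cv(cv)
  expect_equal(cf$tp + cf$fn, sum(cv$y == 1))
  expect_equal(cf$tn + cf$fp, sum(cv$y == -1))
  expect_equal(cf$sensitivity, cf$tp / (cf$tp + cf$fn))
  expect_equal(cf$specificity, cf$tn / (cf$fp + cf$tn))
  # all predicted positive -> sensitivity 1, specificity 0
  allpos <- cv; allpos$yhat_cv <- abs(cv$yhat_cv) + 1
  cfa <- confusion_from_cv(allpos)
  expect_equal(cfa$sensitivity, 1)
  expect_equal(cfa$specificity, 0)
})

test_that("planted effects dominate the p(corr) ranking, null labels do not", {
  ranks <- vapply(1:20, function(seed) {
    coh <- small_cohort(seed + 60)
    tab <- normalized_identified(coh)
    md <- coh$metadata
    rows <- md$pooled_group %in% c("SLE", "HV")
    fit <- fit_oplsda(tab$values[rows, ], md$pooled_group[rows],
                      positive_class = "SLE", n_orth = 1)
    planted <- coh$truth$effects$feature[coh$truth$effects$SLE != 0]
    r <- rank(-abs(fit$pcorr))[planted]
    median(r)
  }, numeric(1))
  expect_lte(median(ranks), 25)
})
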