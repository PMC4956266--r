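#' Fit a two-class OPLS-DA model
#'
#' Single-response orthogonal projections to latent structures discriminant
#' analysis. The response is coded +1 for the positive (disease) class and
#' -1 for the negative class, so the natural class-belonging threshold on
#' the predicted response is zero. After column scaling, the predictive
#' weight is `w = X'y` (unit norm); each of the `n_orth` orthogonal
#' components is extracted as the part of the current X-loading orthogonal
#' to `w` and deflated from X, so that its scores are uncorrelated with both
#' the response and the predictive score. `pcorr` is the Pearson correlation
#' of the predictive score with each original scaled column: the
#' discriminatory profile, positive when a feature is higher in the positive
#' class.
#'
#' @param X Numeric matrix (samples x features) or `metabolite_table`.
#' @param labels Vector with exactly two distinct values.
#' @param positive_class The label coded +1 (default: first value
#'   encountered; in disease-vs-control contrasts pass the disease).
#' @param n_orth Number of orthogonal components (>= 0, default 1).
#' @param scaling A [scaling_spec()].
#' @return An object of class `opls_model`.
#' @export
fit_oplsda <- function(X, labels, positive_class = NULL, n_orth = 1L,
                       scaling = scaling_spec()) {
  if (inherits(X, "metabolite_table")) X <- X$values
  X <- as.matrix(X)
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2)
    stopf("labels must have exactly 2 distinct values, found %d", length(lev))
  if (is.null(positive_class)) positive_class <- lev[1]
  if (!positive_class %in% lev) stopf("positive_class '%s' absent", positive_class)
  negative_class <- setdiff(lev, positive_class)
  if (min(table(labels)) < 3) stopf("each class needs >= 3 samples")
  y <- ifelse(labels == positive_class, 1, -1)
  n_orth <- as.integer(n_orth)
  if (n_orth < 0) stopf("n_orth must be >= 0")

  sc <- fit_scaling(X, scaling)
  Xs <- apply_scaling(X, sc)
  X0 <- Xs              # original scaled matrix, kept for pcorr
  ss0 <- ss(X0)
  w <- crossprod(Xs, y)[, 1]
  wn <- sqrt(sum(w^2))
  if (wn == 0) stopf("response is orthogonal to every column")
  w <- w / wn
  W_o <- P_o <- matrix(0, ncol(X), n_orth)
  T_o <- matrix(0, nrow(X), n_orth)
  for (a in seq_len(n_orth)) {
    t <- Xs %*% w
    p <- crossprod(Xs, t)[, 1] / sum(t^2)
    w_o <- p - sum(w * p) * w
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-12)
      stopf("no orthogonal variation left for component %d", a)
    w_o <- w_o / nrm
    t_o <- Xs %*% w_o
    p_o <- crossprod(Xs, t_o)[, 1] / sum(t_o^2)
    W_o[, a] <- w_o; T_o[, a] <- t_o; P_o[, a] <- p_o
    Xs <- Xs - t_o %*% t(p_o)
  }
  t_pred <- (Xs %*% w)[, 1]
  c_load <- sum(y * t_pred) / sum(t_pred^2)
  p_pred <- crossprod(Xs, t_pred)[, 1] / sum(t_pred^2)
  yhat <- t_pred * c_load
  ss_y <- sum((y - mean(y))^2)
  r2y <- 1 - sum((y - yhat)^2) / ss_y
  captured <- sum(t_pred^2) * sum(p_pred^2) +
    if (n_orth > 0) sum(colSums(T_o^2) * colSums(P_o^2)) else 0
  pcorr <- as.numeric(cor(t_pred, X0))
  names(pcorr) <- colnames(X)
  structure(list(positive_class = positive_class,
                 negative_class = negative_class,
                 means = sc$means, weights = sc$weights, scaling = scaling,
                 w = w, c = c_load, p_pred = p_pred, t_pred = t_pred,
                 W_o = W_o, T_o = T_o, P_o = P_o, n_orth = n_orth,
                 r2x = captured / ss0, r2y = r2y, pcorr = pcorr,
                 var_names = colnames(X), N = nrow(X)),
            class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("opls_model: %s (+1) vs %s (-1), 1 predictive + %d orthogonal, R2X = %.3f, R2Y = %.3f\n",
              x$positive_class, x$negative_class, x$n_orth, x$r2x, x$r2y))
  invisible(x)
}

#' Predict class membership from an OPLS-DA model
#'
#' New observations are scaled with the training parameters, the orthogonal
#' components are filtered out sequentially, and the predicted response is
#' `yhat = (X_filtered w) c`. The class-belonging threshold is zero; an
#' observation with `yhat == 0` (e.g. the training mean row) is assigned the
#' positive class by the documented tie rule.
#'
#' @param object An `opls_model`.
#' @param newdata Matrix with the model's feature columns.
#' @param ... Unused.
#' @return List with `yhat`, `labels` and `t_pred`.
#' @export
predict.opls_model <- function(object, newdata, ...) {
  if (inherits(newdata, "metabolite_table")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$w))
    stopf("newdata has %d columns; model expects %d", ncol(newdata),
          length(object$w))
  Xs <- apply_scaling(newdata, list(means = object$means,
                                    weights = object$weights))
  for (a in seq_len(object$n_orth)) {
    t_o <- Xs %*% object$W_o[, a, drop = FALSE]
    Xs <- Xs - t_o %*% t(object$P_o[, a, drop = FALSE])
  }
  t_pred <- (Xs %*% object$w)[, 1]
  yhat <- t_pred * object$c
  labels <- ifelse(yhat >= 0, object$positive_class, object$negative_class)
  list(yhat = yhat, labels = labels, t_pred = t_pred)
}

#' Cross-validate an OPLS-DA model
#'
#' Deterministic round-robin folds stratified by class (within each class,
#' samples are dealt to folds cyclically in input order). Every fold refits
#' the model, including the column scaling, on the training rows only, and
#' predicts the held-out rows, so each sample receives exactly one
#' cross-validated prediction from a model that never saw it.
#' `Q2 = 1 - PRESS / SS(y - ybar)`.
#'
#' @inheritParams fit_oplsda
#' @param folds Number of folds (>= 2); `folds = N` gives leave-one-out when
#'   class sizes allow.
#' @return An object of class `opls_cv` with `yhat_cv`, `y`, `labels`,
#'   `fold`, `q2`, `n_orth` and the class coding.
#' @export
cross_validate_oplsda <- function(X, labels, positive_class = NULL,
                                  n_orth = 1L, folds = 7L,
                                  scaling = scaling_spec()) {
  if (inherits(X, "metabolite_table")) X <- X$values
  X <- as.matrix(X)
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2) stopf("labels must have exactly 2 distinct values")
  if (is.null(positive_class)) positive_class <- lev[1]
  folds <- as.integer(folds)
  if (folds < 2) stopf("folds must be >= 2")
  fold <- integer(length(labels))
  for (g in lev) {
    idx <- which(labels == g)
    fold[idx] <- ((seq_along(idx) - 1L) %% folds) + 1L
  }
  y <- ifelse(labels == positive_class, 1, -1)
  yhat_cv <- numeric(length(y))
  for (f in sort(unique(fold))) {
    hold <- fold == f
    if (length(unique(labels[!hold])) < 2)
      stopf("fold %d leaves a training split without both classes", f)
    fit <- fit_oplsda(X[!hold, , drop = FALSE], labels[!hold],
                      positive_class = positive_class, n_orth = n_orth,
                      scaling = scaling)
    yhat_cv[hold] <- predict(fit, X[hold, , drop = FALSE])$yhat
  }
  q2 <- 1 - sum((y - yhat_cv)^2) / sum((y - mean(y))^2)
  structure(list(yhat_cv = yhat_cv, y = y, labels = labels, fold = fold,
                 q2 = q2, n_orth = as.integer(n_orth),
                 positive_class = positive_class,
                 negative_class = setdiff(lev, positive_class)),
            class = "opls_cv")
}

#' CV-ANOVA significance of a cross-validated OPLS-DA model
#'
#' Compares the cross-validated prediction error against the total response
#' variance: `F = ((SS_total - PRESS)/df_model) / (PRESS/df_error)` with
#' `df_model = 1 + n_orth` (one predictive plus the orthogonal components)
#' and `df_error = N - 1 - df_model`; the p-value is the upper tail of the
#' corresponding F distribution. When cross-validation does no better than
#' the response mean (`PRESS >= SS_total`) the statistic is truncated at
#' zero and `p = 1`.
#'
#' @param cv An `opls_cv` from [cross_validate_oplsda()].
#' @return List with `ss_total`, `press`, `df_model`, `df_error`, `F`, `p`.
#' @export
cv_anova <- function(cv) {
  stopifnot(inherits(cv, "opls_cv"))
  N <- length(cv$y)
  ss_total <- sum((cv$y - mean(cv$y))^2)
  press <- sum((cv$y - cv$yhat_cv)^2)
  df_model <- 1 + cv$n_orth
  df_error <- N - 1 - df_model
  if (df_error <= 0) stopf("nonpositive error degrees of freedom (N = %d)", N)
  Fstat <- max(0, ((ss_total - press) / df_model) / (press / df_error))
  p <- if (Fstat == 0) 1 else pf(Fstat, df_model, df_error, lower.tail = FALSE)
  list(ss_total = ss_total, press = press, df_model = df_model,
       df_error = df_error, F = Fstat, p = p)
}

#' Confusion summary from cross-validated OPLS-DA predictions
#'
#' Each cross-validated predicted response is classified by its sign (zero
#' counts as the positive class) and tallied against the true labels, the
#' positive class being the disease.
#'
#' @param cv An `opls_cv`.
#' @return A `confusion_summary` (see [confusion_summary()]).
#' @export
confusion_from_cv <- function(cv) {
  stopifnot(inherits(cv, "opls_cv"))
  pred_pos <- cv$yhat_cv >= 0
  true_pos <- cv$y == 1
  confusion_summary(tp = sum(pred_pos & true_pos),
                    fn = sum(!pred_pos & true_pos),
                    tn = sum(!pred_pos & !true_pos),
                    fp = sum(pred_pos & !true_pos))
}

#' Sensitivity/specificity bookkeeping
#'
#' `sensitivity = tp / (tp + fn)`; `specificity = tn / (fp + tn)`.
#'
#' @param tp,fn,tn,fp Nonnegative integer counts.
#' @return An object of class `confusion_summary`.
#' @export
confusion_summary <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0)) stopf("counts must be nonnegative")
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (fp + tn > 0) tn / (fp + tn) else NA_real_),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("confusion: tp=%d fn=%d tn=%d fp=%d | sensitivity %.3f, specificity %.3f\n",
              x$tp, x$fn, x$tn, x$fp, x$sensitivity, x$specificity))
  invisible(x)
}
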