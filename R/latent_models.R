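#' Scaling specification for latent-variable models
#'
#' Column scaling applied before fitting a PCA or OPLS-DA model. Centering
#' subtracts the training column mean; `unit_variance` divides by the
#' training column standard deviation, `pareto` by its square root, `none`
#' leaves columns unscaled. Stored means and weights always come from the
#' training rows only and are reused verbatim when new observations are
#' projected.
#'
#' @param center Subtract column means?
#' @param mode One of `"unit_variance"`, `"pareto"`, `"none"`.
#' @return An object of class `scaling_spec`.
#' @export
scaling_spec <- function(center = TRUE,
                         mode = c("unit_variance", "pareto", "none")) {
  mode <- match.arg(mode)
  structure(list(center = isTRUE(center), mode = mode), class = "scaling_spec")
}

fit_scaling <- function(X, scaling) {
  means <- if (scaling$center) colMeans(X) else rep(0, ncol(X))
  sds <- apply(X, 2, sd)
  weights <- switch(scaling$mode,
                    none = rep(1, ncol(X)),
                    unit_variance = 1 / sds,
                    pareto = 1 / sqrt(sds))
  if (scaling$mode != "none" && any(!is.finite(weights)))
    stopf("zero-variance column(s) cannot be %s scaled: %s", scaling$mode,
          paste(colnames(X)[!is.finite(weights)], collapse = ", "))
  list(means = means, weights = weights)
}

apply_scaling <- function(X, sc) {
  sweep(sweep(X, 2, sc$means, "-"), 2, sc$weights, "*")
}

#' Fit a principal component model by NIPALS
#'
#' Components are extracted one at a time by the NIPALS power iteration with
#' deflation, so component `a` maximizes the residual variance explained.
#' Loading vectors are unit norm and signed so that each one's
#' largest-magnitude element is positive, which makes scores reproducible
#' across runs. The pooled residual standard deviation `s0` feeding the
#' distance-to-model statistic uses `(N - A - 1)(K - A)` degrees of freedom
#' for centered models and `(N - A)(K - A)` otherwise.
#'
#' @param X Numeric matrix (observations x variables), no missing values.
#' @param A Number of components; must not exceed the attainable rank
#'   `min(N - center, K)`.
#' @param scaling A [scaling_spec()].
#' @param tol NIPALS convergence tolerance on the relative score change.
#' @param max_iter Maximum NIPALS iterations per component. When the
#'   iteration cap is reached with the explained variance fully converged
#'   (two leading eigenvalues nearly tied), the current direction is
#'   accepted: any direction in a degenerate eigenspace reconstructs the
#'   data equally well.
#' @return An object of class `pca_model` with loadings `P` (K x A,
#'   orthonormal columns), scores `T` (N x A), per-component and cumulative
#'   explained variance `r2x`/`r2x_cum`, residual scale `s0`, and the stored
#'   scaling parameters.
#' @export
fit_pca <- function(X, A, scaling = scaling_spec(), tol = 1e-12,
                    max_iter = 5000L) {
  X <- as.matrix(X)
  if (anyNA(X)) stopf("X contains missing values")
  N <- nrow(X); K <- ncol(X)
  A <- as.integer(A)
  rank_max <- min(N - as.integer(scaling$center), K)
  if (A < 1) stopf("A must be >= 1")
  if (A > rank_max)
    stopf("A = %d exceeds attainable rank %d for a %d x %d %s matrix",
          A, rank_max, N, K, if (scaling$center) "centered" else "non-centered")
  sc <- fit_scaling(X, scaling)
  Xs <- apply_scaling(X, sc)
  ss0 <- ss(Xs)
  if (ss0 <= 0) stopf("matrix has zero total variance after scaling")
  E <- Xs
  P <- matrix(0, K, A)
  Tm <- matrix(0, N, A)
  r2x <- numeric(A)
  for (a in seq_len(A)) {
    css <- colSums(E^2)
    if (max(css) <= 1e-12 * ss0)
      stopf("A = %d exceeds the effective rank %d of the scaled matrix", A, a - 1L)
    t <- E[, which.max(css)]
    ev_old <- sum(t^2)
    for (iter in seq_len(max_iter)) {
      p <- crossprod(E, t)[, 1] / sum(t^2)
      p <- p / sqrt(sum(p^2))
      t_new <- E %*% p
      delta <- sqrt(sum((t_new - t)^2)) / sqrt(sum(t_new^2))
      t <- t_new[, 1]
      ev <- sum(t^2)
      ev_delta <- abs(ev - ev_old) / ev
      ev_old <- ev
      if (delta < tol) break
      if (iter == max_iter) {
        # nearly tied leading eigenvalues: the score direction drifts within
        # their span while the explained variance has converged; any
        # direction in that span reconstructs equally well, so accept it
        if (ev_delta < 1e-6) break
        stopf("NIPALS failed to converge for component %d in %d iterations",
              a, max_iter)
      }
    }
    if (p[which.max(abs(p))] < 0) { p <- -p; t <- -t }
    P[, a] <- p
    Tm[, a] <- t
    r2x[a] <- sum(t^2) / ss0
    E <- E - tcrossprod(t, p)
  }
  rownames(P) <- colnames(X)
  rownames(Tm) <- rownames(X)
  d2 <- (N - A - as.integer(scaling$center)) * (K - A)
  s0 <- if (d2 > 0) sqrt(ss(E) / d2) else NA_real_
  structure(list(N = N, K = K, A = A, means = sc$means, weights = sc$weights,
                 P = P, T = Tm, r2x = r2x, r2x_cum = cumsum(r2x),
                 s0 = s0, ss_scaled = ss0, scaling = scaling,
                 var_names = colnames(X)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: N = %d, K = %d, A = %d, R2X(cum) = %.3f\n",
              x$N, x$K, x$A, x$r2x_cum[x$A]))
  invisible(x)
}

#' Cross-validated Q2 for a principal component model
#'
#' Rows are assigned to folds by deterministic round-robin in their input
#' order. For every fold the model (including the column scaling) is refit on
#' the retained rows; held-out rows are scaled with the training parameters
#' and their scores obtained by projection onto the training loadings.
#' `Q2(cum)(a) = 1 - PRESS(a) / SS`, where PRESS accumulates the held-out
#' reconstruction error with `a` components and SS the held-out scaled sum of
#' squares. Because projecting a held-out row onto the loadings fits `a`
#' free score parameters out of its `K` values, the raw residual is
#' optimistic; PRESS carries the degrees-of-freedom correction `K / (K - a)`
#' so that structureless data give Q2 near or below zero.
#'
#' @inheritParams fit_pca
#' @param folds Number of folds (>= 2); `folds = N` gives leave-one-out.
#' @return Numeric vector of cumulative Q2 values, one per component.
#' @export
q2_pca <- function(X, A, scaling = scaling_spec(), folds = 7L) {
  X <- as.matrix(X)
  N <- nrow(X)
  folds <- as.integer(folds)
  if (folds < 2) stopf("folds must be >= 2")
  if (folds > N) stopf("folds = %d exceeds N = %d", folds, N)
  assignment <- ((seq_len(N) - 1L) %% folds) + 1L
  press <- numeric(A)
  ss_ho <- 0
  for (f in seq_len(folds)) {
    hold <- assignment == f
    if (all(hold)) stopf("fold %d contains all rows", f)
    fit <- fit_pca(X[!hold, , drop = FALSE], A, scaling = scaling)
    Xs <- apply_scaling(X[hold, , drop = FALSE],
                        list(means = fit$means, weights = fit$weights))
    ss_ho <- ss_ho + ss(Xs)
    Eh <- Xs
    K <- ncol(X)
    for (a in seq_len(A)) {
      t_a <- Eh %*% fit$P[, a, drop = FALSE]
      Eh <- Eh - t_a %*% t(fit$P[, a, drop = FALSE])
      # a score parameters are fitted per held-out row, so the raw residual
      # is optimistic by (K - a)/K; rescale to an honest prediction error
      press[a] <- press[a] + ss(Eh) * if (K > a) K / (K - a) else 1
    }
  }
  if (ss_ho <= 0) stopf("held-out sum of squares is zero (degenerate data)")
  1 - press / ss_ho
}

#' Project new observations onto a fitted principal component model
#'
#' Applies the stored centering/scaling and computes scores by projection
#' onto the orthonormal loadings; residuals are taken in the scaled metric.
#' Training rows reproduce their stored scores.
#'
#' @param model A `pca_model`.
#' @param Xnew Numeric matrix with the model's variables as columns.
#' @return List with `scores` (n x A) and `residuals` (n x K, orthogonal to
#'   the model plane).
#' @export
project_pca <- function(model, Xnew) {
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != model$K)
    stopf("Xnew has %d columns; model expects %d", ncol(Xnew), model$K)
  Xs <- apply_scaling(Xnew, list(means = model$means, weights = model$weights))
  scores <- Xs %*% model$P
  residuals <- Xs - tcrossprod(scores, model$P)
  list(scores = scores, residuals = residuals)
}

#' Distance to model (DModX) of observations
#'
#' The absolute distance of observation i is the standard deviation of its
#' residuals off the model plane, `sqrt(SS(e_i) / (K - A))`; the normalized
#' distance divides by the pooled training residual `s0`. Two documented
#' finite-sample corrections restore a common scale: training rows, whose
#' residuals are shrunk by the fit, are inflated by `sqrt(N / (N - A - 1))`
#' (centered models; `N - A` otherwise); new observations, whose residuals
#' carry the prediction-variance leverage of the estimated subspace and
#' center, are shrunk by `1 / sqrt(1 + (A + 1)/N)` (centered; `(A)/N`
#' otherwise). Observations are flagged inside when the normalized distance
#' does not exceed the critical distance at `alpha`.
#'
#' @param model A `pca_model`.
#' @param Xnew Observations to score.
#' @param is_training Are these the model's own training rows?
#' @param alpha Significance level for the critical distance.
#' @return List with `dmodx_abs`, `dmodx_norm`, `dcrit` and logical `inside`.
#' @export
dmodx <- function(model, Xnew, is_training = FALSE, alpha = 0.05) {
  proj <- project_pca(model, Xnew)
  K <- model$K; A <- model$A; N <- model$N
  dmodx_abs <- sqrt(rowSums(proj$residuals^2) / (K - A))
  nu <- N - A - as.integer(model$scaling$center)
  # training residuals are shrunk by the fit; new-observation residuals are
  # inflated by the estimated subspace/center (prediction-variance leverage
  # ~ 1 + (A + center)/N) and, under unit-variance scaling, by the sampling
  # error of the training column SDs (E[s^2/shat^2] = (N-1)/(N-3)). The
  # corrections restore a common scale.
  scale_infl <- if (model$scaling$mode == "unit_variance" && N > 3)
    (N - 1) / (N - 3) else 1
  corr <- if (is_training) sqrt(N / nu)
          else 1 / sqrt((1 + (A + as.integer(model$scaling$center)) / N) *
                          scale_infl)
  if (is.na(model$s0) || model$s0 == 0) {
    # saturated or exactly reproduced training data: any nonzero new
    # residual is infinitely far from the model (documented sentinel)
    dmodx_norm <- ifelse(dmodx_abs > 1e-12, Inf, 0)
    dc <- if (is.na(model$s0)) NA_real_ else dcrit(model, alpha)
    inside <- dmodx_norm == 0
  } else {
    dmodx_norm <- dmodx_abs / model$s0 * corr
    dc <- dcrit(model, alpha)
    inside <- dmodx_norm <= dc
  }
  list(dmodx_abs = dmodx_abs, dmodx_norm = dmodx_norm, dcrit = dc,
       inside = inside)
}

#' Critical distance for class membership
#'
#' The critical limit for the normalized distance to model is derived from an
#' F distribution: `DCrit = sqrt(F(1 - alpha; K - A, (N - A - 1)(K - A)))`
#' for centered models (`N - A` replaces `N - A - 1` otherwise). Monotone
#' decreasing in `alpha`.
#'
#' @param model A `pca_model`.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return The critical normalized distance.
#' @export
dcrit <- function(model, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  d1 <- model$K - model$A
  d2 <- (model$N - model$A - as.integer(model$scaling$center)) * d1
  if (d1 <= 0 || d2 <= 0)
    stopf("nonpositive degrees of freedom (d1 = %d, d2 = %d)", d1, d2)
  sqrt(qf(1 - alpha, d1, d2))
}
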