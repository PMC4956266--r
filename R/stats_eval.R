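#' Two-sample unequal-variance (Welch) t-test
#'
#' Welch statistic with Satterthwaite degrees of freedom and a two-tailed
#' p-value. Degenerate rule: when both groups have zero variance and equal
#' means the test is uninformative and returns `t = 0, p = 1`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
welch_ttest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stopf("each group needs n >= 2")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    stopf("both groups have zero variance with unequal means")
  }
  ht <- t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' ROC curve and area under the curve
#'
#' Threshold sweep over the unique scores (plus sentinels), producing
#' monotone false/true-positive-rate sequences from (0, 0) to (1, 1); the
#' AUC is the trapezoidal area, which with this construction equals the
#' Mann-Whitney concordance probability with half credit for ties.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary truth (logical, or compared against
#'   `positive_label`).
#' @param positive_high Do larger scores indicate the positive class?
#' @param positive_label Value of `labels` treated as positive when `labels`
#'   is not logical.
#' @return An object of class `roc_curve` with `thresholds`, `fpr`, `tpr`,
#'   `auc`.
#' @export
roc_auc <- function(scores, labels, positive_high = TRUE,
                    positive_label = NULL) {
  if (!is.logical(labels)) {
    if (is.null(positive_label)) {
      lev <- unique(labels)
      if (length(lev) != 2) stopf("labels must be binary")
      positive_label <- lev[1]
    }
    labels <- labels == positive_label
  }
  if (all(labels) || !any(labels)) stopf("both classes must be present")
  if (!positive_high) scores <- -scores
  np <- sum(labels); nn <- sum(!labels)
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thresholds, function(th) sum(scores >= th & labels) / np,
                numeric(1))
  fpr <- vapply(thresholds, function(th) sum(scores >= th & !labels) / nn,
                numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = thresholds, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Per-component ROC discrimination of PCA scores
#'
#' For each requested score vector the AUC of the two-group discrimination
#' is computed, with the score orientation chosen so the reported AUC is
#' >= 0.5; the chosen sign is reported alongside.
#'
#' @param model A `pca_model` whose training rows align with `labels`.
#' @param labels Binary group labels for the training rows.
#' @param components Integer vector of score indices (default first two).
#' @param positive_label Label treated as positive.
#' @return Data frame with `component`, `auc`, `sign`.
#' @export
pca_score_roc <- function(model, labels, components = c(1L, 2L),
                          positive_label = NULL) {
  stopifnot(inherits(model, "pca_model"))
  if (any(components > model$A))
    stopf("component index exceeds the model's %d component(s)", model$A)
  rows <- lapply(components, function(a) {
    r <- roc_auc(model$T[, a], labels, positive_label = positive_label)
    if (r$auc >= 0.5) data.frame(component = a, auc = r$auc, sign = 1L)
    else data.frame(component = a, auc = 1 - r$auc, sign = -1L)
  })
  do.call(rbind, rows)
}

#' Univariate significance table for a two-group contrast
#'
#' Welch t-test per feature on log-transformed intensities (the data model
#' is multiplicative), with the direction taken from the group-mean log
#' difference (positive = higher in `contrast[1]`). Raw p-values are
#' compared against `alpha` by default; Benjamini-Hochberg adjustment is
#' available behind a flag.
#'
#' @param table A normalized `metabolite_table`.
#' @param metadata Metadata with `sample_id` and group columns.
#' @param contrast Length-2 character vector `(group1, group2)`.
#' @param alpha Significance level (default 0.05).
#' @param log_transform Test log intensities (default `TRUE`).
#' @param adjust Apply Benjamini-Hochberg FDR before flagging?
#' @return Data frame with one row per feature: `feature`, `direction`
#'   (sign of the mean log-ratio, group1 vs group2), `log_ratio`, `p`
#'   (and `p_adj` when adjusted) and `significant`.
#' @export
significance_table <- function(table, metadata, contrast, alpha = 0.05,
                               log_transform = TRUE, adjust = FALSE) {
  stopifnot(inherits(table, "metabolite_table"), length(contrast) == 2)
  metadata <- as.data.frame(metadata)
  check_metadata_match(table, metadata)
  gcol <- group_column(metadata)
  md <- metadata[match(table$sample_ids, metadata$sample_id), ]
  rows1 <- md[[gcol]] == contrast[1]
  rows2 <- md[[gcol]] == contrast[2]
  if (!any(rows1) || !any(rows2))
    stopf("contrast group(s) absent: %s",
          paste(contrast[!c(any(rows1), any(rows2))], collapse = ", "))
  V <- table$values
  if (log_transform) {
    if (any(V <= 0)) stopf("log transform requires strictly positive values")
    V <- log(V)
  }
  res <- lapply(seq_len(ncol(V)), function(j) {
    ht <- welch_ttest(V[rows1, j], V[rows2, j])
    data.frame(feature = table$features$name[j],
               log_ratio = mean(V[rows1, j]) - mean(V[rows2, j]),
               p = ht$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$direction <- sign(out$log_ratio)
  if (adjust) {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$significant <- out$p_adj < alpha
  } else {
    out$significant <- out$p < alpha
  }
  out[, c("feature", "direction", "log_ratio", "p",
          if (adjust) "p_adj", "significant")]
}
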