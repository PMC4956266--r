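simca_extract <- function(table, metadata, label, group_col) {
  ids <- metadata$sample_id[metadata[[group_col]] == label]
  rows <- table$sample_ids %in% ids
  if (!any(rows)) stopf("class '%s' absent from metadata", label)
  table$values[rows, , drop = FALSE]
}

group_column <- function(metadata) {
  if ("pooled_group" %in% names(metadata)) "pooled_group" else "group"
}

# Pick the component count maximizing leave-one-out Q2 over 1..5 (capped by
# the attainable rank); fall back to 1 when nothing cross-validates.
choose_components <- function(X, scaling, max_a = 5L) {
  rank_max <- min(nrow(X) - as.integer(scaling$center) - 1L, ncol(X), max_a)
  if (rank_max < 1) return(1L)
  q2 <- tryCatch(q2_pca(X, rank_max, scaling = scaling, folds = nrow(X)),
                 error = function(e) rep(-Inf, rank_max))
  as.integer(which.max(q2))
}

#' Fit a SIMCA soft classification model
#'
#' One principal component model is fit per class on that class's samples
#' only; a new observation belongs to a class when its normalized distance
#' to that class model does not exceed the F-based critical distance at
#' `alpha` (default 0.05). Because every class is modeled independently, a
#' sample may belong to zero, one, or several classes (soft classification).
#'
#' @param table A `metabolite_table` (or plain matrix with `metadata`
#'   row-aligned).
#' @param metadata Data frame with `sample_id` and `group` (and optionally
#'   `pooled_group`, which takes precedence).
#' @param class_labels Character vector of class labels to model.
#' @param components `NULL` to select each class's component count by
#'   leave-one-out Q2 over 1..5, or a named integer vector.
#' @param alpha Membership significance level.
#' @param scaling A [scaling_spec()] shared by every class model.
#' @return An object of class `simca_model`.
#' @export
fit_simca <- function(table, metadata, class_labels, components = NULL,
                      alpha = 0.05, scaling = scaling_spec()) {
  stopifnot(inherits(table, "metabolite_table"))
  metadata <- as.data.frame(metadata)
  check_metadata_match(table, metadata)
  gcol <- group_column(metadata)
  classes <- list()
  for (label in class_labels) {
    Xc <- simca_extract(table, metadata, label, gcol)
    a <- if (!is.null(components)) {
      if (is.null(names(components)) && length(components) == 1)
        as.integer(components) else as.integer(components[[label]])
    } else choose_components(Xc, scaling)
    if (nrow(Xc) < a + 2)
      stopf("class '%s' has %d samples; needs >= %d for %d component(s)",
            label, nrow(Xc), a + 2, a)
    fit <- fit_pca(Xc, a, scaling = scaling)
    classes[[label]] <- list(label = label, model = fit,
                             dcrit = dcrit(fit, alpha))
  }
  structure(list(classes = classes, alpha = alpha, scaling = scaling,
                 features = table$features$name),
            class = "simca_model")
}

#' @export
print.simca_model <- function(x, ...) {
  cat(sprintf("simca_model: %d class(es) at alpha = %.3g\n",
              length(x$classes), x$alpha))
  for (cl in x$classes)
    cat(sprintf("  %s: N = %d, A = %d, DCrit = %.3f\n", cl$label,
                cl$model$N, cl$model$A, cl$dcrit))
  invisible(x)
}

#' Classify observations against a SIMCA model
#'
#' Computes each observation's normalized distance to every class model and
#' flags membership where the distance is within that class's critical
#' limit. For two-class models the distance pair per sample is the Coomans
#' coordinate system: the two critical distances partition the plane into
#' the class-1, class-2, both ("overlap") and neither ("outlier") quadrants.
#'
#' @param model A `simca_model`.
#' @param Xnew Matrix (or `metabolite_table`) with the model's feature
#'   columns.
#' @param labels_new Optional true labels, carried through to the output.
#' @return List with `distance` (n x classes matrix of normalized DModX),
#'   `membership` (logical matrix), `dcrit` (per class) and, for two-class
#'   models, `coomans` (a data frame of coordinates and quadrant calls).
#' @export
classify_simca <- function(model, Xnew, labels_new = NULL) {
  stopifnot(inherits(model, "simca_model"))
  if (inherits(Xnew, "metabolite_table")) {
    if (!identical(Xnew$features$name, model$features))
      stopf("feature columns do not match the SIMCA model")
    Xnew <- Xnew$values
  }
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != length(model$features))
    stopf("Xnew has %d columns; model expects %d", ncol(Xnew),
          length(model$features))
  labs <- names(model$classes)
  distance <- sapply(model$classes, function(cl)
    dmodx(cl$model, Xnew, is_training = FALSE, alpha = model$alpha)$dmodx_norm)
  distance <- matrix(distance, nrow = nrow(Xnew),
                     dimnames = list(rownames(Xnew), labs))
  dcrits <- vapply(model$classes, `[[`, numeric(1), "dcrit")
  membership <- sweep(distance, 2, dcrits, "<=")
  out <- list(distance = distance, membership = membership, dcrit = dcrits,
              labels = labels_new)
  if (length(labs) == 2) {
    quadrant <- ifelse(membership[, 1] & membership[, 2], "both",
                ifelse(membership[, 1], labs[1],
                ifelse(membership[, 2], labs[2], "neither")))
    out$coomans <- data.frame(sample = if (!is.null(rownames(Xnew)))
                                rownames(Xnew) else seq_len(nrow(Xnew)),
                              label = if (!is.null(labels_new)) labels_new
                                      else NA_character_,
                              d1 = distance[, 1], d2 = distance[, 2],
                              dcrit1 = dcrits[1], dcrit2 = dcrits[2],
                              quadrant = quadrant,
                              stringsAsFactors = FALSE)
  }
  out
}

#' Leave-one-out validation of SIMCA class models
#'
#' For every sample of a modeled class, the class model is refit without it
#' (same component count and scaling) and the held-out sample's membership in
#' its own class is assessed against the refit model: the fraction retained
#' is the class model's cross-validated sensitivity. Samples of the other
#' classes are evaluated against the full class model (leave-one-out removal
#' is only defined for a model's own training members); the fraction
#' rejected is the specificity.
#'
#' @inheritParams fit_simca
#' @return List with per-class `confusion` ([confusion_summary()]), the
#'   component counts used, and `coomans` coordinates (cross-validated for
#'   own-class samples) when exactly two classes are modeled.
#' @export
loo_validate_simca <- function(table, metadata, class_labels,
                               components = NULL, alpha = 0.05,
                               scaling = scaling_spec()) {
  stopifnot(inherits(table, "metabolite_table"))
  metadata <- as.data.frame(metadata)
  check_metadata_match(table, metadata)
  gcol <- group_column(metadata)
  full <- fit_simca(table, metadata, class_labels, components = components,
                    alpha = alpha, scaling = scaling)
  used_components <- vapply(full$classes, function(cl) cl$model$A, integer(1))

  md <- metadata[match(table$sample_ids, metadata$sample_id), ]
  confusion <- list()
  dist_cv <- matrix(NA_real_, nrow(table$values), length(class_labels),
                    dimnames = list(table$sample_ids, class_labels))
  for (label in class_labels) {
    own <- which(md[[gcol]] == label)
    other <- which(md[[gcol]] %in% setdiff(class_labels, label))
    a <- used_components[[label]]
    inside_own <- logical(length(own))
    for (k in seq_along(own)) {
      train <- setdiff(own, own[k])
      if (length(train) < a + 2)
        stopf("class '%s' too small for leave-one-out with %d component(s)",
              label, a)
      fit <- fit_pca(table$values[train, , drop = FALSE], a, scaling = scaling)
      d <- dmodx(fit, table$values[own[k], , drop = FALSE],
                 is_training = FALSE, alpha = alpha)
      inside_own[k] <- d$inside
      dist_cv[own[k], label] <- d$dmodx_norm
    }
    d_other <- dmodx(full$classes[[label]]$model,
                     table$values[other, , drop = FALSE],
                     is_training = FALSE, alpha = alpha)
    dist_cv[other, label] <- d_other$dmodx_norm
    confusion[[label]] <- confusion_summary(tp = sum(inside_own),
                                            fn = sum(!inside_own),
                                            tn = sum(!d_other$inside),
                                            fp = sum(d_other$inside))
  }
  out <- list(confusion = confusion, components = used_components,
              model = full)
  if (length(class_labels) == 2) {
    involved <- md[[gcol]] %in% class_labels
    dcrits <- vapply(full$classes, `[[`, numeric(1), "dcrit")
    out$coomans <- data.frame(sample = table$sample_ids[involved],
                              label = md[[gcol]][involved],
                              d1 = dist_cv[involved, 1],
                              d2 = dist_cv[involved, 2],
                              dcrit1 = dcrits[1], dcrit2 = dcrits[2],
                              stringsAsFactors = FALSE)
  }
  out
}
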