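#' Fit an internal-standard normalization model
#'
#' Between-sample intensity differences in GC-MS peak areas arise mainly from
#' injection/inlet efficiency and ion suppression, which act multiplicatively
#' on every compound of a sample. The spiked isotopically labeled internal
#' standards carry only this systematic variation, so a one-component
#' non-centered principal component model of the internal-standard matrix
#' captures it: the magnitude of a sample's t1 score is taken as its general
#' intensity level. Internal-standard columns are first divided by their
#' column means (unit-mean scaling) so no single high-abundance standard
#' dominates, and the per-sample factors are rescaled to median 1 so
#' normalized data stay on the original intensity scale.
#'
#' @param table A `metabolite_table` containing at least two
#'   internal-standard columns, all strictly positive.
#' @return An object of class `normalization_model` with the standard names,
#'   per-standard column divisors, per-sample `factors` (median 1) and the
#'   `rescale_constant` removed from the raw t1 magnitudes.
#' @export
fit_is_normalizer <- function(table) {
  stopifnot(inherits(table, "metabolite_table"))
  is_idx <- which(table$features$is_internal_standard)
  if (length(is_idx) < 2)
    stopf("need >= 2 internal-standard columns, found %d", length(is_idx))
  IS <- table$values[, is_idx, drop = FALSE]
  if (any(IS <= 0)) {
    bad <- colnames(IS)[apply(IS <= 0, 2, any)]
    stopf("internal standard(s) with nonpositive entries: %s",
          paste(bad, collapse = ", "))
  }
  column_scale <- colMeans(IS)
  ISs <- sweep(IS, 2, column_scale, "/")
  fit <- fit_pca(ISs, A = 1, scaling = scaling_spec(center = FALSE, mode = "none"),
                 tol = 1e-12)
  raw <- abs(fit$T[, 1])
  if (any(raw == 0)) stopf("degenerate internal-standard profile (zero t1 score)")
  rescale_constant <- median(raw)
  factors <- raw / rescale_constant
  names(factors) <- table$sample_ids
  structure(list(is_names = colnames(IS), column_scale = column_scale,
                 factors = factors, rescale_constant = rescale_constant,
                 loading = fit$P[, 1]),
            class = "normalization_model")
}

#' @export
print.normalization_model <- function(x, ...) {
  cat(sprintf("normalization_model: %d internal standards, %d samples, factor range [%.3f, %.3f]\n",
              length(x$is_names), length(x$factors), min(x$factors),
              max(x$factors)))
  invisible(x)
}

#' Apply an internal-standard normalization model
#'
#' Divides every analyte value by its sample's intensity factor and drops the
#' internal-standard columns from the output.
#'
#' @param table A `metabolite_table` whose sample ids all have factors in
#'   `model`.
#' @param model A `normalization_model` from [fit_is_normalizer()].
#' @return A normalized `metabolite_table` without internal-standard columns.
#' @export
apply_normalizer <- function(table, model) {
  stopifnot(inherits(table, "metabolite_table"),
            inherits(model, "normalization_model"))
  unknown <- setdiff(table$sample_ids, names(model$factors))
  if (length(unknown) > 0)
    stopf("sample id(s) without a normalization factor: %s",
          paste(unknown, collapse = ", "))
  f <- model$factors[table$sample_ids]
  keep <- !table$features$is_internal_standard
  if (!any(keep)) stopf("table has no analyte columns to normalize")
  vals <- sweep(table$values[, keep, drop = FALSE], 1, f, "/")
  metabolite_table(vals, table$sample_ids, table$features[keep, , drop = FALSE])
}

#' Write per-sample normalization factors to TSV
#'
#' @param model A `normalization_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_normalization_factors <- function(model, path) {
  write.table(data.frame(sample_id = names(model$factors),
                         factor = unname(model$factors)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
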