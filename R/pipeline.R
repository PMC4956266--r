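pipeline_log <- function(log, msg) c(log, msg)

#' Run the full classification analysis pipeline
#'
#' Executes the analysis sequence on a cohort table: internal-standard
#' normalization (fit on the IS columns, applied and IS dropped), feature
#' filtering per `config$feature_set`, subgroup pooling, a phenotype
#' overview PCA of the three lupus subgroups, a pooled four-group overview
#' PCA with per-score ROC panels, SIMCA class models for SLE and HV with
#' leave-one-out validation plus soft prediction of the pSS/SSc groups, the
#' configured OPLS-DA contrasts (p(corr) profile, cross-validation,
#' CV-ANOVA, CV-ROC and confusion summary each), per-contrast univariate
#' significance tables, and a joint cross-contrast p(corr) comparison for
#' the disease-vs-HV models. Steps whose required groups are absent are
#' skipped with a logged notice; everything else still runs. Deterministic
#' given the seed in `config`.
#'
#' @param table A raw `metabolite_table` including internal-standard
#'   columns.
#' @param metadata Sample metadata (`sample_id`, `group`).
#' @param config An [analysis_config()].
#' @param steps Character vector of stages to run; any of `"overview"`,
#'   `"simca"`, `"oplsda"`, `"significance"` (normalization and filtering
#'   always run).
#' @param out_dir Optional directory; when given, plot-ready TSV/JSON
#'   artifacts and a manifest are written there.
#' @return An object of class `pipeline_result`: a list of per-step
#'   artifacts plus a `provenance` block (config, seed, feature set,
#'   scaling, package version) and the step `log`.
#' @export
run_pipeline <- function(table, metadata, config = analysis_config(),
                         steps = c("overview", "simca", "oplsda",
                                   "significance"),
                         out_dir = NULL) {
  stopifnot(inherits(table, "metabolite_table"),
            inherits(config, "analysis_config"))
  metadata <- validate_metadata(metadata)
  check_metadata_match(table, metadata)
  log <- character()
  result <- list()

  norm_model <- fit_is_normalizer(table)
  normalized <- apply_normalizer(table, norm_model)
  log <- pipeline_log(log, sprintf(
    "normalized %d samples on %d internal standards",
    length(norm_model$factors), length(norm_model$is_names)))
  if (config$feature_set == "identified") {
    normalized <- filter_features(normalized, drop_internal_standards = TRUE,
                                  drop_unidentified = TRUE)
    log <- pipeline_log(log, sprintf("restricted to %d identified features",
                                     ncol(normalized$values)))
  }
  metadata <- pool_sle_subgroups(metadata)
  md <- metadata[match(normalized$sample_ids, metadata$sample_id), ]
  small <- names(which(table(md$pooled_group) < 10))
  if (length(small) > 0)
    log <- pipeline_log(log, sprintf("warning: group(s) with < 10 samples: %s",
                                     paste(small, collapse = ", ")))
  result$normalization <- norm_model
  result$table <- normalized
  result$metadata <- metadata
  present <- unique(md$pooled_group)
  scaling <- config$scaling

  if ("overview" %in% steps) {
    sle_rows <- md$pooled_group == "SLE"
    if (sum(sle_rows) >= config$n_components_overview + 2) {
      A <- min(config$n_components_overview,
               sum(sle_rows) - as.integer(scaling$center))
      result$overview_phenotypes <- list(
        model = fit_pca(normalized$values[sle_rows, , drop = FALSE], A,
                        scaling = scaling),
        groups = md$group[sle_rows])
      log <- pipeline_log(log, sprintf(
        "phenotype overview PCA: %d samples, %d components", sum(sle_rows), A))
    } else {
      log <- pipeline_log(log, "skipped phenotype overview: too few SLE samples")
    }
    A4 <- min(config$n_components_overview,
              nrow(normalized$values) - as.integer(scaling$center))
    four <- fit_pca(normalized$values, A4, scaling = scaling)
    roc_pairs <- list(c("SLE", "HV"), c("HV", "SSc"), c("SSc", "pSS"),
                      c("SLE", "SSc"), c("SLE", "pSS"))
    rocs <- list()
    for (pr in roc_pairs) {
      if (!all(pr %in% present)) {
        log <- pipeline_log(log, sprintf(
          "skipped score ROC %s vs %s: group absent", pr[1], pr[2]))
        next
      }
      rows <- md$pooled_group %in% pr
      sub <- fit_pca(normalized$values[rows, , drop = FALSE],
                     min(2L, A4), scaling = scaling)
      rocs[[paste(pr, collapse = "_vs_")]] <-
        pca_score_roc(sub, md$pooled_group[rows] == pr[1],
                      components = seq_len(min(2L, sub$A)),
                      positive_label = TRUE)
    }
    result$overview_four_group <- list(model = four,
                                       groups = md$pooled_group,
                                       score_roc = rocs)
  }

  if ("simca" %in% steps) {
    if (all(c("SLE", "HV") %in% present)) {
      loo <- loo_validate_simca(normalized, metadata, c("SLE", "HV"),
                                components = config$simca_components_per_class,
                                alpha = config$alpha, scaling = scaling)
      external <- setdiff(intersect(c("pSS", "SSc"), present), character(0))
      prediction <- NULL
      if (length(external) > 0) {
        rows <- md$pooled_group %in% external
        prediction <- classify_simca(loo$model,
                                     normalized$values[rows, , drop = FALSE],
                                     labels_new = md$pooled_group[rows])
        # specificity of each class model against the external disease groups
        spec_ext <- colMeans(!prediction$membership)
        prediction$external_specificity <- spec_ext
        prediction$external_specificity_mean <- mean(spec_ext)
      }
      result$simca <- list(loo = loo, prediction = prediction)
      log <- pipeline_log(log, sprintf(
        "SIMCA SLE/HV LOO done (components: %s)",
        paste(loo$components, collapse = "/")))
    } else {
      log <- pipeline_log(log, "skipped SIMCA: SLE or HV group absent")
    }
  }

  if ("oplsda" %in% steps) {
    contrasts <- list()
    for (ct in config$contrasts) {
      key <- paste(ct, collapse = "_vs_")
      if (!all(ct %in% present)) {
        log <- pipeline_log(log, sprintf("skipped OPLS-DA %s: group absent", key))
        next
      }
      rows <- md$pooled_group %in% ct
      X <- normalized$values[rows, , drop = FALSE]
      labs <- md$pooled_group[rows]
      fit <- fit_oplsda(X, labs, positive_class = ct[1],
                        n_orth = config$opls_orthogonal_components,
                        scaling = scaling)
      cv <- cross_validate_oplsda(X, labs, positive_class = ct[1],
                                  n_orth = config$opls_orthogonal_components,
                                  folds = min(config$cv_folds, min(table(labs))),
                                  scaling = scaling)
      contrasts[[key]] <- list(contrast = ct, model = fit, cv = cv,
                               cv_anova = cv_anova(cv),
                               roc = roc_auc(cv$yhat_cv, cv$y == 1,
                                             positive_label = TRUE),
                               confusion = confusion_from_cv(cv))
      log <- pipeline_log(log, sprintf("OPLS-DA %s: Q2 = %.3f", key, cv$q2))
    }
    result$oplsda <- contrasts
    vs_hv <- contrasts[grepl("_vs_HV$", names(contrasts))]
    if (length(vs_hv) > 0)
      result$profile_comparison <- compare_profiles(
        lapply(vs_hv, `[[`, "model"))
  }

  if ("significance" %in% steps) {
    tables <- list()
    for (ct in config$contrasts) {
      key <- paste(ct, collapse = "_vs_")
      if (!all(ct %in% present)) next
      tables[[key]] <- significance_table(normalized, metadata, ct,
                                          alpha = config$alpha)
    }
    result$significance <- tables
  }

  result$provenance <- list(seed = config$seed, alpha = config$alpha,
                            feature_set = config$feature_set,
                            scaling = unclass(scaling),
                            cv_folds = config$cv_folds,
                            n_features = ncol(normalized$values),
                            package_version =
                              as.character(utils::packageVersion("metaboclass")))
  result$log <- log
  result <- structure(result, class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  for (line in x$log) cat(" -", line, "\n")
  invisible(x)
}

#' Joint cross-contrast p(corr) comparison table
#'
#' One row per feature and one p(corr) column per OPLS-DA contrast, all on
#' the shared sign convention of the fitted models (positive = higher in the
#' model's positive class, i.e. the disease in disease-vs-HV contrasts).
#'
#' @param models Named list of `opls_model` objects sharing a feature set.
#' @param feature_order Optional character vector ordering the rows.
#' @return Data frame: `feature` plus one column per model.
#' @export
compare_profiles <- function(models, feature_order = NULL) {
  if (length(models) == 0) stopf("no models supplied")
  feats <- models[[1]]$var_names
  for (m in models)
    if (!identical(m$var_names, feats))
      stopf("models do not share a feature set")
  out <- data.frame(feature = feats, stringsAsFactors = FALSE)
  for (nm in names(models)) out[[nm]] <- unname(models[[nm]]$pcorr)
  if (!is.null(feature_order)) {
    idx <- match(feature_order, out$feature)
    if (anyNA(idx)) stopf("feature_order contains unknown feature(s)")
    out <- out[idx, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# Write plot-ready TSV/JSON artifacts plus a manifest to a run directory.
write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit_tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, name)
  }
  emit_json <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <<- c(files, name)
  }
  write_normalization_factors(result$normalization,
                              file.path(out_dir, "normalization_factors.tsv"))
  files <- c(files, "normalization_factors.tsv")
  if (!is.null(result$overview_four_group)) {
    m <- result$overview_four_group$model
    emit_tsv(data.frame(sample = rownames(m$T), group =
                          result$overview_four_group$groups, m$T),
             "overview_scores.tsv")
  }
  if (!is.null(result$simca) && !is.null(result$simca$loo$coomans))
    emit_tsv(result$simca$loo$coomans, "coomans.tsv")
  if (!is.null(result$simca))
    emit_json(lapply(result$simca$loo$confusion, unclass),
              "simca_confusion.json")
  for (key in names(result$oplsda)) {
    ct <- result$oplsda[[key]]
    emit_tsv(data.frame(feature = ct$model$var_names,
                        pcorr = unname(ct$model$pcorr),
                        direction = sign(unname(ct$model$pcorr))),
             sprintf("pcorr_%s.tsv", key))
    emit_tsv(data.frame(sample = seq_along(ct$cv$yhat_cv),
                        label = ct$cv$labels, y = ct$cv$y,
                        yhat_cv = ct$cv$yhat_cv, fold = ct$cv$fold),
             sprintf("cv_predictions_%s.tsv", key))
    emit_json(list(contrast = ct$contrast, q2 = ct$cv$q2,
                   r2x = ct$model$r2x, r2y = ct$model$r2y,
                   cv_anova = ct$cv_anova, auc = ct$roc$auc,
                   confusion = unclass(ct$confusion)),
              sprintf("oplsda_%s.json", key))
  }
  for (key in names(result$significance))
    emit_tsv(result$significance[[key]], sprintf("significance_%s.tsv", key))
  if (!is.null(result$profile_comparison))
    emit_tsv(result$profile_comparison, "profile_comparison.tsv")
  emit_json(list(provenance = result$provenance, log = result$log,
                 files = files), "manifest.json")
  invisible(out_dir)
}
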