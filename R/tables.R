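#' Sample group labels
#'
#' Controlled vocabulary for the cohort design: three lupus phenotype
#' subgroups (mild, moderately severe, glomerulonephritis), primary
#' Sjogren's syndrome, limited and diffuse cutaneous systemic sclerosis,
#' and healthy volunteers. Labels are case-sensitive; unknown labels are
#' rejected at load time rather than coerced.
#'
#' @format Character vectors.
#' @name group-levels
NULL

#' @rdname group-levels
#' @export
GROUP_LEVELS <- c("SLE_G1", "SLE_G2", "SLE_G3", "pSS", "SSc_lc", "SSc_dc", "HV")

#' @rdname group-levels
#' @export
POOLED_LEVELS <- c("SLE", "pSS", "SSc", "HV")

CHEM_CLASSES <- c("amino_acid", "organic_acid", "fatty_acid", "purine",
                  "other", "unknown")

#' Construct a metabolite intensity table
#'
#' Bundles a samples x features matrix of nonnegative relative intensities
#' (arbitrary peak-area units) with per-feature annotations. The object is
#' validated on construction: dimensions must agree with the identifier
#' vectors, identifiers must be unique, and all values must be finite and
#' nonnegative (missing values are rejected, not imputed).
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param sample_ids Character vector of unique sample identifiers.
#' @param features Data frame of feature annotations with columns `name`,
#'   `identified` (logical), `chem_class` (one of `amino_acid`,
#'   `organic_acid`, `fatty_acid`, `purine`, `other`, `unknown`),
#'   `is_internal_standard` (logical) and `retention_index` (numeric, may be
#'   `NA`).
#' @return An object of class `metabolite_table` with elements `values`,
#'   `sample_ids`, `features`.
#' @export
metabolite_table <- function(values, sample_ids, features) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  required <- c("name", "identified", "chem_class", "is_internal_standard",
                "retention_index")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols) > 0)
    stopf("feature annotations lack column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (nrow(values) != length(sample_ids))
    stopf("values has %d rows but %d sample ids", nrow(values),
          length(sample_ids))
  if (ncol(values) != nrow(features))
    stopf("values has %d columns but %d feature annotations", ncol(values),
          nrow(features))
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s) > 0)
    stopf("duplicate sample id(s): %s", paste(dup_s, collapse = ", "))
  dup_f <- unique(features$name[duplicated(features$name)])
  if (length(dup_f) > 0)
    stopf("duplicate feature name(s): %s", paste(dup_f, collapse = ", "))
  bad_class <- setdiff(unique(features$chem_class), CHEM_CLASSES)
  if (length(bad_class) > 0)
    stopf("unknown chem_class value(s): %s", paste(bad_class, collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stopf("intensity matrix contains missing or non-finite values")
  if (any(values < 0))
    stopf("intensity matrix contains negative values")
  if (any(features$is_internal_standard & features$identified))
    stopf("internal standards must not be flagged as identified analytes")
  dimnames(values) <- list(as.character(sample_ids), features$name)
  structure(list(values = values,
                 sample_ids = as.character(sample_ids),
                 features = features),
            class = "metabolite_table")
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat(sprintf("metabolite_table: %d samples x %d features (%d identified, %d internal standards)\n",
              nrow(x$values), ncol(x$values), sum(x$features$identified),
              sum(x$features$is_internal_standard)))
  invisible(x)
}

#' @export
dim.metabolite_table <- function(x) dim(x$values)

validate_metadata <- function(metadata) {
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(metadata)))
    stopf("metadata needs columns sample_id and group")
  bad <- setdiff(unique(metadata$group), GROUP_LEVELS)
  if (length(bad) > 0)
    stopf("unknown group label(s): %s (allowed: %s)",
          paste(bad, collapse = ", "), paste(GROUP_LEVELS, collapse = ", "))
  dup <- unique(metadata$sample_id[duplicated(metadata$sample_id)])
  if (length(dup) > 0)
    stopf("duplicate metadata sample id(s): %s", paste(dup, collapse = ", "))
  metadata
}

check_metadata_match <- function(table, metadata) {
  orphans <- setdiff(table$sample_ids, metadata$sample_id)
  if (length(orphans) > 0)
    stopf("sample(s) missing from metadata: %s", paste(orphans, collapse = ", "))
  invisible(TRUE)
}

#' Read a metabolite table and sample metadata from tab-separated files
#'
#' The intensity table is tab-separated UTF-8 with one header row naming the
#' features and the first column holding sample identifiers. Metadata is a
#' second TSV with at least `sample_id` and `group` columns; feature
#' annotations may be supplied as a third TSV (columns as in
#' [metabolite_table()]); when absent, all features default to unidentified
#' non-standards.
#'
#' @param path Path to the intensity TSV.
#' @param metadata_path Path to the sample metadata TSV.
#' @param annotations_path Optional path to the feature annotation TSV.
#' @return A list with elements `table` (a `metabolite_table`) and
#'   `metadata` (a data frame, one row per sample).
#' @export
read_metabolite_table <- function(path, metadata_path, annotations_path = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (!file.exists(metadata_path)) stopf("no such file: %s", metadata_path)
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = NULL)
  if (ncol(raw) < 2) stopf("intensity table needs sample ids plus >= 1 feature")
  sample_ids <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stopf("non-numeric cell '%s' at sample '%s', feature '%s'",
          vals[i, j], sample_ids[i], colnames(vals)[j])
  }
  colnames(num) <- colnames(vals)
  if (!is.null(annotations_path)) {
    ann <- read.delim(annotations_path, check.names = FALSE,
                      stringsAsFactors = FALSE)
    ann$identified <- as.logical(ann$identified)
    ann$is_internal_standard <- as.logical(ann$is_internal_standard)
    ann$retention_index <- suppressWarnings(as.numeric(ann$retention_index))
    ord <- match(colnames(num), ann$name)
    if (anyNA(ord))
      stopf("feature(s) missing from annotations: %s",
            paste(colnames(num)[is.na(ord)], collapse = ", "))
    ann <- ann[ord, , drop = FALSE]
  } else {
    ann <- data.frame(name = colnames(num), identified = FALSE,
                      chem_class = "unknown", is_internal_standard = FALSE,
                      retention_index = NA_real_, stringsAsFactors = FALSE)
  }
  table <- metabolite_table(num, sample_ids, ann)
  metadata <- validate_metadata(read.delim(metadata_path, check.names = FALSE,
                                           stringsAsFactors = FALSE))
  check_metadata_match(table, metadata)
  list(table = table, metadata = metadata)
}

#' Write a metabolite table (and optionally metadata) to TSV files
#'
#' Inverse of [read_metabolite_table()]: values at full printed precision
#' (17 significant digits) so that a write/read round trip reproduces the
#' table exactly.
#'
#' @param table A `metabolite_table`.
#' @param path Output path for the intensity TSV.
#' @param annotations_path Optional output path for feature annotations.
#' @param metadata,metadata_path Optional metadata data frame and its path.
#' @return Invisibly, `path`.
#' @export
write_metabolite_table <- function(table, path, annotations_path = NULL,
                                   metadata = NULL, metadata_path = NULL) {
  stopifnot(inherits(table, "metabolite_table"))
  df <- data.frame(sample_id = table$sample_ids,
                   format(table$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", table$features$name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  if (!is.null(annotations_path))
    write.table(table$features, annotations_path, sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(metadata) && !is.null(metadata_path))
    write.table(metadata, metadata_path, sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Pool clinical subgroups into disease-level groups
#'
#' The three lupus phenotype subgroups are pooled into a single SLE group and
#' the limited/diffuse cutaneous sclerosis subgroups into a single SSc group;
#' pSS and HV map to themselves. The original subgroup label is preserved in
#' `group` and the pooled label added as `pooled_group`. Idempotent.
#'
#' @param metadata Data frame with columns `sample_id` and `group`.
#' @return The metadata with a `pooled_group` column.
#' @export
pool_sle_subgroups <- function(metadata) {
  metadata <- validate_metadata(metadata)
  map <- c(SLE_G1 = "SLE", SLE_G2 = "SLE", SLE_G3 = "SLE",
           pSS = "pSS", SSc_lc = "SSc", SSc_dc = "SSc", HV = "HV")
  metadata$pooled_group <- unname(map[metadata$group])
  metadata
}

#' Subset the feature columns of a metabolite table
#'
#' Drops internal-standard columns and/or unidentified putative features,
#' keeping sample rows untouched. The standard modeling set drops both,
#' leaving only uniquely identified analytes.
#'
#' @param table A `metabolite_table`.
#' @param drop_internal_standards Drop internal-standard columns?
#' @param drop_unidentified Drop features not flagged `identified`?
#' @return A new `metabolite_table` with the surviving columns, in the
#'   original order.
#' @export
filter_features <- function(table, drop_internal_standards = TRUE,
                            drop_unidentified = TRUE) {
  stopifnot(inherits(table, "metabolite_table"))
  keep <- rep(TRUE, nrow(table$features))
  is_std <- table$features$is_internal_standard
  if (drop_internal_standards) keep <- keep & !is_std
  if (drop_unidentified) keep <- keep & (table$features$identified | is_std)
  if (!any(keep)) stopf("feature filter removed all features")
  metabolite_table(table$values[, keep, drop = FALSE], table$sample_ids,
                   table$features[keep, , drop = FALSE])
}

#' Analysis configuration
#'
#' Collects the tunable parameters of the full analysis pipeline. Defaults
#' follow the study conventions: membership and significance tests at
#' alpha = 0.05, 7-fold cross-validation for OPLS-DA, a +/- 10 index-unit
#' retention window, and modeling restricted to identified analytes.
#'
#' @param scaling A [scaling_spec()] used by all latent-variable models.
#' @param n_components_overview Components for the overview PCA models.
#' @param simca_components_per_class Named integer vector of per-class
#'   component counts, or `NULL` to select each by leave-one-out Q2.
#' @param alpha Significance level for DCrit and univariate tests.
#' @param cv_folds Folds for OPLS-DA cross-validation.
#' @param opls_orthogonal_components Orthogonal components per OPLS-DA model.
#' @param seed Integer seed controlling any randomized step.
#' @param ri_window Retention-index acceptance half-width (index units).
#' @param min_match_value Minimum spectral match value for identification.
#' @param feature_set `"identified"` (default) or `"all"` putative features.
#' @param contrasts List of length-2 character vectors (disease first) for
#'   the OPLS-DA contrasts.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(scaling = scaling_spec(),
                            n_components_overview = 4L,
                            simca_components_per_class = NULL,
                            alpha = 0.05,
                            cv_folds = 7L,
                            opls_orthogonal_components = 1L,
                            seed = 1L,
                            ri_window = 10,
                            min_match_value = 700,
                            feature_set = c("identified", "all"),
                            contrasts = list(c("SLE", "HV"), c("SSc", "HV"),
                                             c("pSS", "HV"), c("SLE", "pSS"),
                                             c("SLE", "SSc"))) {
  feature_set <- match.arg(feature_set)
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  counts <- c(n_components_overview, cv_folds, opls_orthogonal_components + 1L)
  if (any(counts < 1)) stopf("component/fold counts must be >= 1")
  if (ri_window <= 0) stopf("ri_window must be positive")
  structure(list(scaling = scaling,
                 n_components_overview = as.integer(n_components_overview),
                 simca_components_per_class = simca_components_per_class,
                 alpha = alpha, cv_folds = as.integer(cv_folds),
                 opls_orthogonal_components = as.integer(opls_orthogonal_components),
                 seed = as.integer(seed), ri_window = ri_window,
                 min_match_value = min_match_value, feature_set = feature_set,
                 contrasts = contrasts),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' Fields absent from the file keep their [analysis_config()] defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$scaling))
    raw$scaling <- scaling_spec(center = isTRUE(raw$scaling$center),
                                mode = raw$scaling$mode)
  if (!is.null(raw$contrasts))
    raw$contrasts <- lapply(raw$contrasts, as.character)
  do.call(analysis_config, raw)
}
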