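# Canonical identified-metabolite panel used by the generator: 26 amino
# acids, 10 organic acids, 8 fatty acids, 4 purines and 25 other serum
# metabolites = 73 uniquely identified analytes.
identified_panel <- function() {
  amino <- c("alanine", "arginine", "asparagine", "aspartic acid", "cysteine",
             "glutamic acid", "glutamine", "glycine", "histidine",
             "isoleucine", "leucine", "lysine", "methionine", "phenylalanine",
             "proline", "serine", "threonine", "tryptophan", "tyrosine",
             "valine", "ornithine", "citrulline", "cystine", "taurine",
             "4-hydroxyproline", "beta-alanine")
  organic <- c("fumaric acid", "citric acid", "succinic acid", "lactic acid",
               "malic acid", "2-oxoglutaric acid", "pyruvic acid",
               "glyceric acid", "oxalic acid", "benzoic acid")
  fatty <- c("palmitic acid", "stearic acid", "oleic acid", "linoleic acid",
             "myristic acid", "arachidonic acid", "palmitoleic acid",
             "heptadecanoic acid")
  purine <- c("hypoxanthine", "uric acid", "xanthine", "inosine")
  other <- c("urea", "creatinine", "cholesterol", "glycerol", "glucose",
             "fructose", "galactose", "myo-inositol", "caffeine",
             "theobromine", "quinic acid", "ribose", "mannose", "sorbitol",
             "ethanolamine", "phosphoric acid", "alpha-tocopherol",
             "threitol", "erythritol", "glycerol-3-phosphate", "maltose",
             "sucrose", "pseudouridine", "hippuric acid", "squalene")
  data.frame(name = c(amino, organic, fatty, purine, other),
             chem_class = rep(c("amino_acid", "organic_acid", "fatty_acid",
                                "purine", "other"),
                              c(length(amino), length(organic), length(fatty),
                                length(purine), length(other))),
             stringsAsFactors = FALSE)
}

#' Default planted group-effect specification
#'
#' Natural-log fold-changes versus the healthy-volunteer baseline for the
#' identified analytes, chosen to mirror the qualitative disease profiles the
#' analysis is designed to recover. Versus HV, the SLE column has exactly 5
#' up-shifted and 15 down-shifted analytes (|delta| >= 0.4): tryptophan
#' carries the single largest down-shift (-1.0, the top discriminator by
#' construction); urea, uric acid and cystine are up together with two fatty
#' acids; arginine, ornithine, hypoxanthine, cysteine, tyrosine, fumaric acid
#' and a broad set of amino acids are down. The SSc column down-shifts fewer
#' amino acids than SLE and turns arginine up; the pSS column raises several
#' organic acids, including fumaric acid (down in SLE, so its sign flips
#' between the two contrasts). All unlisted features have zero effect in
#' every group.
#'
#' @return An object of class `effect_spec`: a data frame with columns
#'   `feature`, `SLE`, `pSS`, `SSc` (log-scale offsets; HV is the zero
#'   baseline).
#' @export
default_effect_spec <- function() {
  up_sle <- c("urea" = 0.7, "uric acid" = 0.6, "cystine" = 0.6,
              "palmitic acid" = 0.5, "stearic acid" = 0.45)
  down_sle <- c("tryptophan" = -1.0, "arginine" = -0.6, "ornithine" = -0.55,
                "hypoxanthine" = -0.6, "cysteine" = -0.55, "tyrosine" = -0.6,
                "fumaric acid" = -0.5, "glycine" = -0.45, "alanine" = -0.45,
                "valine" = -0.5, "leucine" = -0.5, "isoleucine" = -0.45,
                "serine" = -0.45, "methionine" = -0.5, "threonine" = -0.4)
  sle <- c(up_sle, down_sle)
  ssc <- c("arginine" = 0.5, "2-oxoglutaric acid" = -0.5, "glycine" = -0.45,
           "alanine" = -0.4, "valine" = -0.45, "leucine" = -0.4,
           "serine" = -0.4, "tyrosine" = -0.45, "tryptophan" = -0.4)
  pss <- c("fumaric acid" = 0.5, "citric acid" = 0.45, "succinic acid" = 0.4,
           "malic acid" = 0.45, "tryptophan" = -0.4)
  features <- unique(c(names(sle), names(ssc), names(pss)))
  spec <- data.frame(feature = features,
                     SLE = unname(ifelse(features %in% names(sle), sle[features], 0)),
                     pSS = unname(ifelse(features %in% names(pss), pss[features], 0)),
                     SSc = unname(ifelse(features %in% names(ssc), ssc[features], 0)),
                     stringsAsFactors = FALSE)
  structure(spec, class = c("effect_spec", "data.frame"))
}

#' Generator configuration for synthetic cohorts
#'
#' Defaults reproduce the study design: 10 + 10 + 10 lupus phenotype
#' subgroups, 20 Sjogren's, 9 limited + 10 diffuse sclerosis, 18 healthy
#' volunteers; 243 putative features of which 73 are identified, plus 11
#' isotopically labeled internal standards.
#'
#' @param group_sizes Named integer vector over the seven subgroup labels.
#' @param n_features Number of putative metabolite features (default 243).
#' @param n_identified Number of identified analytes (default 73, <=
#'   `n_features`).
#' @param n_internal_standards Number of internal-standard columns (11).
#' @param baseline_log_mean_range Interval from which per-feature baseline
#'   log-abundances are drawn (natural log of arbitrary peak-area units).
#' @param injection_sigma SD of the per-sample log injection factor (0.25).
#' @param noise_sigma SD of the per-cell log measurement noise (0.15).
#' @param block_correlation Within-chemical-class noise correlation in
#'   [0, 1) (default 0).
#' @param seed Integer RNG seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(group_sizes = c(SLE_G1 = 10, SLE_G2 = 10,
                                             SLE_G3 = 10, pSS = 20,
                                             SSc_lc = 9, SSc_dc = 10,
                                             HV = 18),
                             n_features = 243L, n_identified = 73L,
                             n_internal_standards = 11L,
                             baseline_log_mean_range = c(8, 13),
                             injection_sigma = 0.25, noise_sigma = 0.15,
                             block_correlation = 0, seed = 1L) {
  if (n_identified > n_features) stopf("n_identified exceeds n_features")
  if (injection_sigma < 0 || noise_sigma < 0) stopf("sigmas must be >= 0")
  if (block_correlation < 0 || block_correlation >= 1)
    stopf("block_correlation must lie in [0, 1)")
  bad <- setdiff(names(group_sizes), GROUP_LEVELS)
  if (length(bad) > 0) stopf("unknown group(s): %s", paste(bad, collapse = ", "))
  structure(list(group_sizes = group_sizes,
                 n_features = as.integer(n_features),
                 n_identified = as.integer(n_identified),
                 n_internal_standards = as.integer(n_internal_standards),
                 baseline_log_mean_range = baseline_log_mean_range,
                 injection_sigma = injection_sigma, noise_sigma = noise_sigma,
                 block_correlation = block_correlation,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic serum metabolomics cohort
#'
#' Multiplicative log-normal model of GC-MS peak areas:
#' `x_ij = f_i * b_j * exp(delta_gj) * exp(eps_ij)` where `f_i` is a
#' per-sample log-normal injection/ion-suppression factor shared by every
#' analyte and internal standard of sample i, `b_j` a per-feature baseline
#' abundance, `delta_gj` the planted log-scale effect of sample i's pooled
#' group on feature j, and `eps_ij` Gaussian log-scale measurement noise
#' (optionally equicorrelated within a chemical class). Internal-standard
#' columns carry no group effect. Output is bitwise reproducible for a fixed
#' seed.
#'
#' @param config A [generator_config()].
#' @param effects An `effect_spec`; feature names must exist in the generated
#'   panel. `NULL` plants no effects.
#' @return List with `table` (a `metabolite_table` whose columns are the
#'   putative features followed by the internal standards), `metadata` (with
#'   `pooled_group` set), and `truth` (the per-sample injection factors and
#'   the planted effect spec).
#' @export
generate_cohort <- function(config = generator_config(),
                            effects = default_effect_spec()) {
  stopifnot(inherits(config, "generator_config"))
  if (any(config$group_sizes < 0)) stopf("negative group size")
  gs <- config$group_sizes[config$group_sizes > 0]
  if (length(gs) == 0) stopf("no groups with positive size")

  panel <- identified_panel()
  n_id <- config$n_identified
  if (n_id <= nrow(panel)) {
    id_feats <- panel[seq_len(n_id), , drop = FALSE]
  } else {
    extra <- data.frame(name = sprintf("metabolite_%02d", seq_len(n_id - nrow(panel))),
                        chem_class = "other", stringsAsFactors = FALSE)
    id_feats <- rbind(panel, extra)
  }
  n_unid <- config$n_features - n_id
  features <- data.frame(
    name = c(id_feats$name,
             if (n_unid > 0) sprintf("U%03d", seq_len(n_unid)),
             sprintf("IS_%02d", seq_len(config$n_internal_standards))),
    identified = rep(c(TRUE, FALSE, FALSE),
                     c(n_id, n_unid, config$n_internal_standards)),
    chem_class = c(id_feats$chem_class, rep("unknown", n_unid),
                   rep("other", config$n_internal_standards)),
    is_internal_standard = rep(c(FALSE, TRUE),
                               c(config$n_features, config$n_internal_standards)),
    retention_index = NA_real_,
    stringsAsFactors = FALSE)

  if (!is.null(effects)) {
    missing <- setdiff(effects$feature, features$name)
    if (length(missing) > 0)
      stopf("effect feature(s) not in generated panel: %s",
            paste(missing, collapse = ", "))
  }
  # per-feature x pooled-group offset matrix (zero for IS and unlisted)
  K <- nrow(features)
  delta <- matrix(0, K, 4, dimnames = list(features$name, POOLED_LEVELS))
  if (!is.null(effects)) {
    idx <- match(effects$feature, features$name)
    delta[idx, "SLE"] <- effects$SLE
    delta[idx, "pSS"] <- effects$pSS
    delta[idx, "SSc"] <- effects$SSc
  }
  delta[features$is_internal_standard, ] <- 0

  groups <- rep(names(gs), gs)
  n <- length(groups)
  with_seed(config$seed, {
    ord <- sample.int(n)  # interleave groups in sample order
    groups <- groups[ord]
    sample_ids <- sprintf("S%03d", seq_len(n))
    pooled <- pool_sle_subgroups(data.frame(sample_id = sample_ids,
                                            group = groups,
                                            stringsAsFactors = FALSE))
    f <- exp(rnorm(n, 0, config$injection_sigma))
    b <- exp(runif(K, config$baseline_log_mean_range[1],
                   config$baseline_log_mean_range[2]))
    eps <- matrix(rnorm(n * K, 0, config$noise_sigma), n, K)
    rho <- config$block_correlation
    if (rho > 0) {
      for (cls in unique(features$chem_class)) {
        cols <- which(features$chem_class == cls)
        shared <- rnorm(n, 0, config$noise_sigma)
        eps[, cols] <- sqrt(rho) * shared +
          sqrt(1 - rho) * eps[, cols, drop = FALSE]
      }
    }
    shift <- delta[, pooled$pooled_group, drop = FALSE]  # K x n
    vals <- f * b[col(eps)] * exp(t(shift)) * exp(eps)
    dim(vals) <- c(n, K)
    age <- round(runif(n, 20, 70))
    sex <- ifelse(runif(n) < 0.9, "F", "M")
    metadata <- cbind(pooled, age = age, sex = sex, stringsAsFactors = FALSE)
    list(table = metabolite_table(vals, sample_ids, features),
         metadata = metadata,
         truth = list(injection_factors = stats::setNames(f, sample_ids),
                      effects = effects))
  })
}

#' Generate synthetic spectra, queries and an alkane ladder
#'
#' Builds a random stick-spectrum library, a query set consisting of the
#' library spectra with multiplicative intensity jitter and a known
#' retention-index offset, and a C10-C40 alkane ladder with strictly
#' increasing retention times; the ground-truth name of each query is
#' returned for recovery testing.
#'
#' @param n_compounds Number of library compounds (>= 1).
#' @param seed Integer RNG seed.
#' @param intensity_jitter SD of the log-normal intensity jitter applied to
#'   query peaks (0 = exact copies).
#' @param ri_jitter_sd SD of the Gaussian retention-index offset of queries
#'   (truncated to +/- 8 so defaults stay within the acceptance window).
#' @return List with `library` (spectral_library_entry list), `queries`
#'   (each a list with `spectrum`, `true_name`, `ri`) and `ladder` (an
#'   [alkane_series()]).
#' @export
generate_spectral_fixtures <- function(n_compounds, seed = 1L,
                                       intensity_jitter = 0.1,
                                       ri_jitter_sd = 3) {
  if (n_compounds < 1) stopf("n_compounds must be >= 1")
  with_seed(seed, {
    ladder <- alkane_series(10:40, cumsum(runif(31, 20, 60)) + 150)
    library <- vector("list", n_compounds)
    queries <- vector("list", n_compounds)
    ris <- seq(1050, 3950, length.out = n_compounds)
    for (i in seq_len(n_compounds)) {
      n_peaks <- sample(6:14, 1)
      mz <- sample(50:500, n_peaks)
      intensity <- rexp(n_peaks, rate = 1 / 100)
      intensity[which.max(intensity)] <- max(intensity) + 100  # clear base peak
      sp <- mass_spectrum(mz, intensity)
      library[[i]] <- spectral_library_entry(sprintf("compound_%03d", i), sp, ris[i])
      jit <- if (intensity_jitter > 0)
        sp$intensity * exp(rnorm(n_peaks, 0, intensity_jitter)) else sp$intensity
      off <- max(-8, min(8, rnorm(1, 0, ri_jitter_sd)))
      queries[[i]] <- list(spectrum = mass_spectrum(sp$mz, jit),
                           true_name = library[[i]]$name,
                           ri = ris[i] + off)
    }
    list(library = library, queries = queries, ladder = ladder)
  })
}
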