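# Independent oracles used to cross-check the package's own implementations.

# Textbook one-component PLS1 score on an already-scaled matrix.
pls1_score_oracle <- function(Xs, y) {
  w <- crossprod(Xs, y)[, 1]
  w <- w / sqrt(sum(w^2))
  as.numeric(Xs %*% w)
}

# Principal angles (radians) between the column spaces of A and B.
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(s, -1), 1))
}

# Mann-Whitney AUC by brute-force pair counting with half credit for ties.
mw_auc_oracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Welch statistic from the textbook formulas (no calls into the package).
welch_oracle <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (length(a)^2 * (length(a) - 1)) +
                 vb^2 / (length(b)^2 * (length(b) - 1)))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Tiny hand-built metabolite table fixture.
tiny_table <- function() {
  vals <- matrix(c(1, 2, 3, 4,
                   2, 4, 6, 8,
                   1.5, 3, 4.5, 6), nrow = 3, byrow = TRUE)
  feats <- data.frame(name = c("tryptophan", "urea", "U001", "IS_01"),
                      identified = c(TRUE, TRUE, FALSE, FALSE),
                      chem_class = c("amino_acid", "other", "unknown", "other"),
                      is_internal_standard = c(FALSE, FALSE, FALSE, TRUE),
                      retention_index = c(1700, 1250, NA, 1100),
                      stringsAsFactors = FALSE)
  metabolite_table(vals, c("S1", "S2", "S3"), feats)
}

tiny_metadata <- function() {
  data.frame(sample_id = c("S1", "S2", "S3"),
             group = c("SLE_G1", "HV", "pSS"),
             stringsAsFactors = FALSE)
}

# Two well-separated Gaussian classes for SIMCA/OPLS tests.
two_class_fixture <- function(seed, n_per = 20, K = 15, shift = 2) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * K), n_per, K),
             matrix(rnorm(n_per * K, mean = shift), n_per, K))
  colnames(X) <- paste0("v", seq_len(K))
  list(X = X, labels = rep(c("case", "control"), each = n_per))
}

# Small cohort settings used when a test only needs the study structure,
# not the full 243-feature panel.
small_cohort <- function(seed, effects = default_effect_spec()) {
  generate_cohort(generator_config(seed = seed), effects)
}

normalized_identified <- function(cohort) {
  model <- fit_is_normalizer(cohort$table)
  filter_features(apply_normalizer(cohort$table, model))
}
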