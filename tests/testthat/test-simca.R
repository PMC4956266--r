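simca_metadata <- function(labels) {
  data.frame(sample_id = sprintf("X%03d", seq_along(labels)), group = "HV",
             pooled_group = labels, stringsAsFactors = FALSE)
}

simca_table <- function(X) {
  X <- X - min(X) + 1  # intensities must be nonnegative
  feats <- data.frame(name = colnames(X), identified = TRUE,
                      chem_class = "other", is_internal_standard = FALSE,
                      retention_index = NA_real_, stringsAsFactors = FALSE)
  metabolite_table(X, sprintf("X%03d", seq_len(nrow(X))), feats)
}

test_that("per-class models keep their own training samples inside", {
  frac_inside <- vapply(1:20, function(seed) {
    fx <- two_class_fixture(seed, n_per = 20, K = 12, shift = 3)
    tab <- simca_table(fx$X)
    md <- simca_metadata(fx$labels)
    model <- fit_simca(tab, md, c("case", "control"), components = c(case = 2, control = 2))
    res <- classify_simca(model, tab$values, fx$labels)
    own <- cbind(res$membership[fx$labels == "case", "case"],
                 res$membership[fx$labels == "control", "control"])
    mean(own)
  }, numeric(1))
  expect_gte(median(frac_inside), 0.9)
})

test_that("a single-class model acts as an outlier detector", {
  fx <- two_class_fixture(31, n_per = 25, K = 10, shift = 6)
  tab <- simca_table(fx$X)
  md <- simca_metadata(fx$labels)
  model <- fit_simca(tab, md, "case", components = 2)
  expect_length(model$classes, 1)
  res <- classify_simca(model, tab$values)
  # the far-away other class is mostly rejected
  expect_gt(mean(!res$membership[fx$labels == "control", 1]), 0.9)
  expect_error(fit_simca(tab, md, "missing_class"), "absent")
  expect_error(fit_simca(tab, md, "case", components = 40), "needs|rank")
})

test_that("soft membership allows none, one or both classes", {
  fx <- two_class_fixture(37, n_per = 20, K = 10, shift = 4)
  tab <- simca_table(fx$X)
  md <- simca_metadata(fx$labels)
  model <- fit_simca(tab, md, c("case", "control"),
                     components = c(case = 1, control = 1))
  # sample equal to the class-1 training mean is inside class 1
  mu1 <- matrix(colMeans(tab$values[fx$labels == "case", ]), 1)
  r1 <- classify_simca(model, mu1)
  expect_true(r1$membership[1, "case"])
  # sample far from both models is inside neither
  far <- mu1 + 1000
  r2 <- classify_simca(model, far)
  expect_false(any(r2$membership))
  # Coomans quadrants agree with the membership flags
  res <- classify_simca(model, tab$values, fx$labels)
  both <- res$membership[, 1] & res$membership[, 2]
  expect_identical(res$coomans$quadrant == "both", unname(both))
  expect_identical(res$coomans$quadrant == "neither",
                   unname(!res$membership[, 1] & !res$membership[, 2]))
  expect_error(classify_simca(model, tab$values[, 1:3]), "columns")
})

test_that("membership is invariant to row order and global rescaling", {
  fx <- two_class_fixture(41, n_per = 15, K = 8, shift = 3)
  tab <- simca_table(fx$X)
  md <- simca_metadata(fx$labels)
  model <- fit_simca(tab, md, c("case", "control"),
                     components = c(case = 1, control = 1))
  res <- classify_simca(model, tab$values)
  perm <- sample(nrow(tab$values))
  res_p <- classify_simca(model, tab$values[perm, ])
  expect_identical(unname(res$membership[perm, ]), unname(res_p$membership))
  # rescale train and test identically, refit -> identical membership
  tab2 <- metabolite_table(tab$values * 3.7, tab$sample_ids, tab$features)
  model2 <- fit_simca(tab2, md, c("case", "control"),
                      components = c(case = 1, control = 1))
  res2 <- classify_simca(model2, tab2$values)
  expect_identical(res$membership, res2$membership)
})

test_that("leave-one-out validation computes honest per-class confusion", {
  # duplicated rows as a class: every held-out row lies in the model plane
  set.seed(51)
  base <- matrix(rnorm(40), 4, 10)
  X <- rbind(base[rep(1:4, 3), ], matrix(rnorm(80, mean = 6), 8, 10))
  colnames(X) <- paste0("v", 1:10)
  labels <- rep(c("dup", "other"), c(12, 8))
  tab <- simca_table(X)
  md <- simca_metadata(labels)
  loo <- loo_validate_simca(tab, md, c("dup", "other"),
                            components = c(dup = 2, other = 2))
  expect_equal(loo$confusion$dup$sensitivity, 1)
  # identities hold exactly
  for (cl in loo$confusion) {
    expect_equal(cl$sensitivity, cl$tp / (cl$tp + cl$fn))
    expect_equal(cl$specificity, cl$tn / (cl$fp + cl$tn))
  }
  expect_equal(nrow(loo$coomans), 20)
})

test_that("cross-validated specificity beats the reported floor on effect cohorts", {
  specs <- vapply(1:20, function(seed) {
    coh <- small_cohort(seed + 300)
    tab <- normalized_identified(coh)
    loo <- loo_validate_simca(tab, coh$metadata, c("SLE", "HV"))
    c(loo$confusion$SLE$specificity, loo$confusion$HV$specificity)
  }, numeric(2))
  expect_gte(median(specs[1, ]), 0.67)
  expect_gte(median(specs[2, ]), 0.67)
})

test_that("own-class rejection under the null approximates alpha", {
  # one Gaussian population (with genuine latent structure matching the
  # modeled components) split arbitrarily into two classes. Mean-centered
  # scaling isolates the distance machinery itself: unit-variance scaling
  # adds per-column SD estimation noise that overdisperses the residual at
  # small class sizes (rejection ~0.08-0.10), and structureless pure noise
  # makes a forced component overfit; both push rejection above alpha.
  rej <- unlist(lapply(1:20, function(seed) {
    set.seed(seed)
    K <- 30
    L <- matrix(rnorm(3 * K), 3, K)
    X <- matrix(rnorm(100 * 3), 100, 3) %*% L * 3 + matrix(rnorm(100 * K), 100, K)
    colnames(X) <- paste0("v", 1:K)
    labels <- rep(c("a", "b"), each = 50)
    tab <- simca_table(X)
    md <- simca_metadata(labels)
    loo <- loo_validate_simca(tab, md, c("a", "b"),
                              components = c(a = 3, b = 3), alpha = 0.05,
                              scaling = scaling_spec(center = TRUE, mode = "none"))
    c(1 - loo$confusion$a$sensitivity, 1 - loo$confusion$b$sensitivity)
  }))
  expect_lte(abs(mean(rej) - 0.05), 0.02)
})
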