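test_that("shrunken-centroid update equations match the hand-worked fixture", {
  x <- matrix(c(0, 2, 4, 6), nrow = 1,
              dimnames = list("p1", paste0("s", 1:4)))
  d <- study_design(paste0("s", 1:4), c("c1", "c1", "c2", "c2"))
  m <- fit_nsc(x, d, delta = 1)
  expect_equal(unname(m$overall_centroid), 3, tolerance = 1e-9)
  expect_equal(unname(m$pooled_sd), sqrt(2), tolerance = 1e-9)
  expect_equal(unname(m$m_k), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(m$shrunken_diff[1, "c1"], -(sqrt(2) - 1), tolerance = 1e-9)
  expect_equal(m$shrunken_centroids[1, "c1"], 1 + sqrt(2), tolerance = 1e-9)
  # unshrunken standardized offset is -sqrt(2): reconstruct from delta = 0
  m0 <- fit_nsc(x, d, delta = 0)
  expect_equal(m0$shrunken_diff[1, "c1"], -sqrt(2), tolerance = 1e-9)
  expect_equal(m0$shrunken_centroids[1, ], c(c1 = 1, c2 = 5),
               tolerance = 1e-9)
})

test_that("delta = 0 predictions equal an independent nearest-centroid oracle", {
  for (seed in c(2, 7, 19)) {
    sim <- planted_dataset(seed = seed, n_proteins = 50)
    feats <- transform_counts(sim$counts, zscore = FALSE)
    m <- fit_nsc(feats, sim$design, delta = 0)
    pred <- predict(m, feats)
    oracle <- oracle_nearest_centroid(feats, as.character(sim$design$group),
                                      feats)
    expect_identical(unname(pred), unname(oracle))
  }
})

test_that("full shrinkage leaves priors-only prediction", {
  sim <- planted_dataset(seed = 4, n_proteins = 40)
  feats <- transform_counts(sim$counts, zscore = FALSE)
  m0 <- fit_nsc(feats, sim$design, delta = 0)
  big <- max(abs(m0$shrunken_diff)) + 1
  m <- fit_nsc(feats, sim$design, delta = big)
  expect_true(all(m$shrunken_diff == 0))
  majority <- names(which.max(m$priors))
  expect_true(all(predict(m, feats) == majority))
  expect_error(fit_nsc(feats, sim$design, delta = -1), ">= 0")
})

test_that("cross-validation reaches zero error on separable data, ties -> largest delta", {
  sim <- generate_counts(synthetic_config(
    n_proteins = 30, n_A = 6, n_B = 6, n_up_A = 6, n_up_B = 0,
    lfc = 6, n_signature = 0, dropout = 0, depth_sd = 0, seed = 31))
  feats <- transform_counts(sim$counts, zscore = FALSE)
  cv <- cross_validate_delta(feats, sim$design)
  expect_equal(min(cv$cv_table$errors), 0)
  zero_err <- cv$cv_table$delta[cv$cv_table$errors == 0]
  expect_equal(cv$delta, max(zero_err))          # tie-break to sparsest

  # duplicated grid entries change nothing
  cv2 <- cross_validate_delta(feats, sim$design,
                              delta_grid = c(cv$delta, cv$delta, 0))
  expect_equal(cv2$delta, cv$delta)
})

test_that("label-permuted data cross-validates near the majority-class rate", {
  sim <- generate_null_dataset(synthetic_config(
    n_proteins = 40, n_A = 7, n_B = 9, n_up_A = 0, n_up_B = 0,
    n_signature = 0, seed = 23))
  set.seed(42)
  shuffled <- study_design(sim$design$sample, sample(sim$design$group))
  feats <- transform_counts(sim$counts, zscore = FALSE)
  cv <- cross_validate_delta(feats, shuffled,
                             delta_grid = seq(0, 3, length.out = 8))
  # chance level for 7 vs 9 is 9/16 correct; allow generous slack
  expect_gte(min(cv$cv_table$error_rate), 0.15)
})

test_that("signature selection applies both criteria and ranks by score", {
  sim <- planted_dataset(seed = 6)
  f <- suppressMessages(apply_presence_filter(sim$counts, sim$design))
  de <- suppressMessages(call_differential(f, sim$design, n_perm = 1000,
                                           seed = 8))
  feats <- transform_counts(f, zscore = FALSE)
  model <- fit_nsc(feats, sim$design, delta = 1)
  sig <- select_signature(model, de, size = 3)
  expect_identical(nrow(sig), 3L)
  expect_true(all(diff(sig$score) <= 0))
  # every member satisfies criterion (ii): SI significance
  rec <- de$records
  expect_true(all(rec$significant[match(sig$protein, rec$protein)]))

  # criterion (ii) excludes a top-score protein that is not SI-significant
  de_none <- de
  de_none$records$significant <- FALSE
  de_none$records$significant[match(rec$protein[10:20], rec$protein)] <- TRUE
  sig2 <- select_signature(model, de_none, size = 3)
  expect_true(all(sig2$protein %in% rec$protein[10:20]))

  # fewer eligible than requested: return all with a warning
  de_two <- de
  de_two$records$significant <- FALSE
  de_two$records$significant[1:2] <- TRUE
  expect_warning(sig3 <- select_signature(model, de_two, size = 3),
                 "eligible")
  expect_lte(nrow(sig3), 2L)
})

test_that("combined score is a signed sum of per-protein z-scores", {
  sim <- planted_dataset(seed = 10, n_proteins = 30)
  counts <- sim$counts
  one <- structure(data.frame(protein = "P0001", score = 1, direction = 1L),
                   class = c("signature", "data.frame"))
  s <- combined_score(counts, one)
  z <- (counts["P0001", ] - mean(counts["P0001", ])) /
    stats::sd(counts["P0001", ])
  expect_equal(s, z, tolerance = 1e-12)

  # direction -1 flips the contribution
  one$direction <- -1L
  expect_equal(combined_score(counts, one), -z, tolerance = 1e-12)

  # zero-variance protein contributes 0 with a warning
  counts["P0002", ] <- 5L
  two <- structure(data.frame(protein = c("P0001", "P0002"),
                              score = c(1, 1), direction = c(1L, 1L)),
                   class = c("signature", "data.frame"))
  expect_warning(s2 <- combined_score(counts, two), "zero-variance")
  expect_equal(s2, z, tolerance = 1e-12)
})

test_that("ROC worked example, degenerate cases, and Youden point", {
  d <- study_design(paste0("s", 1:6), rep(c("pos", "neg"), each = 3))
  sc <- setNames(c(3, 4, 5, 1, 2, 3), paste0("s", 1:6))
  r <- roc_curve(sc, d, positive = "pos")
  expect_equal(r$auc, 8.5 / 9, tolerance = 1e-12)

  perfect <- setNames(c(10, 11, 12, 1, 2, 3), paste0("s", 1:6))
  rp <- roc_curve(perfect, d, positive = "pos")
  expect_equal(rp$auc, 1, tolerance = 1e-12)
  expect_equal(unname(rp$youden[c("sensitivity", "specificity")]), c(1, 1))

  flat <- setNames(rep(2, 6), paste0("s", 1:6))
  expect_equal(roc_curve(flat, d, positive = "pos")$auc, 0.5,
               tolerance = 1e-12)
})

test_that("trapezoid AUC equals the pairwise U-statistic on random scores", {
  set.seed(55)
  d <- study_design(paste0("s", 1:12), rep(c("pos", "neg"), c(5, 7)))
  for (i in 1:100) {
    sc <- setNames(sample(0:6, 12, replace = TRUE) + # heavy ties
                     rnorm(12, sd = ifelse(i %% 2, 0, 0.3)),
                   d$sample)
    r <- roc_curve(sc, d, positive = "pos")
    expect_equal(r$auc, oracle_auc_u(sc[1:5], sc[6:12]), tolerance = 1e-10)
  }
})
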