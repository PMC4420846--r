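test_that("MCC reproduces hand-derived values and conventions", {
  expect_equal(compute_mcc(10, 10, 0, 0), 1)
  expect_equal(compute_mcc(0, 0, 5, 5), -1)
  expect_equal(compute_mcc(6, 4, 2, 3), 18 / sqrt(3024))
  expect_equal(compute_mcc(confusion_counts(6, 4, 2, 3)), 18 / sqrt(3024))
  # zero-denominator convention
  expect_equal(compute_mcc(5, 0, 0, 5), 0)
  expect_equal(compute_mcc(0, 0, 0, 0), 0)
})

test_that("MCC symmetry and inversion properties hold", {
  set.seed(13)
  for (rep in 1:50) {
    cc <- sample(0:30, 4, replace = TRUE)
    m <- compute_mcc(cc[1], cc[2], cc[3], cc[4])
    expect_equal(compute_mcc(cc[2], cc[1], cc[4], cc[3]), m)  # class swap
    expect_equal(compute_mcc(cc[4], cc[3], cc[2], cc[1]), -m) # negated preds
    expect_true(m >= -1 && m <= 1)
  }
})

test_that("AUROC equals the all-pairs Mann-Whitney count", {
  expect_equal(compute_auroc(c(2, 3), c(0, 1)), 1)
  expect_equal(compute_auroc(c(0.9, 0.4), c(0.8, 0.1)), 0.75)
  expect_equal(compute_auroc(0.5, 0.5), 0.5)
  set.seed(17)
  for (rep in 1:30) {
    pos <- round(runif(sample(2:8, 1)), 2)
    neg <- round(runif(sample(2:8, 1)), 2)
    pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    expect_equal(compute_auroc(pos, neg), mean(pairs))
    expect_equal(compute_auroc(-pos, -neg), 1 - compute_auroc(pos, neg))
  }
})

test_that("a symmetric 1-D problem puts the boundary at zero", {
  x <- matrix(c(-1, 1), ncol = 1)
  m <- svm_linear(x, c(-1L, 1L), C = 1e4)
  expect_equal(m$b, 0, tolerance = 1e-6)
  expect_equal(predict(m, x), c(-1L, 1L))
  expect_equal(predict(m, matrix(0.5), type = "decision"),
               0.5 * m$w[1], tolerance = 1e-6)
})

test_that("training refuses degenerate inputs", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(svm_linear(x, rep(1L, 5)), "both classes")
  expect_error(svm_linear(x, c(1, 1, -1, -1, -1), C = -1), "positive")
  x[1, 1] <- NA
  expect_error(svm_linear(x, c(1, 1, -1, -1, -1)), "non-finite")
})

test_that("the dual solution matches a brute-force QP oracle on toy sets", {
  set.seed(23)
  for (rep in 1:12) {
    n <- sample(4:6, 1)
    x <- matrix(rnorm(2 * n), n, 2)
    y <- c(rep(1L, 2), rep(-1L, n - 2))
    for (C in c(0.5, 10)) {
      m <- svm_linear(x, y, C = C)
      expect_equal(m$dual_objective, oracle_svm_dual(x, y, C),
                   tolerance = 1e-4)
      check_dual_feasibility(m, y)
    }
  }
})

test_that("dual feasibility holds after every training run", {
  coll <- small_sim(seed = 3)
  fm <- collection_profiles(coll)
  for (C in c(0.01, 1, 100)) {
    m <- svm_linear(fm, C = C)
    expect_true(check_dual_feasibility(m))
    expect_true(all(m$alpha >= -1e-8 & m$alpha <= C + 1e-8))
    expect_lt(abs(sum(m$alpha * fm$y)), 1e-6 * max(1, sum(m$alpha)))
    # w is the support expansion
    expect_equal(m$w, drop(t(m$alpha * fm$y) %*% fm$x), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("training MCC approaches 1 on separable data as C grows", {
  set.seed(29)
  x <- rbind(matrix(rnorm(40, 2), 20, 2), matrix(rnorm(40, -2), 20, 2))
  y <- rep(c(1L, -1L), each = 20)
  m <- svm_linear(x, y, C = 1e4)
  cc <- count_confusion(y, predict(m, x))
  expect_equal(compute_mcc(cc), 1)
})

test_that("cross-validation stratifies by group and selects C by pooled MCC", {
  coll <- small_sim(seed = 8)
  fm <- collection_profiles(coll)
  cv <- cross_validate(fm, k_folds = 5, seed = 42)
  expect_equal(nrow(cv$per_C), 7)       # default grid
  expect_equal(cv$per_C$C, c(0.01, 0.1, 1, 10, 100, 1000, 10000))
  expect_equal(cv$best_mcc, max(cv$per_C$mcc_pooled))
  # tie rule: best_C is the smallest cost attaining the maximum
  tied <- cv$per_C$C[cv$per_C$mcc_pooled == cv$best_mcc]
  expect_equal(cv$best_C, min(tied))
  # pooled counts cover every instance exactly once
  expect_equal(cv$counts$tp + cv$counts$tn + cv$counts$fp + cv$counts$fn,
               nrow(fm$x))
  # folds respect groups
  expect_true(all(tapply(cv$folds, fm$groups,
                         function(f) length(unique(f))) == 1))
})

test_that("noise-free fingerprints cross-validate at MCC 1 for all C >= 1", {
  coll <- simulate_fingerprints(fingerprint_sim_config(
    n_active = 20, n_inactive = 20, n_decoy = 0, n_conformations = 4,
    n_residues = 8, n_signal_bits = 3, flip_prob = 0, background_rate = 0,
    pose_fail_prob = 0, seed = 2))
  fm <- collection_profiles(coll)
  cv <- cross_validate(fm, C_grid = c(1, 10, 100), k_folds = 5, seed = 1)
  expect_true(all(cv$per_C$mcc_pooled == 1))
})

test_that("cross-validation is reproducible for a fixed seed", {
  coll <- small_sim(seed = 12)
  fm <- collection_profiles(coll)
  cv1 <- cross_validate(fm, C_grid = c(0.1, 1), k_folds = 5, seed = 42)
  cv2 <- cross_validate(fm, C_grid = c(0.1, 1), k_folds = 5, seed = 42)
  expect_identical(cv1$per_C, cv2$per_C)
  expect_identical(cv1$folds, cv2$folds)
  expect_error(cross_validate(fm, k_folds = 25, seed = 1), "too few")
})
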