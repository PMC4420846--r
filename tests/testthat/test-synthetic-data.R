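test_that("simulation is bit-identical for a fixed configuration and seed", {
  c1 <- small_sim(seed = 7)
  c2 <- small_sim(seed = 7)
  expect_identical(c1$bits, c2$bits)
  expect_identical(c1$pose, c2$pose)
  c3 <- small_sim(seed = 8)
  expect_false(identical(c1$bits, c3$bits))
})

test_that("generated chunks always satisfy the fingerprint implications", {
  for (s in 1:5) {
    coll <- simulate_fingerprints(fingerprint_sim_config(
      n_active = 15, n_inactive = 15, n_decoy = 10, n_conformations = 4,
      n_residues = 6, n_signal_bits = 4, flip_prob = 0.4,
      background_rate = 0.2, pose_fail_prob = 0.3, seed = s))
    flat <- matrix(aperm(coll$bits, c(3, 1, 2)), nrow = 9)
    any_b <- flat[1, ]; main_b <- flat[2, ]; side_b <- flat[3, ]
    typed <- colSums(flat[4:9, , drop = FALSE])
    expect_true(all(any_b == (typed > 0)))
    expect_true(all(main_b + side_b == any_b))
    expect_true(all((main_b | side_b) <= any_b))
  }
})

test_that("the noiseless limit gives clean profiles and perfect screening", {
  coll <- simulate_fingerprints(fingerprint_sim_config(
    n_active = 12, n_inactive = 12, n_decoy = 0, n_conformations = 5,
    n_residues = 8, n_signal_bits = 3, flip_prob = 0, background_rate = 0,
    pose_fail_prob = 0, seed = 5))
  fm <- collection_profiles(coll)
  act <- coll$labels == "active"
  expect_true(all(fm$x[act, coll$signal_positions] == 1))
  nonsignal <- setdiff(ensift:::typed_positions(8), coll$signal_positions)
  expect_true(all(fm$x[, nonsignal] == 0))
  expect_true(all(fm$x[!act, ] == 0))
  cv <- cross_validate(fm, C_grid = c(1, 10), k_folds = 4, seed = 1)
  expect_equal(cv$best_mcc, 1)
})

test_that("signal-bit profile values follow the binomial mean", {
  # flip probability 0.5: expected profile value 0.5 at signal positions
  coll5 <- simulate_fingerprints(fingerprint_sim_config(
    n_active = 200, n_inactive = 5, n_decoy = 0, n_conformations = 20,
    n_residues = 10, n_signal_bits = 3, flip_prob = 0.5,
    background_rate = 0, pose_fail_prob = 0, seed = 31))
  act <- coll5$labels == "active"
  vals <- collection_profiles(coll5)$x[act, coll5$signal_positions]
  se <- sqrt(0.5 * 0.5 / (20 * sum(act) * 3))
  expect_lt(abs(mean(vals) - 0.5), 3 * se)
  # defaults-like noise: 1 - p = 0.7
  coll7 <- simulate_fingerprints(fingerprint_sim_config(
    n_active = 200, n_inactive = 5, n_decoy = 0, n_conformations = 20,
    n_residues = 10, n_signal_bits = 3, flip_prob = 0.3,
    background_rate = 0.05, pose_fail_prob = 0, seed = 7))
  act <- coll7$labels == "active"
  vals <- collection_profiles(coll7)$x[act, coll7$signal_positions]
  se <- sqrt(0.7 * 0.3 / (20 * sum(act) * 3))
  expect_lt(abs(mean(vals) - 0.7), 3 * se)
})

test_that("profile variance at signal bits shrinks as 1/size", {
  cfg <- fingerprint_sim_config(
    n_active = 400, n_inactive = 5, n_decoy = 0, n_conformations = 20,
    n_residues = 10, n_signal_bits = 3, flip_prob = 0.3,
    background_rate = 0, pose_fail_prob = 0, seed = 13)
  coll <- simulate_fingerprints(cfg)
  act <- coll$labels == "active"
  for (s in c(5, 20)) {
    x <- collection_profiles(coll, coll$conformation_ids[seq_len(s)])$x
    v <- mean(apply(x[act, coll$signal_positions], 2, var))
    expected <- 0.3 * 0.7 / s
    expect_lt(abs(v - expected), 0.35 * expected)
  }
})

test_that("compounds losing every pose are omitted", {
  coll <- simulate_fingerprints(fingerprint_sim_config(
    n_active = 60, n_inactive = 60, n_decoy = 0, n_conformations = 2,
    n_residues = 5, n_signal_bits = 2, pose_fail_prob = 0.6, seed = 19))
  expect_true(all(rowSums(coll$pose) >= 1))
  expect_lt(dim(coll$bits)[1], 120)
})

test_that("centroid-score informativeness maps onto AUROC as designed", {
  # null conformation: AUROC near 0.5
  aurocs <- vapply(1:50, function(s) {
    sc <- simulate_centroid_scores(c(a = 0), n_per_class = 100, seed = s)
    compute_auroc(sc$a$pos, sc$a$neg)
  }, numeric(1))
  expect_lt(abs(mean(aurocs) - 0.5), 3 * sd(aurocs) / sqrt(50))
  # full informativeness: 3 sigma shift -> AUROC = Phi(3/sqrt(2)) ~ 0.983
  hits <- vapply(1:100, function(s) {
    sc <- simulate_centroid_scores(c(a = 1), n_per_class = 100, seed = s)
    compute_auroc(sc$a$pos, sc$a$neg) > 0.95
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  expect_error(simulate_centroid_scores(c(a = 2)), "informativeness")
})

test_that("toy complexes reject unknown interaction classes", {
  expect_error(make_toy_complex(list(c("hb_donor", "halogen"))),
               "unsatisfiable")
  # empty plan still yields a valid (distant) ligand
  tc <- make_toy_complex(list(character(0)))
  expect_gte(nrow(tc$ligand$atoms), 1)
})
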