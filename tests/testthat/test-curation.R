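test_that("affinity thresholds label compounds as printed", {
  rec <- data.frame(
    compound_id = c("a", "b", "c", "d", "e", "f"),
    measure = c("Ki", "IC50", "Ki", "Ki", "Ki", "Ki"),
    value_nM = c(50, 150, 500, 5000, 100, 1000))
  lab <- label_compounds(rec)
  get <- function(id) as.character(lab$label[lab$compound_id == id])
  expect_equal(get("a"), "active")          # Ki 50 < 100
  expect_equal(get("b"), "active")          # IC50 150 -> Ki 75
  expect_equal(get("c"), "excluded")        # 100..1000 band
  expect_equal(get("d"), "inactive")        # Ki 5000 > 1000
  expect_equal(get("e"), "excluded")        # boundary: strict inequality
  expect_equal(get("f"), "excluded")
  expect_error(label_compounds(transform(rec, value_nM = -1)), "positive")
})

test_that("replicates merge by geometric mean and labelling is idempotent", {
  rec <- data.frame(compound_id = c("a", "a", "b"),
                    measure = c("Ki", "Ki", "IC50"),
                    value_nM = c(10, 1000, 30))
  lab <- label_compounds(rec)
  expect_equal(lab$ki_nM[lab$compound_id == "a"], 100)  # sqrt(10 * 1000)
  expect_equal(lab$ki_nM[lab$compound_id == "b"], 15)
  # order independence
  lab2 <- label_compounds(rec[c(3, 1, 2), ])
  expect_equal(lab, lab2)
})

test_that("the cluster-count rule is floor(30%)", {
  expect_equal(cluster_count(271), 81L)
  expect_equal(cluster_count(324), 97L)
  expect_equal(cluster_count(10), 3L)
  expect_equal(cluster_count(1), 1L)
})

test_that("centroids minimise mean intra-cluster Tanimoto distance", {
  set.seed(21)
  # two well-separated fingerprint blobs
  blob <- function(pattern, n, flip = 2) {
    t(vapply(seq_len(n), function(i) {
      v <- pattern
      ix <- sample(length(v), flip)
      v[ix] <- 1 - v[ix]
      v
    }, numeric(length(pattern))))
  }
  p1 <- c(rep(1, 10), rep(0, 20))
  p2 <- c(rep(0, 20), rep(1, 10))
  fp <- rbind(blob(p1, 6), blob(p2, 6))
  rownames(fp) <- sprintf("m%02d", 1:12)
  cent <- cluster_and_pick_centroids(fp, k = 2)
  expect_length(cent, 2)
  # brute-force: each centroid minimises the mean distance in its blob
  d <- 1 - tanimoto_matrix(fp)
  for (members in list(1:6, 7:12)) {
    ids <- rownames(fp)[members]
    got <- intersect(cent, ids)
    expect_length(got, 1)
    meand <- sapply(members, function(i) mean(d[i, setdiff(members, i)]))
    best <- ids[meand == min(meand)]
    expect_true(got %in% best)
  }
})

test_that("degenerate clustering cases obey the tie rules", {
  fp <- matrix(rep(c(1, 0, 1), each = 3), nrow = 3, byrow = FALSE)
  rownames(fp) <- c("b", "a", "c")
  expect_equal(cluster_and_pick_centroids(fp, k = 1), "a")  # lexicographic
  expect_setequal(cluster_and_pick_centroids(fp, k = 3), c("a", "b", "c"))
  expect_error(cluster_and_pick_centroids(fp, k = 4), "exceeds")
  expect_error(cluster_and_pick_centroids(fp[0, ], k = 1), "no compounds")
})

test_that("decoy selection filters by property windows and dissimilarity", {
  set.seed(31)
  actives <- data.frame(compound_id = c("act1", "act2"),
                        mw = c(300, 400), logp = c(2, 3),
                        hbd = c(1, 2), hba = c(3, 4), rotb = c(4, 5))
  afp <- matrix(0, 2, 40, dimnames = list(actives$compound_id, NULL))
  afp[1, 1:10] <- 1
  afp[2, 11:20] <- 1
  n_cand <- 60
  cand <- data.frame(
    compound_id = sprintf("z%03d", seq_len(n_cand)),
    mw = c(rep(305, 30), rep(800, 30)),      # half outside the MW window
    logp = 2.2, hbd = 1, hba = 3, rotb = 4)
  cfp <- matrix(0, n_cand, 40, dimnames = list(cand$compound_id, NULL))
  for (i in seq_len(n_cand)) cfp[i, 20 + (i %% 20)] <- 1
  picked <- select_decoys(cand, cfp, actives, afp, n = 20, seed = 3)
  expect_length(picked, 20)
  expect_true(all(picked %in% cand$compound_id[1:30]))
  # reproducible and disjoint from actives
  expect_equal(picked, select_decoys(cand, cfp, actives, afp, 20, seed = 3))
  expect_false(any(picked %in% actives$compound_id))
  # a candidate identical to an active is excluded (Tanimoto = 1)
  cfp[1, ] <- afp[1, ]
  surv <- select_decoys(cand, cfp, actives, afp, n = 29, seed = 3)
  expect_false("z001" %in% surv)
  expect_error(select_decoys(cand, cfp, actives, afp, n = 30, seed = 3),
               "survive")
})

test_that("brute-force filter enumeration matches select_decoys", {
  actives <- data.frame(compound_id = "a", mw = 300, logp = 2, hbd = 1,
                        hba = 2, rotb = 3)
  afp <- matrix(c(1, 1, 0, 0, 0, 0), 1, dimnames = list("a", NULL))
  cand <- data.frame(
    compound_id = paste0("c", 1:10),
    mw = c(310, 320, 324, 300, 290, 300, 300, 300, 500, 275),
    logp = c(2, 2.5, 2, 3.1, 2, 2, 2, 2, 2, 2),
    hbd = c(1, 1, 1, 1, 3, 1, 1, 1, 1, 1),
    hba = c(2, 2, 2, 2, 2, 5, 2, 2, 2, 2),
    rotb = c(3, 4, 3, 3, 3, 3, 6, 3, 3, 3))
  cfp <- matrix(0, 10, 6, dimnames = list(cand$compound_id, NULL))
  cfp[, 5] <- 1
  cfp[8, ] <- c(1, 1, 0, 0, 1, 0)  # Tanimoto 2/3 > 0.6 to the active
  # survivors by hand: inside all windows and dissimilar
  expect_setequal(select_decoys(cand, cfp, actives, afp, n = 4, seed = 1),
                  c("c1", "c2", "c3", "c10"))
})
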