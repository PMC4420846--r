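test_that("chunks are nine bits wide and concatenated in residue order", {
  tc <- make_toy_complex(list(character(0)))
  s1 <- compute_sift(tc$receptor, tc$ligand)
  expect_length(s1, 9)
  tc3 <- make_toy_complex(list(character(0), "hb_donor", character(0)))
  s3 <- compute_sift(tc3$receptor, tc3$ligand)
  expect_length(s3, 27)
  # only chunk 2 carries bits
  expect_equal(sum(s3[1:9]), 0)
  expect_equal(sum(s3[19:27]), 0)
  expect_gt(sum(s3[10:18]), 0)
})

test_that("a distant ligand yields an all-zero fingerprint", {
  tc <- make_toy_complex(list(character(0), character(0), character(0)))
  expect_equal(sum(compute_sift(tc$receptor, tc$ligand)), 0)
})

test_that("planted interactions set exactly the requested bits", {
  bit <- function(s, res, name)
    s[(res - 1) * 9 + match(name, ensift:::BIT_NAMES)]
  # backbone hydrogen bond donated by the residue
  tc <- make_toy_complex(list("hb_donor"))
  s <- compute_sift(tc$receptor, tc$ligand)
  expect_equal(as.integer(s),
               c(1L, 1L, 0L, 1L, 0L, 0L, 1L, 0L, 0L))
  # side-chain hydrophobic contact
  tc <- make_toy_complex(list(c("side_chain", "hydrophobic")))
  s <- compute_sift(tc$receptor, tc$ligand)
  expect_equal(bit(s, 1, "any"), 1L)
  expect_equal(bit(s, 1, "side_chain"), 1L)
  expect_equal(bit(s, 1, "hydrophobic"), 1L)
  expect_equal(bit(s, 1, "main_chain"), 0L)
  expect_equal(bit(s, 1, "polar"), 0L)
  # all nine classes on one residue
  tc <- make_toy_complex(list(c("main_chain", "side_chain", "polar",
                                "hydrophobic", "hb_acceptor", "hb_donor",
                                "aromatic", "charged")))
  expect_equal(as.integer(compute_sift(tc$receptor, tc$ligand)), rep(1L, 9))
})

test_that("compute_sift matches the exhaustive pairwise oracle", {
  set.seed(101)
  for (rep in 1:300) {
    cx <- random_complex()
    expect_equal(as.integer(compute_sift(cx$receptor, cx$ligand)),
                 oracle_sift(cx$receptor, cx$ligand))
  }
})

test_that("fingerprints are invariant under rigid motion of the complex", {
  rot <- function(theta) matrix(c(cos(theta), -sin(theta), 0,
                                  sin(theta), cos(theta), 0,
                                  0, 0, 1), 3, 3)
  set.seed(7)
  for (rep in 1:20) {
    cx <- random_complex()
    R <- rot(runif(1, 0, 2 * pi))
    shift <- runif(3, -20, 20)
    move <- function(at) {
      xyz <- as.matrix(at[, c("x", "y", "z")]) %*% R
      at$x <- xyz[, 1] + shift[1]
      at$y <- xyz[, 2] + shift[2]
      at$z <- xyz[, 3] + shift[3]
      at
    }
    rec2 <- cx$receptor
    rec2$residues <- lapply(rec2$residues, function(r) {
      r$atoms <- move(r$atoms); r
    })
    lig2 <- cx$ligand
    lig2$atoms <- move(lig2$atoms)
    expect_equal(as.integer(compute_sift(rec2, lig2)),
                 as.integer(compute_sift(cx$receptor, cx$ligand)))
  }
})

test_that("implication chain and cutoff monotonicity hold", {
  set.seed(42)
  base <- geometry_config()
  larger <- geometry_config(contact_cutoff = 6.5)
  bitmat <- function(s) matrix(as.integer(s), ncol = 9, byrow = TRUE,
                               dimnames = list(NULL, ensift:::BIT_NAMES))
  for (rep in 1:100) {
    cx <- random_complex()
    b <- bitmat(compute_sift(cx$receptor, cx$ligand, base))
    typed <- b[, c("polar", "hydrophobic", "hb_acceptor", "hb_donor",
                   "aromatic", "charged"), drop = FALSE]
    expect_true(all(b[rowSums(typed) > 0, "any"] == 1))
    expect_true(all(b[(b[, "hb_donor"] | b[, "hb_acceptor"]) == 1, "polar"] == 1))
    expect_true(all(b[, "main_chain"] + b[, "side_chain"] >= b[, "any"]))
    b2 <- bitmat(compute_sift(cx$receptor, cx$ligand, larger))
    expect_true(all(b2[, "any"] >= b[, "any"]))
  }
})

test_that("geometry config validates its cutoffs and reads key=value files", {
  expect_error(geometry_config(contact_cutoff = -1), "positive")
  expect_error(geometry_config(hbond_dist = 5, contact_cutoff = 4.5),
               "hbond_dist")
  path <- tempfile()
  writeLines(c("contact_cutoff = 5.0", "# comment", "hbond_dist = 3.2"),
             path)
  cfg <- read_geometry_config(path)
  expect_equal(cfg$contact_cutoff, 5.0)
  expect_equal(cfg$hbond_dist, 3.2)
  expect_equal(cfg$polar_cutoff, 3.5)
})

test_that("SIFt tables round-trip through TSV", {
  tc <- make_toy_complex(list("hb_donor", "aromatic"))
  s <- compute_sift(tc$receptor, tc$ligand)
  path <- tempfile(fileext = ".tsv")
  write_sifts(list(s), path)
  back <- read_sifts(path)[[1]]
  expect_equal(as.integer(back), as.integer(s))
  expect_equal(attr(back, "compound_id"), attr(s, "compound_id"))
})
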