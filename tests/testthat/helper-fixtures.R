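# Programmatic fixtures: small molecule files, random toy geometries, and
# the independent brute-force oracles used to validate the fingerprint and
# SVM implementations.

sdf_benzene <- function() {
  c("benzene", "  fixture", "",
    "  6  6  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    1.4000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.2124    0.7000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.2124   -0.7000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000   -1.4000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -1.2124   -0.7000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -1.2124    0.7000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  2  0", "  2  3  1  0", "  3  4  2  0", "  4  5  1  0",
    "  5  6  2  0", "  6  1  1  0",
    "M  END", "$$$$")
}

sdf_ethanol <- function() {
  c("ethanol", "  fixture", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.1000    1.2000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  2  3  1  0",
    "M  END", "$$$$")
}

sdf_acetate <- function() {
  c("acetate", "  fixture", "",
    "  4  3  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.1000    1.1000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.1000   -1.1000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  2  3  2  0", "  2  4  1  0",
    "M  CHG  1   4  -1",
    "M  END", "$$$$")
}

write_fixture_sdf <- function(lines) {
  path <- tempfile(fileext = ".sdf")
  writeLines(lines, path)
  path
}

# A small real-residue PDB written in code: GLY-SER-LEU strand.
write_toy_pdb <- function(path = tempfile(fileext = ".pdb"),
                          with_water = FALSE) {
  fmt <- function(serial, name, res, resno, x, y, z, el) {
    sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, name, res, resno, x, y, z, el)
  }
  lines <- c(
    fmt(1, " N", "GLY", 1, 0, 0, 0, "N"),
    fmt(2, " CA", "GLY", 1, 1.45, 0, 0, "C"),
    fmt(3, " C", "GLY", 1, 2.2, 1.2, 0, "C"),
    fmt(4, " O", "GLY", 1, 3.4, 1.2, 0, "O"),
    fmt(5, " N", "SER", 2, 1.6, 2.4, 0, "N"),
    fmt(6, " CA", "SER", 2, 2.2, 3.7, 0, "C"),
    fmt(7, " C", "SER", 2, 1.4, 4.9, 0.5, "C"),
    fmt(8, " O", "SER", 2, 0.2, 4.9, 0.6, "O"),
    fmt(9, " CB", "SER", 2, 2.6, 4.0, -1.4, "C"),
    fmt(10, " OG", "SER", 2, 3.3, 5.2, -1.5, "O"),
    fmt(11, " N", "LEU", 3, 2.1, 6.0, 0.8, "N"),
    fmt(12, " CA", "LEU", 3, 1.5, 7.3, 1.1, "C"),
    fmt(13, " C", "LEU", 3, 2.5, 8.4, 1.4, "C"),
    fmt(14, " O", "LEU", 3, 3.7, 8.2, 1.4, "O"),
    fmt(15, " CB", "LEU", 3, 0.7, 7.2, 2.4, "C"),
    fmt(16, " CG", "LEU", 3, -0.3, 8.3, 2.7, "C"),
    fmt(17, " CD1", "LEU", 3, -1.1, 8.0, 3.9, "C"),
    fmt(18, " CD2", "LEU", 3, 0.4, 9.6, 2.9, "C"))
  if (with_water)
    lines <- c(lines,
               sub("^ATOM  ", "HETATM",
                   fmt(19, " O", "HOH", 101, 9, 9, 9, "O")))
  writeLines(c(lines, "END"), path)
  path
}

# --- random toy geometries for the fingerprint oracle ---------------------

random_residue <- function(resnum, center, n_atoms) {
  el <- sample(c("C", "N", "O", "S"), n_atoms, replace = TRUE)
  atoms <- data.frame(
    name = paste0(el, seq_len(n_atoms)), element = el,
    x = center[1] + runif(n_atoms, -4, 4),
    y = center[2] + runif(n_atoms, -4, 4),
    z = center[3] + runif(n_atoms, -4, 4),
    is_main_chain = sample(c(TRUE, FALSE), n_atoms, replace = TRUE),
    is_polar = el %in% c("N", "O", "S"),
    is_hydrophobic = el %in% c("C", "S") & runif(n_atoms) < 0.5,
    is_donor = el %in% c("N", "O", "S") & runif(n_atoms) < 0.4,
    is_acceptor = el %in% c("N", "O", "S") & runif(n_atoms) < 0.4,
    is_aromatic = FALSE,
    formal_charge = sample(c(-1L, 0L, 0L, 0L, 1L), n_atoms, replace = TRUE),
    stringsAsFactors = FALSE)
  rings <- list()
  if (n_atoms >= 5 && runif(1) < 0.5) {
    ix <- sample(n_atoms, 3)
    atoms$is_aromatic[ix] <- TRUE
    rings <- list(ix)
  }
  list(chain = "A", resnum = resnum, resname = "UNK", atoms = atoms,
       rings = rings)
}

random_complex <- function(n_res = NULL, n_lig = NULL) {
  if (is.null(n_res)) n_res <- sample(2:6, 1)
  if (is.null(n_lig)) n_lig <- sample(4:14, 1)
  residues <- lapply(seq_len(n_res), function(i) {
    random_residue(i, c(runif(1, 0, 10), runif(1, 0, 10), runif(1, 0, 10)),
                   sample(3:7, 1))
  })
  receptor <- receptor_conformation("rc", residues)
  el <- sample(c("C", "N", "O", "H"), n_lig, replace = TRUE,
               prob = c(0.5, 0.2, 0.2, 0.1))
  if (all(el == "H")) el[1] <- "C"
  atoms <- data.frame(
    name = paste0(el, seq_len(n_lig)), element = el,
    x = runif(n_lig, 0, 10), y = runif(n_lig, 0, 10), z = runif(n_lig, 0, 10),
    is_main_chain = FALSE,
    is_polar = el %in% c("N", "O", "S"),
    is_hydrophobic = el == "C" & runif(n_lig) < 0.5,
    is_donor = el %in% c("N", "O") & runif(n_lig) < 0.4,
    is_acceptor = el %in% c("N", "O") & runif(n_lig) < 0.4,
    is_aromatic = FALSE,
    formal_charge = sample(c(-1L, 0L, 0L, 1L), n_lig, replace = TRUE),
    stringsAsFactors = FALSE)
  heavy <- which(el != "H")
  rings <- list()
  if (length(heavy) >= 4 && runif(1) < 0.5) {
    ix <- sample(heavy, 3)
    atoms$is_aromatic[ix] <- TRUE
    rings <- list(ix)
  }
  ligand <- ligand_pose("lig", "rc", atoms, rings)
  list(receptor = receptor, ligand = ligand)
}

# Independent exhaustive pairwise fingerprint oracle: explicit loops over
# residue-atom / ligand-atom pairs, structured differently from the
# package implementation.
oracle_sift <- function(receptor, ligand, cfg = geometry_config()) {
  la <- ligand$atoms
  lh <- which(la$element != "H")
  ligH <- which(la$element == "H")
  out <- integer(0)
  for (res in receptor$residues) {
    ra <- res$atoms
    rh <- which(ra$element != "H")
    resH <- which(ra$element == "H")
    bits <- stats::setNames(integer(9), ensift:::BIT_NAMES)
    nearest <- c(Inf, NA)
    for (i in rh) {
      for (j in lh) {
        d <- sqrt(sum((c(ra$x[i], ra$y[i], ra$z[i]) -
                         c(la$x[j], la$y[j], la$z[j]))^2))
        if (d < nearest[1]) nearest <- c(d, i)
        if (d <= cfg$contact_cutoff) {
          bits["any"] <- 1L
          if (ra$is_main_chain[i]) bits["main_chain"] <- 1L
          else bits["side_chain"] <- 1L
        }
        if (d <= cfg$polar_cutoff && ra$is_polar[i] && la$is_polar[j])
          bits["polar"] <- 1L
        if (d <= cfg$hydrophobic_cutoff && ra$is_hydrophobic[i] &&
            la$is_hydrophobic[j])
          bits["hydrophobic"] <- 1L
        if (d <= cfg$hbond_dist && ra$is_donor[i] && la$is_acceptor[j] &&
            oracle_angle_ok(ra, i, la, j, resH, cfg))
          bits["hb_donor"] <- 1L
        if (d <= cfg$hbond_dist && la$is_donor[j] && ra$is_acceptor[i] &&
            oracle_angle_ok(la, j, ra, i, ligH, cfg))
          bits["hb_acceptor"] <- 1L
        if (d <= cfg$charged_cutoff &&
            ra$formal_charge[i] * la$formal_charge[j] < 0)
          bits["charged"] <- 1L
      }
    }
    for (rr in res$rings) {
      for (ls in ligand$ring_systems) {
        rc <- c(mean(ra$x[rr]), mean(ra$y[rr]), mean(ra$z[rr]))
        lc <- c(mean(la$x[ls]), mean(la$y[ls]), mean(la$z[ls]))
        if (sqrt(sum((rc - lc)^2)) <= cfg$aromatic_centroid_cutoff)
          bits["aromatic"] <- 1L
      }
    }
    if (any(bits[4:9] == 1L) && bits["any"] == 0L) {
      bits["any"] <- 1L
      if (ra$is_main_chain[nearest[2]]) bits["main_chain"] <- 1L
      else bits["side_chain"] <- 1L
    }
    out <- c(out, bits)
  }
  unname(out)
}

# donor-side angle test for the oracle: any hydrogen within 1.3 A of the
# donor must give D-H...A >= the minimum angle; no riding H = distance-only
oracle_angle_ok <- function(da, i, aa, j, h_ix, cfg) {
  if (length(h_ix) == 0) return(TRUE)
  d <- c(da$x[i], da$y[i], da$z[i])
  a <- c(aa$x[j], aa$y[j], aa$z[j])
  riding <- h_ix[vapply(h_ix, function(h) {
    sqrt(sum((c(da$x[h], da$y[h], da$z[h]) - d)^2)) < 1.3
  }, logical(1))]
  if (length(riding) == 0) return(TRUE)
  for (h in riding) {
    hx <- c(da$x[h], da$y[h], da$z[h])
    v1 <- d - hx; v2 <- a - hx
    ang <- acos(max(-1, min(1, sum(v1 * v2) /
                              sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    if (ang >= cfg$hbond_angle_min) return(TRUE)
  }
  FALSE
}

# --- brute-force dual QP oracle for the linear SVM ------------------------
# Enumerates every {lower, upper, free} active-set assignment of the box
# constraints and solves the equality-constrained KKT system on the free
# set; returns the optimal dual objective.
oracle_svm_dual <- function(x, y, C) {
  n <- nrow(x)
  Q <- (y %*% t(y)) * (x %*% t(x))
  best <- -Inf
  objective <- function(a) sum(a) - 0.5 * drop(t(a) %*% Q %*% a)
  assign <- rep(0L, n)
  states <- expand.grid(rep(list(0:2), n))  # 0 = at 0, 1 = at C, 2 = free
  for (r in seq_len(nrow(states))) {
    st <- as.integer(states[r, ])
    a <- ifelse(st == 1L, C, 0)
    free <- which(st == 2L)
    if (length(free) > 0) {
      rhs1 <- 1 - Q[free, st == 1L, drop = FALSE] %*%
        rep(C, sum(st == 1L))
      A <- rbind(cbind(Q[free, free, drop = FALSE], y[free]),
                 c(y[free], 0))
      b <- c(rhs1, -C * sum(y[st == 1L]))
      sol <- tryCatch(solve(A, b), error = function(e) NULL)
      if (is.null(sol)) next
      af <- sol[seq_along(free)]
      if (any(af < -1e-9) || any(af > C + 1e-9)) next
      a[free] <- pmin(pmax(af, 0), C)
    }
    if (abs(sum(a * y)) > 1e-8 * max(1, C)) next
    best <- max(best, objective(a))
  }
  best
}

# quick labelled dataset helpers
small_sim <- function(seed = 1L, ...) {
  simulate_fingerprints(fingerprint_sim_config(
    n_active = 20, n_inactive = 20, n_decoy = 0, n_conformations = 5,
    n_residues = 8, n_signal_bits = 3, pose_fail_prob = 0, seed = seed, ...))
}
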