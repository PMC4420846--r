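# Synthetic inputs: toy 3D complexes with planted interactions, and
# fingerprint-level multi-conformation datasets with a controlled
# signal/noise model.

#' Configuration for the fingerprint-dataset simulator
#'
#' The simulator emulates the statistical structure of ensemble-docking
#' fingerprints: actives share a conserved interaction pattern
#' (`n_signal_bits` positions always set before noise), which each
#' receptor conformation reports imperfectly (`flip_prob` per-conformation
#' Bernoulli dropout of signal bits, standing in for pose fluctuation);
#' all remaining typed positions carry sparse background contacts at rate
#' `background_rate`; and each (compound, conformation) pair fails to
#' produce a pose with probability `pose_fail_prob`. Averaging over
#' conformations therefore denoises the signal - the mechanism ensemble
#' screening relies on. `noise_correlation` (rho in [0, 1)) makes the
#' per-conformation noise draws correlated across conformations via a
#' Gaussian copula while keeping the marginal rates fixed: rho = 0 models
#' independently generated receptor conformations, large rho a
#' "crystal-like" ensemble whose conformations make the same mistakes.
#'
#' The default compound counts mirror a retrospective screening campaign
#' of realistic size (550 active and 601 inactive instances, a 2526-strong
#' decoy set, 20 receptor conformations); tests and examples use reduced
#' counts.
#'
#' @param n_active,n_inactive,n_decoy Compound counts per class.
#' @param n_conformations Ensemble size.
#' @param n_residues Binding-site residues (9 bits each).
#' @param n_signal_bits Conserved interaction positions for actives.
#' @param flip_prob Per-conformation signal dropout probability in `[0, 1)`.
#' @param background_rate Background bit density in `[0, 1)`.
#' @param pose_fail_prob Probability a compound gets no pose in a
#'   conformation.
#' @param noise_correlation Inter-conformation noise correlation in
#'   `[0, 1)`.
#' @param seed Integer seed; identical configurations generate bit-identical
#'   datasets.
#' @return A list of class `fingerprint_sim_config`.
#' @export
fingerprint_sim_config <- function(n_active = 550, n_inactive = 601,
                                   n_decoy = 2526, n_conformations = 20,
                                   n_residues = 30, n_signal_bits = 3,
                                   flip_prob = 0.3, background_rate = 0.05,
                                   pose_fail_prob = 0.05,
                                   noise_correlation = 0, seed = 1L) {
  cfg <- list(n_active = n_active, n_inactive = n_inactive,
              n_decoy = n_decoy, n_conformations = n_conformations,
              n_residues = n_residues, n_signal_bits = n_signal_bits,
              flip_prob = flip_prob, background_rate = background_rate,
              pose_fail_prob = pose_fail_prob,
              noise_correlation = noise_correlation, seed = as.integer(seed))
  if (n_signal_bits > 6 * n_residues)
    stop("n_signal_bits exceeds the number of typed interaction positions")
  probs <- c(flip_prob, background_rate, pose_fail_prob, noise_correlation)
  if (any(probs < 0) || any(probs >= 1))
    stop("probabilities must lie in [0, 1)")
  structure(cfg, class = "fingerprint_sim_config")
}

# 1-based offsets of the six typed interaction bits inside a chunk
# (polar, hydrophobic, hb_acceptor, hb_donor, aromatic, charged).
#' @noRd
typed_offsets <- function() 4:9

#' @noRd
typed_positions <- function(n_residues) {
  as.vector(outer(typed_offsets(), 9 * (seq_len(n_residues) - 1), "+"))
}

# Correlated Bernoulli(p) events, one row per compound-free draw unit,
# columns = conformations; a Gaussian copula shares sqrt(rho) of each
# latent normal across conformations.
#' @noRd
correlated_events <- function(n, n_conf, p, rho) {
  if (p == 0) return(matrix(FALSE, n, n_conf))
  z_common <- stats::rnorm(n)
  z <- sqrt(rho) * matrix(z_common, n, n_conf) +
    sqrt(1 - rho) * matrix(stats::rnorm(n * n_conf), n, n_conf)
  z < stats::qnorm(p)
}

#' Simulate a multi-conformation fingerprint dataset
#'
#' Generates per-conformation binary SIFts for actives, inactives and
#' decoys under the signal/noise model of [fingerprint_sim_config()].
#' After the noisy typed bits are drawn, the derived positions of each
#' chunk are repaired: `any` is recomputed as the OR of the six typed
#' bits and attributed to the main chain or the side chain by a fixed
#' per-residue assignment, so every chunk satisfies the fingerprint
#' implication invariants. Compounds whose poses all fail are omitted.
#'
#' @param cfg A [fingerprint_sim_config()].
#' @return Object of class `sift_collection`: list with `bits` (3D 0/1
#'   array: compound x conformation x position), `pose` (logical compound
#'   x conformation matrix), `labels` (named vector:
#'   active/inactive/decoy), `conformation_ids`, `residue_labels`,
#'   `signal_positions`.
#' @export
simulate_fingerprints <- function(cfg) {
  stopifnot(inherits(cfg, "fingerprint_sim_config"))
  set.seed(cfg$seed)
  nres <- cfg$n_residues
  npos <- 9 * nres
  typed <- typed_positions(nres)
  signal <- sort(sample(typed, cfg$n_signal_bits))
  n_cmpd <- cfg$n_active + cfg$n_inactive + cfg$n_decoy
  nconf <- cfg$n_conformations
  ids <- c(sprintf("ACT%04d", seq_len(cfg$n_active)),
           sprintf("INA%04d", seq_len(cfg$n_inactive)),
           sprintf("DEC%04d", seq_len(cfg$n_decoy)))
  labels <- stats::setNames(rep(c("active", "inactive", "decoy"),
                                c(cfg$n_active, cfg$n_inactive, cfg$n_decoy)),
                            ids)
  is_active <- labels == "active"
  # per-residue main/side attribution of repaired contacts
  main_attr <- sample(c(TRUE, FALSE), nres, replace = TRUE)
  bits <- array(0L, dim = c(n_cmpd, nconf, npos),
                dimnames = list(ids, NULL, NULL))
  rho <- cfg$noise_correlation
  for (pos in typed) {
    sig_here <- pos %in% signal
    base <- ifelse(is_active & sig_here, 1L, 0L)
    # background draws for positions/compounds without planted signal
    bg <- correlated_events(n_cmpd, nconf, cfg$background_rate, rho)
    flip <- correlated_events(n_cmpd, nconf, cfg$flip_prob, rho)
    on_bit <- matrix(base, n_cmpd, nconf)
    on_bit <- ifelse(on_bit == 1L, ifelse(flip, 0L, 1L),
                     ifelse(bg, 1L, 0L))
    bits[, , pos] <- on_bit
  }
  pose <- !correlated_events(n_cmpd, nconf, cfg$pose_fail_prob, 0)
  dimnames(pose) <- list(ids, NULL)
  keep <- rowSums(pose) >= 1
  bits <- bits[keep, , , drop = FALSE]
  pose <- pose[keep, , drop = FALSE]
  labels <- labels[keep]
  bits <- repair_chunks(bits, main_attr)
  structure(list(bits = bits, pose = pose, labels = labels,
                 conformation_ids = sprintf("conf%02d", seq_len(nconf)),
                 residue_labels = sprintf("A%d", seq_len(nres)),
                 signal_positions = signal, main_attr = main_attr,
                 cfg = cfg),
            class = "sift_collection")
}

# Recompute any/main_chain/side_chain from the typed bits of every chunk.
#' @noRd
repair_chunks <- function(bits, main_attr) {
  nres <- dim(bits)[3] / 9
  for (r in seq_len(nres)) {
    off <- 9 * (r - 1)
    any_bit <- 0L
    for (k in typed_offsets()) any_bit <- any_bit | bits[, , off + k]
    bits[, , off + 1] <- any_bit
    bits[, , off + 2] <- if (main_attr[r]) any_bit else 0L
    bits[, , off + 3] <- if (main_attr[r]) 0L else any_bit
  }
  bits
}

#' @export
print.sift_collection <- function(x, ...) {
  cat(sprintf(
    "SIFt collection: %d compounds x %d conformations x %d positions (%d signal)\n",
    dim(x$bits)[1], dim(x$bits)[2], dim(x$bits)[3],
    length(x$signal_positions)))
  print(table(x$labels))
  invisible(x)
}

#' Extract one compound's SIFts from a collection
#'
#' @param collection A `sift_collection`.
#' @param compound_id Compound to extract.
#' @return List of `sift` objects, one per conformation with a pose.
#' @export
collection_sifts <- function(collection, compound_id) {
  i <- match(compound_id, rownames(collection$bits))
  if (is.na(i)) stop("unknown compound: ", compound_id)
  confs <- which(collection$pose[i, ])
  lapply(confs, function(j) {
    new_sift(collection$bits[i, j, ], compound_id,
             collection$conformation_ids[j], collection$residue_labels)
  })
}

#' Build the labelled profile feature matrix of a collection
#'
#' Vectorised equivalent of calling [build_profile()] per compound and
#' [profile_matrix()] on the results, restricted to the ensemble prefix
#' `ensemble_ids`; compounds without any pose in that prefix are dropped.
#'
#' @param collection A `sift_collection`.
#' @param ensemble_ids Conformation ids to average over (default: all).
#' @param denominator `"ensemble"` or `"poses"` (see [build_profile()]).
#' @return A [feature_matrix()] with labels active = +1, others = -1.
#' @export
collection_profiles <- function(collection,
                                ensemble_ids = collection$conformation_ids,
                                denominator = c("ensemble", "poses")) {
  denominator <- match.arg(denominator)
  sel <- match(ensemble_ids, collection$conformation_ids)
  if (anyNA(sel)) stop("unknown conformation id in ensemble_ids")
  n <- dim(collection$bits)[1]
  npos <- dim(collection$bits)[3]
  acc <- matrix(0, n, npos)
  for (j in sel) acc <- acc + collection$bits[, j, ] * collection$pose[, j]
  nposes <- rowSums(collection$pose[, sel, drop = FALSE])
  keep <- nposes >= 1
  denom <- if (denominator == "ensemble") length(sel) else nposes[keep]
  x <- acc[keep, , drop = FALSE] / denom
  rownames(x) <- rownames(collection$bits)[keep]
  y <- ifelse(collection$labels[keep] == "active", 1L, -1L)
  feature_matrix(x, y, rownames(x))
}

#' Simulate per-conformation centroid docking scores
#'
#' Emulates the pre-evaluation stage in which each receptor conformation
#' is scored by how well it separates active from inactive cluster
#' centroids: scores are unit-variance Gaussians whose class means differ
#' by `3 * informativeness` standard deviations.
#'
#' @param informativeness Numeric vector in `[0, 1]`, one entry per
#'   conformation (names become conformation ids).
#' @param n_per_class Centroids per class.
#' @param seed Integer seed.
#' @return Named list per conformation with elements `pos` and `neg`.
#' @export
simulate_centroid_scores <- function(informativeness, n_per_class = 100,
                                     seed = 1L) {
  if (any(informativeness < 0 | informativeness > 1))
    stop("informativeness values must lie in [0, 1]")
  set.seed(seed)
  ids <- names(informativeness)
  if (is.null(ids)) ids <- sprintf("conf%02d", seq_along(informativeness))
  out <- lapply(seq_along(informativeness), function(j) {
    list(pos = stats::rnorm(n_per_class, mean = 3 * informativeness[j]),
         neg = stats::rnorm(n_per_class))
  })
  stats::setNames(out, ids)
}

#' Generate a toy receptor-ligand complex with planted interactions
#'
#' Builds a synthetic receptor and a ligand pose whose atoms are placed so
#' that exactly the requested interaction classes hold per residue under
#' the default [geometry_config()]: hydrogen-bond pairs at 2.9 A, polar
#' pairs at 3.3 A, hydrophobic and plain contacts at 4.0 A, stacked
#' aromatic rings at 4.0 A, charged pairs at 3.5 A, and all unrelated
#' atom pairs kept farther than 6 A (residue anchors are spread on a
#' deliberately exaggerated toy geometry to rule out cross-talk). Each
#' residue carries a full complement of anchor atoms (backbone N/CA/C/O,
#' hydrophobic CB, plain side-chain carbon, side-chain hydroxyl, charged
#' amine, six-membered aromatic ring), so any combination of the nine
#' classes is realisable on any residue.
#'
#' @param plan List, one element per residue (in order); each element is a
#'   character vector of requested classes among `main_chain`,
#'   `side_chain`, `polar`, `hydrophobic`, `hb_acceptor`, `hb_donor`,
#'   `aromatic`, `charged`, `any` (empty vector: no interaction). For
#'   `polar`, `hb_donor` and `hb_acceptor` the main-chain anchor is used
#'   unless `side_chain` is also requested.
#' @param compound_id,conformation_id Identifiers for the generated pose.
#' @param seed Integer seed (the construction is deterministic; the seed
#'   is fixed for interface uniformity with the other generators).
#' @return List with elements `receptor` ([receptor_conformation()]) and
#'   `ligand` ([ligand_pose()]).
#' @export
make_toy_complex <- function(plan, compound_id = "toy",
                             conformation_id = "conf01", seed = 1L) {
  known <- c("any", "main_chain", "side_chain", "polar", "hydrophobic",
             "hb_acceptor", "hb_donor", "aromatic", "charged")
  for (req in plan) {
    bad <- setdiff(req, known)
    if (length(bad) > 0)
      stop("unsatisfiable interaction plan: unknown class ",
           paste(bad, collapse = ", "))
  }
  residues <- vector("list", length(plan))
  lig_rows <- list()
  for (i in seq_along(plan)) {
    o <- c(60 * (i - 1), 0, 0)
    residues[[i]] <- toy_residue(i, o)
    placed <- place_toy_ligand_atoms(plan[[i]], o)
    lig_rows <- c(lig_rows, placed$atoms)
  }
  if (length(lig_rows) == 0) {
    lig_rows <- list(toy_atom("C1", "C", c(-500, -500, -500)))
  }
  atoms <- do.call(rbind, lig_rows)
  atoms$name <- paste0(atoms$element, seq_len(nrow(atoms)))
  # re-derive ring index sets from the aromatic flag (rings are the only
  # aromatic ligand atoms, placed in consecutive blocks of six)
  rings <- split(which(atoms$is_aromatic),
                 (seq_len(sum(atoms$is_aromatic)) - 1) %/% 6)
  rings <- unname(rings[vapply(rings, length, integer(1)) == 6])
  receptor <- receptor_conformation(conformation_id, residues)
  ligand <- ligand_pose(compound_id, conformation_id, atoms, rings)
  list(receptor = receptor, ligand = ligand)
}

#' @noRd
toy_atom <- function(name, element, xyz, main = FALSE, polar = FALSE,
                     hyd = FALSE, don = FALSE, acc = FALSE, arom = FALSE,
                     charge = 0L) {
  data.frame(name = name, element = element,
             x = xyz[1], y = xyz[2], z = xyz[3],
             is_main_chain = main, is_polar = polar, is_hydrophobic = hyd,
             is_donor = don, is_acceptor = acc, is_aromatic = arom,
             formal_charge = as.integer(charge), stringsAsFactors = FALSE)
}

# Synthetic residue with every anchor type; flags assigned directly (the
# residue is written as UNK when exported to PDB).
#' @noRd
toy_residue <- function(resnum, o) {
  ring_center <- o + c(0, 20, 0)
  ring <- lapply(1:6, function(k) {
    ang <- 2 * pi * (k - 1) / 6
    toy_atom(paste0("CD", k), "C",
             ring_center + 1.4 * c(cos(ang), 0, sin(ang)),
             arom = TRUE)
  })
  atoms <- rbind(
    toy_atom("N", "N", o + c(0, 0, 0), main = TRUE, polar = TRUE,
             don = TRUE),
    toy_atom("CA", "C", o + c(5, 0, 0), main = TRUE),
    toy_atom("C", "C", o + c(10, 0, 0), main = TRUE),
    toy_atom("O", "O", o + c(15, 0, 0), main = TRUE, polar = TRUE,
             acc = TRUE),
    toy_atom("CB", "C", o + c(0, 10, 0), hyd = TRUE),
    toy_atom("CG", "C", o + c(5, 10, 0)),
    toy_atom("OG", "O", o + c(10, 10, 0), polar = TRUE, don = TRUE,
             acc = TRUE),
    toy_atom("NZ", "N", o + c(15, 10, 0), polar = TRUE, charge = 1L),
    do.call(rbind, ring))
  list(chain = "A", resnum = resnum, resname = "UNK", atoms = atoms,
       rings = list(9:14))
}

# Ligand atoms fulfilling the requested classes of one residue; returns a
# list of single-row atom data.frames plus local ring index layouts.
#' @noRd
place_toy_ligand_atoms <- function(req, o) {
  if (length(req) == 0) return(list(atoms = list(), rings = list()))
  side <- "side_chain" %in% req
  atoms <- list()
  rings <- list()
  k <- 0
  shoot <- function(anchor, dist, down) {
    # successive requests at one anchor fan out in z to stay separated
    phi <- c(0, 25, -25, 50, -50)[k %% 5 + 1] * pi / 180
    k <<- k + 1
    anchor + dist * c(0, ifelse(down, -1, 1) * cos(phi), sin(phi))
  }
  add <- function(a) atoms[[length(atoms) + 1]] <<- a
  if ("hb_donor" %in% req) {           # residue donates
    anchor <- if (side) o + c(10, 10, 0) else o
    add(toy_atom("O", "O", shoot(anchor, 2.9, !side), polar = TRUE,
                 acc = TRUE))
  }
  if ("hb_acceptor" %in% req) {        # residue accepts
    anchor <- if (side) o + c(10, 10, 0) else o + c(15, 0, 0)
    add(toy_atom("N", "N", shoot(anchor, 2.9, !side), polar = TRUE,
                 don = TRUE))
  }
  if ("polar" %in% req && !any(c("hb_donor", "hb_acceptor") %in% req)) {
    anchor <- if (side) o + c(10, 10, 0) else o + c(15, 0, 0)
    add(toy_atom("N", "N", shoot(anchor, 3.3, !side), polar = TRUE))
  }
  if ("hydrophobic" %in% req) {
    add(toy_atom("C", "C", o + c(0, 10, 0) + c(-4, 0, 0), hyd = TRUE))
  }
  if ("charged" %in% req) {
    add(toy_atom("C", "C", o + c(15, 10, 0) + c(3.5, 0, 0), charge = -1L))
  }
  if ("aromatic" %in% req) {
    center <- o + c(0, 20, 0) + c(0, 0, 4.0)
    ring <- lapply(1:6, function(j) {
      ang <- 2 * pi * (j - 1) / 6
      toy_atom("C", "C", center + 1.4 * c(cos(ang), sin(ang), 0),
               arom = TRUE)
    })
    for (a in ring) add(a)
    rings <- c(rings, list(seq_len(6)))
  }
  if ("main_chain" %in% req || ("any" %in% req && length(atoms) == 0)) {
    add(toy_atom("C", "C", shoot(o + c(5, 0, 0), 4.0, TRUE)))
  }
  if ("side_chain" %in% req &&
      !any(c("hb_donor", "hb_acceptor", "polar", "hydrophobic", "aromatic",
             "charged") %in% req)) {
    add(toy_atom("C", "C", shoot(o + c(5, 10, 0), 4.0, FALSE)))
  }
  list(atoms = atoms, rings = rings)
}

#' Jitter the coordinates of a receptor conformation
#'
#' Produces additional ensemble members for toy receptors: every atom is
#' displaced by isotropic Gaussian noise while the residue sequence (and
#' hence fingerprint position layout) is preserved.
#'
#' @param conf A [receptor_conformation()].
#' @param conformation_id Identifier of the new conformation.
#' @param sd Displacement standard deviation per coordinate, in angstroms.
#' @param seed Integer seed.
#' @return A new `receptor_conformation`.
#' @export
perturb_conformation <- function(conf, conformation_id, sd = 0.2,
                                 seed = 1L) {
  set.seed(seed)
  residues <- lapply(conf$residues, function(r) {
    n <- nrow(r$atoms)
    r$atoms$x <- r$atoms$x + stats::rnorm(n, sd = sd)
    r$atoms$y <- r$atoms$y + stats::rnorm(n, sd = sd)
    r$atoms$z <- r$atoms$z + stats::rnorm(n, sd = sd)
    r
  })
  receptor_conformation(conformation_id, residues,
                        source_path = conf$source_path)
}
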