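# Nine-bit-per-residue structural interaction fingerprints.

BIT_NAMES <- c("any", "main_chain", "side_chain", "polar", "hydrophobic",
               "hb_acceptor", "hb_donor", "aromatic", "charged")

#' Geometric cutoffs for interaction detection
#'
#' All cutoffs are heavy-atom distances in angstroms. The defaults follow
#' common interaction-fingerprint practice; every value is a tunable choice
#' of this implementation, not a literature constant:
#' \describe{
#'   \item{contact_cutoff (4.5)}{any residue/ligand heavy-atom pair closer
#'     than this sets the "any" bit, partitioned into main-chain and
#'     side-chain contact by the residue atom.}
#'   \item{polar_cutoff (3.5)}{N/O/S to N/O/S pair distance for a polar
#'     interaction.}
#'   \item{hydrophobic_cutoff (4.5)}{apolar carbon/sulfur pair distance.}
#'   \item{hbond_dist (3.5), hbond_angle_min (120)}{donor-acceptor
#'     heavy-atom distance; when explicit hydrogens ride the donor the
#'     D-H...A angle must also exceed the minimum, otherwise the test is
#'     distance-only.}
#'   \item{aromatic_centroid_cutoff (5.0)}{ring-centroid separation between
#'     an aromatic residue ring (PHE/TYR/TRP/HIS) and a ligand ring system.}
#'   \item{charged_cutoff (4.0)}{distance between residue and ligand atoms
#'     of opposite formal charge.}
#' }
#'
#' @param contact_cutoff,polar_cutoff,hydrophobic_cutoff,hbond_dist,hbond_angle_min,aromatic_centroid_cutoff,charged_cutoff
#'   Numeric cutoffs, see Details.
#' @return A list of class `geometry_config`.
#' @export
geometry_config <- function(contact_cutoff = 4.5, polar_cutoff = 3.5,
                            hydrophobic_cutoff = 4.5, hbond_dist = 3.5,
                            hbond_angle_min = 120,
                            aromatic_centroid_cutoff = 5.0,
                            charged_cutoff = 4.0) {
  cfg <- list(contact_cutoff = contact_cutoff, polar_cutoff = polar_cutoff,
              hydrophobic_cutoff = hydrophobic_cutoff,
              hbond_dist = hbond_dist, hbond_angle_min = hbond_angle_min,
              aromatic_centroid_cutoff = aromatic_centroid_cutoff,
              charged_cutoff = charged_cutoff)
  num <- vapply(cfg, is.numeric, logical(1))
  if (!all(num)) stop("all geometry cutoffs must be numeric")
  if (any(unlist(cfg) <= 0)) stop("all geometry cutoffs must be positive")
  if (hbond_dist > contact_cutoff)
    stop("hbond_dist must not exceed contact_cutoff")
  structure(cfg, class = "geometry_config")
}

#' Read a flat key=value geometry configuration file
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path Text file with one `key = value` pair per line; `#` starts a
#'   comment.
#' @return A [geometry_config()].
#' @export
read_geometry_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- lines[grepl("=", lines)]
  kv <- strsplit(lines, "=")
  keys <- trimws(vapply(kv, `[[`, character(1), 1))
  vals <- as.numeric(trimws(vapply(kv, `[[`, character(1), 2)))
  args <- as.list(vals)
  names(args) <- keys
  do.call(geometry_config, args)
}

#' @noRd
pair_dist <- function(a, b) {
  # a: n x 3, b: m x 3 -> n x m Euclidean distances
  sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b))
}

#' @noRd
coords_of <- function(atoms, ix = seq_len(nrow(atoms))) {
  as.matrix(atoms[ix, c("x", "y", "z"), drop = FALSE])
}

# Angle at h between d and a, degrees.
#' @noRd
dha_angle <- function(d, h, a) {
  v1 <- d - h; v2 <- a - h
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# Directed hydrogen-bond test: any donor atom (rows of don_xyz) within
# hbond_dist of any acceptor atom, with the D-H...A angle check applied
# only when the donor carries explicit hydrogens (within 1.3 A).
#' @noRd
hbond_present <- function(don_xyz, acc_xyz, h_xyz, cfg) {
  if (nrow(don_xyz) == 0 || nrow(acc_xyz) == 0) return(FALSE)
  dd <- pair_dist(don_xyz, acc_xyz)
  hits <- which(dd <= cfg$hbond_dist, arr.ind = TRUE)
  if (nrow(hits) == 0) return(FALSE)
  if (is.null(h_xyz) || nrow(h_xyz) == 0) return(TRUE)
  for (k in seq_len(nrow(hits))) {
    d <- don_xyz[hits[k, 1], ]
    a <- acc_xyz[hits[k, 2], ]
    dh <- pair_dist(matrix(d, 1), h_xyz)
    riding <- which(dh < 1.3)
    if (length(riding) == 0) return(TRUE)  # no H on this donor: distance-only
    for (j in riding) {
      if (dha_angle(d, h_xyz[j, ], a) >= cfg$hbond_angle_min) return(TRUE)
    }
  }
  FALSE
}

#' Interaction bits of one residue against one ligand pose
#'
#' Evaluates the nine geometric interaction classes for a single residue:
#' any contact, main-chain contact, side-chain contact, polar, hydrophobic,
#' hydrogen-bond acceptor, hydrogen-bond donor, aromatic and charged. The
#' donor/acceptor bits use the residue-centric convention of the original
#' SIFt literature: `hb_donor` means the residue donates the hydrogen bond
#' to the ligand, `hb_acceptor` means the residue accepts one from it.
#'
#' @param residue One residue record (element of
#'   `receptor_conformation$residues`).
#' @param ligand A [ligand_pose()].
#' @param cfg A [geometry_config()].
#' @return Named integer vector of length 9 in the fixed bit order
#'   `any, main_chain, side_chain, polar, hydrophobic, hb_acceptor,
#'   hb_donor, aromatic, charged`.
#' @export
residue_bits <- function(residue, ligand, cfg = geometry_config()) {
  ra <- residue$atoms
  la <- ligand$atoms
  rheavy <- ra$element != "H"
  lheavy <- la$element != "H"
  rxyz <- coords_of(ra, which(rheavy))
  lxyz <- coords_of(la, which(lheavy))
  bits <- integer(9)
  names(bits) <- BIT_NAMES
  d <- pair_dist(rxyz, lxyz)
  contact <- d <= cfg$contact_cutoff
  if (any(contact)) {
    bits["any"] <- 1L
    rmain <- ra$is_main_chain[rheavy]
    if (any(contact[rmain, , drop = FALSE])) bits["main_chain"] <- 1L
    if (any(contact[!rmain, , drop = FALSE])) bits["side_chain"] <- 1L
  }
  rpol <- ra$is_polar[rheavy]
  lpol <- la$is_polar[lheavy]
  if (any(rpol) && any(lpol) &&
      any(d[rpol, lpol, drop = FALSE] <= cfg$polar_cutoff))
    bits["polar"] <- 1L
  rhyd <- ra$is_hydrophobic[rheavy]
  lhyd <- la$is_hydrophobic[lheavy]
  if (any(rhyd) && any(lhyd) &&
      any(d[rhyd, lhyd, drop = FALSE] <= cfg$hydrophobic_cutoff))
    bits["hydrophobic"] <- 1L
  rh_xyz <- coords_of(ra, which(!rheavy))
  lh_xyz <- coords_of(la, which(!lheavy))
  # residue donates: residue donor -> ligand acceptor (residue hydrogens)
  if (hbond_present(coords_of(ra, which(rheavy & ra$is_donor)),
                    coords_of(la, which(lheavy & la$is_acceptor)),
                    rh_xyz, cfg))
    bits["hb_donor"] <- 1L
  # residue accepts: ligand donor -> residue acceptor (ligand hydrogens)
  if (hbond_present(coords_of(la, which(lheavy & la$is_donor)),
                    coords_of(ra, which(rheavy & ra$is_acceptor)),
                    lh_xyz, cfg))
    bits["hb_acceptor"] <- 1L
  if (length(residue$rings) > 0 && length(ligand$ring_systems) > 0) {
    rc <- t(vapply(residue$rings,
                   function(ix) colMeans(coords_of(ra, ix)), numeric(3)))
    lc <- t(vapply(ligand$ring_systems,
                   function(ix) colMeans(coords_of(la, ix)), numeric(3)))
    if (any(pair_dist(rc, lc) <= cfg$aromatic_centroid_cutoff))
      bits["aromatic"] <- 1L
  }
  rq <- ra$formal_charge[rheavy]
  lq <- la$formal_charge[lheavy]
  if (any(rq != 0) && any(lq != 0)) {
    opp <- outer(rq, lq) < 0
    if (any(opp & d <= cfg$charged_cutoff)) bits["charged"] <- 1L
  }
  # typed interactions imply a contact record even if slightly beyond the
  # generic contact cutoff (aromatic centroids, for instance)
  if (any(bits[4:9] == 1L) && bits["any"] == 0L) {
    bits["any"] <- 1L
    nearest <- which(d == min(d), arr.ind = TRUE)[1, 1]
    if (ra$is_main_chain[rheavy][nearest]) bits["main_chain"] <- 1L
    else bits["side_chain"] <- 1L
  }
  bits
}

#' Compute the SIFt of one ligand pose against one receptor conformation
#'
#' Concatenates the [residue_bits()] chunks of every residue, in the
#' receptor's residue order, into one binary string of length
#' `9 * n_residues`.
#'
#' @param receptor A [receptor_conformation()] in the ensemble reference
#'   residue order.
#' @param pose A [ligand_pose()] sharing the receptor's coordinate frame.
#' @param cfg A [geometry_config()].
#' @return An object of class `sift`: integer bit vector with attributes
#'   `compound_id`, `conformation_id` and `residue_labels`.
#' @export
compute_sift <- function(receptor, pose, cfg = geometry_config()) {
  chunks <- lapply(receptor$residues, residue_bits, ligand = pose, cfg = cfg)
  bits <- unlist(chunks, use.names = FALSE)
  labels <- vapply(receptor$residues,
                   function(r) paste0(r$chain, r$resnum), character(1))
  new_sift(bits, pose$compound_id,
           if (!is.null(pose$conformation_id)) pose$conformation_id
           else receptor$conformation_id,
           labels)
}

#' @noRd
new_sift <- function(bits, compound_id, conformation_id, residue_labels) {
  stopifnot(length(bits) %% 9 == 0)
  structure(as.integer(bits), class = "sift",
            compound_id = compound_id, conformation_id = conformation_id,
            residue_labels = residue_labels)
}

#' @export
print.sift <- function(x, ...) {
  cat(sprintf("SIFt %s @ %s: %d residues, %d bits set\n",
              attr(x, "compound_id"), attr(x, "conformation_id"),
              length(x) / 9, sum(x)))
  invisible(x)
}

#' @noRd
sift_colnames <- function(residue_labels) {
  as.vector(t(outer(residue_labels, BIT_NAMES, paste, sep = "_")))
}

#' Write SIFts to a delimited text file
#'
#' One row per (compound, conformation); bit columns are headed
#' `<chain><resnum>_<bitname>`.
#'
#' @param sifts List of `sift` objects of equal length.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_sifts <- function(sifts, path) {
  stopifnot(length(sifts) >= 1)
  lens <- vapply(sifts, length, integer(1))
  if (length(unique(lens)) != 1) stop("SIFts have differing lengths")
  mat <- do.call(rbind, lapply(sifts, as.integer))
  colnames(mat) <- sift_colnames(attr(sifts[[1]], "residue_labels"))
  out <- data.frame(
    compound_id = vapply(sifts, attr, character(1), "compound_id"),
    conformation_id = vapply(sifts, attr, character(1), "conformation_id"),
    mat, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read SIFts from a delimited text file written by [write_sifts()]
#'
#' @param path TSV file.
#' @return List of `sift` objects.
#' @export
read_sifts <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  bitcols <- setdiff(names(tab), c("compound_id", "conformation_id"))
  labels <- unique(sub("_[a-z_]+$", "", bitcols))
  lapply(seq_len(nrow(tab)), function(i) {
    new_sift(as.integer(tab[i, bitcols]), tab$compound_id[i],
             tab$conformation_id[i], labels)
  })
}
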