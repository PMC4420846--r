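# Readers for receptor conformations (PDB) and docked ligand poses
# (SDF V2000 / MOL2), plus ensemble assembly.

#' Construct a receptor conformation object
#'
#' Low-level constructor used by [read_receptor()] and the synthetic-complex
#' generator. `residues` is a list in binding-order; each element must carry
#' `chain`, `resnum`, `resname`, an `atoms` data.frame (columns `name`,
#' `element`, `x`, `y`, `z`, plus the role flags produced by
#' `annotate_residue_atoms()`) and a `rings` list of atom-index vectors.
#'
#' @param conformation_id Identifier of this conformation within an ensemble.
#' @param residues List of residue records.
#' @param source_path Optional file of origin.
#' @return An object of class `receptor_conformation`.
#' @export
receptor_conformation <- function(conformation_id, residues,
                                  source_path = NA_character_) {
  stopifnot(is.character(conformation_id), length(residues) >= 1)
  structure(list(conformation_id = conformation_id,
                 residues = residues,
                 source_path = source_path),
            class = "receptor_conformation")
}

#' @export
print.receptor_conformation <- function(x, ...) {
  natoms <- sum(vapply(x$residues, function(r) nrow(r$atoms), integer(1)))
  cat(sprintf("Receptor conformation '%s': %d residues, %d atoms\n",
              x$conformation_id, length(x$residues), natoms))
  invisible(x)
}

#' Construct a ligand pose object
#'
#' @param compound_id Compound identifier.
#' @param conformation_id Receptor conformation the pose was docked into.
#' @param atoms data.frame with columns `name`, `element`, `x`, `y`, `z`,
#'   `is_polar`, `is_hydrophobic`, `is_donor`, `is_acceptor`, `is_aromatic`,
#'   `formal_charge`.
#' @param ring_systems List of integer vectors indexing aromatic-ring atoms.
#' @return An object of class `ligand_pose`.
#' @export
ligand_pose <- function(compound_id, conformation_id, atoms,
                        ring_systems = list()) {
  heavy <- atoms$element != "H"
  if (!any(heavy)) stop("ligand pose has no heavy atoms")
  for (rs in ring_systems) {
    if (!all(atoms$is_aromatic[rs]))
      stop("ring_systems may contain only aromatic atoms")
  }
  structure(list(compound_id = compound_id,
                 conformation_id = conformation_id,
                 atoms = atoms, ring_systems = ring_systems),
            class = "ligand_pose")
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat(sprintf("Ligand pose '%s' (conformation '%s'): %d atoms, %d aromatic ring(s)\n",
              x$compound_id, x$conformation_id, nrow(x$atoms),
              length(x$ring_systems)))
  invisible(x)
}

#' Read one receptor conformation from a PDB file
#'
#' Parses ATOM records of a single-model PDB file, keeps protein residues
#' only (waters and other HETATM groups are dropped), resolves alternate
#' locations by highest occupancy (ties go to altloc 'A'), and annotates
#' every atom with main-chain/side-chain and interaction-role flags.
#' Residues are ordered by (chain, residue number).
#'
#' @param path PDB file.
#' @param conformation_id Identifier to assign; defaults to the file name
#'   without extension.
#' @return A [receptor_conformation()] object.
#' @export
read_receptor <- function(path, conformation_id = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  if (is.null(conformation_id))
    conformation_id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) stop("unreadable PDB file: ",
                                           conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid != "HOH", , drop = FALSE]
  if (nrow(at) == 0) stop("no protein ATOM records in ", path)
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes are not supported")
  # altloc resolution: keep the highest-occupancy location per atom
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    key <- paste(at$chain, at$resno, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(key, -occ, ifelse(alt == "", "0", alt))
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), , drop = FALSE]
    at <- at[order(at$chain, at$resno, at$eleno), , drop = FALSE]
  }
  rkey <- paste(at$chain, at$resno, sep = "_")
  split_ix <- split(seq_len(nrow(at)), factor(rkey, levels = unique(rkey)))
  residues <- lapply(split_ix, function(ix) {
    resname <- unique(at$resid[ix])
    if (length(resname) > 1)
      stop("duplicate (chain, resnum) with distinct residue names: ",
           rkey[ix[1]])
    el <- at$elesy[ix]
    if (is.null(el) || all(is.na(el)) || all(el == ""))
      el <- element_from_atom_name(at$elety[ix])
    ann <- annotate_residue_atoms(resname, at$elety[ix], toupper(el))
    ann$x <- at$x[ix]; ann$y <- at$y[ix]; ann$z <- at$z[ix]
    list(chain = at$chain[ix[1]], resnum = at$resno[ix[1]],
         resname = resname, atoms = ann,
         rings = residue_ring_sets(resname, at$elety[ix]))
  })
  ord <- order(vapply(residues, `[[`, character(1), "chain"),
               vapply(residues, `[[`, integer(1), "resnum"))
  receptor_conformation(conformation_id, residues[ord], source_path = path)
}

#' Write a receptor conformation to a PDB file
#'
#' Inverse of [read_receptor()] for synthetic receptors; coordinates are
#' written at the fixed-width PDB precision (1e-3 A).
#'
#' @param conf A `receptor_conformation`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_receptor_pdb <- function(conf, path) {
  rows <- do.call(rbind, lapply(conf$residues, function(r) {
    data.frame(chain = r$chain, resno = r$resnum, resid = r$resname,
               elety = r$atoms$name, elesy = r$atoms$element,
               x = r$atoms$x, y = r$atoms$y, z = r$atoms$z,
               stringsAsFactors = FALSE)
  }))
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(rows[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(rows)),
                   eleno = seq_len(nrow(rows)), elety = rows$elety,
                   resid = rows$resid, chain = rows$chain,
                   resno = rows$resno, elesy = rows$elesy)
  invisible(path)
}

#' Assemble an ordered ensemble of receptor conformations
#'
#' Reads (or accepts pre-read) conformations and verifies that they share
#' an identical residue sequence - the same (chain, resnum, resname) in the
#' same order - which is what makes their fingerprints position-compatible.
#' The input order is preserved: it defines the one-by-one addition order
#' used by [run_sweep()].
#'
#' @param paths Character vector of PDB files, or a list of
#'   `receptor_conformation` objects.
#' @return List of `receptor_conformation` objects, in input order.
#' @export
assemble_ensemble <- function(paths) {
  stopifnot(length(paths) >= 1)
  confs <- if (is.character(paths)) lapply(paths, read_receptor) else paths
  sig <- function(conf) paste(
    vapply(conf$residues, `[[`, character(1), "chain"),
    vapply(conf$residues, `[[`, integer(1), "resnum"),
    vapply(conf$residues, `[[`, character(1), "resname"),
    collapse = ";")
  ref <- sig(confs[[1]])
  for (i in seq_along(confs)) {
    if (!identical(sig(confs[[i]]), ref))
      stop("residue sequence of conformation ", confs[[i]]$conformation_id,
           " does not match the first conformation")
  }
  confs
}

#' Read a docked ligand pose
#'
#' Reads an SDF (V2000) or MOL2 file with explicit bonds and derives the
#' chemistry annotations needed for fingerprinting from connectivity:
#' aromaticity (aromatic bond order, or kekulized 5/6-rings with the
#' matching double-bond count), hydrogen-bond donors (N/O/S with at least
#' one explicit or valence-implied hydrogen), acceptors (N/O with a free
#' valence and non-positive charge, and neutral S), hydrophobic atoms
#' (C/S with no bonded N or O) and formal charges (`M  CHG`). Hydrogens are
#' accepted but optional: all annotations are computable from heavy atoms.
#'
#' @param path SDF or MOL2 file (format chosen by extension).
#' @param compound_id Compound identifier.
#' @param conformation_id Receptor conformation identifier for this pose.
#' @return A [ligand_pose()] object.
#' @export
read_pose <- function(path, compound_id, conformation_id) {
  if (!file.exists(path)) stop("cannot read pose file: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "mol2") {
    if (!requireNamespace("ChemmineOB", quietly = TRUE))
      stop("reading MOL2 requires the ChemmineOB package")
    tmp <- tempfile(fileext = ".sdf")
    on.exit(unlink(tmp), add = TRUE)
    ChemmineOB::convertFormatFile("MOL2", "SDF", path, tmp)
    path <- tmp
  }
  parsed <- parse_sdf_v2000(path)
  pose_from_connectivity(parsed$atoms, parsed$bonds, compound_id,
                         conformation_id)
}

# SDF V2000 structure parsing is delegated to ChemmineR; formal charges
# are supplemented from the raw `M  CHG` properties block, which
# ChemmineR's atom block does not carry.
#' @noRd
parse_sdf_v2000 <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("reading SDF requires the ChemmineR package")
  sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                     error = function(e) stop("unparsable SDF file: ", path,
                                              " (", conditionMessage(e), ")"))
  if (length(sdfset) == 0) stop("SDF file has no molecules: ", path)
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  if (is.null(ab) || nrow(ab) == 0) stop("SDF file has no atoms: ", path)
  bb <- ChemmineR::bondblock(sdf)
  atoms <- data.frame(
    x = ab[, 1], y = ab[, 2], z = ab[, 3],
    element = sub("_[0-9]+$", "", rownames(ab)),
    stringsAsFactors = FALSE)
  bonds <- if (!is.null(bb) && nrow(bb) > 0) {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  } else data.frame(a1 = integer(), a2 = integer(), order = integer())
  if (anyNA(bonds$a1) || anyNA(bonds$order))
    stop("unparsable SDF bond block: ", path)
  atoms$formal_charge <- 0L
  lines <- readLines(path, warn = FALSE)
  end1 <- grep("^\\$\\$\\$\\$", lines)[1]
  if (!is.na(end1)) lines <- lines[seq_len(end1)]
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)),
                                "[[:space:]]+")[[1]])
    n <- toks[1]
    for (k in seq_len(n)) {
      atoms$formal_charge[toks[2 * k]] <- toks[2 * k + 1]
    }
  }
  list(atoms = atoms, bonds = bonds)
}

#' @noRd
pose_from_connectivity <- function(atoms, bonds, compound_id,
                                   conformation_id) {
  n <- nrow(atoms)
  el <- toupper(atoms$element)
  chg <- atoms$formal_charge
  nbr <- vector("list", n)
  border <- vector("list", n)  # bond orders parallel to nbr
  for (i in seq_len(nrow(bonds))) {
    a <- bonds$a1[i]; b <- bonds$a2[i]; o <- bonds$order[i]
    nbr[[a]] <- c(nbr[[a]], b); border[[a]] <- c(border[[a]], o)
    nbr[[b]] <- c(nbr[[b]], a); border[[b]] <- c(border[[b]], o)
  }
  rings <- find_rings(nbr, max_size = 6)
  arom_atom <- rep(FALSE, n)
  bond_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  bkey <- bond_key(bonds$a1, bonds$a2)
  ring_systems <- list()
  for (r in rings) {
    edges <- cbind(r, c(r[-1], r[1]))
    ek <- bond_key(edges[, 1], edges[, 2])
    ords <- bonds$order[match(ek, bkey)]
    if (anyNA(ords)) next
    ndouble <- sum(ords == 2)
    aromatic <- all(ords == 4) ||
      (length(r) == 6 && ndouble == 3) ||
      (length(r) == 5 && ndouble >= 2)
    if (aromatic && all(el[r] %in% c("C", "N", "O", "S"))) {
      arom_atom[r] <- TRUE
      ring_systems <- c(ring_systems, list(sort(r)))
    }
  }
  # valence bookkeeping with aromatic bonds counted as 1.5
  ordsum <- vapply(seq_len(n), function(i) {
    o <- border[[i]]
    if (is.null(o)) 0 else sum(ifelse(o == 4, 1.5, o))
  }, numeric(1))
  n_exp_h <- vapply(seq_len(n), function(i) sum(el[nbr[[i]]] == "H"),
                    numeric(1))
  default_val <- c(N = 3, O = 2, S = 2, C = 4, F = 1)
  implied_h <- vapply(seq_len(n), function(i) {
    dv <- default_val[el[i]]
    if (is.na(dv)) return(0)
    dv <- dv + if (el[i] == "N") chg[i] else -abs(chg[i])
    max(0, round(dv - ordsum[i]))
  }, numeric(1))
  has_h <- n_exp_h > 0 | (n_exp_h == 0 & implied_h > 0)
  polar <- el %in% c("N", "O", "S")
  donor <- polar & has_h & chg >= 0
  acceptor <- (el == "O" & chg <= 0) |
    (el == "N" & chg <= 0 & (ordsum + n_exp_h + implied_h) < 3.5) |
    (el == "S" & chg <= 0)
  bonded_NO <- vapply(seq_len(n), function(i) any(el[nbr[[i]]] %in% c("N", "O")),
                      logical(1))
  hydrophobic <- el %in% c("C", "S") & !bonded_NO
  out <- data.frame(
    name = paste0(el, seq_len(n)), element = el,
    x = atoms$x, y = atoms$y, z = atoms$z,
    is_main_chain = FALSE, is_polar = polar, is_hydrophobic = hydrophobic,
    is_donor = donor, is_acceptor = acceptor, is_aromatic = arom_atom,
    formal_charge = as.integer(chg), stringsAsFactors = FALSE)
  ligand_pose(compound_id, conformation_id, out, ring_systems)
}

# Simple bounded-length cycle enumeration; adequate for drug-sized ligands.
#' @noRd
find_rings <- function(nbr, max_size = 6) {
  n <- length(nbr)
  found <- list()
  seen <- character(0)
  walk <- function(path) {
    last <- path[length(path)]
    for (nx in nbr[[last]]) {
      if (nx == path[1] && length(path) >= 3) {
        key <- paste(sort(path), collapse = "-")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          found[[length(found) + 1]] <<- path
        }
      } else if (!(nx %in% path) && length(path) < max_size && nx > path[1]) {
        walk(c(path, nx))
      }
    }
  }
  for (s in seq_len(n)) walk(s)
  found
}

#' Read a pose manifest
#'
#' A manifest is a TSV with columns `compound_id`, `conformation_id`,
#' `path`; alternatively pose files may follow the naming convention
#' `<compound_id>__<conformation_id>.sdf`.
#'
#' @param manifest Path to the TSV manifest.
#' @param base_dir Directory against which relative pose paths are resolved.
#' @return List of [ligand_pose()] objects.
#' @export
read_pose_manifest <- function(manifest, base_dir = dirname(manifest)) {
  tab <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  need <- c("compound_id", "conformation_id", "path")
  if (!all(need %in% names(tab)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    p <- tab$path[i]
    if (!file.exists(p)) p <- file.path(base_dir, tab$path[i])
    read_pose(p, tab$compound_id[i], tab$conformation_id[i])
  })
}
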