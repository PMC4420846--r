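# Heavy-atom chemistry annotation for the 20 standard amino acids.
#
# Interaction fingerprints are computed from heavy atoms only, so every
# donor/acceptor/charge/aromatic assignment here must be derivable without
# hydrogens.  Atom roles follow conventional protein-ligand interaction
# fingerprint practice:
#   * donors: N/O/S carrying at least one (possibly implicit) hydrogen;
#   * acceptors: N/O/S with an available lone pair (HIS ND1/NE2 are kept
#     as both donor and acceptor because the tautomer is unknown without
#     hydrogens);
#   * charged: carboxylate oxygens of ASP/GLU (-1), LYS NZ (+1) and the
#     ARG guanidinium nitrogens (+1) at physiological pH;
#   * hydrophobic: carbon or sulfur atoms with no bonded N or O.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' @noRd
.res_chem <- local({
  # per residue: donors, acceptors, pos/neg charged atoms, hydrophobic
  # side-chain atoms, aromatic ring atom sets
  tbl <- list(
    ALA = list(hyd = "CB"),
    ARG = list(hyd = c("CB", "CG"),
               don = c("NE", "NH1", "NH2"),
               pos = c("NE", "NH1", "NH2")),
    ASN = list(hyd = "CB", don = "ND2", acc = "OD1"),
    ASP = list(hyd = "CB", acc = c("OD1", "OD2"), neg = c("OD1", "OD2")),
    CYS = list(hyd = c("CB", "SG"), don = "SG", acc = "SG"),
    GLN = list(hyd = c("CB", "CG"), don = "NE2", acc = "OE1"),
    GLU = list(hyd = c("CB", "CG"), acc = c("OE1", "OE2"),
               neg = c("OE1", "OE2")),
    GLY = list(),
    HIS = list(hyd = "CB", don = c("ND1", "NE2"), acc = c("ND1", "NE2"),
               ring = list(c("CG", "ND1", "CD2", "CE1", "NE2"))),
    ILE = list(hyd = c("CB", "CG1", "CG2", "CD1")),
    LEU = list(hyd = c("CB", "CG", "CD1", "CD2")),
    LYS = list(hyd = c("CB", "CG", "CD"), don = "NZ", pos = "NZ"),
    MET = list(hyd = c("CB", "CG", "SD", "CE"), acc = "SD"),
    PHE = list(hyd = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
               ring = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))),
    PRO = list(hyd = c("CB", "CG")),
    SER = list(don = "OG", acc = "OG"),
    THR = list(hyd = "CG2", don = "OG1", acc = "OG1"),
    TRP = list(hyd = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
               don = "NE1",
               ring = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
                           c("CD2", "CE3", "CZ3", "CH2", "CZ2", "CE2"))),
    TYR = list(hyd = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
               don = "OH", acc = "OH",
               ring = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))),
    VAL = list(hyd = c("CB", "CG1", "CG2"))
  )
  tbl
})

#' Annotate the atoms of one standard residue
#'
#' Assigns main-chain/side-chain flags and heavy-atom interaction roles
#' (polar, hydrophobic, donor, acceptor, aromatic, formal charge) from the
#' residue name and PDB atom names.
#'
#' @param resname Three-letter residue code.
#' @param atom_names Character vector of PDB atom names.
#' @param elements Element symbols, same length as `atom_names`. Derived
#'   from the atom names when `NULL`.
#' @return A data.frame with one row per atom and logical/integer role
#'   columns.
#' @keywords internal
annotate_residue_atoms <- function(resname, atom_names, elements = NULL) {
  if (is.null(elements)) elements <- element_from_atom_name(atom_names)
  chem <- .res_chem[[resname]]
  if (is.null(chem)) chem <- list()  # unknown residue: element-only rules
  is_h <- elements == "H"
  main <- atom_names %in% BACKBONE_ATOMS
  # hydrogens follow the heavy atom they are named after (H, HA main chain)
  main[is_h & atom_names %in% c("H", "HA", "H1", "H2", "H3", "HA2", "HA3")] <- TRUE
  polar <- elements %in% c("N", "O", "S")
  don <- atom_names %in% c(chem$don, if (resname != "PRO") "N")
  acc <- atom_names %in% c(chem$acc, "O", "OXT")
  hyd <- atom_names %in% chem$hyd
  charge <- integer(length(atom_names))
  charge[atom_names %in% chem$pos] <- 1L
  charge[atom_names %in% chem$neg] <- -1L
  arom <- atom_names %in% unlist(chem$ring)
  data.frame(name = atom_names, element = elements,
             is_main_chain = main, is_polar = polar, is_hydrophobic = hyd,
             is_donor = don, is_acceptor = acc, is_aromatic = arom,
             formal_charge = charge, stringsAsFactors = FALSE)
}

#' @noRd
residue_ring_sets <- function(resname, atom_names) {
  chem <- .res_chem[[resname]]
  if (is.null(chem$ring)) return(list())
  out <- lapply(chem$ring, function(r) match(r, atom_names))
  Filter(function(ix) !anyNA(ix), out)
}

#' @noRd
element_from_atom_name <- function(atom_names) {
  # PDB heavy-atom convention: element is the leading letter(s); strip digits
  el <- sub("^[0-9]*", "", atom_names)
  el <- substr(el, 1, 1)
  toupper(el)
}
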