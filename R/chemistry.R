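# Hydrogen-bond donor/acceptor and apolar-carbon assignments for protein and
# nucleic acid atoms, plus van der Waals radii for the steric screen.
#
# Roles:
#   donor / acceptor / both  - polar atoms eligible for direct H-bonds
#                              (distance-only; crystal models carry no H)
#   apolar                   - carbon/sulfur atoms eligible for apolar
#                              proximity.  On the DNA side only the exposed
#                              CH/methyl base carbons carry the role, so
#                              apolar contacts are base readout by
#                              construction.
# His ND1/NE2 are both donor and acceptor (protonation unresolved in crystal
# models).  Carboxamide/carboxylate/guanidinium carbons are not apolar.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

.rows <- function(res, atoms, role) {
  if (!length(atoms)) return(NULL)
  data.frame(res = res, atom = atoms, role = role, stringsAsFactors = FALSE)
}

build_chemistry_table <- function() {
  aa <- list(
    ALA = list(ap = "CB"),
    ARG = list(don = c("NE", "NH1", "NH2"), ap = c("CB", "CG", "CD")),
    ASN = list(don = "ND2", acc = "OD1", ap = "CB"),
    ASP = list(acc = c("OD1", "OD2"), ap = "CB"),
    CYS = list(ap = c("CB", "SG")),
    GLN = list(don = "NE2", acc = "OE1", ap = c("CB", "CG")),
    GLU = list(acc = c("OE1", "OE2"), ap = c("CB", "CG")),
    GLY = list(),
    HIS = list(both = c("ND1", "NE2"), ap = c("CB", "CG", "CD2", "CE1")),
    ILE = list(ap = c("CB", "CG1", "CG2", "CD1")),
    LEU = list(ap = c("CB", "CG", "CD1", "CD2")),
    LYS = list(don = "NZ", ap = c("CB", "CG", "CD", "CE")),
    MET = list(ap = c("CB", "CG", "SD", "CE")),
    PHE = list(ap = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
    PRO = list(ap = c("CB", "CG", "CD")),
    SER = list(both = "OG", ap = "CB"),
    THR = list(both = "OG1", ap = c("CB", "CG2")),
    TRP = list(don = "NE1",
               ap = c("CB", "CG", "CD1", "CD2", "CE2", "CE3",
                      "CZ2", "CZ3", "CH2")),
    TYR = list(both = "OH",
               ap = c("CB", "CG", "CD1", "CD2", "CE1", "CE2")),
    VAL = list(ap = c("CB", "CG1", "CG2"))
  )
  nt <- list(
    A = list(don = "N6", acc = c("N7", "N1", "N3"), ap = c("C2", "C8")),
    G = list(don = c("N1", "N2"), acc = c("O6", "N7", "N3"), ap = "C8"),
    C = list(don = "N4", acc = c("N3", "O2"), ap = c("C5", "C6")),
    T = list(don = "N3", acc = c("O2", "O4"), ap = c("C5", "C6", "C7")),
    U = list(don = "N3", acc = c("O2", "O4"), ap = c("C5", "C6"))
  )
  out <- list()
  add <- function(res, spec, backbone) {
    out[[length(out) + 1L]] <<- do.call(rbind, c(list(
      .rows(res, spec$don, "donor"),
      .rows(res, spec$acc, "acceptor"),
      .rows(res, spec$both, "both"),
      .rows(res, spec$ap, "apolar")),
      list(backbone)))
  }
  for (r in names(aa)) {
    bb <- rbind(
      if (r != "PRO") .rows(r, "N", "donor"),
      .rows(r, c("O", "OXT"), "acceptor"))
    add(r, aa[[r]], bb)
  }
  for (b in names(nt)) {
    bb <- .rows(b, c("OP1", "OP2", "O1P", "O2P", "O5'", "O3'", "O4'"),
                "acceptor")
    for (res in c(b, paste0("D", b))) add(res, nt[[b]], bb)
  }
  out[[length(out) + 1L]] <- .rows("HOH", "O", "both")
  out[[length(out) + 1L]] <- .rows("WAT", "O", "both")
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab
}

CHEMISTRY_TABLE <- build_chemistry_table()

#' Atom chemistry table used for contact detection
#'
#' Donor/acceptor/apolar role of each named atom of the 20 amino acids, the
#' A/C/G/T/U nucleotides (both `A` and `DA` style residue names) and water
#' oxygen.
#'
#' @return `data.frame` with columns `res`, `atom`, `role`.
#' @export
chemistry_table <- function() CHEMISTRY_TABLE

# DNA atom class: base / phosphate / sugar, by atom name.
dna_atom_class <- function(atom) {
  ifelse(atom %in% c("P", "OP1", "OP2", "O1P", "O2P", "O5'", "O3'"),
         "phosphate",
         ifelse(grepl("'", atom, fixed = TRUE), "sugar", "base"))
}

# Element from atom name (fixture files and most PDBs: first letter of the
# stripped name, with two-letter elements not expected here).
element_of <- function(atom) substring(gsub("[0-9']", "", atom), 1L, 1L)

# Chain classification by residue name.
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
NT_RES <- c("A", "C", "G", "T", "U", "DA", "DC", "DG", "DT", "DU")
WATER_RES <- c("HOH", "WAT")

classify_residue <- function(resid) {
  ifelse(resid %in% AA3, "protein",
         ifelse(resid %in% NT_RES, "nucleic",
                ifelse(resid %in% WATER_RES, "water", "other")))
}
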