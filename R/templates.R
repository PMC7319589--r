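# Idealized amino-acid templates. Each residue is defined by a Z-matrix over
# heavy atoms: every side-chain atom is placed from three previously placed
# atoms by bond length, bond angle and torsion (Engh-Huber-like values,
# extended chi angles, no rotamer search). Backbone N/CA/C/O/CB are shared.

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")
AA1 <- stats::setNames(names(AA3), AA3)
BACKBONE_ATOMS <- c("N", "CA", "C", "O")

aa_one <- function(name3) {
  out <- unname(AA1[toupper(name3)])
  if (any(is.na(out))) stop("nonstandard residue name: ",
                            paste(name3[is.na(out)], collapse = ", "))
  out
}

aa_three <- function(code1) {
  out <- unname(AA3[toupper(code1)])
  if (any(is.na(out))) stop("nonstandard amino-acid code: ",
                            paste(code1[is.na(out)], collapse = ", "))
  out
}

# Side-chain Z-matrix rows: atom, ref atoms a/b/c, bond |c-d|, angle(b,c,d),
# torsion(a,b,c,d). CB is defined once for all non-GLY residues.
zrow <- function(atom, a, b, c, bond, angle, dihedral)
  list(atom = atom, a = a, b = b, c = c, bond = bond, angle = angle, dih = dihedral)

SIDECHAIN_Z <- list(
  ALA = list(),
  SER = list(zrow("OG", "N", "CA", "CB", 1.417, 110.8, 180)),
  CYS = list(zrow("SG", "N", "CA", "CB", 1.808, 113.8, 180)),
  THR = list(zrow("OG1", "N", "CA", "CB", 1.433, 109.6, 180),
             zrow("CG2", "N", "CA", "CB", 1.521, 110.5, -60)),
  VAL = list(zrow("CG1", "N", "CA", "CB", 1.527, 110.7, 180),
             zrow("CG2", "N", "CA", "CB", 1.527, 110.4, 60)),
  LEU = list(zrow("CG", "N", "CA", "CB", 1.530, 116.3, 180),
             zrow("CD1", "CA", "CB", "CG", 1.521, 110.7, 180),
             zrow("CD2", "CA", "CB", "CG", 1.521, 110.7, 60)),
  ILE = list(zrow("CG1", "N", "CA", "CB", 1.530, 110.4, 180),
             zrow("CG2", "N", "CA", "CB", 1.521, 110.5, -60),
             zrow("CD1", "CA", "CB", "CG1", 1.513, 113.8, 180)),
  MET = list(zrow("CG", "N", "CA", "CB", 1.520, 114.1, 180),
             zrow("SD", "CA", "CB", "CG", 1.803, 112.7, 180),
             zrow("CE", "CB", "CG", "SD", 1.791, 100.9, 180)),
  PRO = list(zrow("CG", "N", "CA", "CB", 1.492, 100.7, 32.4),
             zrow("CD", "CA", "CB", "CG", 1.503, 105.2, -28.2)),
  PHE = list(zrow("CG", "N", "CA", "CB", 1.502, 113.8, 180),
             zrow("CD1", "CA", "CB", "CG", 1.384, 120.8, 90),
             zrow("CD2", "CA", "CB", "CG", 1.384, 120.8, -90),
             zrow("CE1", "CB", "CG", "CD1", 1.382, 121.1, 180),
             zrow("CE2", "CB", "CG", "CD2", 1.382, 121.1, 180),
             zrow("CZ", "CG", "CD1", "CE1", 1.382, 119.9, 0)),
  TYR = list(zrow("CG", "N", "CA", "CB", 1.512, 113.9, 180),
             zrow("CD1", "CA", "CB", "CG", 1.389, 120.8, 90),
             zrow("CD2", "CA", "CB", "CG", 1.389, 120.8, -90),
             zrow("CE1", "CB", "CG", "CD1", 1.382, 121.1, 180),
             zrow("CE2", "CB", "CG", "CD2", 1.382, 121.1, 180),
             zrow("CZ", "CG", "CD1", "CE1", 1.378, 119.6, 0),
             zrow("OH", "CD1", "CE1", "CZ", 1.376, 119.9, 180)),
  TRP = list(zrow("CG", "N", "CA", "CB", 1.498, 113.6, 180),
             zrow("CD1", "CA", "CB", "CG", 1.365, 126.9, 90),
             zrow("CD2", "CA", "CB", "CG", 1.433, 126.7, -90),
             zrow("NE1", "CB", "CG", "CD1", 1.374, 110.2, 180),
             zrow("CE2", "CG", "CD1", "NE1", 1.370, 108.9, 0),
             zrow("CE3", "CB", "CG", "CD2", 1.398, 133.9, 0),
             zrow("CZ2", "CD1", "NE1", "CE2", 1.394, 130.1, 180),
             zrow("CZ3", "CG", "CD2", "CE3", 1.382, 118.8, 180),
             zrow("CH2", "NE1", "CE2", "CZ2", 1.368, 117.5, 180)),
  HIS = list(zrow("CG", "N", "CA", "CB", 1.504, 113.8, 180),
             zrow("ND1", "CA", "CB", "CG", 1.378, 122.7, 90),
             zrow("CD2", "CA", "CB", "CG", 1.354, 131.2, -90),
             zrow("CE1", "CB", "CG", "ND1", 1.321, 109.3, 180),
             zrow("NE2", "CB", "CG", "CD2", 1.374, 107.2, 180)),
  ASP = list(zrow("CG", "N", "CA", "CB", 1.516, 112.6, 180),
             zrow("OD1", "CA", "CB", "CG", 1.249, 118.4, 0),
             zrow("OD2", "CA", "CB", "CG", 1.249, 118.4, 180)),
  ASN = list(zrow("CG", "N", "CA", "CB", 1.516, 112.6, 180),
             zrow("OD1", "CA", "CB", "CG", 1.231, 120.8, 0),
             zrow("ND2", "CA", "CB", "CG", 1.328, 116.4, 180)),
  GLU = list(zrow("CG", "N", "CA", "CB", 1.520, 114.1, 180),
             zrow("CD", "CA", "CB", "CG", 1.516, 112.6, 180),
             zrow("OE1", "CB", "CG", "CD", 1.249, 118.4, 0),
             zrow("OE2", "CB", "CG", "CD", 1.249, 118.4, 180)),
  GLN = list(zrow("CG", "N", "CA", "CB", 1.520, 114.1, 180),
             zrow("CD", "CA", "CB", "CG", 1.516, 112.6, 180),
             zrow("OE1", "CB", "CG", "CD", 1.231, 120.8, 0),
             zrow("NE2", "CB", "CG", "CD", 1.328, 116.4, 180)),
  LYS = list(zrow("CG", "N", "CA", "CB", 1.520, 114.1, 180),
             zrow("CD", "CA", "CB", "CG", 1.520, 111.3, 180),
             zrow("CE", "CB", "CG", "CD", 1.520, 111.3, 180),
             zrow("NZ", "CG", "CD", "CE", 1.489, 111.9, 180)),
  ARG = list(zrow("CG", "N", "CA", "CB", 1.520, 114.1, 180),
             zrow("CD", "CA", "CB", "CG", 1.520, 111.3, 180),
             zrow("NE", "CB", "CG", "CD", 1.461, 112.0, 180),
             zrow("CZ", "CG", "CD", "NE", 1.329, 124.2, 180),
             zrow("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0),
             zrow("NH2", "CD", "NE", "CZ", 1.326, 120.0, 180)),
  GLY = list()
)

atom_element <- function(atom) {
  # PDB v3 protein heavy-atom names start with the element symbol
  substr(gsub("[0-9]", "", atom), 1, 1)
}

#' Idealized residue template
#'
#' Returns the heavy atoms of one amino acid built from ideal internal
#' coordinates in a canonical backbone frame (CA at the origin). Used by
#' [build_mutant()] to graft side chains and by [make_toy_complex()] to
#' construct synthetic structures.
#'
#' @param name3 Three-letter residue name (e.g. `"LYS"`).
#' @return A tibble with columns `atom`, `element`, `x`, `y`, `z`,
#'   `is_backbone`.
#' @export
residue_template <- function(name3) {
  name3 <- toupper(name3)
  if (!name3 %in% names(SIDECHAIN_Z)) stop("nonstandard residue name: ", name3)
  pos <- list(
    N = c(1.458, 0, 0),
    CA = c(0, 0, 0),
    C = 1.525 * c(cos(111 * pi / 180), sin(111 * pi / 180), 0)
  )
  pos$O <- place_atom(pos$N, pos$CA, pos$C, 1.231, 120.5, -45)
  if (name3 != "GLY") {
    pos$CB <- place_atom(pos$C, pos$N, pos$CA, 1.530, 110.5, 122.5)
    for (z in SIDECHAIN_Z[[name3]]) {
      pos[[z$atom]] <- place_atom(pos[[z$a]], pos[[z$b]], pos[[z$c]],
                                  z$bond, z$angle, z$dih)
    }
  }
  atoms <- names(pos)
  m <- do.call(rbind, pos)
  tibble::tibble(
    atom = atoms,
    element = atom_element(atoms),
    x = m[, 1], y = m[, 2], z = m[, 3],
    is_backbone = atoms %in% BACKBONE_ATOMS
  )
}
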