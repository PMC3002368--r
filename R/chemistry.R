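# Amino-acid chemistry tables: residue topologies with ideal internal
# coordinates (bond lengths/angles in the united-atom, heavy-atom model),
# chi torsion definitions, van der Waals radii, and reference accessible
# surface areas. These tables drive side-chain building, chi measurement and
# the non-bonded exclusion rules.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# one topology row: atom placed from reference atoms a-b-c (NeRF), with the
# torsion a-b-c-atom given either by a chi angle (+offset) or a fixed value
sc_row <- function(atom, a, b, c, len, ang, tors_type, chi_index, offset) {
  data.frame(atom = atom, a = a, b = b, c = c, len = len, ang = ang,
             tors_type = tors_type, chi_index = chi_index, offset = offset,
             stringsAsFactors = FALSE)
}

cb_row <- function(len = 1.530, ang = 110.5)
  sc_row("CB", "C", "N", "CA", len, ang, "fixed", 0L, 122.6)

sidechain_topology <- local({
  tp <- list()
  tp$ALA <- cb_row(1.521, 110.4)
  tp$SER <- rbind(cb_row(),
    sc_row("OG", "N", "CA", "CB", 1.417, 110.8, "chi", 1L, 0))
  tp$CYS <- rbind(cb_row(),
    sc_row("SG", "N", "CA", "CB", 1.808, 113.8, "chi", 1L, 0))
  tp$THR <- rbind(cb_row(1.542, 111.5),
    sc_row("OG1", "N", "CA", "CB", 1.433, 109.6, "chi", 1L, 0),
    sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, "chi", 1L, -122.0))
  tp$VAL <- rbind(cb_row(1.540, 111.5),
    sc_row("CG1", "N", "CA", "CB", 1.521, 110.5, "chi", 1L, 0),
    sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, "chi", 1L, 122.3))
  tp$ILE <- rbind(cb_row(1.540, 111.5),
    sc_row("CG1", "N", "CA", "CB", 1.530, 110.4, "chi", 1L, 0),
    sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, "chi", 1L, -122.3),
    sc_row("CD1", "CA", "CB", "CG1", 1.513, 113.9, "chi", 2L, 0))
  tp$LEU <- rbind(cb_row(),
    sc_row("CG", "N", "CA", "CB", 1.530, 116.3, "chi", 1L, 0),
    sc_row("CD1", "CA", "CB", "CG", 1.521, 110.7, "chi", 2L, 0),
    sc_row("CD2", "CA", "CB", "CG", 1.521, 110.7, "chi", 2L, 122.3))
  tp$MET <- rbind(cb_row(),
    sc_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi", 1L, 0),
    sc_row("SD", "CA", "CB", "CG", 1.803, 112.7, "chi", 2L, 0),
    sc_row("CE", "CB", "CG", "SD", 1.791, 100.9, "chi", 3L, 0))
  tp$ASP <- rbind(cb_row(),
    sc_row("CG", "N", "CA", "CB", 1.516, 112.6, "chi", 1L, 0),
    sc_row("OD1", "CA", "CB", "CG", 1.249, 118.4, "chi", 2L, 0),
    sc_row("OD2", "CA", "CB", "CG", 1.249, 118.4, "chi", 2L, 180))
  tp$ASN <- rbind(cb_row(),
    sc_row("CG", "N", "CA", "CB", 1.516, 112.6, "chi", 1L, 0),
    sc_row("OD1", "CA", "CB", "CG", 1.231, 120.8, "chi", 2L, 0),
    sc_row("ND2", "CA", "CB", "CG", 1.328, 116.4, "chi", 2L, 180))
  tp$GLU <- rbind(cb_row(),
    sc_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi", 1L, 0),
    sc_row("CD", "CA", "CB", "CG", 1.516, 112.6, "chi", 2L, 0),
    sc_row("OE1", "CB", "CG", "CD", 1.249, 118.4, "chi", 3L, 0),
    sc_row("OE2", "CB", "CG", "CD", 1.249, 118.4, "chi", 3L, 180))
  tp$GLN <- rbind(cb_row(),
    sc_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi", 1L, 0),
    sc_row("CD", "CA", "CB", "CG", 1.516, 112.6, "chi", 2L, 0),
    sc_row("OE1", "CB", "CG", "CD", 1.231, 120.8, "chi", 3L, 0),
    sc_row("NE2", "CB", "CG", "CD", 1.328, 116.4, "chi", 3L, 180))
  tp$LYS <- rbind(cb_row(),
    sc_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi", 1L, 0),
    sc_row("CD", "CA", "CB", "CG", 1.520, 111.3, "chi", 2L, 0),
    sc_row("CE", "CB", "CG", "CD", 1.520, 111.3, "chi", 3L, 0),
    sc_row("NZ", "CG", "CD", "CE", 1.489, 111.9, "chi", 4L, 0))
  tp$ARG <- rbind(cb_row(),
    sc_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi", 1L, 0),
    sc_row("CD", "CA", "CB", "CG", 1.520, 111.3, "chi", 2L, 0),
    sc_row("NE", "CB", "CG", "CD", 1.461, 112.0, "chi", 3L, 0),
    sc_row("CZ", "CG", "CD", "NE", 1.329, 124.2, "chi", 4L, 0),
    sc_row("NH1", "CD", "NE", "CZ", 1.326, 120.0, "chi", 5L, 0),
    sc_row("NH2", "CD", "NE", "CZ", 1.326, 120.0, "chi", 5L, 180))
  tp$HIS <- rbind(cb_row(),
    sc_row("CG", "N", "CA", "CB", 1.497, 113.8, "chi", 1L, 0),
    sc_row("ND1", "CA", "CB", "CG", 1.378, 122.7, "chi", 2L, 0),
    sc_row("CD2", "CA", "CB", "CG", 1.354, 131.0, "chi", 2L, 180),
    sc_row("CE1", "CB", "CG", "ND1", 1.320, 109.3, "fixed", 0L, 180),
    sc_row("NE2", "CG", "ND1", "CE1", 1.310, 111.7, "fixed", 0L, 0))
  tp$PHE <- rbind(cb_row(),
    sc_row("CG", "N", "CA", "CB", 1.502, 113.8, "chi", 1L, 0),
    sc_row("CD1", "CA", "CB", "CG", 1.384, 120.7, "chi", 2L, 0),
    sc_row("CD2", "CA", "CB", "CG", 1.384, 120.7, "chi", 2L, 180),
    sc_row("CE1", "CB", "CG", "CD1", 1.384, 120.7, "fixed", 0L, 180),
    sc_row("CE2", "CB", "CG", "CD2", 1.384, 120.7, "fixed", 0L, 180),
    sc_row("CZ", "CG", "CD1", "CE1", 1.384, 120.0, "fixed", 0L, 0))
  tp$TYR <- rbind(cb_row(),
    sc_row("CG", "N", "CA", "CB", 1.512, 113.9, "chi", 1L, 0),
    sc_row("CD1", "CA", "CB", "CG", 1.389, 120.8, "chi", 2L, 0),
    sc_row("CD2", "CA", "CB", "CG", 1.389, 120.8, "chi", 2L, 180),
    sc_row("CE1", "CB", "CG", "CD1", 1.389, 121.2, "fixed", 0L, 180),
    sc_row("CE2", "CB", "CG", "CD2", 1.389, 121.2, "fixed", 0L, 180),
    sc_row("CZ", "CG", "CD1", "CE1", 1.378, 119.6, "fixed", 0L, 0),
    sc_row("OH", "CD1", "CE1", "CZ", 1.376, 119.9, "fixed", 0L, 180))
  tp$TRP <- rbind(cb_row(),
    sc_row("CG", "N", "CA", "CB", 1.498, 113.6, "chi", 1L, 0),
    sc_row("CD1", "CA", "CB", "CG", 1.365, 127.0, "chi", 2L, 0),
    sc_row("CD2", "CA", "CB", "CG", 1.433, 126.6, "chi", 2L, 180),
    sc_row("NE1", "CB", "CG", "CD1", 1.374, 110.2, "fixed", 0L, 180),
    sc_row("CE2", "CB", "CG", "CD2", 1.409, 107.2, "fixed", 0L, 180),
    sc_row("CE3", "CB", "CG", "CD2", 1.398, 133.9, "fixed", 0L, 0),
    sc_row("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, "fixed", 0L, 180),
    sc_row("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, "fixed", 0L, 180),
    sc_row("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, "fixed", 0L, 0))
  # proline ring is built as a rigid approximation (single pucker); it is
  # carried as a one-rotamer type, never sampled freely
  tp$PRO <- rbind(cb_row(1.530, 103.0),
    sc_row("CG", "N", "CA", "CB", 1.492, 104.5, "chi", 1L, 0),
    sc_row("CD", "CA", "CB", "CG", 1.503, 106.1, "fixed", 0L, -35))
  tp
})

# chi torsion definitions: list of 4 atom names per chi, per residue type
chi_definitions <- list(
  SER = list(c("N", "CA", "CB", "OG")),
  CYS = list(c("N", "CA", "CB", "SG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  VAL = list(c("N", "CA", "CB", "CG1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ"),
             c("CD", "NE", "CZ", "NH1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"))
)

#' Number of chi torsion angles of a residue type
#'
#' @param res_type 3-letter residue code.
#' @return integer count (0 for ALA/GLY).
#' @export
n_chi <- function(res_type) {
  d <- chi_definitions[[res_type]]
  if (is.null(d)) 0L else length(d)
}

# flexible types: everything but ALA/GLY
FLEXIBLE_TYPES <- setdiff(AA3, c("ALA", "GLY"))

# ARG/LYS terminal torsions are defaulted when absent from a library row;
# the atoms they place are excluded from energy calculations
CHI_DEFAULTS <- list(LYS = c(chi4 = 180), ARG = c(chi4 = 180, chi5 = 0))
EXCLUDED_ENERGY_ATOMS <- list(LYS = "NZ", ARG = c("CZ", "NH1", "NH2"))

#' Side-chain atom names of a residue type, in build order
#' @param res_type 3-letter residue code.
#' @return character vector (empty for GLY).
#' @export
sidechain_atoms <- function(res_type) {
  tp <- sidechain_topology[[res_type]]
  if (is.null(tp)) character(0) else tp$atom
}

#' Chemical element from a PDB heavy-atom name
#' @param name atom name(s), e.g. "OG1".
#' @return element symbol(s): C, N, O or S.
#' @export
atom_element <- function(name) {
  substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", name)), 1, 1)
}

# united-atom van der Waals radii (Angstrom) for surface computation
VDW_RADII <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85)

# reference accessible surface areas (Angstrom^2) of residue X in an
# extended Gly-X-Gly tripeptide (theoretical maxima, Tien et al. 2013)
REFERENCE_ASA <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLU = 223,
  GLN = 225, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
  MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
  TYR = 263, VAL = 174)

# intra-residue bond graph (backbone + side-chain tree + ring closures),
# used for the <4-bonds non-bonded exclusion; returns a bond-separation
# matrix between all heavy atoms of the type
RING_CLOSURES <- list(
  HIS = list(c("NE2", "CD2")),
  PHE = list(c("CZ", "CE2")),
  TYR = list(c("CZ", "CE2")),
  TRP = list(c("NE1", "CE2"), c("CZ3", "CH2")),
  PRO = list(c("CD", "N")))

bond_separation_matrix <- function(res_type) {
  atoms <- c(BACKBONE_ATOMS, sidechain_atoms(res_type))
  bonds <- list(c("N", "CA"), c("CA", "C"), c("C", "O"))
  tp <- sidechain_topology[[res_type]]
  if (!is.null(tp))
    bonds <- c(bonds, lapply(seq_len(nrow(tp)),
                             function(i) c(tp$c[i], tp$atom[i])))
  bonds <- c(bonds, RING_CLOSURES[[res_type]])
  n <- length(atoms)
  adj <- matrix(FALSE, n, n, dimnames = list(atoms, atoms))
  for (b in bonds) adj[b[1], b[2]] <- adj[b[2], b[1]] <- TRUE
  sep <- matrix(Inf, n, n, dimnames = list(atoms, atoms))
  diag(sep) <- 0
  for (i in seq_len(n)) {   # BFS from each atom (graphs are tiny)
    frontier <- i
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) &
                     !is.finite(sep[i, ]))
      sep[i, nxt] <- d
      frontier <- nxt
    }
  }
  sep
}

bond_separation_cache <- new.env(parent = emptyenv())

get_bond_separation <- function(res_type) {
  if (is.null(bond_separation_cache[[res_type]]))
    bond_separation_cache[[res_type]] <- bond_separation_matrix(res_type)
  bond_separation_cache[[res_type]]
}
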