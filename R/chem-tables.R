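# Static chemistry tables: chi-angle definitions, rotamer library, van der
# Waals radii, scattering amplitudes.  Angles in degrees, lengths in angstroms.

.backbone_atoms <- c("N", "CA", "C", "O")

.aromatic_residues <- c("HIS", "TYR", "PHE", "TRP")

# Atom quadruples defining each chi torsion, per residue type.
.chi_atoms <- list(
  SER = list(c("N", "CA", "CB", "OG")),
  CYS = list(c("N", "CA", "CB", "SG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  VAL = list(c("N", "CA", "CB", "CG1")),
  PRO = list(c("N", "CA", "CB", "CG")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ"))
)

# Atoms displaced when each chi is rotated (everything distal to the rotated
# bond, branch-aware).  Proline chi1 moves only CG: the CD-N closure is kept
# fixed and the small ring distortion is tolerated (pucker sampling contract
# is on the chi1 torsion).
.chi_moving <- list(
  SER = list("OG"),
  CYS = list("SG"),
  THR = list(c("OG1", "CG2")),
  VAL = list(c("CG1", "CG2")),
  PRO = list("CG"),
  ILE = list(c("CG1", "CG2", "CD1"), "CD1"),
  LEU = list(c("CG", "CD1", "CD2"), c("CD1", "CD2")),
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
             c("CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
             c("CD1", "CD2", "CE1", "CE2", "CZ", "OH")),
  TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
             c("CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2"),
             c("ND1", "CD2", "CE1", "NE2")),
  ASP = list(c("CG", "OD1", "OD2"), c("OD1", "OD2")),
  ASN = list(c("CG", "OD1", "ND2"), c("OD1", "ND2")),
  MET = list(c("CG", "SD", "CE"), c("SD", "CE"), "CE"),
  GLU = list(c("CG", "CD", "OE1", "OE2"), c("CD", "OE1", "OE2"),
             c("OE1", "OE2")),
  GLN = list(c("CG", "CD", "OE1", "NE2"), c("CD", "OE1", "NE2"),
             c("OE1", "NE2")),
  LYS = list(c("CG", "CD", "CE", "NZ"), c("CD", "CE", "NZ"),
             c("CE", "NZ"), "NZ"),
  ARG = list(c("CG", "CD", "NE", "CZ", "NH1", "NH2"),
             c("CD", "NE", "CZ", "NH1", "NH2"),
             c("NE", "CZ", "NH1", "NH2"), c("CZ", "NH1", "NH2"))
)

#' Built-in idealized rotamer library
#'
#' Compact table of idealized rotamer chi-angle means (penultimate-style
#' values, degrees) per residue type.  Sampling explores +/-24 degrees around
#' each mean, so modest differences from any particular published library are
#' immaterial.  Proline is handled as its two ring puckers (exo/endo).
#'
#' @return Named list mapping three-letter residue codes to numeric matrices,
#'   one row per rotamer, one column per chi angle.
#' @export
rotamer_library <- function() .rotamer_lib

.rotamer_lib <- {
  m <- function(...) {
    x <- rbind(...)
    colnames(x) <- paste0("chi", seq_len(ncol(x)))
    x
  }
  list(
    SER = m(62, -177, -65),
    CYS = m(62, -177, -65),
    THR = m(62, -175, -65),
    VAL = m(63, 175, -60),
    PRO = m(-25, 25),
    ILE = m(c(62, 100), c(62, 170), c(-177, 66), c(-177, 165),
            c(-65, 100), c(-65, 170), c(-57, -60)),
    LEU = m(c(62, 80), c(-177, 65), c(-172, 145), c(-85, 65), c(-65, 175)),
    PHE = m(c(62, 90), c(-177, 80), c(-65, -85), c(-65, -30)),
    TYR = m(c(62, 90), c(-177, 80), c(-65, -85), c(-65, -30)),
    TRP = m(c(62, -90), c(62, 90), c(-177, -105), c(-177, 90),
            c(-65, -90), c(-65, 5), c(-65, 95)),
    HIS = m(c(62, -75), c(62, 80), c(-177, -165), c(-177, -80),
            c(-177, 60), c(-65, -70), c(-65, 165), c(-65, 80)),
    ASP = m(c(62, 10), c(-177, 0), c(-70, -15)),
    ASN = m(c(62, -10), c(-174, -20), c(-65, -75), c(-65, 120)),
    MET = m(c(62, 180, 75), c(62, 180, -75), c(-177, 65, 75),
            c(-177, 180, 75), c(-67, 180, 75), c(-67, 180, -75),
            c(-65, -65, 103)),
    GLU = m(c(62, 180, -20), c(-177, 65, 10), c(-177, 180, 0),
            c(-80, -180, 0), c(-65, -65, -40)),
    GLN = m(c(62, 180, 20), c(-177, 65, -100), c(-177, 180, 0),
            c(-65, -65, -40), c(-65, 180, 0)),
    LYS = m(c(62, 180, 180, 180), c(-177, 68, 180, 180),
            c(-177, 180, 180, 180), c(-90, 68, 180, 180),
            c(-67, 180, 180, 180), c(-67, -68, 180, 180)),
    ARG = m(c(62, 180, 65, 85), c(62, 180, 180, 180),
            c(-177, 65, 65, 85), c(-177, 180, 180, 180),
            c(-67, 180, 65, 85), c(-67, 180, 180, 180),
            c(-67, -167, 180, 180))
  )
}

# Number of chi angles sampled for a residue type (0 when absent).
.n_chi <- function(resn) {
  defs <- .chi_atoms[[resn]]
  if (is.null(defs)) 0L else length(defs)
}

# Distinct idealized means for one chi of a residue type.
.chi_means <- function(resn, chi_index, library = .rotamer_lib) {
  lib <- library[[resn]]
  if (is.null(lib) || chi_index > ncol(lib))
    stop("no rotamer means for ", resn, " chi", chi_index)
  unique(lib[, chi_index])
}

# van der Waals radii (angstroms) for the hard-sphere clash model.
.vdw_radii <- c(H = 1.10, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85)

.vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  r[is.na(r)] <- 1.7
  unname(r)
}

# X-ray scattering amplitude: total electron count per element.
.electron_counts <- c(H = 1, C = 6, N = 7, O = 8, S = 16, P = 15,
                      SE = 34, F = 9, CL = 17, BR = 35)

# Electron (cryo-EM) forward-scattering amplitudes: sums of the Gaussian
# form-factor coefficients (Peng-style parameterization), arbitrary units --
# only relative weights matter for the linear density fit.
.electron_scattering <- c(H = 0.53, C = 2.51, N = 2.21, O = 1.98, S = 5.46,
                          P = 5.49, SE = 5.96, F = 1.80, CL = 4.86, BR = 5.90)

.scatter_amp <- function(element, mode) {
  el <- toupper(element)
  tab <- if (identical(mode, "em")) .electron_scattering else .electron_counts
  a <- tab[el]
  a[is.na(a)] <- if (identical(mode, "em")) 2.5 else 6
  unname(a)
}

.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

# heavy-atom covalent connectivity of the standard residues (intra-residue),
# used for 1-2/1-3 clash exclusions; robust to distorted input geometry
.bb_bonds <- list(c("N", "CA"), c("CA", "C"), c("C", "O"), c("C", "OXT"),
                  c("CA", "CB"))
.sc_bonds <- list(
  ALA = list(), GLY = list(),
  SER = list(c("CB", "OG")),
  CYS = list(c("CB", "SG")),
  THR = list(c("CB", "OG1"), c("CB", "CG2")),
  VAL = list(c("CB", "CG1"), c("CB", "CG2")),
  LEU = list(c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2")),
  ILE = list(c("CB", "CG1"), c("CB", "CG2"), c("CG1", "CD1")),
  PRO = list(c("CB", "CG"), c("CG", "CD"), c("CD", "N")),
  MET = list(c("CB", "CG"), c("CG", "SD"), c("SD", "CE")),
  PHE = list(c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"), c("CD1", "CE1"),
             c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ")),
  TYR = list(c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"), c("CD1", "CE1"),
             c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ"), c("CZ", "OH")),
  TRP = list(c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"), c("CD1", "NE1"),
             c("NE1", "CE2"), c("CD2", "CE2"), c("CD2", "CE3"),
             c("CE2", "CZ2"), c("CE3", "CZ3"), c("CZ2", "CH2"),
             c("CZ3", "CH2")),
  HIS = list(c("CB", "CG"), c("CG", "ND1"), c("CG", "CD2"), c("ND1", "CE1"),
             c("CD2", "NE2"), c("CE1", "NE2")),
  ASP = list(c("CB", "CG"), c("CG", "OD1"), c("CG", "OD2")),
  ASN = list(c("CB", "CG"), c("CG", "OD1"), c("CG", "ND2")),
  GLU = list(c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"), c("CD", "OE2")),
  GLN = list(c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"), c("CD", "NE2")),
  LYS = list(c("CB", "CG"), c("CG", "CD"), c("CD", "CE"), c("CE", "NZ")),
  ARG = list(c("CB", "CG"), c("CG", "CD"), c("CD", "NE"), c("NE", "CZ"),
             c("CZ", "NH1"), c("CZ", "NH2"))
)
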