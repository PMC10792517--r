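# Chemical tables: residue codes, chi-angle definitions, bond topology,
# van der Waals radii, reference accessible areas, and the assessment's
# threshold constants.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
names(AA1) <- AA3

aa_three_to_one <- function(res) {
  out <- AA1[res]
  out[is.na(out)] <- "X"
  unname(out)
}

# Heavy-atom vdW radii (A); used by the clash surrogate, SASA and CAD.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# Theoretical maximum accessible areas (A^2) in a Gly-X-Gly tripeptide
# (Tien et al. values), the denominators of relative SASA.
MAX_SASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
              GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
              LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
              SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

# Canonical chi-angle atom quadruples, chi1..chi4 per residue type.
CHI_ATOMS <- list(
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  CYS = list(c("N", "CA", "CB", "SG")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  VAL = list(c("N", "CA", "CB", "CG1"))
)

# Side chains whose terminal dihedral is chemically symmetric under a 180
# degree flip about the preceding bond: residue -> index of that chi.
# Configurable; His ring flips are offered separately where relevant.
CHI_SYMMETRIC <- c(ASP = 2L, GLU = 3L, PHE = 2L, TYR = 2L)

# Atom-name swaps realising the 180-degree flip, for coordinate-space
# comparisons (site RMSD).
FLIP_SWAPS <- list(
  ASP = list(c("OD1", "OD2")),
  GLU = list(c("OE1", "OE2")),
  PHE = list(c("CD1", "CD2"), c("CE1", "CE2")),
  TYR = list(c("CD1", "CD2"), c("CE1", "CE2")),
  HIS = list(c("ND1", "CD2"), c("CE1", "NE2"))
)

# Within-residue heavy-atom bonds (beyond the N-CA, CA-C, C-O backbone).
SIDECHAIN_BONDS <- list(
  ALA = list(c("CA", "CB")),
  ARG = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "NE"),
             c("NE", "CZ"), c("CZ", "NH1"), c("CZ", "NH2")),
  ASN = list(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"), c("CG", "ND2")),
  ASP = list(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"), c("CG", "OD2")),
  CYS = list(c("CA", "CB"), c("CB", "SG")),
  GLN = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"),
             c("CD", "NE2")),
  GLU = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"),
             c("CD", "OE2")),
  GLY = list(),
  HIS = list(c("CA", "CB"), c("CB", "CG"), c("CG", "ND1"), c("CG", "CD2"),
             c("ND1", "CE1"), c("CD2", "NE2"), c("CE1", "NE2")),
  ILE = list(c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2"), c("CG1", "CD1")),
  LEU = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2")),
  LYS = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "CE"),
             c("CE", "NZ")),
  MET = list(c("CA", "CB"), c("CB", "CG"), c("CG", "SD"), c("SD", "CE")),
  PHE = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
             c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ")),
  PRO = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "N")),
  SER = list(c("CA", "CB"), c("CB", "OG")),
  THR = list(c("CA", "CB"), c("CB", "OG1"), c("CB", "CG2")),
  TRP = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
             c("CD1", "NE1"), c("NE1", "CE2"), c("CD2", "CE2"), c("CD2", "CE3"),
             c("CE2", "CZ2"), c("CZ2", "CH2"), c("CH2", "CZ3"), c("CZ3", "CE3")),
  TYR = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
             c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ"),
             c("CZ", "OH")),
  VAL = list(c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2"))
)

BACKBONE_BONDS <- list(c("N", "CA"), c("CA", "C"), c("C", "O"), c("C", "OXT"))

#' Assessment threshold constants
#'
#' All fixed thresholds used across the assessment pipeline, in one place.
#' These are the values the ranking and analyses are defined with; functions
#' take them as defaults and accept overrides.
#'
#' @return Named list of constants.
#' @export
mc_defaults <- function() {
  list(
    z_outlier_cut = -2,
    composite_weights = c(group1 = 1 / 16, group2 = 1 / 12, group3 = 1 / 4),
    min_eus = 10,
    n_eus_total = 112,
    gdt_ts_thresholds = c(1, 2, 4, 8),
    gdt_ha_thresholds = c(0.5, 1, 2, 4),
    lddt_radius = 15,
    lddt_thresholds = c(0.5, 1, 2, 4),
    sg_radius = 6,
    sg_rmsd_cut = 2,
    clash_overlap_cut = 0.4,
    chi_tolerance = 40,
    rel_sasa_surface = 0.20,
    sasa_probe = 1.4,
    context_radius = 10,
    context_min_contacts = 3,
    region_window = 5,
    region_min_len = 3,
    region_cut = 3,
    region_density = 0.5,
    plddt_trim_cutoff = 70,
    llg_min = 60,
    gdt_ts_quality_filter = 80,
    gdt_ha_site_filter = 30,
    model1_random_baseline = 20,
    neff_identity_threshold = 0.8
  )
}
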