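# Amino-acid constant tables used across the feature providers.

#' @keywords internal
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

AA3_FROM_1 <- structure(names(AA1), names = unname(AA1))

# Residue maximal accessible surface areas (A^2) in an extended Gly-X-Gly
# context; theoretical values of Tien et al. (2013) PLoS ONE 8:e80635.
MAX_SASA <- c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0,
              CYS = 167.0, GLN = 225.0, GLU = 223.0, GLY = 104.0,
              HIS = 224.0, ILE = 197.0, LEU = 201.0, LYS = 236.0,
              MET = 224.0, PHE = 240.0, PRO = 159.0, SER = 155.0,
              THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

# Kyte-Doolittle hydropathy scale (J Mol Biol 1982, 157:105).
KD_HYDROPATHY <- c(ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5,
                   CYS = 2.5, GLN = -3.5, GLU = -3.5, GLY = -0.4,
                   HIS = -3.2, ILE = 4.5, LEU = 3.8, LYS = -3.9,
                   MET = 1.9, PHE = 2.8, PRO = -1.6, SER = -0.8,
                   THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2)

# Background amino-acid frequencies (UniProtKB/Swiss-Prot composition).
AA_BACKGROUND <- c(ALA = 0.0826, ARG = 0.0553, ASN = 0.0406, ASP = 0.0546,
                   CYS = 0.0137, GLN = 0.0393, GLU = 0.0674, GLY = 0.0708,
                   HIS = 0.0227, ILE = 0.0593, LEU = 0.0965, LYS = 0.0582,
                   MET = 0.0241, PHE = 0.0386, PRO = 0.0472, SER = 0.0660,
                   THR = 0.0535, TRP = 0.0110, TYR = 0.0292, VAL = 0.0687)

# van der Waals radii (A) by element, Bondi-style; default covers rare types.
VDW_RADII <- c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
VDW_DEFAULT <- 1.70

# Non-standard residue names mapped to a standard parent type.
NONSTANDARD_MAP <- c(MSE = "MET", SEC = "CYS", SEP = "SER", TPO = "THR",
                     PTR = "TYR", HYP = "PRO", CSO = "CYS", PCA = "GLU",
                     KCX = "LYS", MLY = "LYS", LLP = "LYS", CME = "CYS",
                     CSD = "CYS", OCS = "CYS", PYL = "LYS", ASX = "ASN",
                     GLX = "GLN")

# 20x20 residue-contact pseudo-energy: a rank-one "hydrophobic force"
# construction e(l,k) = -h_l * h_k / max|h|^2 from the Kyte-Doolittle scale,
# so hydrophobic-hydrophobic contacts are favourable (negative).  This is a
# transparent stand-in for knowledge-based contact potentials and is
# replaceable: any symmetric 20x20 matrix with AA3 dimnames works.
contact_potential <- function() {
  h <- KD_HYDROPATHY / max(abs(KD_HYDROPATHY))
  m <- -outer(h, h)
  dimnames(m) <- list(AA3, AA3)
  m
}
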