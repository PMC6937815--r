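# Geometry helpers and amino-acid reference tables used across the package.
# All coordinates are in Angstroms.

AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA3TO1 <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
  HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
  PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
  TRP = "W", TYR = "Y",
  # common non-standard residues mapped to their parent amino acid
  MSE = "M", SEC = "C", PYL = "K", HYP = "P", SEP = "S", TPO = "T",
  PTR = "Y", CSO = "C", MLY = "K", M3L = "K", KCX = "K", CME = "C"
)

AA1TO3 <- setNames(names(AA3TO1)[1:20], AA3TO1[1:20])

# Maximum accessible surface areas (A^2) of residue X in an extended
# Gly-X-Gly context (theoretical values of Tien et al. 2013), used to turn
# absolute SASA into relative SASA.
MAX_SASA <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0
)

# Bondi-type van der Waals radii by element (A); heavy atoms only in
# practice since X-ray PDBs rarely carry hydrogens.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               H = 1.20, SE = 1.90)
VDW_DEFAULT <- 1.70

# Hydrophobic amino acids for the segment score (Nhyd); W is also counted by
# Nwryp — the two terms are independent.
HYDROPHOBIC_AA <- c("A", "C", "F", "I", "L", "M", "V", "W")
WRYP_AA <- c("W", "R", "Y", "P")

# Ideal peptide backbone internal coordinates (A, degrees).
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
BOND_C_O  <- 1.231
BOND_CA_CB <- 1.521
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.8
OMEGA_TRANS  <- 180

# Span of one virtual peptide bond (Calpha-Calpha in trans), used by the
# alanine-linker insertion rule.
PEPTIDE_BOND_SPAN <- 3.8

vec_norm <- function(v) sqrt(sum(v * v))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Euclidean distance between two points
#' @param a,b numeric 3-vectors (Angstroms).
#' @return numeric scalar.
#' @keywords internal
euclid <- function(a, b) sqrt(sum((a - b)^2))

# wrap an angle difference (degrees) into [-180, 180]
wrap_angle <- function(x) ((x + 180) %% 360) - 180

# Torsion angle (degrees) defined by four points.
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / vec_norm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Place a new atom D given three reference atoms A-B-C, the C-D bond length,
# the B-C-D bond angle (degrees) and the A-B-C-D torsion (degrees).
# Standard internal-to-Cartesian (NeRF) construction.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  # negate so that dihedral4(a, b, c, result) == torsion (IUPAC sign)
  tor <- -torsion * pi / 180
  bc <- c - b
  bc <- bc / vec_norm(bc)
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / vec_norm(n)
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta),
        y = sin(phi) * sin(theta),
        z = cos(phi))
}

# residue key helper: "chain:resno:ins"
residue_key <- function(chain, resno, ins = "") {
  ins <- ifelse(is.na(ins) | ins == " ", "", ins)
  paste(chain, resno, ins, sep = ":")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
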