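# Generates the protein-block (PB) data files shipped under
# inst/extdata/pb/. Run from the package root:
#   Rscript data-raw/make_pb_data.R
#
# pb_prototypes.tsv           published PB reference dihedrals
# pb_transitions_synthetic.tsv  constructed from window-overlap geometry
# pb_propensities_synthetic.tsv constructed from Chou-Fasman class
#                               propensities + per-position conformation

# 16 protein blocks, 8 reference dihedrals each, spanning a 5-residue window:
# psi(n-2), phi(n-1), psi(n-1), phi(n), psi(n), phi(n+1), psi(n+1), phi(n+2).
# Values from the protein-blocks structural alphabet literature
# (de Brevern, Etchebest & Hazout 2000, Proteins 41:271-287).
prototypes <- matrix(c(
  41.14,   75.53,  13.92,  -99.80,  131.88,  -96.27, 122.08,  -99.68,
  108.24,  -90.12, 119.54,  -92.21,  -18.06, -128.93, 147.04,  -99.90,
  -11.61, -105.66,  94.81, -106.09,  133.56, -106.93, 135.97, -100.63,
  141.98, -112.79, 132.20, -114.79,  140.11, -111.05, 139.54, -103.16,
  133.25, -112.37, 137.64, -108.13,  133.00,  -87.30, 120.51,   77.28,
  116.40, -105.53, 129.32,  -96.68,  140.72,  -74.19, -26.65,  -94.51,
  0.40,  -81.83,   4.91, -100.59,   85.50,  -71.65, 130.78,   84.98,
  119.14, -102.58, 130.83,  -67.91,  121.55,   76.25,  -2.95,  -90.88,
  130.68,  -56.92, 119.26,   77.85,   10.42,  -99.43, 141.40,  -98.01,
  114.32, -121.47, 118.14,   82.88, -150.05,  -83.81,  23.35,  -85.82,
  117.16,  -95.41, 140.40,  -59.35,  -29.23,  -72.39, -25.08,  -76.16,
  139.20,  -55.96, -32.70,  -68.51,  -26.09,  -74.44, -22.60,  -71.74,
  -39.62,  -64.73, -39.52,  -65.54,  -38.88,  -66.89, -37.76,  -70.19,
  -35.34,  -65.03, -38.12,  -66.34,  -29.51,  -89.10,  -2.91,   77.90,
  -45.29,  -67.44, -27.72,  -87.27,    5.13,   77.49,  30.71,  -93.23,
  -27.09,  -86.14,   0.30,   59.85,   21.51,  -96.30, 132.67,  -92.91
), nrow = 16, byrow = TRUE,
dimnames = list(letters[1:16],
                c("psi_m2", "phi_m1", "psi_m1", "phi_0",
                  "psi_0", "phi_p1", "psi_p1", "phi_p2")))

wrap <- function(x) ((x + 180) %% 360) - 180
rmsda <- function(a, b) sqrt(mean(wrap(a - b)^2))

dir.create("inst/extdata/pb", recursive = TRUE, showWarnings = FALSE)

hdr1 <- c(
  "# Protein-block reference dihedral angles (degrees).",
  "# 16 blocks (a-p), each an 8-dihedral prototype over a 5-residue window:",
  "# psi(n-2) phi(n-1) psi(n-1) phi(n) psi(n) phi(n+1) psi(n+1) phi(n+2).",
  "# Source: the protein-blocks structural alphabet",
  "# (de Brevern, Etchebest & Hazout 2000, Proteins 41:271-287).")
proto_df <- data.frame(pb = rownames(prototypes), prototypes,
                       check.names = FALSE)
con <- file("inst/extdata/pb/pb_prototypes.tsv", "w")
writeLines(hdr1, con)
write.table(proto_df, con, sep = "\t", quote = FALSE, row.names = FALSE)
close(con)

# --- transitions -----------------------------------------------------------
# Consecutive PB windows overlap by four residues, so six of their reference
# dihedrals describe the same bonds: angles 3..8 of the first block must be
# compatible with angles 1..6 of the second. The synthetic transition weight
# is exp(-RMSDA_overlap / 30), zeroed beyond 80 degrees — a transition is
# possible only when the shared backbone stretch agrees geometrically.
w <- matrix(0, 16, 16, dimnames = list(letters[1:16], letters[1:16]))
for (i in 1:16) {
  for (j in 1:16) {
    r <- rmsda(prototypes[i, 3:8], prototypes[j, 1:6])
    w[i, j] <- if (r <= 80) round(exp(-r / 30), 4) else 0
  }
}
hdr2 <- c(
  "# SYNTHETIC protein-block transition weights (16 x 16, row = preceding",
  "# block, column = following block). Constructed deterministically from",
  "# the bundled prototypes: weight = exp(-RMSDA/30) over the 6 dihedrals",
  "# shared by overlapping windows, zeroed when RMSDA > 80 deg. A stand-in",
  "# for the published PB transition statistics, which are not redistributed",
  "# here; the algorithms only require a weighted 16 x 16 table.")
trans_df <- data.frame(pb = rownames(w), w, check.names = FALSE)
con <- file("inst/extdata/pb/pb_transitions_synthetic.tsv", "w")
writeLines(hdr2, con)
write.table(trans_df, con, sep = "\t", quote = FALSE, row.names = FALSE)
close(con)

# --- amino-acid propensities ----------------------------------------------
# Chou-Fasman conformational propensities (helix, sheet, turn).
aa <- c("A","C","D","E","F","G","H","I","K","L",
        "M","N","P","Q","R","S","T","V","W","Y")
p_helix <- c(1.42,0.70,1.01,1.51,1.13,0.57,1.00,1.08,1.16,1.21,
             1.45,0.67,0.57,1.11,0.98,0.77,0.83,1.06,1.08,0.69)
p_sheet <- c(0.83,1.19,0.54,0.37,1.38,0.75,0.87,1.60,0.74,1.30,
             1.05,0.89,0.55,1.10,0.93,0.75,1.19,1.70,1.37,1.47)
p_turn  <- c(0.66,1.19,1.46,0.74,0.60,1.56,0.95,0.47,1.01,0.59,
             0.60,1.56,1.52,0.98,0.95,1.43,0.96,0.50,0.96,1.14)

# (phi, psi) available at each window position from the prototype
pos_angles <- function(proto) {
  proto <- unname(proto)
  list(
    `1` = c(phi = NA, psi = proto[1]),
    `2` = c(phi = proto[2], psi = proto[3]),
    `3` = c(phi = proto[4], psi = proto[5]),
    `4` = c(phi = proto[6], psi = proto[7]),
    `5` = c(phi = proto[8], psi = NA))
}

gauss <- function(x, mu, s) exp(-0.5 * (wrap(x - mu) / s)^2)
class_weights <- function(ang) {
  # fuzzy membership of the local backbone state in the helix, extended and
  # turn/coil basins; missing angles use the marginal membership
  wb <- function(mu_phi, mu_psi, s) {
    g <- 1
    if (!is.na(ang["phi"])) g <- g * gauss(ang[["phi"]], mu_phi, s)
    if (!is.na(ang["psi"])) g <- g * gauss(ang[["psi"]], mu_psi, s)
    unname(g)
  }
  c(helix = wb(-63, -45, 45),
    sheet = wb(-120, 135, 55),
    turn = 0.15 + wb(60, 40, 60))
}

rows <- list()
for (pb in rownames(prototypes)) {
  pa <- pos_angles(prototypes[pb, ])
  for (pos in 1:5) {
    cw <- class_weights(pa[[pos]])
    cw <- cw / sum(cw)
    score <- cw["helix"] * p_helix + cw["sheet"] * p_sheet +
      cw["turn"] * p_turn
    rows[[length(rows) + 1]] <-
      data.frame(pb = pb, position = pos, aa = aa,
                 score = round(score, 4))
  }
}
prop_df <- do.call(rbind, rows)
hdr3 <- c(
  "# SYNTHETIC amino-acid propensities per (protein block, window position).",
  "# Constructed deterministically: each position's prototype (phi, psi) is",
  "# given fuzzy memberships in helix/extended/turn basins and the score is",
  "# the corresponding mixture of Chou-Fasman class propensities. A stand-in",
  "# for published per-position PB amino-acid statistics, which are not",
  "# redistributed here.")
con <- file("inst/extdata/pb/pb_propensities_synthetic.tsv", "w")
writeLines(hdr3, con)
write.table(prop_df, con, sep = "\t", quote = FALSE, row.names = FALSE)
close(con)

cat("wrote", nrow(prop_df), "propensity rows;",
    sum(w > 0), "allowed transitions of 256\n")
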