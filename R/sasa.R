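# Shrake-Rupley solvent-accessible surface area.
#
# Each atom is inflated by the probe radius and sampled with a fixed
# Fibonacci lattice of points; a point counts as accessible when it lies
# outside every neighbouring atom's inflated sphere. Deterministic by
# construction (no random sphere points).

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' @param xyz numeric matrix (n x 3) of atom coordinates in Angstroms.
#' @param elements character vector of element symbols (drives van der Waals
#'   radii; unknown elements fall back to 1.70 A).
#' @param probe_radius probe sphere radius in Angstroms.
#' @param n_points sphere sample points per atom.
#' @return numeric vector of per-atom SASA in square Angstroms.
#' @export
shrake_rupley <- function(xyz, elements, probe_radius = 1.4,
                          n_points = 960) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(n == length(elements), ncol(xyz) == 3)
  radii <- unname(VDW_RADII[toupper(elements)])
  radii[is.na(radii)] <- VDW_DEFAULT
  r_ext <- radii + probe_radius
  sphere <- fibonacci_sphere(n_points)
  out <- numeric(n)
  max_reach <- max(r_ext)
  for (i in seq_len(n)) {
    di <- sqrt((xyz[, 1] - xyz[i, 1])^2 +
                 (xyz[, 2] - xyz[i, 2])^2 +
                 (xyz[, 3] - xyz[i, 3])^2)
    nb <- which(di < r_ext[i] + max_reach & seq_len(n) != i)
    nb <- nb[di[nb] < r_ext[i] + r_ext[nb]]
    pts <- sweep(sphere * r_ext[i], 2, xyz[i, ], `+`)
    if (length(nb) == 0) {
      acc <- n_points
    } else {
      buried <- rep(FALSE, n_points)
      for (j in nb) {
        if (all(buried)) break
        idx <- which(!buried)
        d2 <- (pts[idx, 1] - xyz[j, 1])^2 +
          (pts[idx, 2] - xyz[j, 2])^2 +
          (pts[idx, 3] - xyz[j, 3])^2
        buried[idx[d2 < r_ext[j]^2]] <- TRUE
      }
      acc <- sum(!buried)
    }
    out[i] <- 4 * pi * r_ext[i]^2 * acc / n_points
  }
  out
}
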