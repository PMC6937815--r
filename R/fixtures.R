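# Deterministic synthetic structures and toy antigen-antibody complexes.
#
# Backbones are built from ideal internal coordinates (NeRF construction)
# driven by per-residue (phi, psi) templates, so protein-block encoding,
# SASA and all design methods can be exercised without any external file.

GEOMETRY_TEMPLATES <- list(
  helix = c(phi = -57, psi = -47),
  strand = c(phi = -120, psi = 135),
  pp2 = c(phi = -75, psi = 145)
)

# (phi, psi) basins sampled for "coil" geometry
COIL_BASINS <- matrix(c(
  -57, -47,
  -120, 135,
  -75, 145,
  -90, 0,
  60, 40
), ncol = 2, byrow = TRUE)

#' Backbone dihedral template for a fixture
#'
#' @param n_residues chain length.
#' @param geometry `"helix"`, `"strand"`, `"pp2"`, `"coil"` (random basins,
#'   seeded) or a two-column matrix/data frame of per-residue `(phi, psi)`.
#' @param seed integer seed used only for `"coil"`.
#' @return matrix with columns `phi`, `psi` (degrees), one row per residue.
#' @export
dihedral_template <- function(n_residues, geometry = "helix", seed = 1) {
  if (is.matrix(geometry) || is.data.frame(geometry)) {
    m <- as.matrix(geometry)
    stopifnot(nrow(m) == n_residues, ncol(m) == 2)
    colnames(m) <- c("phi", "psi")
    return(m)
  }
  if (geometry == "coil") {
    idx <- sample_with_seed(seed, nrow(COIL_BASINS), n_residues,
                            replace = TRUE)
    m <- COIL_BASINS[idx, , drop = FALSE]
    colnames(m) <- c("phi", "psi")
    return(m)
  }
  tpl <- GEOMETRY_TEMPLATES[[geometry]]
  if (is.null(tpl)) stop("unknown geometry: ", geometry)
  matrix(rep(tpl, each = n_residues), ncol = 2,
         dimnames = list(NULL, c("phi", "psi")))
}

# local, state-isolated random draw
sample_with_seed <- function(seed, n, size, replace = FALSE) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(n, size, replace = replace)
}

# Build ideal backbone coordinates (N, CA, C, O, CB) for one chain.
# Returns a list of per-residue matrices.
build_backbone <- function(dihedrals) {
  n <- nrow(dihedrals)
  phi <- dihedrals[, "phi"]
  psi <- dihedrals[, "psi"]
  res <- vector("list", n)
  # residue 1: place N, CA, then C using phi(1) against a virtual pre-atom
  N1 <- c(0, 0, 0)
  CA1 <- c(BOND_N_CA, 0, 0)
  virt <- c(-0.5, 1.2, 0) # stands in for C of a virtual preceding residue
  C1 <- place_atom(virt, N1, CA1, BOND_CA_C, ANGLE_N_CA_C, phi[1])
  res[[1]] <- rbind(N = N1, CA = CA1, C = C1)
  for (i in seq_len(n)[-1]) {
    p <- res[[i - 1]]
    Ni <- place_atom(p["N", ], p["CA", ], p["C", ], BOND_C_N,
                     ANGLE_CA_C_N, psi[i - 1])
    CAi <- place_atom(p["CA", ], p["C", ], Ni, BOND_N_CA,
                      ANGLE_C_N_CA, OMEGA_TRANS)
    Ci <- place_atom(p["C", ], Ni, CAi, BOND_CA_C, ANGLE_N_CA_C, phi[i])
    res[[i]] <- rbind(N = Ni, CA = CAi, C = Ci)
  }
  for (i in seq_len(n)) {
    p <- res[[i]]
    # carbonyl O in the peptide plane, trans to the next N
    O <- place_atom(p["N", ], p["CA", ], p["C", ], BOND_C_O,
                    ANGLE_CA_C_O, psi[i] + 180)
    # CB from the standard local frame of N, CA, C
    b <- p["CA", ] - p["N", ]
    cc <- p["C", ] - p["CA", ]
    a <- cross3(b, cc)
    CB <- -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + p["CA", ]
    res[[i]] <- rbind(p, O = O, CB = CB)
  }
  res
}

#' Build a synthetic single-chain structure
#'
#' Constructs an ideal-geometry backbone (N, CA, C, O and CB except for
#' glycine) from a dihedral template. Accessibility can be planted in two
#' ways: `mask` asserts the accessible flag directly (annotation, no
#' geometry), while `cage` surrounds the listed residues with a dense shell
#' of occluder pseudo-atoms (HETATM) so that geometric SASA computation finds
#' them buried.
#'
#' @param n_residues chain length.
#' @param geometry see [dihedral_template()].
#' @param sequence one-letter amino-acid string or vector (default
#'   poly-alanine).
#' @param chain chain identifier.
#' @param mask optional logical accessibility mask (length `n_residues`).
#' @param cage optional integer vector of residue indices to bury
#'   geometrically.
#' @param start_resno first residue number.
#' @param id structure label.
#' @param seed seed for `"coil"` geometry.
#' @return a `pep_structure` (accessibility annotated only if `mask` given).
#' @export
make_structure <- function(n_residues, geometry = "helix", sequence = NULL,
                           chain = "A", mask = NULL, cage = NULL,
                           start_resno = 1L, id = "fixture", seed = 1) {
  if (is.null(sequence)) {
    sequence <- rep("A", n_residues)
  } else if (length(sequence) == 1 && nchar(sequence[1]) > 1) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  stopifnot(length(sequence) == n_residues,
            all(sequence %in% AA1))
  dih <- dihedral_template(n_residues, geometry, seed = seed)
  bb <- build_backbone(dih)
  rows <- purrr::map2_dfr(seq_len(n_residues), bb, function(i, m) {
    ats <- rownames(m)
    if (sequence[i] == "G") {
      keep <- ats != "CB"
      m <- m[keep, , drop = FALSE]
      ats <- ats[keep]
    }
    tibble(chain = chain, resno = start_resno + i - 1L, ins = "",
           resid = unname(AA1TO3[sequence[i]]), aa = sequence[i],
           elety = ats, element = substr(ats, 1, 1),
           x = m[, 1], y = m[, 2], z = m[, 3])
  })
  het <- NULL
  if (!is.null(cage)) {
    het <- purrr::map_dfr(cage, function(i) {
      sel <- rows$resno == start_resno + i - 1L
      ctr <- colMeans(as.matrix(rows[sel, c("x", "y", "z")]))
      rmax <- max(sqrt(colSums((t(as.matrix(rows[sel, c("x", "y", "z")])) -
                                  ctr)^2)))
      radius <- rmax + 2.6
      npt <- ceiling(4 * pi * radius^2 / 1.3^2)
      sph <- fibonacci_sphere(npt) * radius
      tibble(chain = "Z", resno = 900L + i, ins = "",
             resid = "DUM", aa = NA_character_, elety = "C",
             element = "C",
             x = sph[, 1] + ctr[1], y = sph[, 2] + ctr[2],
             z = sph[, 3] + ctr[3])
    })
  }
  s <- new_pep_structure(rows, het = het, id = id, source = "synthetic")
  if (!is.null(mask)) {
    s <- set_accessibility(s, mask)
  }
  s
}

#' Build a toy antigen-antibody complex with planted contacts
#'
#' The antigen chain is built with [make_structure()]. Each planted contact
#' is realised by a single-glycine antibody "probe" residue placed outward
#' from the antigen so that the minimum atom distance between the probe and
#' the target antigen residue equals the requested distance (solved to
#' better than 0.01 A). Probe residues share one antibody chain but carry
#' non-consecutive residue numbers, so no peptide bond is implied between
#' them. The construction errors if a probe comes closer than `exclusion` to
#' any antigen residue that was not planted.
#'
#' @param n_ag antigen chain length.
#' @param contacts tibble/data frame with columns `ag_resno`, `dist`, and
#'   optionally `ab_resno` (defaults to 10, 20, 30, ...).
#' @param geometry,sequence,mask,seed passed to [make_structure()] for the
#'   antigen.
#' @param ag_chain,ab_chain chain identifiers.
#' @param exclusion minimum allowed probe distance to non-planted antigen
#'   residues (Angstroms).
#' @param strict error when a probe comes within `exclusion` of a
#'   non-planted residue. With `strict = FALSE` the construction is kept and
#'   the realised epitope is simply whatever [extract_epitope()] finds —
#'   as with a real crystal structure.
#' @param id complex label, also used as `complex_key`.
#' @return a `pep_complex`.
#' @export
make_complex <- function(n_ag, contacts, geometry = "strand",
                         sequence = NULL, mask = NULL,
                         ag_chain = "A", ab_chain = "B",
                         exclusion = 4.05, id = "complex", seed = 1,
                         strict = TRUE) {
  contacts <- as_tibble(contacts)
  stopifnot(all(c("ag_resno", "dist") %in% names(contacts)))
  if (!"ab_resno" %in% names(contacts)) {
    contacts$ab_resno <- 10L * seq_len(nrow(contacts))
  }
  ag <- make_structure(n_ag, geometry = geometry, sequence = sequence,
                       chain = ag_chain, mask = mask, id = id, seed = seed)
  ag_xyz <- as.matrix(ag$atoms[, c("x", "y", "z")])
  ag_ctr <- colMeans(ag_xyz)
  # template probe residue (glycine backbone) centred on its CA
  probe <- build_backbone(dihedral_template(1, "strand"))[[1]]
  probe <- probe[rownames(probe) != "CB", , drop = FALSE]
  probe <- sweep(probe, 2, probe["CA", ])
  probe_rows <- purrr::pmap_dfr(contacts, function(ag_resno, dist, ab_resno) {
    sel <- ag$atoms$resno == ag_resno & ag$atoms$chain == ag_chain
    if (!any(sel)) stop("planted contact on absent residue ", ag_resno)
    tgt <- as.matrix(ag$atoms[sel, c("x", "y", "z")])
    ctr <- colMeans(tgt)
    # approach along the side-chain direction, perpendicularised against the
    # local chain tangent so the probe does not graze sequence neighbours
    res_at <- ag$atoms[sel, ]
    ca_here <- as.numeric(res_at[res_at$elety == "CA", c("x", "y", "z")][1, ])
    cas <- ag$atoms[ag$atoms$elety == "CA" & ag$atoms$chain == ag_chain, ]
    i_ca <- which(cas$resno == ag_resno)
    lo <- max(1, i_ca - 1); hi <- min(nrow(cas), i_ca + 1)
    tangent <- as.numeric(cas[hi, c("x", "y", "z")]) -
      as.numeric(cas[lo, c("x", "y", "z")])
    tangent <- tangent / max(vec_norm(tangent), 1e-9)
    other_xyz <- as.matrix(ag$atoms[!sel, c("x", "y", "z")])
    # candidate approach directions (quasi-uniform, excluding those nearly
    # parallel to the chain); the probe's long axis is aligned radially and
    # the direction giving maximal clearance from all other residues wins
    cands <- fibonacci_sphere(42)
    cands <- cands[abs(cands %*% tangent) < 0.7, , drop = FALSE]
    axis0 <- probe["C", ] - probe["N", ]
    axis0 <- axis0 / vec_norm(axis0)
    place_along <- function(u) {
      v <- cross3(axis0, u)
      sv <- vec_norm(v)
      cs <- sum(axis0 * u)
      R <- if (sv < 1e-9 && cs > 0) {
        diag(3)
      } else if (sv < 1e-9) {
        p <- cross3(u, if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
        p <- p / vec_norm(p)
        2 * outer(p, p) - diag(3)
      } else {
        vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
        diag(3) + vx + vx %*% vx * ((1 - cs) / sv^2)
      }
      probe_o <- probe %*% t(R)
      f <- function(t) {
        min(proxy_min_dist(sweep(probe_o, 2, ctr + u * t, `+`), tgt)) - dist
      }
      root <- stats::uniroot(f, lower = dist - 2.5, upper = dist + 10,
                             tol = 1e-8, extendInt = "upX")$root
      # polish and bias the placement so the realised minimum distance sits
      # at, or an epsilon below, the planted value (inclusive cutoffs)
      for (k in 1:50) {
        m <- f(root)
        if (abs(m) < 1e-10) break
        root <- root + m * ifelse(m > 0, -1, -0.5)
      }
      if (f(root) > 0) root <- root - 5e-9
      pos <- sweep(probe_o, 2, ctr + u * root, `+`)
      rownames(pos) <- rownames(probe)
      pos
    }
    best_pos <- NULL
    best_clear <- -Inf
    for (ci in seq_len(nrow(cands))) {
      pos <- place_along(as.numeric(cands[ci, ]))
      clear <- min(proxy_min_dist(pos, other_xyz))
      if (clear > best_clear + 1e-9) {
        best_clear <- clear
        best_pos <- pos
      }
    }
    pos <- best_pos
    tibble(chain = ab_chain, resno = as.integer(ab_resno), ins = "",
           resid = "GLY", aa = "G", elety = rownames(probe),
           element = substr(rownames(probe), 1, 1),
           x = pos[, 1], y = pos[, 2], z = pos[, 3])
  })
  all_atoms <- bind_rows(ag$atoms |> select(-"key"), probe_rows)
  s <- new_pep_structure(all_atoms, het = ag$het, id = id,
                         source = "synthetic")
  if (!is.null(mask)) {
    full_mask <- c(mask, rep(TRUE, nrow(probe_rows) / nrow(probe)))
    s <- set_accessibility(s, full_mask)
  }
  cx <- new_pep_complex(s, ag_chains = ag_chain, ab_chains = ab_chain,
                        complex_key = id)
  # verify exclusion: probes must not graze non-planted antigen residues
  if (strict) {
    ep <- extract_epitope(cx, cutoff = exclusion)
    extra <- setdiff(ep$resno, contacts$ag_resno)
    if (length(extra) > 0) {
      stop("unrealizable contacts: probe grazes non-planted residue(s) ",
           paste(extra, collapse = ", "))
    }
  }
  cx
}

# minimum distances between two coordinate sets (rows = atoms)
proxy_min_dist <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    sqrt(min((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 +
               (b[, 3] - a[i, 3])^2))
  }, numeric(1))
}

#' Random benchmark antigen-antibody fixture
#'
#' Draws a synthetic antigen (mixed helix/strand/coil stretches, random
#' sequence, random accessibility mask with contiguous buried stretches) and
#' plants a discontinuous epitope of several segments on its surface,
#' mirroring the composition of crystallographic epitopes (a handful of
#' segments of one to a few residues each). Fully determined by `seed`.
#'
#' @param seed integer seed.
#' @param n_residues antigen length (default drawn from 30-50).
#' @return a `pep_complex` whose antigen carries an asserted accessibility
#'   mask.
#' @export
make_benchmark_complex <- function(seed, n_residues = NULL) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  n <- n_residues %||% sample(30:50, 1)
  # mixed secondary structure stretches
  dih <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("phi", "psi")))
  i <- 1
  while (i <= n) {
    len <- min(sample(4:10, 1), n - i + 1)
    tpl <- GEOMETRY_TEMPLATES[[sample(names(GEOMETRY_TEMPLATES), 1)]]
    dih[i:(i + len - 1), ] <- matrix(rep(tpl, each = len), ncol = 2)
    i <- i + len
  }
  sequence <- sample(AA1, n, replace = TRUE)
  # accessibility mask: mostly accessible with a few buried stretches
  mask <- rep(TRUE, n)
  n_buried <- sample(2:4, 1)
  for (k in seq_len(n_buried)) {
    st <- sample(seq_len(n - 2), 1)
    mask[st:min(n, st + sample(1:3, 1))] <- FALSE
  }
  # planted epitope: 2-5 segments of 1-4 accessible residues
  acc_idx <- which(mask)
  n_seg <- sample(2:5, 1)
  starts <- sort(sample(acc_idx, n_seg))
  ep_res <- unique(unlist(lapply(starts, function(s) {
    run <- s:min(n, s + sample(0:3, 1))
    run[mask[run]]
  })))
  contacts <- tibble(ag_resno = ep_res,
                     dist = stats::runif(length(ep_res), 3.2, 3.95))
  make_complex(n_ag = n, contacts = contacts, geometry = dih,
               sequence = sequence, mask = mask, strict = FALSE,
               id = sprintf("synth%04d", seed), seed = seed)
}
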