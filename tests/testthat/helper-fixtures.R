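# Shared test helpers: hand-built structures, brute-force oracles.

# structure from explicit atom placements; `spec` is a data frame with
# chain, resno, aa, elety, x, y, z (one row per atom)
make_point_structure <- function(spec, id = "points", accessible = TRUE) {
  spec$ins <- ""
  spec$resid <- unname(setNames(names(pepmimic:::AA3TO1)[1:20],
                                pepmimic:::AA3TO1[1:20])[spec$aa])
  spec$element <- substr(spec$elety, 1, 1)
  s <- new_pep_structure(spec, id = id)
  mask <- if (length(accessible) == 1) {
    rep(accessible, nrow(s$residues))
  } else {
    accessible
  }
  set_accessibility(s, mask)
}

# one CA-only residue per row of (x, y, z)
ca_structure <- function(xyz, aa = "A", chain = "A", id = "ca") {
  n <- nrow(xyz)
  spec <- data.frame(chain = chain, resno = seq_len(n),
                     aa = rep(aa, length.out = n), elety = "CA",
                     x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  make_point_structure(spec, id = id)
}

# segment tibble with singleton point segments (for optimizer oracles)
point_segments <- function(pts) {
  tibble::tibble(
    segment_id = seq_len(nrow(pts)),
    chain = "A",
    keys = lapply(seq_len(nrow(pts)), function(i) sprintf("A:%d:", i)),
    resnos = lapply(seq_len(nrow(pts)), identity),
    sequence = "A",
    length = 1L,
    cog = lapply(seq_len(nrow(pts)), function(i) as.numeric(pts[i, ])),
    nterm_ca = lapply(seq_len(nrow(pts)), function(i) as.numeric(pts[i, ])),
    cterm_ca = lapply(seq_len(nrow(pts)), function(i) as.numeric(pts[i, ])),
    nterm_n = lapply(seq_len(nrow(pts)), function(i) as.numeric(pts[i, ])),
    cterm_c = lapply(seq_len(nrow(pts)), function(i) as.numeric(pts[i, ]))
  )
}

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

# brute-force minimum open-path cost over a distance matrix
brute_force_path_cost <- function(D) {
  n <- nrow(D)
  p <- perms(n)
  costs <- rep(0, nrow(p))
  for (k in seq_len(n - 1)) {
    costs <- costs + D[cbind(p[, k], p[, k + 1])]
  }
  min(costs)
}

# independent multiset-overlap oracle: iterative removal
multiset_overlap <- function(a, b) {
  tp <- 0L
  for (x in a) {
    hit <- match(x, b)
    if (!is.na(hit)) {
      tp <- tp + 1L
      b <- b[-hit]
    }
  }
  tp
}

# epitope-like tibble from amino-acid letters (keys synthesised)
toy_epitope <- function(aa, keys = NULL) {
  tibble::tibble(
    key = keys %||% sprintf("A:%d:", seq_along(aa)),
    chain = "A", resno = seq_along(aa), ins = "",
    aa = aa, min_dist = 3.5, segment = seq_along(aa)
  )
}

# rigid-body transform of a structure (rotation matrix + translation)
transform_structure <- function(structure, R = diag(3), t = c(0, 0, 0)) {
  rot <- function(d) {
    m <- as.matrix(d[, c("x", "y", "z")]) %*% t(R)
    d$x <- m[, 1] + t[1]
    d$y <- m[, 2] + t[2]
    d$z <- m[, 3] + t[3]
    d
  }
  structure$atoms <- rot(structure$atoms)
  if (nrow(structure$het) > 0) structure$het <- rot(structure$het)
  structure
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
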