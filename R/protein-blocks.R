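# Protein blocks (PB): a 16-letter structural alphabet of 5-residue backbone
# prototypes. Used to encode segment backbones and to choose linker amino
# acids in the SA/SAS design methods.

pb_env <- new.env(parent = emptyenv())

read_pb_tsv <- function(name) {
  path <- system.file("extdata", "pb", name, package = "pepmimic")
  if (path == "") {
    # during development (load_all) fall back to the source tree
    path <- file.path("inst", "extdata", "pb", name)
  }
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Protein-block prototype library
#'
#' @return matrix 16 x 8 of reference dihedrals (degrees); rows are PB labels
#'   `a`-`p`, columns the window dihedrals psi(n-2), phi(n-1), psi(n-1),
#'   phi(n), psi(n), phi(n+1), psi(n+1), phi(n+2).
#' @export
pb_prototypes <- function() {
  if (is.null(pb_env$proto)) {
    d <- read_pb_tsv("pb_prototypes.tsv")
    m <- as.matrix(d[, -1])
    rownames(m) <- d$pb
    stopifnot(nrow(m) == 16, ncol(m) == 8)
    pb_env$proto <- m
  }
  pb_env$proto
}

#' Protein-block transition weight table
#'
#' @return matrix 16 x 16; `[i, j]` is the weight of block i being followed
#'   by block j. The bundled table is synthetic (derived from window-overlap
#'   geometry of the prototypes; see the data file header).
#' @export
pb_transitions <- function() {
  if (is.null(pb_env$trans)) {
    d <- read_pb_tsv("pb_transitions_synthetic.tsv")
    m <- as.matrix(d[, -1])
    rownames(m) <- d$pb
    stopifnot(nrow(m) == 16, ncol(m) == 16)
    pb_env$trans <- m
  }
  pb_env$trans
}

#' Amino-acid propensities per protein block and window position
#'
#' @return tibble with columns `pb`, `position` (1-5), `aa`, `score`.
#' @export
pb_propensities <- function() {
  if (is.null(pb_env$prop)) {
    pb_env$prop <- read_pb_tsv("pb_propensities_synthetic.tsv")
  }
  pb_env$prop
}

# RMSDA: root-mean-square deviation over dihedral differences with angular
# wrap-around; NA positions are dropped symmetrically.
rmsda <- function(a, b) {
  d <- wrap_angle(a - b)
  sqrt(mean(d^2, na.rm = TRUE))
}

# phi/psi table for an ordered run of residues (by key) of one chain
backbone_dihedrals <- function(structure, keys) {
  at <- structure$atoms
  get3 <- function(k, e) {
    m <- at[at$key == k & at$elety == e, c("x", "y", "z")]
    if (nrow(m) == 0) return(NULL)
    as.numeric(m[1, ])
  }
  n <- length(keys)
  phi <- rep(NA_real_, n)
  psi <- rep(NA_real_, n)
  bb <- lapply(keys, function(k) {
    list(N = get3(k, "N"), CA = get3(k, "CA"), C = get3(k, "C"))
  })
  for (i in seq_len(n)) {
    b <- bb[[i]]
    if (any(vapply(b, is.null, logical(1)))) next
    if (i > 1 && !is.null(bb[[i - 1]]$C)) {
      phi[i] <- dihedral4(bb[[i - 1]]$C, b$N, b$CA, b$C)
    }
    if (i < n && !is.null(bb[[i + 1]]$N)) {
      psi[i] <- dihedral4(b$N, b$CA, b$C, bb[[i + 1]]$N)
    }
  }
  tibble(key = keys, phi = phi, psi = psi)
}

#' Encode a residue run into protein blocks
#'
#' Assigns one PB letter per residue by sliding a 5-residue window along the
#' run and picking the prototype with minimal RMSDA (root-mean-square
#' angular deviation over the window's 8 dihedrals, with wrap-around).
#' Residues whose window is incomplete (the two at each end, or any window
#' touching a missing backbone atom) are left unassigned (`NA`).
#'
#' @param structure a `pep_structure`.
#' @param keys ordered residue keys (N to C) of one chain; defaults to all
#'   residues of the structure's first chain.
#' @return character vector of PB labels (with `NA` for unassignable
#'   positions), one per residue in `keys`.
#' @export
encode_pb <- function(structure, keys = NULL) {
  stopifnot(inherits(structure, "pep_structure"))
  if (is.null(keys)) {
    res <- structure$residues
    keys <- res$key[res$chain == res$chain[1]]
  }
  n <- length(keys)
  if (n < 5) {
    warning("fewer than 5 residues; empty PB encoding")
    return(rep(NA_character_, n))
  }
  dih <- backbone_dihedrals(structure, keys)
  proto <- pb_prototypes()
  out <- rep(NA_character_, n)
  for (i in 3:(n - 2)) {
    win <- c(dih$psi[i - 2], dih$phi[i - 1], dih$psi[i - 1],
             dih$phi[i], dih$psi[i],
             dih$phi[i + 1], dih$psi[i + 1], dih$phi[i + 2])
    if (any(is.na(win))) next
    dev <- apply(proto, 1, function(p) rmsda(win, p))
    out[i] <- names(which.min(dev))
  }
  out
}

#' Is a protein-block transition allowed?
#'
#' @param pb1,pb2 PB labels (`a`-`p`).
#' @param matrix transition weight table; defaults to the bundled one.
#' @param threshold minimal weight counting as allowed. The default demands
#'   a strictly positive weight.
#' @return logical.
#' @export
allowed_transition <- function(pb1, pb2, matrix = pb_transitions(),
                               threshold = NULL) {
  check_pb_label(pb1, matrix)
  check_pb_label(pb2, matrix)
  thr <- threshold %||% .Machine$double.xmin
  matrix[pb1, pb2] >= thr
}

check_pb_label <- function(pb, matrix = pb_transitions()) {
  if (!is.character(pb) || length(pb) != 1 || !(pb %in% rownames(matrix))) {
    stop("unknown protein-block label: ", paste(pb, collapse = ","))
  }
  invisible(pb)
}

#' Best protein-block insertion bridging two blocks
#'
#' If the transition `pb_end -> pb_start` is already allowed, no insertion
#' is needed. Otherwise the single block x maximising
#' `min(weight(end -> x), weight(x -> start))` is returned provided it makes
#' both hops allowed; failing that, the best pair (x, y) by the same
#' criterion over all three hops. If no one- or two-block bridge exists the
#' peptide junction is not realisable.
#'
#' @inheritParams allowed_transition
#' @param pb_end last PB of the preceding segment.
#' @param pb_start first PB of the following segment.
#' @param max_insert maximum number of inserted blocks (1 or 2).
#' @return character vector of 0-2 PB labels, or `NULL` when no bridge
#'   exists (the caller should flag the peptide as not possible).
#' @export
best_linker_pbs <- function(pb_end, pb_start, max_insert = 2,
                            matrix = pb_transitions(), threshold = NULL) {
  thr <- threshold %||% .Machine$double.xmin
  check_pb_label(pb_end, matrix)
  check_pb_label(pb_start, matrix)
  if (matrix[pb_end, pb_start] >= thr) {
    return(character(0))
  }
  labels <- rownames(matrix)
  # single insertion
  w1 <- pmin(matrix[pb_end, ], matrix[, pb_start])
  names(w1) <- labels
  if (max(w1) >= thr) {
    return(names(which.max(w1)))
  }
  if (max_insert < 2) {
    return(NULL)
  }
  # double insertion: bottleneck weight over the three hops
  best <- NULL
  best_w <- -Inf
  for (x in labels) {
    for (y in labels) {
      w <- min(matrix[pb_end, x], matrix[x, y], matrix[y, pb_start])
      if (w >= thr && w > best_w) {
        best_w <- w
        best <- c(x, y)
      }
    }
  }
  best
}

#' Preferred amino acid of a protein block position
#'
#' @param pb PB label.
#' @param position window position 1-5.
#' @param propensities propensity table; defaults to the bundled one.
#' @return single one-letter amino-acid code (arg-max score; ties broken
#'   alphabetically).
#' @export
pb_preferred_aa <- function(pb, position = 3, propensities = pb_propensities()) {
  stopifnot(position %in% 1:5)
  d <- propensities[propensities$pb == pb &
                      propensities$position == position, ]
  if (nrow(d) == 0) {
    stop("unknown protein-block label: ", pb)
  }
  d <- d[order(d$aa), ]
  d$aa[which.max(d$score)]
}
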