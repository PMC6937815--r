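# Graph-based design methods: shortest-path (SHP) and travelling-salesman
# (TSP) peptides over segment or residue graphs.

#' Build a design graph over segments or accessible residues
#'
#' Three graph flavours, all weighted by Euclidean distances:
#' * `"natural"` — directed graph over segments; an edge i -> j is weighted
#'   by the distance from i's C-terminal CA to j's N-terminal CA, so paths
#'   traverse segments in natural (N to C) sense only.
#' * `"reversed"` — undirected segment graph; edge weight is the minimum
#'   over the four N/C terminus pairings.
#' * `"aa"` — undirected graph over accessible residues, CA-CA distances.
#'
#' `cutoff` limits edges to element pairs closer than the given distance;
#' the default `Inf` yields the complete graph (used by TSP methods), while
#' shortest-path methods need a sparse neighbour graph to produce paths
#' through intermediate elements.
#'
#' @param structure the annotated `pep_structure`.
#' @param segments a [build_segments()] tibble (ignored for `mode = "aa"`).
#' @param mode `"natural"`, `"reversed"` or `"aa"`.
#' @param cutoff edge inclusion threshold in Angstroms.
#' @return an igraph graph whose vertex names are segment ids or residue
#'   keys.
#' @export
build_design_graph <- function(structure, segments = NULL,
                               mode = c("natural", "reversed", "aa"),
                               cutoff = Inf) {
  mode <- match.arg(mode)
  if (mode == "aa") {
    res <- structure$residues
    acc <- res[which(res$accessible), ]
    at <- structure$atoms
    ca <- do.call(rbind, lapply(acc$key, function(k) atom_coord(at, k, "CA")))
    D <- as.matrix(dist(ca))
    dimnames(D) <- list(acc$key, acc$key)
    A <- D
    A[D > cutoff] <- 0
    diag(A) <- 0
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE)
    return(g)
  }
  stopifnot(!is.null(segments), nrow(segments) >= 1)
  n <- nrow(segments)
  ids <- as.character(segments$segment_id)
  cterm <- do.call(rbind, segments$cterm_ca)
  nterm <- do.call(rbind, segments$nterm_ca)
  if (mode == "natural") {
    # D[i, j] = C-terminus of i to N-terminus of j
    D <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
      euclid(cterm[i, ], nterm[j, ])
    }))
  } else {
    D <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        D[i, j] <- min(
          euclid(nterm[i, ], nterm[j, ]), euclid(nterm[i, ], cterm[j, ]),
          euclid(cterm[i, ], nterm[j, ]), euclid(cterm[i, ], cterm[j, ])
        )
      }
    }
  }
  dimnames(D) <- list(ids, ids)
  A <- D
  A[D > cutoff] <- 0
  diag(A) <- 0
  igraph::graph_from_adjacency_matrix(
    A, mode = if (mode == "natural") "directed" else "undirected",
    weighted = TRUE)
}

# total aa carried by a vector of element names
elements_aa <- function(elements, segments = NULL) {
  if (is.null(segments)) {
    length(elements) # aa graph: one residue per element
  } else {
    sum(segments$length[match(as.numeric(elements), segments$segment_id)])
  }
}

#' Shortest-path peptide design (SHPnat, SHPrev, SHPaa)
#'
#' Over all pairs of area members, computes the shortest path in the
#' area-induced subgraph and keeps the path covering the most amino acids
#' (ties: smaller total distance, then lexicographic element ids). The
#' requested length plays no role: the peptide length is determined by the
#' winning path.
#'
#' @param method `"SHPnat"`, `"SHPrev"` or `"SHPaa"`.
#' @param area one row of a surface-area tibble (cluster or patch); members
#'   are segment ids for nat/rev, residue keys for aa.
#' @param graph the matching [build_design_graph()] graph (sparse).
#' @param segments the segment tibble (nat/rev modes).
#' @param structure the annotated structure (aa mode).
#' @return a one-row designed-peptide tibble, or `NULL` when no pair of
#'   members is connected.
#' @export
design_shp <- function(method = c("SHPnat", "SHPrev", "SHPaa"), area, graph,
                       segments = NULL, structure = NULL) {
  method <- match.arg(method)
  aa_mode <- method == "SHPaa"
  members <- area$members[[1]]
  members <- as.character(members)
  members <- intersect(members, igraph::V(graph)$name)
  if (length(members) == 0) return(NULL)
  sub <- igraph::induced_subgraph(graph, members)
  if (length(members) == 1) {
    best_path <- members
  } else {
    best_path <- NULL
    best_naa <- -Inf
    best_dist <- Inf
    for (from in members) {
      sp <- suppressWarnings(
        igraph::shortest_paths(sub, from = from, to = members,
                               mode = "out", output = "vpath"))
      for (vp in sp$vpath) {
        nodes <- names(vp)
        if (length(nodes) < 2) next
        d <- igraph::distances(
          sub, v = nodes[1], to = nodes[length(nodes)],
          mode = "out")[1, 1]
        naa <- elements_aa(nodes, if (aa_mode) NULL else segments)
        better <- naa > best_naa ||
          (naa == best_naa && d < best_dist - 1e-12) ||
          (naa == best_naa && abs(d - best_dist) <= 1e-12 &&
             !is.null(best_path) &&
             paste(nodes, collapse = ",") < paste(best_path, collapse = ","))
        if (better) {
          best_path <- nodes
          best_naa <- naa
          best_dist <- d
        }
      }
    }
    if (is.null(best_path)) best_path <- members[1]
  }
  path_to_peptide(method, area, best_path,
                  segments = if (aa_mode) NULL else segments,
                  structure = structure, requested_length = NA)
}

# build a designed-peptide row from an ordered element path
path_to_peptide <- function(method, area, path, segments = NULL,
                            structure = NULL, requested_length = NA,
                            distance = NA_real_) {
  if (is.null(segments)) {
    res <- structure$residues
    aa_by_key <- setNames(res$aa, res$key)
    pos <- tibble(pos = seq_along(path), aa = unname(aa_by_key[path]),
                  source_key = path, origin = "residue",
                  segment_id = NA_integer_)
    su <- tibble(segment_id = integer(0), orientation = character(0))
  } else {
    ids <- as.numeric(path)
    pos <- assemble_positions(segments, ids, rep("natural", length(ids)))
    su <- tibble(segment_id = ids,
                 orientation = rep("natural", length(ids)))
  }
  new_peptide(method, area$area_id, requested_length, su, pos,
              path_distance = distance)
}

#' Travelling-salesman peptide design (TSPnat1-4, TSPrev1-4, TSPaa)
#'
#' Solves the open-path TSP over the area members, slides along the optimal
#' path enumerating every contiguous run whose amino-acid count first
#' reaches the requested length, and picks the final run by the variant
#' rule: highest segment score (1), shortest traveled distance (2),
#' shortest distance per segment (3), containing the area's two closest
#' members (4); TSPaa uses the shortest traveled distance. If the whole
#' area holds fewer amino acids than requested, the full path is returned
#' flagged `"short"`.
#'
#' @param method one of `"TSPnat1"`-`"TSPnat4"`, `"TSPrev1"`-`"TSPrev4"`,
#'   `"TSPaa"`.
#' @param area one row of a surface-area tibble.
#' @param requested_length requested peptide length (amino acids).
#' @param segments segment tibble (nat/rev variants).
#' @param structure annotated structure (needed for `"TSPaa"` and for the
#'   score used by variant 1).
#' @param turns optional precomputed turn flags for variant-1 scoring.
#' @param exact_limit see [solve_tsp_path()].
#' @return a one-row designed-peptide tibble.
#' @export
design_tsp <- function(method, area, requested_length, segments = NULL,
                       structure = NULL, turns = NULL, exact_limit = 12) {
  stopifnot(method %in% c(paste0("TSPnat", 1:4), paste0("TSPrev", 1:4),
                          "TSPaa"))
  aa_mode <- method == "TSPaa"
  variant <- if (aa_mode) "dist" else substr(method, 7, 7)
  members <- sort(as.character(area$members[[1]]))
  m <- length(members)
  D <- tsp_distance_matrix(method, members, segments, structure)
  ord <- solve_tsp_path(D, exact_limit = exact_limit)
  path <- members[ord]
  aa_counts <- if (aa_mode) {
    rep(1L, m)
  } else {
    segments$length[match(as.numeric(path), segments$segment_id)]
  }
  Dsym <- pmin(D, t(D))
  # enumerate candidate runs: from each start, the shortest run reaching
  # the requested length
  runs <- list()
  for (s in seq_len(m)) {
    tot <- cumsum(aa_counts[s:m])
    e_rel <- which(tot >= requested_length)
    if (length(e_rel) == 0) next
    e <- s + e_rel[1] - 1
    runs[[length(runs) + 1]] <- s:e
  }
  status <- "ok"
  if (length(runs) == 0) {
    runs <- list(seq_len(m))
    status <- "short"
  }
  run_dist <- vapply(runs, function(r) path_cost(D[ord, ord, drop = FALSE], r),
                     numeric(1))
  pick <- switch(
    variant,
    "1" = {
      scores <- vapply(runs, function(r) {
        pep <- path_to_peptide(method, area, path[r], segments = segments,
                               structure = structure)
        score_peptide(pep, structure, turns = turns)$score
      }, numeric(1))
      pick_run(runs, path, -scores, run_dist)
    },
    "2" = pick_run(runs, path, run_dist, run_dist),
    "3" = pick_run(runs, path, run_dist / lengths(runs), run_dist),
    "4" = {
      # the run must contain the two closest members of the area
      closest <- closest_pair(Dsym, members)
      has <- vapply(runs, function(r) all(closest %in% path[r]), logical(1))
      cand <- if (any(has)) runs[has] else runs
      cand_dist <- run_dist[if (any(has)) has else rep(TRUE, length(runs))]
      pick_run(cand, path, cand_dist, cand_dist)
    },
    "dist" = pick_run(runs, path, run_dist, run_dist)
  )
  r <- pick$run
  pep <- path_to_peptide(method, area, path[r],
                         segments = if (aa_mode) NULL else segments,
                         structure = structure,
                         requested_length = requested_length,
                         distance = pick$dist)
  pep$status <- status
  pep
}

tsp_distance_matrix <- function(method, members, segments, structure) {
  if (method == "TSPaa") {
    at <- structure$atoms
    ca <- do.call(rbind, lapply(members, function(k) atom_coord(at, k, "CA")))
    D <- as.matrix(dist(ca))
  } else if (startsWith(method, "TSPnat")) {
    sub <- segments[match(as.numeric(members), segments$segment_id), ]
    n <- nrow(sub)
    D <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j) D[i, j] <- euclid(sub$cterm_ca[[i]], sub$nterm_ca[[j]])
      }
    }
  } else {
    sub <- segments[match(as.numeric(members), segments$segment_id), ]
    n <- nrow(sub)
    D <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j) {
          D[i, j] <- min(
            euclid(sub$nterm_ca[[i]], sub$nterm_ca[[j]]),
            euclid(sub$nterm_ca[[i]], sub$cterm_ca[[j]]),
            euclid(sub$cterm_ca[[i]], sub$nterm_ca[[j]]),
            euclid(sub$cterm_ca[[i]], sub$cterm_ca[[j]]))
        }
      }
    }
  }
  dimnames(D) <- list(members, members)
  D
}

closest_pair <- function(Dsym, members) {
  if (length(members) < 2) return(members)
  diag(Dsym) <- Inf
  i <- which(Dsym == min(Dsym), arr.ind = TRUE)[1, ]
  sort(c(members[i[1]], members[i[2]]))
}

# deterministic run selection: minimise `criterion`, ties by smaller
# distance, then lexicographic element ids
pick_run <- function(runs, path, criterion, run_dist) {
  keys <- vapply(runs, function(r) paste(path[r], collapse = ","),
                 character(1))
  ord <- order(criterion, run_dist, keys)
  list(run = runs[[ord[1]]], dist = run_dist[ord[1]])
}
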