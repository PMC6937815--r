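# Whole-surface peptide banks: every segment (or accessible residue patch /
# cluster) of the antigen is used in turn as a design reference.

#' The 34 discontinuous-epitope design methods
#'
#' @return tibble with columns `method`, `family` (`prime`, `linker`,
#'   `graph`), `prime_base` (the underlying prime method for linker
#'   variants), `linker` (`ALA`/`SA`/`SAS` or NA) and `graph_kind`
#'   (`segment`/`aa` or NA).
#' @export
pepmimic_methods <- function() {
  prime <- c("NN", "uNN", "FN", "ONN", "OFN", "OPP")
  ala <- c("NN", "uNN", "ONN", "FN", "OFN", "OPP")
  sa <- c("NN", "ONN", "FN", "OFN", "OPP")
  bind_rows(
    tibble(method = prime, family = "prime", prime_base = prime,
           linker = NA_character_, graph_kind = NA_character_),
    tibble(method = paste0(ala, "ala"), family = "linker", prime_base = ala,
           linker = "ALA", graph_kind = NA_character_),
    tibble(method = paste0(sa, "sa"), family = "linker", prime_base = sa,
           linker = "SA", graph_kind = NA_character_),
    tibble(method = paste0(sa, "sas"), family = "linker", prime_base = sa,
           linker = "SAS", graph_kind = NA_character_),
    tibble(method = c("SHPnat", "SHPrev", "SHPaa"), family = "graph",
           prime_base = NA_character_, linker = NA_character_,
           graph_kind = c("segment", "segment", "aa")),
    tibble(method = c(paste0("TSPnat", 1:4), paste0("TSPrev", 1:4), "TSPaa"),
           family = "graph", prime_base = NA_character_,
           linker = NA_character_,
           graph_kind = c(rep("segment", 8), "aa"))
  )
}

#' Default requested peptide length of a method
#'
#' Prime and linker methods default to 12 amino acids, graph-based methods
#' to 16, matching the lengths that bring the average final peptide close to
#' the typical size of a discontinuous epitope.
#'
#' @param method method name.
#' @return integer length.
#' @export
default_requested_length <- function(method) {
  reg <- pepmimic_methods()
  fam <- reg$family[match(method, reg$method)]
  ifelse(fam == "graph", 16L, 12L)
}

#' Precompute the surface model of an antigen
#'
#' Bundles everything the design methods share: segments, clusters, 10/15 A
#' patches, varying patches, turn flags and per-residue protein-block
#' labels.
#'
#' @param structure an accessibility-annotated `pep_structure`.
#' @param cluster_cutoff see [build_clusters()].
#' @param shp_cutoff_segment,shp_cutoff_aa edge cutoffs of the sparse
#'   shortest-path graphs (Angstroms).
#' @return a list used by [generate_peptide_bank()].
#' @export
surface_model <- function(structure, cluster_cutoff = 20,
                          shp_cutoff_segment = 20, shp_cutoff_aa = 8) {
  segments <- build_segments(structure)
  if (nrow(segments) == 0) {
    stop("structure has no accessible segment")
  }
  list(
    structure = structure,
    segments = segments,
    clusters = build_clusters(segments, cutoff = cluster_cutoff),
    patch10 = build_patches(segments, 10),
    patch15 = build_patches(segments, 15),
    vpatches = build_varying_patches(structure),
    turns = assign_turns(structure),
    pb_cache = pb_labels_by_key(structure),
    shp_graphs = list(
      natural = build_design_graph(structure, segments, "natural",
                                   cutoff = shp_cutoff_segment),
      reversed = build_design_graph(structure, segments, "reversed",
                                    cutoff = shp_cutoff_segment),
      aa = build_design_graph(structure, mode = "aa", cutoff = shp_cutoff_aa)
    )
  )
}

# cluster areas recast as residue-key areas for the aa-graph methods
cluster_as_aa_area <- function(cluster, segments) {
  keys <- unlist(lapply(cluster$members[[1]], function(id) {
    segments$keys[[which(segments$segment_id == id)]]
  }))
  tibble(area_id = cluster$area_id, kind = "cluster_aa",
         reference = cluster$reference, members = list(keys),
         n_aa = length(keys))
}

#' Generate a whole-surface peptide bank
#'
#' Runs one or more design methods with every admissible reference on the
#' antigen: each segment for prime/linker methods, each cluster and 15 A
#' patch for segment-graph methods, each cluster and varying patch for
#' aa-graph methods. Within a method, duplicate peptide sequences are
#' removed (first occurrence kept) and peptides whose structural-alphabet
#' linker failed are dropped.
#'
#' @param structure an accessibility-annotated `pep_structure`.
#' @param methods character vector of method names (default: all 34).
#' @param requested_length requested length in amino acids; `NULL` uses each
#'   method's default (12 prime/linker, 16 graph).
#' @param model optional precomputed [surface_model()].
#' @param score score every peptide (adds the `score` column values).
#' @return a tibble of designed peptides (one row each) with an `antigen`
#'   column.
#' @export
generate_peptide_bank <- function(structure,
                                  methods = pepmimic_methods()$method,
                                  requested_length = NULL, model = NULL,
                                  score = TRUE) {
  reg <- pepmimic_methods()
  bad <- setdiff(methods, reg$method)
  if (length(bad) > 0) {
    stop("unknown method(s): ", paste(bad, collapse = ", "))
  }
  model <- model %||% surface_model(structure)
  out <- purrr::map_dfr(methods, function(m) {
    generate_method_bank(m, model, requested_length, score = score)
  })
  out$antigen <- structure$id
  out
}

generate_method_bank <- function(method, model, requested_length = NULL,
                                 score = TRUE) {
  reg <- pepmimic_methods()
  info <- reg[reg$method == method, ]
  L <- requested_length %||% default_requested_length(method)
  segments <- model$segments
  structure <- model$structure
  peps <- if (info$family %in% c("prime", "linker")) {
    purrr::map_dfr(segments$segment_id, function(ref) {
      base <- switch(info$prime_base,
        NN = design_nn(segments, ref, L),
        uNN = design_unn(segments, ref, L),
        FN = design_fn(segments, ref, L),
        ONN = design_optimized(segments, ref, L, "ONN"),
        OFN = design_optimized(segments, ref, L, "OFN"),
        OPP = design_optimized(segments, ref, L, "OPP",
                               patches = model$patch10)
      )
      if (info$family == "linker") {
        add_linkers(base, info$linker, structure, segments,
                    pb_cache = model$pb_cache)
      } else {
        base
      }
    })
  } else if (info$graph_kind == "segment") {
    areas <- bind_rows(model$clusters, model$patch15)
    purrr::map_dfr(seq_len(nrow(areas)), function(i) {
      a <- areas[i, ]
      if (startsWith(method, "SHP")) {
        g <- model$shp_graphs[[if (method == "SHPnat") "natural" else "reversed"]]
        design_shp(method, a, g, segments = segments,
                   structure = structure) %||% tibble()
      } else {
        design_tsp(method, a, L, segments = segments,
                   structure = structure, turns = model$turns)
      }
    })
  } else {
    clusters_aa <- purrr::map_dfr(seq_len(nrow(model$clusters)), function(i) {
      cluster_as_aa_area(model$clusters[i, ], segments)
    })
    areas <- bind_rows(clusters_aa, model$vpatches)
    purrr::map_dfr(seq_len(nrow(areas)), function(i) {
      a <- areas[i, ]
      if (method == "SHPaa") {
        design_shp("SHPaa", a, model$shp_graphs$aa,
                   structure = structure) %||% tibble()
      } else {
        design_tsp("TSPaa", a, L, structure = structure)
      }
    })
  }
  if (nrow(peps) == 0) {
    return(peps)
  }
  peps <- peps[peps$status != "not_possible", , drop = FALSE]
  peps <- peps[!duplicated(peps$sequence), , drop = FALSE]
  if (score && nrow(peps) > 0) {
    peps <- purrr::map_dfr(seq_len(nrow(peps)), function(i) {
      if (nrow(peps$segments_used[[i]]) > 0) {
        score_peptide(peps[i, ], structure, turns = model$turns)
      } else {
        peps[i, ]
      }
    })
  }
  peps
}
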