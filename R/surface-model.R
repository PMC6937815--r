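# The surface vocabulary: segments (maximal runs of accessible residues),
# clusters of segments, fixed-radius patches and varying-radius patches.

#' Build surface segments
#'
#' A segment is a maximal run of surface-accessible, chain-contiguous
#' residues (contiguity = consecutive position in the chain's residue
#' ordering). Every accessible residue belongs to exactly one segment. The
#' centre of gravity is the unweighted mean over all heavy atoms of the
#' segment.
#'
#' @param structure a `pep_structure` with accessibility annotated (via
#'   [compute_accessibility()] or [set_accessibility()]).
#' @return tibble with one row per segment: `segment_id`, `chain`, `keys`
#'   (list of residue keys N to C), `resnos` (list), `sequence`, `length`,
#'   and list-columns of 3-vectors `cog`, `nterm_ca`, `cterm_ca` (CA of the
#'   terminal residues), `nterm_n` (N atom of the first residue) and
#'   `cterm_c` (C atom of the last residue).
#' @export
build_segments <- function(structure) {
  stopifnot(inherits(structure, "pep_structure"))
  res <- structure$residues
  if (all(is.na(res$accessible))) {
    stop("accessibility not annotated; run compute_accessibility() first")
  }
  if (!any(res$accessible, na.rm = TRUE)) {
    warning("no accessible residue; returning empty segment table")
    return(empty_segments())
  }
  res$ord <- seq_len(nrow(res))
  acc <- res[which(res$accessible), ]
  acc$segment_id <- cumsum(residue_run_breaks(res, acc$ord))
  at <- structure$atoms
  acc |>
    group_by(.data$segment_id) |>
    summarise(
      chain = .data$chain[1],
      keys = list(.data$key),
      resnos = list(.data$resno),
      sequence = paste(.data$aa, collapse = ""),
      length = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(
      cog = purrr::map(.data$keys, function(k) {
        colMeans(as.matrix(at[at$key %in% k, c("x", "y", "z")]))
      }),
      nterm_ca = purrr::map(.data$keys, function(k) atom_coord(at, k[1], "CA")),
      cterm_ca = purrr::map(.data$keys, function(k) {
        atom_coord(at, k[length(k)], "CA")
      }),
      nterm_n = purrr::map(.data$keys, function(k) atom_coord(at, k[1], "N")),
      cterm_c = purrr::map(.data$keys, function(k) {
        atom_coord(at, k[length(k)], "C")
      })
    )
}

empty_segments <- function() {
  tibble(segment_id = integer(), chain = character(), keys = list(),
         resnos = list(), sequence = character(), length = integer(),
         cog = list(), nterm_ca = list(), cterm_ca = list(),
         nterm_n = list(), cterm_c = list())
}

atom_coord <- function(at, key, elety) {
  m <- at[at$key == key & at$elety == elety, c("x", "y", "z")]
  if (nrow(m) == 0) {
    # fall back to the residue's first atom if the named atom is absent
    m <- at[at$key == key, c("x", "y", "z")][1, ]
  }
  as.numeric(m[1, ])
}

#' Distance between two segments
#'
#' @param s1,s2 one-row slices of a [build_segments()] tibble.
#' @param anchor `"cog"` (Euclidean distance between centres of gravity) or
#'   `"termini"` (minimum over the four N/C-terminus CA pairings).
#' @return for `"cog"` a numeric scalar; for `"termini"` a list with `dist`
#'   and `pairing` (e.g. `"C1-N2"`).
#' @export
segment_distance <- function(s1, s2, anchor = c("cog", "termini")) {
  anchor <- match.arg(anchor)
  if (anchor == "cog") {
    return(euclid(s1$cog[[1]], s2$cog[[1]]))
  }
  d <- c(
    "N1-N2" = euclid(s1$nterm_ca[[1]], s2$nterm_ca[[1]]),
    "N1-C2" = euclid(s1$nterm_ca[[1]], s2$cterm_ca[[1]]),
    "C1-N2" = euclid(s1$cterm_ca[[1]], s2$nterm_ca[[1]]),
    "C1-C2" = euclid(s1$cterm_ca[[1]], s2$cterm_ca[[1]])
  )
  i <- which.min(d)
  list(dist = unname(d[i]), pairing = names(d)[i])
}

# full cog distance matrix of a segment table
segment_cog_dist <- function(segments) {
  cogs <- do.call(rbind, segments$cog)
  as.matrix(dist(cogs))
}

#' Group segments into spatial clusters
#'
#' Average-linkage hierarchical clustering on inter-segment centre-of-gravity
#' distances, cut at a fixed height. This is a deterministic functional
#' stand-in for tree-based segment grouping: nearby segments coalesce into a
#' number of clusters that grows only weakly with antigen size.
#'
#' @param segments a [build_segments()] tibble.
#' @param cutoff merge height in Angstroms.
#' @return tibble of surface areas: `area_id`, `kind` (`"cluster"`),
#'   `reference` (NA for clusters), `members` (list of segment ids), `n_aa`.
#' @export
build_clusters <- function(segments, cutoff = 20) {
  stopifnot(nrow(segments) >= 1)
  if (nrow(segments) == 1) {
    cl <- 1L
  } else {
    hc <- hclust(dist(do.call(rbind, segments$cog)), method = "average")
    cl <- cutree(hc, h = cutoff)
  }
  tibble(segment_id = segments$segment_id, length = segments$length,
         cluster = cl) |>
    group_by(.data$cluster) |>
    summarise(members = list(.data$segment_id),
              n_aa = sum(.data$length), .groups = "drop") |>
    mutate(area_id = paste0("cluster", .data$cluster), kind = "cluster",
           reference = NA_character_) |>
    select("area_id", "kind", "reference", "members", "n_aa")
}

#' Build fixed-radius segment patches
#'
#' Each segment is used in turn as the reference; the patch gathers every
#' segment whose centre of gravity lies within `radius` (inclusive) of the
#' reference centre of gravity. The number of patches equals the number of
#' segments.
#'
#' @param segments a [build_segments()] tibble.
#' @param radius patch radius in Angstroms (10 or 15 in standard use).
#' @return tibble of surface areas (`kind` = `"patch<radius>"`), one per
#'   segment, `reference` = the reference segment id.
#' @export
build_patches <- function(segments, radius) {
  stopifnot(nrow(segments) >= 1, length(radius) == 1, radius > 0)
  dmat <- segment_cog_dist(segments)
  purrr::map_dfr(seq_len(nrow(segments)), function(i) {
    mem <- segments$segment_id[dmat[i, ] <= radius]
    tibble(area_id = sprintf("patch%g_%d", radius, segments$segment_id[i]),
           kind = paste0("patch", radius),
           reference = as.character(segments$segment_id[i]),
           members = list(mem),
           n_aa = sum(segments$length[segments$segment_id %in% mem]))
  })
}

#' Build varying-radius residue patches
#'
#' Each accessible residue is used in turn as the reference. The number of
#' accessible residues within radii 15-20 A (1 A steps, CA-CA distances,
#' inclusive) of the reference CA is counted; the final radius is the
#' smallest one whose count reaches the mean of the six counts, and the
#' patch members are the accessible residues within that radius.
#'
#' @param structure a `pep_structure` with accessibility annotated.
#' @param radii candidate radii in Angstroms.
#' @return tibble of surface areas (`kind` = `"varying_patch"`), one per
#'   accessible residue; `members` holds residue keys, `radius` the selected
#'   radius.
#' @export
build_varying_patches <- function(structure, radii = 15:20) {
  res <- structure$residues
  acc <- res[which(res$accessible), ]
  if (nrow(acc) == 0) {
    stop("no accessible residue")
  }
  at <- structure$atoms
  ca <- do.call(rbind, lapply(acc$key, function(k) atom_coord(at, k, "CA")))
  dmat <- as.matrix(dist(ca))
  purrr::map_dfr(seq_len(nrow(acc)), function(i) {
    counts <- vapply(radii, function(r) sum(dmat[i, ] <= r), integer(1))
    target <- mean(counts)
    r_final <- radii[which(counts >= target)[1]]
    mem <- acc$key[dmat[i, ] <= r_final]
    tibble(area_id = paste0("vpatch_", acc$key[i]),
           kind = "varying_patch",
           reference = acc$key[i],
           members = list(mem),
           n_aa = length(mem),
           radius = r_final)
  })
}
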