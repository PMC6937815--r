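# Prime design methods (NN, uNN, FN and their order-optimised versions),
# linker insertion (ALA, SA, SAS) and peptide scoring.
#
# A designed peptide is a one-row tibble with per-position provenance
# (`positions` list-column) and the ordered segments it was built from
# (`segments_used` list-column), so that linker-stripping and position-aware
# evaluation can always trace every character back to the antigen.

new_peptide <- function(method, reference, requested_length, segments_used,
                        positions, path_distance = NA_real_,
                        score = NA_real_, status = "ok") {
  tibble(
    method = method,
    reference = as.character(reference),
    requested_length = as.integer(requested_length),
    final_length = nrow(positions),
    sequence = paste(positions$aa, collapse = ""),
    path_distance = path_distance,
    score = score,
    status = status,
    positions = list(positions),
    segments_used = list(segments_used)
  )
}

seg_row <- function(segments, id) {
  segments[segments$segment_id == id, ]
}

# positions tibble of one segment in a given orientation
segment_positions <- function(segments, id, orientation = "natural") {
  s <- seg_row(segments, id)
  keys <- s$keys[[1]]
  aas <- strsplit(s$sequence, "")[[1]]
  if (orientation == "reversed") {
    keys <- rev(keys)
    aas <- rev(aas)
  }
  tibble(aa = aas, source_key = keys, origin = "segment",
         segment_id = id)
}

assemble_positions <- function(segments, order_ids, orientations) {
  purrr::map2_dfr(order_ids, orientations,
                  function(id, o) segment_positions(segments, id, o)) |>
    mutate(pos = row_number()) |>
    select("pos", "aa", "source_key", "origin", "segment_id")
}

order_path_distance <- function(segments, order_ids) {
  if (length(order_ids) < 2) return(0)
  cogs <- lapply(order_ids, function(id) seg_row(segments, id)$cog[[1]])
  sum(vapply(seq_len(length(cogs) - 1),
             function(i) euclid(cogs[[i]], cogs[[i + 1]]), numeric(1)))
}

# nearest unused segment to an anchor cog; ties broken by smaller id
nearest_segment <- function(segments, anchor_cog, unused_ids) {
  d <- vapply(unused_ids, function(id) {
    euclid(anchor_cog, seg_row(segments, id)$cog[[1]])
  }, numeric(1))
  ord <- order(d, unused_ids)
  unused_ids[ord[1]]
}

#' Nearest-neighbour peptide design (NN)
#'
#' Starting from the reference segment, repeatedly appends the unused
#' segment nearest (centre-of-gravity distance) to the most recently added
#' segment, C-terminally and in natural sense, until the peptide reaches the
#' requested length or segments run out. A segment that overshoots the
#' requested length is added whole.
#'
#' @param segments a [build_segments()] tibble.
#' @param reference segment id of the reference (starting) segment.
#' @param requested_length requested peptide length in amino acids.
#' @return a one-row designed-peptide tibble.
#' @export
design_nn <- function(segments, reference, requested_length) {
  design_greedy(segments, reference, requested_length, oriented = FALSE)
}

#' Upset nearest-neighbour design (uNN)
#'
#' As [design_nn()], but each appended segment joins by whichever terminus
#' lies closer to the growing peptide's C-terminal residue: if the segment's
#' C-terminus is closer it is appended in reverse sense (ties keep the
#' natural sense).
#'
#' @inheritParams design_nn
#' @return a one-row designed-peptide tibble.
#' @export
design_unn <- function(segments, reference, requested_length) {
  design_greedy(segments, reference, requested_length, oriented = TRUE)
}

design_greedy <- function(segments, reference, requested_length, oriented) {
  stopifnot(reference %in% segments$segment_id, requested_length >= 1)
  order_ids <- reference
  orientations <- "natural"
  total <- seg_row(segments, reference)$length
  unused <- setdiff(segments$segment_id, reference)
  while (total < requested_length && length(unused) > 0) {
    last <- seg_row(segments, order_ids[length(order_ids)])
    nxt <- nearest_segment(segments, last$cog[[1]], unused)
    o <- "natural"
    if (oriented) {
      # C-terminal residue of the forming peptide (orientation-aware)
      last_o <- orientations[length(orientations)]
      c_end <- if (last_o == "natural") last$cterm_ca[[1]] else last$nterm_ca[[1]]
      s <- seg_row(segments, nxt)
      dN <- euclid(c_end, s$nterm_ca[[1]])
      dC <- euclid(c_end, s$cterm_ca[[1]])
      if (dC < dN) o <- "reversed"
    }
    order_ids <- c(order_ids, nxt)
    orientations <- c(orientations, o)
    total <- total + seg_row(segments, nxt)$length
    unused <- setdiff(unused, nxt)
  }
  if (total < requested_length) {
    warning("segments exhausted before requested length was reached")
  }
  method <- if (oriented) "uNN" else "NN"
  pos <- assemble_positions(segments, order_ids, orientations)
  new_peptide(method, reference, requested_length,
              tibble(segment_id = order_ids, orientation = orientations),
              pos, path_distance = order_path_distance(segments, order_ids))
}

#' Flanking nearest-neighbour design (FN)
#'
#' Nearest unused segments are appended alternately C-terminally and
#' N-terminally (always natural sense), each time to the segment currently
#' holding that end, so the reference segment stays centrally placed.
#'
#' @inheritParams design_nn
#' @return a one-row designed-peptide tibble.
#' @export
design_fn <- function(segments, reference, requested_length) {
  stopifnot(reference %in% segments$segment_id, requested_length >= 1)
  c_side <- integer(0)
  n_side <- integer(0) # stored outermost-first
  total <- seg_row(segments, reference)$length
  unused <- setdiff(segments$segment_id, reference)
  c_next <- TRUE
  while (total < requested_length && length(unused) > 0) {
    anchor_id <- if (c_next) {
      if (length(c_side) > 0) c_side[length(c_side)] else reference
    } else {
      if (length(n_side) > 0) n_side[1] else reference
    }
    anchor <- seg_row(segments, anchor_id)$cog[[1]]
    nxt <- nearest_segment(segments, anchor, unused)
    if (c_next) {
      c_side <- c(c_side, nxt)
    } else {
      n_side <- c(nxt, n_side)
    }
    total <- total + seg_row(segments, nxt)$length
    unused <- setdiff(unused, nxt)
    c_next <- !c_next
  }
  if (total < requested_length) {
    warning("segments exhausted before requested length was reached")
  }
  order_ids <- c(n_side, reference, c_side)
  orientations <- rep("natural", length(order_ids))
  pos <- assemble_positions(segments, order_ids, orientations)
  new_peptide("FN", reference, requested_length,
              tibble(segment_id = order_ids, orientation = orientations),
              pos, path_distance = order_path_distance(segments, order_ids))
}

#' Order-optimised prime designs (ONN, OFN, OPP)
#'
#' Takes the segment set selected by NN (for ONN), by FN (for OFN) or the
#' members of the reference's 10 A patch (for OPP), and re-orders it to
#' minimise the total inter-segment centre-of-gravity distance over the
#' whole arrangement (exact enumeration via dynamic programming up to
#' `exact_limit` segments, 2-opt refinement beyond). Segments are
#' concatenated in natural sense; no extra amino acid is added.
#'
#' @inheritParams design_nn
#' @param method `"ONN"`, `"OFN"` or `"OPP"`.
#' @param patches for OPP: a `build_patches(segments, 10)` tibble; computed
#'   on the fly when omitted.
#' @param exact_limit see [solve_tsp_path()].
#' @return a one-row designed-peptide tibble.
#' @export
design_optimized <- function(segments, reference, requested_length,
                             method = c("ONN", "OFN", "OPP"),
                             patches = NULL, exact_limit = 12) {
  method <- match.arg(method)
  set_ids <- switch(
    method,
    ONN = design_nn(segments, reference, requested_length)$segments_used[[1]]$segment_id,
    OFN = design_fn(segments, reference, requested_length)$segments_used[[1]]$segment_id,
    OPP = {
      p <- patches %||% build_patches(segments, 10)
      p$members[[which(p$reference == as.character(reference))]]
    }
  )
  set_ids <- sort(set_ids)
  sub <- segments[match(set_ids, segments$segment_id), ]
  D <- segment_cog_dist(sub)
  ord <- solve_tsp_path(D, exact_limit = exact_limit)
  order_ids <- set_ids[ord]
  orientations <- rep("natural", length(order_ids))
  pos <- assemble_positions(segments, order_ids, orientations)
  new_peptide(method, reference, requested_length,
              tibble(segment_id = order_ids, orientation = orientations),
              pos, path_distance = order_path_distance(segments, order_ids))
}

# junction atoms of a segment as oriented within the peptide
junction_atoms <- function(structure, segments, id, orientation) {
  s <- seg_row(segments, id)
  keys <- s$keys[[1]]
  if (orientation == "reversed") keys <- rev(keys)
  at <- structure$atoms
  list(
    c_atom = atom_coord(at, keys[length(keys)], "C"), # peptide-C side
    n_atom = atom_coord(at, keys[1], "N"),            # peptide-N side
    first_keys = keys, last_keys = keys
  )
}

#' Insert linker amino acids between the segments of a prime peptide
#'
#' Three linker chemistries:
#' * `"ALA"` — between consecutive segments, insert
#'   `max(0, round(gap / 3.8) - 1)` alanines, where `gap` is the distance
#'   between the C atom of the preceding junction residue and the N atom of
#'   the following one: one alanine per additional virtual peptide bond the
#'   spatial gap can hold.
#' * `"SA"` — encode both segments in protein blocks; if the junction
#'   transition is allowed insert nothing, otherwise insert the one or two
#'   blocks bridging it best ([best_linker_pbs()]), realised as each block's
#'   preferred central amino acid. An unbridgeable junction marks the whole
#'   peptide `"not_possible"`.
#' * `"SAS"` — encode the 5-residue window spanning the junction (last two
#'   residues of the preceding segment, first three of the following) and
#'   insert exactly one amino acid: the preferred central residue of the
#'   protein block closest to that junction geometry.
#'
#' Inserted positions carry a linker origin marker instead of a source
#' residue, so stripping all linker positions recovers the parent peptide.
#'
#' @param peptide a one-row designed-peptide tibble from a prime method.
#' @param linker `"ALA"`, `"SA"` or `"SAS"`.
#' @param structure the antigen `pep_structure`.
#' @param segments the [build_segments()] tibble the peptide was built from.
#' @param pb_cache optional precomputed per-residue PB labels (named by
#'   residue key), reused across peptides of a bank.
#' @return a one-row designed-peptide tibble (method tag suffixed with the
#'   lower-case linker name).
#' @export
add_linkers <- function(peptide, linker = c("ALA", "SA", "SAS"),
                        structure, segments, pb_cache = NULL) {
  linker <- match.arg(linker)
  su <- peptide$segments_used[[1]]
  stopifnot(nrow(su) >= 1)
  if (linker %in% c("SA", "SAS") && is.null(pb_cache)) {
    pb_cache <- pb_labels_by_key(structure)
  }
  parts <- list(segment_positions(segments, su$segment_id[1],
                                  su$orientation[1]))
  status <- "ok"
  if (nrow(su) > 1) {
    for (i in 2:nrow(su)) {
      prev <- junction_atoms(structure, segments, su$segment_id[i - 1],
                             su$orientation[i - 1])
      nxt <- junction_atoms(structure, segments, su$segment_id[i],
                            su$orientation[i])
      ins <- switch(
        linker,
        ALA = {
          gap <- euclid(prev$c_atom, nxt$n_atom)
          n_ala <- max(0, round(gap / PEPTIDE_BOND_SPAN) - 1)
          rep("A", n_ala)
        },
        SA = {
          pb_end <- last_pb_label(pb_cache, prev$last_keys)
          pb_start <- first_pb_label(pb_cache, nxt$first_keys)
          if (is.na(pb_end) || is.na(pb_start)) {
            character(0) # no encodable junction: join directly
          } else {
            bridge <- best_linker_pbs(pb_end, pb_start)
            if (is.null(bridge)) {
              status <- "not_possible"
              character(0)
            } else {
              vapply(bridge, pb_preferred_aa, character(1), position = 3)
            }
          }
        },
        SAS = {
          sas_linker_aa(structure, prev$last_keys, nxt$first_keys)
        }
      )
      if (length(ins) > 0) {
        parts[[length(parts) + 1]] <-
          tibble(aa = ins, source_key = NA_character_, origin = linker,
                 segment_id = NA_integer_)
      }
      parts[[length(parts) + 1]] <-
        segment_positions(segments, su$segment_id[i], su$orientation[i])
    }
  }
  pos <- bind_rows(parts) |>
    mutate(pos = row_number()) |>
    select("pos", "aa", "source_key", "origin", "segment_id")
  out <- new_peptide(paste0(peptide$method, tolower(linker)),
                     peptide$reference, peptide$requested_length,
                     su, pos, path_distance = peptide$path_distance,
                     status = status)
  out
}

# per-residue PB labels for every chain of the structure, named by key
pb_labels_by_key <- function(structure) {
  res <- structure$residues
  out <- character(0)
  for (ch in unique(res$chain)) {
    keys <- res$key[res$chain == ch]
    lab <- if (length(keys) >= 5) {
      suppressWarnings(encode_pb(structure, keys))
    } else {
      rep(NA_character_, length(keys))
    }
    out <- c(out, setNames(lab, keys))
  }
  out
}

# last/first non-NA PB label of an oriented key run
last_pb_label <- function(pb_cache, keys) {
  lab <- pb_cache[keys]
  lab <- lab[!is.na(lab)]
  if (length(lab) == 0) NA_character_ else lab[[length(lab)]]
}
first_pb_label <- function(pb_cache, keys) {
  lab <- pb_cache[keys]
  lab <- lab[!is.na(lab)]
  if (length(lab) == 0) NA_character_ else lab[[1]]
}

# SAS: one amino acid chosen from the protein block nearest to the junction
# window geometry (last 2 residues of the preceding segment + first 3 of
# the following; dihedrals computed across the spatial gap).
sas_linker_aa <- function(structure, prev_keys, next_keys) {
  k1 <- tail(prev_keys, 2)
  k2 <- head(next_keys, 5 - length(k1))
  keys <- c(k1, k2)
  if (length(keys) < 5) {
    extra <- head(prev_keys, max(0, length(prev_keys) - length(k1)))
    keys <- c(tail(extra, 5 - length(keys)), keys)
  }
  if (length(keys) < 5) {
    return("A") # junction too short to encode; neutral default
  }
  dih <- backbone_dihedrals(structure, keys)
  win <- c(dih$psi[1], dih$phi[2], dih$psi[2], dih$phi[3], dih$psi[3],
           dih$phi[4], dih$psi[4], dih$phi[5])
  if (all(is.na(win))) {
    return("A")
  }
  proto <- pb_prototypes()
  dev <- apply(proto, 1, function(p) rmsda(win, p))
  pb <- names(which.min(dev))
  pb_preferred_aa(pb, 3)
}

#' Score a designed peptide
#'
#' The peptide score Sp is the sum of its segments' scores,
#' `Ss = Naa + Naccess + Nhyd + Nwryp + Nturn`: residue count, mean relative
#' accessibility of the segment scaled by 10 (so its magnitude is
#' commensurate with the counts), number of hydrophobic residues
#' (A, C, F, I, L, M, V, W), number of W/R/Y/P residues (counted
#' independently of hydrophobicity), and number of residues in
#' hydrogen-bonded turns.
#'
#' @param peptide a one-row designed-peptide tibble with `segments_used`.
#' @param structure the annotated antigen structure.
#' @param turns optional precomputed [assign_turns()] vector; set to
#'   `FALSE` to disable the turn term.
#' @return the peptide (one-row tibble) with its `score` filled in.
#' @export
score_peptide <- function(peptide, structure, turns = NULL) {
  su <- peptide$segments_used[[1]]
  if (is.null(su) || nrow(su) == 0) {
    return(peptide)
  }
  if (is.null(turns)) {
    turns <- assign_turns(structure)
  } else if (isFALSE(turns)) {
    turns <- rep(FALSE, nrow(structure$residues))
  }
  res <- structure$residues
  turn_by_key <- setNames(turns, res$key)
  rel_by_key <- setNames(res$sasa_rel, res$key)
  aa_by_key <- setNames(res$aa, res$key)
  ss <- vapply(su$segment_id, function(id) {
    # score segments from their structure residues (orientation-independent)
    seg_keys <- peptide$positions[[1]] |>
      filter(.data$segment_id == id) |>
      pull("source_key")
    aas <- aa_by_key[seg_keys]
    naa <- length(seg_keys)
    naccess <- mean(rel_by_key[seg_keys], na.rm = TRUE) * 10
    nhyd <- sum(aas %in% HYDROPHOBIC_AA)
    nwryp <- sum(aas %in% WRYP_AA)
    nturn <- sum(turn_by_key[seg_keys], na.rm = TRUE)
    naa + naccess + nhyd + nwryp + nturn
  }, numeric(1))
  peptide$score <- sum(ss)
  peptide
}
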