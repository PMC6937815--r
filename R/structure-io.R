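# Reading protein structures, accessibility annotation, crystallographic
# epitope extraction and dataset redundancy filtering.

#' Construct a protein structure object
#'
#' A `pep_structure` is a light container holding an atom-level tibble and a
#' residue-level tibble. Downstream functions (segments, patches, design
#' methods, evaluation) consume and return plain tibbles; the structure object
#' only carries the coordinates and per-residue annotations they need.
#'
#' @param atoms tibble with columns `chain`, `resno`, `ins`, `resid`
#'   (three-letter code), `aa` (one-letter code), `elety` (atom name),
#'   `element`, `x`, `y`, `z`.
#' @param het optional tibble of non-protein atoms (same columns); these take
#'   part in surface-burial calculations but are not residues of the protein.
#' @param id structure label.
#' @param source provenance string (file path or "synthetic").
#' @return an object of class `pep_structure` with elements `atoms`, `het`,
#'   `residues`, `id`, `source`.
#' @export
new_pep_structure <- function(atoms, het = NULL, id = "structure",
                              source = "in-memory") {
  atoms <- as_tibble(atoms)
  if (is.null(het)) {
    het <- atoms[0, ]
  }
  atoms$key <- residue_key(atoms$chain, atoms$resno, atoms$ins)
  res <- atoms |>
    dplyr::distinct(.data$key, .data$chain, .data$resno, .data$ins, .data$aa)
  res <- res |>
    mutate(sasa_abs = NA_real_, sasa_rel = NA_real_, accessible = NA)
  structure(
    list(atoms = atoms, het = as_tibble(het), residues = res,
         id = id, source = source),
    class = "pep_structure"
  )
}

#' @export
print.pep_structure <- function(x, ...) {
  nacc <- sum(x$residues$accessible, na.rm = TRUE)
  cat(sprintf(
    "<pep_structure> %s: %d residues in %d chain(s), %d atoms%s\n",
    x$id, nrow(x$residues), length(unique(x$residues$chain)),
    nrow(x$atoms),
    if (all(is.na(x$residues$accessible))) ""
    else sprintf(", %d accessible", nacc)))
  invisible(x)
}

#' Residue table of a structure
#'
#' @param structure a `pep_structure`.
#' @return tibble with one row per residue: `key`, `chain`, `resno`, `ins`,
#'   `aa`, and (after [compute_accessibility()]) `sasa_abs`, `sasa_rel`,
#'   `accessible`.
#' @export
residues <- function(structure) {
  stopifnot(inherits(structure, "pep_structure"))
  structure$residues
}

#' Atom table of a structure
#' @inheritParams residues
#' @return tibble with one row per heavy atom.
#' @export
atoms <- function(structure) {
  stopifnot(inherits(structure, "pep_structure"))
  structure$atoms
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records via bio3d, keeping heavy atoms of protein residues.
#' Water is dropped; other HETATM records are retained separately so that
#' ligands still occlude the surface in accessibility calculations.
#' Alternate locations are resolved by keeping the highest-occupancy
#' conformer. Non-standard residues with a known parent amino acid (MSE and
#' friends) are mapped to it; unknown residues are excluded with a warning.
#'
#' @param path path to a PDB file.
#' @param chains optional character vector of chain identifiers to keep.
#' @param id structure label; defaults to the file name.
#' @return a [new_pep_structure()] object.
#' @export
read_structure <- function(path, chains = NULL, id = NULL) {
  if (!file.exists(path)) {
    stop("PDB file not found: ", path)
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- as_tibble(pdb$atom)
  at$ins <- ifelse(is.na(at$insert), "", at$insert)
  # drop hydrogens and resolve altlocs by occupancy (then altloc label)
  at <- at[is.na(at$elesy) | !(at$elesy %in% c("H", "D")), ]
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # altloc resolution by occupancy, preserving the file's atom order
  at$.ord <- seq_len(nrow(at))
  at <- at |>
    arrange(dplyr::desc(.data$o), .data$alt, .data$.ord) |>
    distinct(.data$chain, .data$resno, .data$ins, .data$elety,
             .keep_all = TRUE) |>
    arrange(.data$.ord)
  prot <- at[at$type == "ATOM", ]
  het <- at[at$type == "HETATM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ]
  # non-standard protein residues recorded as HETATM (e.g. MSE)
  known_het_aa <- het$resid %in% names(AA3TO1)
  prot <- bind_rows(prot, het[known_het_aa, ])
  het <- het[!known_het_aa, ]
  if (nrow(prot) == 0) {
    stop("no protein chain in ", path)
  }
  unknown <- setdiff(unique(prot$resid), names(AA3TO1))
  if (length(unknown) > 0) {
    warning("excluding residues with unknown amino-acid type: ",
            paste(unknown, collapse = ", "))
    prot <- prot[!(prot$resid %in% unknown), ]
  }
  if (!is.null(chains)) {
    missing_ch <- setdiff(chains, unique(prot$chain))
    if (length(missing_ch) > 0) {
      stop("requested chain(s) absent: ", paste(missing_ch, collapse = ", "))
    }
    prot <- prot[prot$chain %in% chains, ]
    het <- het[het$chain %in% chains, ]
  }
  if (nrow(prot) == 0) {
    stop("no protein chain after selection in ", path)
  }
  shape <- function(d) {
    tibble(chain = d$chain, resno = d$resno, ins = d$ins,
           resid = d$resid, aa = unname(AA3TO1[d$resid]),
           elety = d$elety,
           element = as.character(ifelse(is.na(d$elesy) | d$elesy == "",
                                         substr(gsub("[0-9]", "", d$elety),
                                                1, 1),
                                         d$elesy)),
           x = d$x, y = d$y, z = d$z)
  }
  prot <- prot |> arrange(.data$chain, .data$resno, .data$ins, .data$.ord)
  h <- shape(het)
  h$aa <- NA_character_
  new_pep_structure(shape(prot), het = h,
                    id = id %||% basename(path), source = path)
}

#' Write a structure to a PDB file
#'
#' @inheritParams residues
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  at <- bind_rows(
    mutate(structure$atoms, type = "ATOM"),
    mutate(structure$het, type = "HETATM")
  )
  at$resid[is.na(at$resid)] <- "DUM"
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz, type = at$type,
    resno = at$resno, resid = at$resid, chain = at$chain,
    insert = ifelse(at$ins == "", NA, at$ins),
    elety = at$elety, eleno = seq_len(nrow(at)),
    elesy = at$element
  )
  invisible(path)
}

#' Annotate residues with solvent accessibility
#'
#' Computes per-atom solvent-accessible surface area with the Shrake-Rupley
#' rolling-probe method (deterministic Fibonacci sphere points), sums it per
#' residue, and derives relative accessibility by dividing by the residue's
#' maximum SASA in an extended Gly-X-Gly context. Non-protein (HETATM) atoms
#' occlude the surface but receive no annotation. A residue is flagged
#' accessible when its relative SASA reaches `rel_threshold`.
#'
#' @inheritParams residues
#' @param probe_radius probe sphere radius in Angstroms (water: 1.4).
#' @param rel_threshold relative-SASA threshold for the accessible flag.
#' @param n_points number of sphere sample points per atom.
#' @return the structure with `sasa_abs`, `sasa_rel` and `accessible` filled
#'   in its residue table.
#' @export
compute_accessibility <- function(structure, probe_radius = 1.4,
                                  rel_threshold = 0.05, n_points = 960) {
  stopifnot(inherits(structure, "pep_structure"))
  all_at <- bind_rows(structure$atoms, structure$het)
  xyz <- as.matrix(all_at[, c("x", "y", "z")])
  area <- shrake_rupley(xyz, all_at$element, probe_radius = probe_radius,
                        n_points = n_points)
  n_prot <- nrow(structure$atoms)
  prot_area <- area[seq_len(n_prot)]
  per_res <- tibble(key = structure$atoms$key, a = prot_area) |>
    group_by(.data$key) |>
    summarise(sasa_abs = sum(.data$a), .groups = "drop")
  res <- structure$residues |>
    select(-"sasa_abs", -"sasa_rel", -"accessible") |>
    left_join(per_res, by = "key")
  no_atoms <- is.na(res$sasa_abs)
  if (any(no_atoms)) {
    warning(sum(no_atoms), " residue(s) without atoms flagged inaccessible")
    res$sasa_abs[no_atoms] <- 0
  }
  ref <- MAX_SASA[res$aa]
  res$sasa_rel <- pmin(1, res$sasa_abs / ref)
  res$accessible <- res$sasa_rel >= rel_threshold
  structure$residues <- res
  structure
}

#' Assert an accessibility mask directly
#'
#' Fixture shortcut: annotates residues as accessible/buried from a logical
#' mask instead of computing SASA geometrically. Asserted residues get a
#' nominal relative SASA of 1 (accessible) or 0 (buried).
#'
#' @inheritParams residues
#' @param mask logical vector, one value per residue in residue-table order.
#' @return the annotated structure.
#' @export
set_accessibility <- function(structure, mask) {
  stopifnot(inherits(structure, "pep_structure"),
            length(mask) == nrow(structure$residues))
  structure$residues$sasa_rel <- as.numeric(mask)
  structure$residues$sasa_abs <-
    as.numeric(mask) * MAX_SASA[structure$residues$aa]
  structure$residues$accessible <- as.logical(mask)
  structure
}

#' Construct an antigen-antibody complex object
#'
#' @param structure a `pep_structure` holding both antigen and antibody
#'   chains.
#' @param ag_chains,ab_chains chain identifiers of the antigen and antibody;
#'   they must be disjoint and non-empty.
#' @param complex_key identifier of the antigen-antibody *pair*, used for
#'   redundancy filtering across crystal structures of the same complex.
#' @param resolution crystallographic resolution (Angstroms), if known.
#' @return an object of class `pep_complex`.
#' @export
new_pep_complex <- function(structure, ag_chains, ab_chains,
                            complex_key = structure$id, resolution = NA) {
  stopifnot(inherits(structure, "pep_structure"),
            length(ag_chains) > 0, length(ab_chains) > 0,
            length(intersect(ag_chains, ab_chains)) == 0)
  present <- unique(structure$atoms$chain)
  missing_ch <- setdiff(c(ag_chains, ab_chains), present)
  if (length(missing_ch) > 0) {
    stop("chain(s) absent from structure: ",
         paste(missing_ch, collapse = ", "))
  }
  structure(
    list(structure = structure, ag_chains = ag_chains, ab_chains = ab_chains,
         complex_key = complex_key, resolution = resolution),
    class = "pep_complex"
  )
}

#' @export
print.pep_complex <- function(x, ...) {
  cat(sprintf("<pep_complex> %s: Ag chains [%s] vs Ab chains [%s]\n",
              x$complex_key, paste(x$ag_chains, collapse = ","),
              paste(x$ab_chains, collapse = ",")))
  invisible(x)
}

#' Extract the crystallographic epitope of an antigen-antibody complex
#'
#' The epitope is the set of antigen residues having at least one atom within
#' `cutoff` (inclusive) of any antibody atom. Maximal runs of chain-contiguous
#' epitope residues are reported as epitope segments; contiguity means
#' consecutive position in the chain's residue ordering (insertion codes
#' respected), not residue-number arithmetic.
#'
#' @param complex a `pep_complex`.
#' @param cutoff contact distance threshold in Angstroms.
#' @return a tibble with one row per epitope residue: `key`, `chain`,
#'   `resno`, `ins`, `aa`, `min_dist` (closest approach to the antibody) and
#'   `segment` (epitope segment index). Zero rows if there is no contact.
#' @export
extract_epitope <- function(complex, cutoff = 4.0) {
  stopifnot(inherits(complex, "pep_complex"))
  at <- complex$structure$atoms
  ag <- at[at$chain %in% complex$ag_chains, ]
  ab <- at[at$chain %in% complex$ab_chains, ]
  stopifnot(nrow(ag) > 0, nrow(ab) > 0)
  ag_xyz <- as.matrix(ag[, c("x", "y", "z")])
  ab_xyz <- as.matrix(ab[, c("x", "y", "z")])
  # per antigen atom, squared distance to the closest antibody atom
  min_d2 <- vapply(seq_len(nrow(ag_xyz)), function(i) {
    d2 <- (ab_xyz[, 1] - ag_xyz[i, 1])^2 +
      (ab_xyz[, 2] - ag_xyz[i, 2])^2 +
      (ab_xyz[, 3] - ag_xyz[i, 3])^2
    min(d2)
  }, numeric(1))
  per_res <- tibble(key = ag$key, d = sqrt(min_d2)) |>
    group_by(.data$key) |>
    summarise(min_dist = min(.data$d), .groups = "drop")
  res <- complex$structure$residues
  res <- res[res$chain %in% complex$ag_chains, ]
  res$ord <- seq_len(nrow(res))
  out <- res |>
    left_join(per_res, by = "key") |>
    filter(!is.na(.data$min_dist), .data$min_dist <= cutoff)
  if (nrow(out) == 0) {
    return(tibble(key = character(), chain = character(), resno = integer(),
                  ins = character(), aa = character(), min_dist = numeric(),
                  segment = integer()))
  }
  # maximal runs of contiguous residues (within-chain ordering)
  out$segment <- cumsum(residue_run_breaks(res, out$ord))
  out |>
    select("key", "chain", "resno", "ins", "aa", "min_dist", "segment")
}

# TRUE where a new contiguous run starts, for a subset of residue-table
# rows (`ord` = row indices into `res`, increasing). Two residues are
# contiguous when they are consecutive in the chain's residue ordering AND
# either the residue number steps by one or an insertion-code continuation
# keeps the same number; a numbering gap is a chain break.
residue_run_breaks <- function(res, ord) {
  n <- length(ord)
  if (n == 0) return(logical(0))
  if (n == 1) return(TRUE)
  prev <- ord[-n]
  cur <- ord[-1]
  adjacent <- cur - prev == 1 &
    res$chain[cur] == res$chain[prev] &
    (res$resno[cur] - res$resno[prev] == 1 |
       (res$resno[cur] == res$resno[prev] &
          res$ins[cur] != res$ins[prev]))
  c(TRUE, !adjacent)
}

#' Extract the antigen chains of a complex as a standalone structure
#'
#' @param complex a `pep_complex`.
#' @return a `pep_structure` containing only the antigen chains, keeping
#'   any accessibility annotation.
#' @export
antigen_structure <- function(complex) {
  stopifnot(inherits(complex, "pep_complex"))
  subset_chains(complex$structure, complex$ag_chains)
}

#' Restrict a structure to a set of chains
#'
#' @inheritParams residues
#' @param chains chain identifiers to keep.
#' @return a `pep_structure`; accessibility annotation is carried over.
#' @export
subset_chains <- function(structure, chains) {
  stopifnot(inherits(structure, "pep_structure"))
  keep <- structure$atoms$chain %in% chains
  if (!any(keep)) stop("no atoms in requested chain(s)")
  out <- new_pep_structure(structure$atoms[keep, setdiff(names(structure$atoms), "key")],
                           het = structure$het,
                           id = structure$id, source = structure$source)
  ann <- structure$residues[structure$residues$chain %in% chains,
                            c("key", "sasa_abs", "sasa_rel", "accessible")]
  out$residues <- out$residues |>
    select(-"sasa_abs", -"sasa_rel", -"accessible") |>
    left_join(ann, by = "key")
  out
}

#' Summary statistics over a set of epitopes
#'
#' @param epitopes list of epitope tibbles as returned by
#'   [extract_epitope()].
#' @return a one-row tibble: number of epitopes, mean and median epitope size
#'   (residues), mean number of segments per epitope, and mean residues per
#'   segment (pooled over all segments).
#' @export
epitope_statistics <- function(epitopes) {
  if (length(epitopes) == 0) {
    stop("no epitopes supplied")
  }
  sizes <- vapply(epitopes, nrow, integer(1))
  n_seg <- vapply(epitopes, function(e) {
    if (nrow(e) == 0) 0L else max(e$segment)
  }, integer(1))
  tibble(
    n_epitopes = length(epitopes),
    mean_size = mean(sizes),
    median_size = stats::median(sizes),
    mean_segments = mean(n_seg),
    mean_residues_per_segment = sum(sizes) / sum(n_seg)
  )
}

#' Filter a complex manifest for redundancy
#'
#' Keeps exactly one entry per `complex_key` (one crystal structure per
#' antigen-antibody pair). Retention is deterministic: the entry with the
#' best (smallest) stated resolution wins, ties broken by lexicographic
#' structure id.
#'
#' @param manifest tibble with at least `complex_key` and `structure_id`
#'   columns; an optional numeric `resolution` column drives retention
#'   (missing resolutions sort last).
#' @return a list with tibbles `kept` and `rejected`.
#' @export
deduplicate_complexes <- function(manifest) {
  manifest <- as_tibble(manifest)
  if (nrow(manifest) == 0) {
    return(list(kept = manifest, rejected = manifest))
  }
  stopifnot(all(c("complex_key", "structure_id") %in% names(manifest)))
  if (!"resolution" %in% names(manifest)) {
    manifest$resolution <- NA_real_
  }
  ranked <- manifest |>
    mutate(.row = row_number()) |>
    arrange(.data$complex_key,
            is.na(.data$resolution), .data$resolution,
            .data$structure_id)
  keep_rows <- ranked |>
    distinct(.data$complex_key, .keep_all = TRUE) |>
    pull(".row")
  list(
    kept = manifest[sort(keep_rows), , drop = FALSE],
    rejected = manifest[setdiff(seq_len(nrow(manifest)), keep_rows), ,
                        drop = FALSE]
  )
}

#' Read a complex dataset manifest from TSV
#'
#' Expected columns: `structure_id`, `path`, `ag_chains`, `ab_chains`,
#' `complex_key`, `resolution` (chain lists comma-separated).
#'
#' @param path TSV file.
#' @return tibble.
#' @export
read_manifest <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
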