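# Peptide-epitope mimicry evaluation: sensitivity (Se) and positive
# predictive value (PPV) in composition and position-aware modes, per-method
# summaries, peptide/epitope size analysis and chance baselines.

count_aa <- function(seq_chars) {
  table(factor(seq_chars, levels = AA1))
}

#' Composition-mode evaluation of one peptide against one epitope
#'
#' Amino-acid identities are compared as multisets, ignoring positions:
#' `tp` is the summed per-letter overlap, `fp` the remaining peptide
#' residues, `fn` the remaining epitope residues. `se = tp / (tp + fn)`,
#' `ppv = tp / (tp + fp)`.
#'
#' @param peptide a one-row designed-peptide tibble, or a plain sequence
#'   string.
#' @param epitope an [extract_epitope()] tibble.
#' @return a one-row tibble: `mode`, `tp`, `fp`, `fn`, `se`, `ppv`.
#' @export
evaluate_composition <- function(peptide, epitope) {
  seq <- if (is.character(peptide)) peptide else peptide$sequence
  pep <- strsplit(seq, "")[[1]]
  epi <- epitope$aa
  if (length(pep) == 0 || length(epi) == 0) {
    return(tibble(mode = "composition", tp = 0L, fp = length(pep),
                  fn = length(epi), se = NA_real_, ppv = NA_real_))
  }
  tp <- sum(pmin(count_aa(pep), count_aa(epi)))
  fp <- length(pep) - tp
  fn <- length(epi) - tp
  tibble(mode = "composition", tp = as.integer(tp), fp = as.integer(fp),
         fn = as.integer(fn), se = tp / (tp + fn), ppv = tp / (tp + fp))
}

#' Position-aware evaluation of one peptide against one epitope
#'
#' A peptide position counts as a true positive when its source residue in
#' the antigen is an epitope residue (each epitope residue creditable
#' once). Linker positions, which have no source residue, are compared
#' last: they match by amino-acid identity against epitope residues not yet
#' credited.
#'
#' @param peptide a one-row designed-peptide tibble with provenance.
#' @param epitope an [extract_epitope()] tibble.
#' @return a one-row tibble as in [evaluate_composition()].
#' @export
evaluate_position_aware <- function(peptide, epitope) {
  pos <- peptide$positions[[1]]
  if (is.null(pos) || nrow(pos) == 0 || nrow(epitope) == 0) {
    return(tibble(mode = "position_aware", tp = 0L,
                  fp = if (is.null(pos)) 0L else nrow(pos),
                  fn = nrow(epitope), se = NA_real_, ppv = NA_real_))
  }
  remaining <- epitope$key
  remaining_aa <- epitope$aa
  tp <- 0L
  # pass 1: positions with residue provenance
  for (k in pos$source_key[!is.na(pos$source_key)]) {
    hit <- match(k, remaining)
    if (!is.na(hit)) {
      tp <- tp + 1L
      remaining <- remaining[-hit]
      remaining_aa <- remaining_aa[-hit]
    }
  }
  # pass 2: linker positions, identity-matched against what is left
  for (a in pos$aa[is.na(pos$source_key)]) {
    hit <- match(a, remaining_aa)
    if (!is.na(hit)) {
      tp <- tp + 1L
      remaining <- remaining[-hit]
      remaining_aa <- remaining_aa[-hit]
    }
  }
  fp <- nrow(pos) - tp
  fn <- nrow(epitope) - tp
  tibble(mode = "position_aware", tp = tp, fp = as.integer(fp),
         fn = as.integer(fn), se = tp / (tp + fn), ppv = tp / (tp + fp))
}

#' Evaluate every peptide of a bank against an epitope
#'
#' @param bank a [generate_peptide_bank()] tibble.
#' @param epitope an [extract_epitope()] tibble of the bank's antigen.
#' @param mode `"composition"`, `"position_aware"` or both.
#' @return a tibble with one row per peptide and mode: the bank's `method`,
#'   `reference`, `sequence`, `final_length` and `antigen` columns joined
#'   with `mode`, `tp`, `fp`, `fn`, `se`, `ppv` and `epitope_size`.
#' @export
evaluate_bank <- function(bank, epitope,
                          mode = c("composition", "position_aware")) {
  mode <- match.arg(mode, several.ok = TRUE)
  keep <- intersect(c("method", "reference", "antigen", "sequence",
                      "final_length"), names(bank))
  purrr::map_dfr(seq_len(nrow(bank)), function(i) {
    row <- bank[i, ]
    purrr::map_dfr(mode, function(m) {
      ev <- if (m == "composition") {
        evaluate_composition(row, epitope)
      } else {
        evaluate_position_aware(row, epitope)
      }
      bind_cols(row[, keep], ev)
    })
  }) |>
    mutate(epitope_size = nrow(epitope))
}

#' Per-method performance summary
#'
#' @param results an [evaluate_bank()] tibble (one or more antigens and
#'   modes).
#' @param threshold the Se/PPV threshold; a peptide qualifies when both its
#'   Se and its PPV are strictly greater than the threshold.
#' @return a tibble of class `pep_method_summary`, one row per method and
#'   mode: `n_peptides`, `mean_se`, `mean_ppv`, `prop_above` and
#'   `n_antigens_hit` (antigens with at least one qualifying peptide).
#' @export
method_performance <- function(results, threshold = 0.7) {
  if (nrow(results) == 0) {
    stop("empty evaluation results")
  }
  if (!"antigen" %in% names(results)) {
    results$antigen <- "antigen"
  }
  out <- results |>
    mutate(qual = !is.na(.data$se) & !is.na(.data$ppv) &
             .data$se > threshold & .data$ppv > threshold) |>
    group_by(.data$method, .data$mode) |>
    summarise(
      n_peptides = dplyr::n(),
      mean_se = mean(.data$se, na.rm = TRUE),
      mean_ppv = mean(.data$ppv, na.rm = TRUE),
      prop_above = mean(.data$qual),
      n_antigens_hit = dplyr::n_distinct(.data$antigen[.data$qual]),
      .groups = "drop"
    )
  attr(out, "threshold") <- threshold
  class(out) <- c("pep_method_summary", class(out))
  out
}

#' Qualifying peptides by peptide-epitope size difference
#'
#' Bins the evaluated peptides by the absolute difference between the final
#' peptide length and the epitope size, reporting how many peptides qualify
#' (Se and PPV strictly above the threshold) in each bin.
#'
#' @inheritParams method_performance
#' @return tibble with `size_diff` (absolute difference), `n_peptides`,
#'   `n_qualifying`, `prop_qualifying`.
#' @export
size_difference_analysis <- function(results, threshold = 0.7) {
  stopifnot(all(c("final_length", "epitope_size") %in% names(results)))
  results |>
    mutate(size_diff = abs(.data$final_length - .data$epitope_size),
           qual = !is.na(.data$se) & !is.na(.data$ppv) &
             .data$se > threshold & .data$ppv > threshold) |>
    group_by(.data$size_diff) |>
    summarise(n_peptides = dplyr::n(),
              n_qualifying = sum(.data$qual),
              prop_qualifying = mean(.data$qual),
              .groups = "drop") |>
    arrange(.data$size_diff)
}

#' Random-peptide baseline
#'
#' Draws peptides whose residues are i.i.d. samples from the antigen's
#' amino-acid composition and whose lengths are drawn from a supplied
#' empirical length distribution (typically the lengths of the designed
#' peptides being compared).
#'
#' @param structure the antigen `pep_structure`.
#' @param n_peptides number of peptides to draw.
#' @param lengths integer vector: the empirical length distribution to
#'   sample from.
#' @param seed integer seed; the output is fully reproducible from it.
#' @return a bank-like tibble (`method = "random"`) with sequences but no
#'   structural provenance.
#' @export
random_baseline <- function(structure, n_peptides, lengths, seed) {
  stopifnot(n_peptides >= 1, length(lengths) >= 1)
  comp <- structure$residues$aa
  rng <- local({
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
    lens <- sample(lengths, n_peptides, replace = TRUE)
    lapply(lens, function(l) sample(comp, l, replace = TRUE))
  })
  tibble(
    method = "random",
    reference = as.character(seq_len(n_peptides)),
    requested_length = NA_integer_,
    final_length = lengths(rng),
    sequence = vapply(rng, paste, character(1), collapse = ""),
    path_distance = NA_real_,
    score = NA_real_,
    status = "ok",
    positions = lapply(rng, function(ch) {
      tibble(pos = seq_along(ch), aa = ch, source_key = NA_character_,
             origin = "random", segment_id = NA_integer_)
    }),
    segments_used = list(tibble(segment_id = integer(0),
                                orientation = character(0))),
    antigen = structure$id
  )
}

#' Probability of drawing a specific peptide by chance
#'
#' Closed form for ordered draws without replacement from the antigen's
#' accessible residues: with `n_X` occurrences of amino acid X among the
#' `n` accessible residues and `p_X` occurrences in the peptide of length
#' `P`, the probability is `prod_X A(n_X, p_X) / A(n, P)` where
#' `A(n, p) = n! / (n - p)!`. Computed in log space.
#'
#' @param sequence peptide sequence (string).
#' @param structure accessibility-annotated antigen.
#' @return probability in \[0, 1\]; 0 when the peptide needs more copies of
#'   a residue type than the accessible surface offers.
#' @export
chance_probability <- function(sequence, structure) {
  res <- structure$residues
  acc <- res$aa[which(res$accessible)]
  pep <- strsplit(sequence, "")[[1]]
  n <- length(acc)
  P <- length(pep)
  if (P > n) return(0)
  n_x <- count_aa(acc)
  p_x <- count_aa(pep)
  if (any(p_x > n_x)) return(0)
  log_arr <- function(nn, pp) lgamma(nn + 1) - lgamma(nn - pp + 1)
  exp(sum(log_arr(as.numeric(n_x), as.numeric(p_x))) - log_arr(n, P))
}
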