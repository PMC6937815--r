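# broom-style accessors.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a protein structure into its residue table
#'
#' @param x a `pep_structure`.
#' @param ... unused.
#' @return the residue tibble (see [residues()]).
#' @export
tidy.pep_structure <- function(x, ...) {
  residues(x)
}

#' One-row summary of a protein structure
#'
#' @param x a `pep_structure`.
#' @param ... unused.
#' @return tibble with residue/chain/atom counts and the accessible
#'   fraction (NA before accessibility annotation).
#' @export
glance.pep_structure <- function(x, ...) {
  res <- residues(x)
  tibble(
    id = x$id,
    n_residues = nrow(res),
    n_chains = length(unique(res$chain)),
    n_atoms = nrow(x$atoms),
    accessible_fraction = mean(res$accessible)
  )
}

#' Tidy a method-performance summary
#'
#' @param x a `pep_method_summary`.
#' @param ... unused.
#' @return the underlying tibble without the extra class.
#' @export
tidy.pep_method_summary <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "pep_method_summary")
  out
}

#' Overall glance at a method-performance summary
#'
#' @param x a `pep_method_summary`.
#' @param ... unused.
#' @return one row per evaluation mode with peptide-weighted overall
#'   means and the best method by qualifying proportion.
#' @export
glance.pep_method_summary <- function(x, ...) {
  x |>
    group_by(.data$mode) |>
    summarise(
      n_methods = dplyr::n(),
      mean_se = stats::weighted.mean(.data$mean_se, .data$n_peptides),
      mean_ppv = stats::weighted.mean(.data$mean_ppv, .data$n_peptides),
      best_method = .data$method[which.max(.data$prop_above)],
      prop_above = stats::weighted.mean(.data$prop_above, .data$n_peptides),
      n_peptides = sum(.data$n_peptides),
      .groups = "drop"
    )
}
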