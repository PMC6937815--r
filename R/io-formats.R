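# Plain-text exports: FASTA and TSV dumps of epitopes, surface areas and
# peptide banks.

#' Write a peptide bank as FASTA
#'
#' Headers carry method, reference, score and final length.
#'
#' @param bank a [generate_peptide_bank()] tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bank_fasta <- function(bank, path) {
  names <- sprintf("%s|ref=%s|score=%s|len=%d",
                   bank$method, bank$reference,
                   ifelse(is.na(bank$score), ".", sprintf("%.2f", bank$score)),
                   bank$final_length)
  seqinr::write.fasta(as.list(bank$sequence), names = names,
                      file.out = path, nbchar = 80)
  invisible(path)
}

#' Write a peptide bank as TSV with per-position provenance
#'
#' One row per peptide position: peptide identity columns plus `pos`,
#' `aa`, `source_key` and `origin` (segment residue or linker marker).
#'
#' @inheritParams write_bank_fasta
#' @return `path`, invisibly.
#' @export
write_bank_tsv <- function(bank, path) {
  flat <- bank |>
    mutate(.pep = row_number()) |>
    select(".pep", "method", "reference", "antigen" = dplyr::any_of("antigen"),
           "requested_length", "final_length", "sequence", "score",
           "positions") |>
    tidyr::unnest("positions")
  readr::write_tsv(flat, path)
  invisible(path)
}

#' Write an epitope report as TSV
#'
#' @param epitope an [extract_epitope()] tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_epitope_tsv <- function(epitope, path) {
  readr::write_tsv(epitope, path)
  invisible(path)
}

#' Write epitope segment sequences as FASTA
#'
#' @inheritParams write_epitope_tsv
#' @return `path`, invisibly.
#' @export
write_epitope_fasta <- function(epitope, path) {
  segs <- epitope |>
    group_by(.data$segment) |>
    summarise(seq = paste(.data$aa, collapse = ""),
              from = .data$key[1], .groups = "drop")
  seqinr::write.fasta(as.list(segs$seq),
                      names = sprintf("segment%d|%s", segs$segment, segs$from),
                      file.out = path)
  invisible(path)
}

#' Write surface areas (clusters/patches) as TSV
#'
#' @param areas a tibble from [build_clusters()], [build_patches()] or
#'   [build_varying_patches()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_areas_tsv <- function(areas, path) {
  flat <- areas |>
    mutate(members = vapply(.data$members, paste, character(1),
                            collapse = ","))
  readr::write_tsv(flat, path)
  invisible(path)
}
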