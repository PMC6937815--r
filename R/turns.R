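# Hydrogen-bonded turn assignment (DSSP-style, backbone-only).
#
# Amide hydrogens are reconstructed from the preceding carbonyl geometry and
# backbone hydrogen bonds scored with the Kabsch-Sander electrostatic model.
# A CO(i)..HN(i+n) bond with n in 3..5 defines an n-turn; the residues
# between the bonded pair are flagged as turn residues.

#' Flag residues involved in hydrogen-bonded turns
#'
#' @param structure a `pep_structure`.
#' @param energy_cutoff hydrogen-bond energy threshold in kcal/mol
#'   (Kabsch-Sander electrostatic model; a bond requires E below this).
#' @return logical vector, one element per residue (in residue-table
#'   order); `TRUE` when the residue lies inside a 3-, 4- or 5-turn.
#'   Residues lacking backbone atoms are `FALSE`.
#' @export
assign_turns <- function(structure, energy_cutoff = -0.5) {
  res <- structure$residues
  at <- structure$atoms
  n <- nrow(res)
  get3 <- function(k, e) {
    m <- at[at$key == k & at$elety == e, c("x", "y", "z")]
    if (nrow(m) == 0) return(NULL)
    as.numeric(m[1, ])
  }
  Npos <- lapply(res$key, get3, "N")
  CApos <- lapply(res$key, get3, "CA")
  Cpos <- lapply(res$key, get3, "C")
  Opos <- lapply(res$key, get3, "O")
  # reconstructed amide H: 1.0 A from N, anti-parallel to the preceding C=O
  Hpos <- vector("list", n)
  for (j in 2:max(2, n)) {
    if (j > n) break
    if (res$chain[j] != res$chain[j - 1]) next
    if (res$aa[j] == "P") next # proline has no amide H
    if (is.null(Npos[[j]]) || is.null(Cpos[[j - 1]]) || is.null(Opos[[j - 1]])) next
    d <- Cpos[[j - 1]] - Opos[[j - 1]]
    Hpos[[j]] <- Npos[[j]] + d / vec_norm(d)
  }
  turn <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (is.null(Cpos[[i]]) || is.null(Opos[[i]])) next
    for (k in 3:5) {
      j <- i + k
      if (j > n) next
      if (res$chain[j] != res$chain[i]) next
      if (is.null(Hpos[[j]]) || is.null(Npos[[j]])) next
      rON <- euclid(Opos[[i]], Npos[[j]])
      rCH <- euclid(Cpos[[i]], Hpos[[j]])
      rOH <- euclid(Opos[[i]], Hpos[[j]])
      rCN <- euclid(Cpos[[i]], Npos[[j]])
      if (min(rON, rCH, rOH, rCN) < 0.5) next
      e <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      if (e < energy_cutoff) {
        turn[(i + 1):(j - 1)] <- TRUE
      }
    }
  }
  turn
}
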